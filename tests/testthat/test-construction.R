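test_that("mean-plus-SD threshold keeps only clearly strong correlations", {
  # hand-checkable 4x4: off-diagonal strengths {0.9, 0.1 x5}
  cm <- matrix(0.1, 4, 4); diag(cm) <- 1; cm[1, 2] <- cm[2, 1] <- 0.9
  vals <- c(0.9, 0.1, 0.1, 0.1, 0.1, 0.1)
  theta <- mean(vals) + sd(vals)
  adj <- threshold_adjacency(cm)
  expect_equal(attr(adj, "theta"), theta)
  expected <- matrix(0L, 4, 4); expected[1, 2] <- expected[2, 1] <- 1L
  expect_equal(unclass(adj), expected, ignore_attr = TRUE)

  # constant matrix: nothing strictly exceeds mean + 0
  cm2 <- matrix(0.5, 3, 3); diag(cm2) <- 1
  expect_warning(adj2 <- threshold_adjacency(cm2), "identical")
  expect_true(all(adj2 == 0))

  # a single off-diagonal value never exceeds itself
  cm3 <- matrix(c(1, 0.7, 0.7, 1), 2, 2)
  expect_true(all(threshold_adjacency(cm3) == 0))
})

test_that("threshold is equivariant under constant shifts", {
  withr::local_seed(21)
  for (rep in 1:10) {
    cm <- cor(matrix(rnorm(200), 20, 10))
    a <- threshold_adjacency(cm)
    b <- threshold_adjacency(cm + 0.05)   # mean + SD shifts along
    expect_equal(unclass(a), unclass(b), ignore_attr = TRUE)
  }
})

test_that("lasso memberships match an independent coordinate-descent solver", {
  withr::local_seed(31)
  for (rep in 1:40) {
    m <- sample(3:4, 1)
    n <- sample(c(25, 60), 1)
    x <- matrix(rnorm(n * m), n, m)
    # induce some structure half the time
    if (rep %% 2 == 0) x[, 2] <- 0.7 * x[, 1] + 0.5 * rnorm(n)
    lam <- sample(c(0.01, 0.05, 0.1, 0.3), 1)
    h <- lasso_hyperedges(x, lambda = lam)
    xs <- scale(x)
    for (i in seq_len(m)) {
      a <- oracle_lasso_cd(xs[, -i, drop = FALSE], xs[, i], lam)
      expected <- integer(m)
      expected[setdiff(seq_len(m), i)[a > 1e-9]] <- 1L
      mismatch <- which(h[, i] != expected)
      # memberships must agree except for coefficients at the zero boundary
      for (j in mismatch) {
        aj <- a[match(j, setdiff(seq_len(m), i))]
        expect_lt(abs(aj), 1e-6)
      }
      expect_lt(length(mismatch), 2)
    }
  }
})

test_that("single-predictor lasso equals the closed-form soft threshold", {
  withr::local_seed(7)
  for (lam in c(0.01, 0.1, 0.5, 2)) {
    n <- 50
    x1 <- rnorm(n)
    x2 <- 0.9 * x1 + 0.05 * rnorm(n)
    h <- lasso_hyperedges(cbind(x1, x2), lambda = lam)
    s1 <- as.numeric(scale(x1)); s2 <- as.numeric(scale(x2))
    v <- sum(s1^2) / n
    alpha <- soft_threshold(sum(s1 * s2) / n, lam) / v
    expect_equal(h[1, 2], as.integer(alpha > 1e-8))
    expect_equal(h[2, 1], as.integer(alpha > 1e-8))  # symmetric by construction here
  }
  # exact anti-correlation: negative coefficient is never a membership
  x1 <- rnorm(30)
  h <- lasso_hyperedges(cbind(x1, -x1), lambda = 0.01)
  expect_equal(sum(h), 0L)
})

test_that("overwhelming penalty empties the incidence matrix", {
  withr::local_seed(3)
  x <- matrix(rnorm(50 * 5), 50, 5)
  expect_true(all(lasso_hyperedges(x, lambda = 10) == 0))
  expect_error(lasso_hyperedges(x, lambda = -1), "positive")
})

test_that("spatial network has the contracted shapes and block structure", {
  parc <- toy_parcellation(2, 2, 1)   # 2 MRSNs x 2 GM + 1 WM
  withr::local_seed(13)
  x <- matrix(rnorm(30 * 5), 30, 5)
  net <- build_spatial_fcn(x, parc)
  expect_equal(dim(net$H), c(2, 2))
  expect_equal(dim(net$A1), c(4, 4))
  expect_equal(dim(net$A2), c(1, 4))
  expect_equal(diag(net$H), c(0L, 0L), ignore_attr = TRUE)

  # A1 block discipline on a bigger random instance
  parc2 <- toy_parcellation(3, c(3, 4, 2), 4)
  x2 <- matrix(rnorm(60 * n_roi(parc2)), 60)
  net2 <- build_spatial_fcn(x2, parc2)
  gm_mrsn <- parc2$mrsn[parc2$tissue == "GM"]
  cross <- outer(gm_mrsn, gm_mrsn, "!=")
  expect_true(all(net2$A1[cross] == 0))
  expect_equal(net2$A1, t(net2$A1))
  expect_true(all(diag(net2$A1) == 0))
})

test_that("default parcellation yields 14 hyperedges and 90/48 layer shapes", {
  parc <- default_parcellation()
  cfg <- sim_config(parcellation = parc, L = 300, W = 100, S = 100, seed = 5)
  ts <- simulate_subject(cfg, "shape-check")
  net <- build_spatial_fcn(ts$data[1:100, ], parc)
  expect_equal(dim(net$H), c(14, 14))
  expect_equal(dim(net$A1), c(90, 90))
  expect_equal(dim(net$A2), c(48, 90))
})

test_that("temporal construction is deterministic and layer count follows T", {
  parc <- toy_parcellation()
  cfg <- sim_config(parcellation = parc, L = 300, W = 100, S = 50, seed = 17)
  ts <- simulate_subject(cfg, "s1")
  net1 <- build_temporal_fcn(ts, parc, window = 100, stride = 50)
  net2 <- build_temporal_fcn(ts, parc, window = 100, stride = 50)
  expect_length(net1$layers, 5)
  expect_identical(lapply(net1$layers, `[[`, "H"),
                   lapply(net2$layers, `[[`, "H"))
  expect_error(build_temporal_fcn(ts, parc, window = 400, stride = 50),
               "exceeds")
})

test_that("network edge tables round-trip layer contents", {
  parc <- toy_parcellation(2, 2, 2)
  cfg <- sim_config(parcellation = parc, L = 120, W = 40, S = 40, seed = 2)
  ts <- simulate_subject(cfg, "s1")
  net <- build_temporal_fcn(ts, parc, window = 40, stride = 40)
  edges <- tidy(net)
  expect_named(edges, c("layer", "matrix", "row", "col"))
  l1h <- edges[edges$layer == 1 & edges$matrix == "H", ]
  expect_equal(nrow(l1h), sum(net$layers[[1]]$H))
  dir <- withr::local_tempdir()
  write_temporal_fcn(net, dir)
  expect_true(file.exists(file.path(dir, "network_edges.tsv")))
  expect_true(file.exists(file.path(dir, "network_manifest.json")))
})
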