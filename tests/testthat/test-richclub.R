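test_that("multilayer degrees match exhaustive neighbour counts", {
  withr::local_seed(41)
  for (rep in 1:30) {
    parc <- random_small_parcellation()
    layer <- random_layer(parc)
    deg <- multilayer_degrees(layer, parc)
    o <- oracle_degrees(layer, parc)
    expect_equal(deg$d1, o$d1)
    expect_equal(deg$d2, o$d2)
    expect_equal(deg$d3, o$d3)
  }
})

test_that("degree inheritance gives every member its MRSN's hyperedge count", {
  parc <- toy_parcellation(3, 2, 1)
  layer <- random_layer(parc, p_edge = 0)
  layer$H[2, c(1, 3)] <- 1L   # MRSN 2 belongs to two hyperedges
  deg <- multilayer_degrees(layer, parc)
  members <- parc$roi_index[parc$mrsn == "NET2"]
  expect_true(all(deg$d1[members] == 2))
  expect_true(all(deg$d1[-members] == 0))
  # empty network: all degrees zero
  empty <- random_layer(parc, p_edge = 0)
  expect_true(all(unlist(multilayer_degrees(empty, parc)[, -1]) == 0))
})

test_that("normalised degree saturates and ratios match raw recomputation", {
  parc <- default_parcellation()
  dmax <- max_degrees(parc)
  an <- parc$roi_index[parc$mrsn == "AN"][1]
  deg <- tibble::tibble(roi_index = parc$roi_index, d1 = 0L, d2 = 0L, d3 = 0L)
  deg$d1[an] <- 13L; deg$d2[an] <- 2L; deg$d3[an] <- 48L
  wm1 <- parc$roi_index[parc$tissue == "WM"][1]
  deg$d3[wm1] <- 45L
  nd <- normalized_degree(deg, dmax)
  expect_equal(nd$norm_degree[an], 1)
  expect_equal(nd$norm_degree[wm1], 0.5)
})

test_that("core selection takes the top n with deterministic tie-breaks", {
  expect_equal(which(select_core(rep(1, 20), 5) == 1), 1:5)
  nd <- c(5, 1, 4, 2, 3) / 10
  expect_equal(which(select_core(nd, 2) == 1), c(1, 3))
  expect_equal(sum(select_core(runif(30), 15)), 15)
  expect_error(select_core(runif(5), 6), "exceeds")
})

test_that("temporal centrality and stability follow their definitions", {
  r <- rbind(c(1, 0, 1, 0),
             c(1, 1, 1, 1),
             c(1, 1, 0, 1),
             c(0, 0, 0, 0))
  expect_equal(temporal_centrality(r), c(0.5, 1, 0.75, 0))
  expect_equal(temporal_stability(r, "literal"), c(1, 0, 2 / 3, 0))
  expect_equal(temporal_stability(r, "prose"), c(0, 1, 1 / 3, 1))
  expect_error(temporal_stability(r[, 1, drop = FALSE]), "two layers")
})

test_that("shared-core matrix agrees with brute-force enumeration", {
  withr::local_seed(51)
  for (rep in 1:15) {
    parc <- random_small_parcellation()
    t_n <- sample(2:4, 1)
    net <- random_temporal_net(parc, t_n)
    n_core <- sample(1:min(4, n_roi(parc)), 1)
    r <- core_assignment(net, n_core)
    o <- oracle_metrics(lapply(net$layers, identity), parc, n_core)
    p <- shared_core_matrix(net, r)
    expect_equal(p, o$P, tolerance = 1e-12)
    expect_equal(p, t(p))
    expect_true(all(diag(p) == 0))
  }
})

test_that("LF/JF aggregate the shared-core matrix over the right partitions", {
  parc <- toy_parcellation(2, c(3, 2), 1)
  n <- n_roi(parc)
  withr::local_seed(8)
  p <- matrix(runif(n * n), n); p <- (p + t(p)) / 2; diag(p) <- 0
  lf <- local_functionality(p, parc)
  jf <- joint_functionality(p, parc)
  for (i in seq_len(n)) {
    same <- which(parc$mrsn == parc$mrsn[i])
    expect_equal(lf[i], sum(p[i, setdiff(same, i)]) / length(same))
    expect_equal(jf[i], sum(p[i, -same]) / (n - length(same)))
  }
  # constant-P algebra: LF = p (n_S - 1) / n_S, JF = p
  p2 <- matrix(0.4, n, n); diag(p2) <- 0
  lf2 <- local_functionality(p2, parc)
  expect_equal(lf2[1], 0.4 * 2 / 3)
  expect_equal(joint_functionality(p2, parc)[1], 0.4)
  # single-network parcellation: JF undefined
  parc1 <- toy_parcellation(1, 3, 0)
  expect_error(joint_functionality(matrix(0, 3, 3), parc1), "undefined")
})

test_that("full metric pipeline matches the brute-force oracle on random nets", {
  withr::local_seed(61)
  for (rep in 1:20) {
    parc <- random_small_parcellation()
    net <- random_temporal_net(parc, sample(2:4, 1))
    n_core <- sample(1:min(4, n_roi(parc)), 1)
    m <- richclub_metrics(net, n_core = n_core)
    o <- oracle_metrics(net$layers, parc, n_core)
    expect_equal(m$tc, o$tc)
    expect_equal(m$ts_literal, o$ts_literal)
    expect_equal(m$lf, o$lf, tolerance = 1e-12)
    expect_equal(m$jf, o$jf, tolerance = 1e-12)
    expect_equal(unclass(attr(m, "core")), o$R, ignore_attr = TRUE)
  }
})

test_that("metric invariants hold on random networks", {
  withr::local_seed(71)
  for (rep in 1:25) {
    parc <- random_small_parcellation()
    net <- random_temporal_net(parc, sample(2:4, 1))
    n_core <- sample(1:min(4, n_roi(parc)), 1)
    m <- richclub_metrics(net, n_core = n_core)
    vals <- unlist(m[, c("tc", "ts_prose", "ts_literal", "lf", "jf")])
    expect_true(all(vals >= 0 & vals <= 1))
    expect_equal(sum(m$tc), n_core)
    expect_equal(m$ts_prose + m$ts_literal, rep(1, n_roi(parc)))
  }
})

test_that("adding a core-peripheral edge never decreases shared-core values", {
  withr::local_seed(81)
  for (rep in 1:10) {
    parc <- toy_parcellation(2, 2, 2)
    net <- random_temporal_net(parc, 3)
    n_core <- 2
    r <- core_assignment(net, n_core)
    p0 <- shared_core_matrix(net, r)
    # add one absent WM-GM edge in one layer, keeping the same assignment
    l <- sample(3, 1)
    zeros <- which(net$layers[[l]]$A2 == 0, arr.ind = TRUE)
    if (nrow(zeros) == 0) next
    pick <- zeros[sample(nrow(zeros), 1), ]
    net$layers[[l]]$A2[pick[1], pick[2]] <- 1L
    p1 <- shared_core_matrix(net, r)
    expect_true(all(p1 - p0 >= -1e-12))
  }
})

test_that("aggregation means are exact at each scale", {
  parc <- toy_parcellation(2, 2, 2)
  net <- local({ withr::local_seed(4); random_temporal_net(parc, 3) })
  m <- richclub_metrics(net, n_core = 2)
  ag <- aggregate_metrics(m, "mrsn")
  for (u in unique(parc$mrsn)) {
    expect_equal(ag$tc[ag$unit == u], mean(m$tc[parc$mrsn == u]))
  }
  wb <- aggregate_metrics(m, "whole_brain")
  expect_equal(wb$lf, mean(m$lf))
  # whole-brain TC is structurally n_core / N
  expect_equal(wb$tc, 2 / n_roi(parc))
})
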