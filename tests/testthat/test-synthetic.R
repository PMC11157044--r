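test_that("generator is deterministic under a fixed seed", {
  cfg <- sim_config(L = 200, W = 50, S = 50, seed = 5)
  a <- simulate_subject(cfg, "x1")
  b <- simulate_subject(cfg, "x1")
  expect_identical(a$data, b$data)
  c_ <- simulate_subject(cfg, "x2")
  expect_false(identical(a$data, c_$data))
})

test_that("empirical correlations track the generative design", {
  tp <- toy_parcellation()
  # independence: no within-block or cross coupling
  cfg0 <- sim_config(parcellation = tp, L = 600, W = 200, S = 200,
                     within_block_corr = 0, cross_block_corr = 0,
                     baseline_cross = 0, wm_gm_corr = 0,
                     wm_baseline_corr = 0, seed = 9)
  x0 <- simulate_subject(cfg0, "indep")$data
  c0 <- cor(x0)
  expect_lt(max(abs(c0[upper.tri(c0)])), 0.2)

  # within-block correlation near its nominal value at L = 1200
  cfg1 <- sim_config(parcellation = tp, seed = 10)
  x1 <- simulate_subject(cfg1, "s")$data
  blocks <- split(tp$roi_index[tp$tissue == "GM"], tp$mrsn[tp$tissue == "GM"])
  rs <- unlist(lapply(blocks, function(b) {
    cb <- cor(x1[, b]); cb[upper.tri(cb)]
  }))
  expect_gt(mean(rs), 0.7)
  expect_lt(mean(rs), 0.9)
})

test_that("retest reliability one gives bit-identical sessions", {
  cfg <- sim_config(L = 150, W = 50, S = 50, n_sessions = 2,
                    retest_reliability = 1, seed = 2)
  s1 <- simulate_subject(cfg, "a", session = 1)
  s2 <- simulate_subject(cfg, "a", session = 2)
  expect_identical(s1$data, s2$data)
  cfg2 <- sim_config(L = 150, W = 50, S = 50, n_sessions = 2,
                     retest_reliability = 0.5, seed = 2)
  expect_false(identical(simulate_subject(cfg2, "a", 1)$data,
                         simulate_subject(cfg2, "a", 2)$data))
})

test_that("cohort manifest records design and planted truth", {
  cfg <- sim_config(L = 120, W = 40, S = 40, n_subjects = 3, n_sessions = 2,
                    seed = 4)
  co <- simulate_cohort(cfg)
  expect_length(co$timeseries, 12)
  expect_equal(nrow(co$manifest), 12)
  expect_setequal(unique(co$manifest$group), c("A", "B"))
  expect_equal(co$truth$hub_gm_rois, 1:4)
  expect_equal(co$truth$hub_mrsn, 1)
})

test_that("planted hubs dominate the core sets at default conditions", {
  tp <- toy_parcellation()
  fr <- sapply(1:8, function(s) {
    cfg <- sim_config(parcellation = tp, seed = s)
    ts <- simulate_subject(cfg, paste0("hub", s))
    net <- build_temporal_fcn(ts, tp, window = cfg$W, stride = cfg$S)
    r <- core_assignment(net, 5)
    mean(unclass(r)[c(1:4, 21), ] == 1)
  })
  expect_gt(mean(fr), 0.9)
  # and the hub ROIs take the top temporal-centrality ranks
  cfg <- sim_config(parcellation = tp, seed = 33)
  ts <- simulate_subject(cfg, "ranks")
  net <- build_temporal_fcn(ts, tp, window = cfg$W, stride = cfg$S)
  m <- richclub_metrics(net, n_core = 5)
  top5 <- m$roi_index[order(-m$tc, m$roi_index)][1:5]
  expect_setequal(top5, c(1:4, 21))
})

test_that("regime switches depress temporal stability of rotating hubs", {
  tp <- toy_parcellation()
  delta <- sapply(1:6, function(s) {
    cfg_sw <- sim_config(parcellation = tp, L = 1200, W = 200, S = 200,
                         regime_switch_windows = 4, seed = s)
    cfg_st <- sim_config(parcellation = tp, L = 1200, W = 200, S = 200,
                         seed = s)
    ts_mode <- function(cfg) {
      ts <- simulate_subject(cfg, paste0("sw", s))
      net <- build_temporal_fcn(ts, tp, window = 200, stride = 200)
      m <- richclub_metrics(net, n_core = 5)
      mean(m$ts_prose[1:4])   # initial hub MRSN members
    }
    ts_mode(cfg_st) - ts_mode(cfg_sw)
  })
  # seed-averaged, directional: stability drops when the hub role rotates
  expect_gt(mean(delta), 0)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(within_block_corr = 1), "within_block_corr")
  expect_error(sim_config(retest_reliability = 1.2), "retest_reliability")
  expect_error(sim_config(hub_mrsn = "nope"), "hub_mrsn")
  expect_error(sim_config(hub_wm_rois = 1), "WM ROIs")
  expect_error(sim_config(L = 100, W = 200), "exceeds")
})
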