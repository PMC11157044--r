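#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' block-correlated multivariate time series driven by one latent factor per
#' MRSN, a shared global factor on which designated hub MRSNs load heavily
#' (making them the best lasso predictors of every other network and hence
#' frequent hyperedge members), WM series coupled to GM factors, optional
#' regime switches that rotate the hub role at stated windows, a group
#' effect expressed as a reduction of the hub loading, and paired
#' test-retest sessions obtained by mixing the underlying standard-normal
#' draws of session 1 with fresh draws.
#'
#' The factor construction guarantees a positive semidefinite implied
#' covariance for any valid loadings.  Marginal ROI variance is 1 before
#' `noise_sd` scaling; the correlation between two ROIs of one block equals
#' `within_block_corr`.
#'
#' @param parcellation A [parcellation()]; default [toy_parcellation()]
#'   (5 MRSNs x 4 GM ROIs + 6 WM ROIs).
#' @param L,W,S Series length and sliding-window parameters (defaults 1200,
#'   200, 100: eleven windows, the standard long-acquisition configuration).
#' @param n_subjects Subjects per group.
#' @param n_sessions 1 or 2.
#' @param within_block_corr Correlation between ROIs of one MRSN (default
#'   0.8).
#' @param cross_block_corr Loading of hub MRSN factors on the global factor
#'   (default 0.95).
#' @param baseline_cross Loading of non-hub MRSN factors on the global
#'   factor (default 0.35).
#' @param wm_gm_corr Coupling of designated hub WM ROIs to the current hub
#'   MRSN factor (default 0.95).
#' @param wm_baseline_corr Coupling of the remaining WM ROIs to their
#'   (cyclically) assigned MRSN factor (default 0.15).
#' @param hub_mrsn Name or index of the planted hub MRSN (default the
#'   first).
#' @param hub_wm_rois ROI indices of planted hub WM ROIs (default the first
#'   WM ROI).
#' @param regime_switch_windows Integer window indices at whose start the
#'   hub role rotates to the next MRSN (default none).
#' @param group_effect_size Reduction of the hub loading in group B
#'   (default 0.4).
#' @param retest_reliability In `[0, 1]`: weight of session-1 underlying
#'   draws in session 2; 1 makes the sessions bit-identical (default 0.8).
#' @param noise_sd Overall scale of the series (default 1).
#' @param seed Integer master seed; fully determines every output.
#' @return A list of class `mlfcn_sim_config`.
#' @export
sim_config <- function(parcellation = toy_parcellation(),
                       L = 1200, W = 200, S = 100,
                       n_subjects = 8, n_sessions = 1,
                       within_block_corr = 0.8,
                       cross_block_corr = 0.95,
                       baseline_cross = 0.35,
                       wm_gm_corr = 0.95,
                       wm_baseline_corr = 0.15,
                       hub_mrsn = 1,
                       hub_wm_rois = NULL,
                       regime_switch_windows = integer(),
                       group_effect_size = 0.4,
                       retest_reliability = 0.8,
                       noise_sd = 1,
                       seed = 1L) {
  parc <- parcellation
  levs <- attr(parc, "mrsn_levels")
  if (is.character(hub_mrsn)) hub_mrsn <- match(hub_mrsn, levs)
  if (is.na(hub_mrsn) || hub_mrsn < 1 || hub_mrsn > length(levs)) {
    abort("hub_mrsn must name one of the parcellation's MRSNs")
  }
  wm_idx <- parc$roi_index[parc$tissue == "WM"]
  if (is.null(hub_wm_rois)) hub_wm_rois <- head(wm_idx, 1)
  if (!all(hub_wm_rois %in% wm_idx)) abort("hub_wm_rois must be WM ROIs")
  for (nm in c("within_block_corr", "baseline_cross", "wm_baseline_corr")) {
    v <- get(nm)
    if (v < 0 || v >= 1) abort(paste0(nm, " must be in [0, 1)"))
  }
  if (cross_block_corr < 0 || cross_block_corr > 1) {
    abort("cross_block_corr must be in [0, 1]")
  }
  if (wm_gm_corr < 0 || wm_gm_corr > 1) abort("wm_gm_corr must be in [0, 1]")
  if (cross_block_corr - group_effect_size < -1) {
    abort("group_effect_size drives the hub loading below -1")
  }
  if (retest_reliability < 0 || retest_reliability > 1) {
    abort("retest_reliability must be in [0, 1]")
  }
  n_windows(L, W, S)  # validates W <= L
  cfg <- list(parcellation = parc, L = as.integer(L), W = as.integer(W),
              S = as.integer(S), n_subjects = as.integer(n_subjects),
              n_sessions = as.integer(n_sessions),
              within_block_corr = within_block_corr,
              cross_block_corr = cross_block_corr,
              baseline_cross = baseline_cross,
              wm_gm_corr = wm_gm_corr, wm_baseline_corr = wm_baseline_corr,
              hub_mrsn = as.integer(hub_mrsn),
              hub_wm_rois = as.integer(hub_wm_rois),
              regime_switch_windows = as.integer(regime_switch_windows),
              group_effect_size = group_effect_size,
              retest_reliability = retest_reliability,
              noise_sd = noise_sd, seed = as.integer(seed))
  class(cfg) <- "mlfcn_sim_config"
  cfg
}

#' @export
print.mlfcn_sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<mlfcn_sim_config: %d ROIs, L=%d W=%d S=%d, %d subj/group, ",
    "hub MRSN %d, seed %d>\n"),
    n_roi(x$parcellation), x$L, x$W, x$S, x$n_subjects, x$hub_mrsn, x$seed))
  invisible(x)
}

# Regime index (0-based) of each time point: increments at the start of each
# listed switch window.
regime_of_timepoints <- function(cfg) {
  reg <- integer(cfg$L)
  if (length(cfg$regime_switch_windows) > 0) {
    starts <- (sort(cfg$regime_switch_windows) - 1L) * cfg$S + 1L
    for (s in starts) reg[seq(s, cfg$L)] <- reg[seq(s, cfg$L)] + 1L
  }
  reg
}

# All underlying standard-normal draws for one subject-session, with the
# session-2 draws a reliability-weighted mixture of the session-1 draws and
# fresh ones (so retest_reliability = 1 reproduces session 1 exactly).
subject_draws <- function(cfg, subject_seed, session) {
  parc <- cfg$parcellation
  m <- length(attr(parc, "mrsn_levels"))
  n_cols <- 1L + m + n_roi(parc)   # global factor, MRSN factors, ROI noise
  z1 <- local_seed(subject_seed,
                   matrix(rnorm(cfg$L * n_cols), cfg$L, n_cols))
  if (session == 1) return(z1)
  r <- cfg$retest_reliability
  if (r == 1) return(z1)
  z2 <- local_seed(subject_seed + 499979L,
                   matrix(rnorm(cfg$L * n_cols), cfg$L, n_cols))
  r * z1 + sqrt(1 - r^2) * z2
}

#' Simulate one subject's ROI time series
#'
#' Draws a single subject-session under a [sim_config()].  Group `"B"`
#' subjects have their hub loading reduced by `group_effect_size`.  The
#' subject seed (derived from the config seed and `subject_key` unless given
#' explicitly) fully determines the output; the same seed yields
#' bit-identical matrices.
#'
#' @param cfg A `mlfcn_sim_config`.
#' @param subject_id Identifier string.
#' @param session 1 or 2.
#' @param group `"A"` or `"B"`.
#' @param subject_key Integer distinguishing subjects (default derived by
#'   hashing `subject_id` characters).
#' @return A `mlfcn_timeseries`.
#' @export
simulate_subject <- function(cfg, subject_id, session = 1, group = "A",
                             subject_key = NULL) {
  parc <- cfg$parcellation
  levs <- attr(parc, "mrsn_levels")
  m <- length(levs)
  if (is.null(subject_key)) {
    subject_key <- sum(utf8ToInt(as.character(subject_id)) *
                         seq_along(utf8ToInt(as.character(subject_id)))) %% 100000L
  }
  subject_seed <- (cfg$seed * 131L + subject_key * 7L) %% .Machine$integer.max
  z <- subject_draws(cfg, subject_seed, session)
  zg <- z[, 1]
  zf <- z[, 1 + seq_len(m), drop = FALSE]
  ze <- z[, (1 + m) + seq_len(n_roi(parc)), drop = FALSE]

  hub_load <- cfg$cross_block_corr -
    if (identical(group, "B")) cfg$group_effect_size else 0
  reg <- regime_of_timepoints(cfg)
  hub_of_regime <- ((cfg$hub_mrsn - 1L + unique(sort(reg))) %% m) + 1L
  hub_at_t <- hub_of_regime[match(reg, unique(sort(reg)))]

  # latent factor per MRSN: unit variance, loading c(t) on the global factor
  f <- matrix(0, cfg$L, m)
  for (k in seq_len(m)) {
    c_t <- ifelse(hub_at_t == k, hub_load, cfg$baseline_cross)
    f[, k] <- sqrt(pmax(1 - c_t^2, 0)) * zf[, k] + c_t * zg
  }

  x <- matrix(0, cfg$L, n_roi(parc))
  w <- cfg$within_block_corr
  gm <- which(parc$tissue == "GM")
  for (j in gm) {
    k <- match(parc$mrsn[j], levs)
    x[, j] <- sqrt(w) * f[, k] + sqrt(1 - w) * ze[, j]
  }
  wm <- which(parc$tissue == "WM")
  for (i in seq_along(wm)) {
    j <- wm[i]
    if (j %in% cfg$hub_wm_rois) {
      rho <- cfg$wm_gm_corr
      target <- f[cbind(seq_len(cfg$L), hub_at_t)]
    } else {
      rho <- cfg$wm_baseline_corr
      target <- f[, ((i - 1L) %% m) + 1L]
    }
    x[, j] <- rho * target + sqrt(1 - rho^2) * ze[, j]
  }
  roi_timeseries(x * cfg$noise_sd, parc, subject_id = subject_id,
                 session_id = as.character(session))
}

#' Simulate a full cohort with manifest
#'
#' Generates two groups of `n_subjects` subjects, each with `n_sessions`
#' sessions, and a samples manifest recording the design plus the planted
#' ground truth (hub MRSN/ROIs, switch windows, effect size) needed by
#' recovery tests.
#'
#' @param cfg A `mlfcn_sim_config`.
#' @return A list with elements `timeseries` (named list of
#'   `mlfcn_timeseries`), `manifest` (tibble: `subject_id`, `group`,
#'   `session_id`, `subject_key`), and `truth` (list of planted structure).
#' @export
simulate_cohort <- function(cfg) {
  parc <- cfg$parcellation
  design <- tidyr::expand_grid(
    group = c("A", "B"),
    subject = seq_len(cfg$n_subjects),
    session = seq_len(cfg$n_sessions))
  design$subject_id <- sprintf("%s%02d", design$group, design$subject)
  design$subject_key <- match(design$subject_id, unique(design$subject_id))
  ts <- purrr::pmap(design, function(group, subject, session, subject_id,
                                     subject_key) {
    simulate_subject(cfg, subject_id, session = session, group = group,
                     subject_key = subject_key)
  })
  names(ts) <- sprintf("%s_ses%d", design$subject_id, design$session)
  hub_gm <- parc$roi_index[parc$mrsn ==
                             attr(parc, "mrsn_levels")[cfg$hub_mrsn]]
  list(
    timeseries = ts,
    manifest = tibble(subject_id = design$subject_id, group = design$group,
                      session_id = as.character(design$session),
                      subject_key = design$subject_key),
    truth = list(hub_mrsn = cfg$hub_mrsn, hub_gm_rois = hub_gm,
                 hub_wm_rois = cfg$hub_wm_rois,
                 regime_switch_windows = cfg$regime_switch_windows,
                 group_effect_size = cfg$group_effect_size,
                 seed = cfg$seed))
}
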