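#' Run the full analysis pipeline
#'
#' Orchestrates construct -> metrics -> group analyses end to end from a
#' single configuration (an R list or a YAML file) and writes every stage
#' output plus a reproducible run manifest.  Stages: load or simulate the
#' cohort; per subject-session, build the temporal multilayer network and
#' its rich-club metrics; aggregate to MRSN and whole-brain scale; then run
#' the requested analyses (`"icc"` needs two sessions, `"groupdiff"` two
#' groups).  Deterministic given the config (simulation is seeded), so
#' re-running from the same manifest reproduces the outputs.
#'
#' Configuration fields: `parcellation` (path, `"default"`, or `"toy"`),
#' `timeseries` (directory of per-subject TSVs with a `manifest.tsv`, or
#' `NULL` to simulate), `simulate` (list of [sim_config()] overrides),
#' `window`, `stride`, `lambda`, `n_core`, `ts_mode`, `connectivity`,
#' `analyses` (character subset of `"icc"`, `"groupdiff"`), `out_dir`,
#' `seed`.
#'
#' @param config A named list or path to a YAML file.
#' @return Invisibly, a list with `metrics` (per-subject node-level tibble),
#'   `mrsn_metrics`, `whole_brain_metrics`, `icc`, `groupdiff`, and
#'   `manifest` (the serialised run manifest), all also written under
#'   `out_dir` when one is given.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(parcellation = "toy", timeseries = NULL, simulate = list(),
                   window = NULL, stride = NULL, lambda = 0.1,
                   n_core = NULL, ts_mode = "prose",
                   connectivity = "union_clique",
                   analyses = character(), out_dir = NULL, seed = 1L)
  cfg <- modifyList(defaults, config)

  parc <- if (identical(cfg$parcellation, "toy")) {
    toy_parcellation()
  } else if (identical(cfg$parcellation, "default")) {
    default_parcellation()
  } else {
    read_parcellation(cfg$parcellation)
  }
  if (is.null(cfg$n_core)) {
    cfg$n_core <- if (n_roi(parc) >= 138) 15L else
      length(attr(parc, "mrsn_levels")) + (n_wm(parc) > 0)
  }

  if (is.null(cfg$timeseries)) {
    sim_args <- modifyList(list(parcellation = parc, seed = cfg$seed),
                           cfg$simulate)
    sim <- do.call(sim_config, sim_args)
    if (is.null(cfg$window)) cfg$window <- sim$W
    if (is.null(cfg$stride)) cfg$stride <- sim$S
    cohort <- simulate_cohort(sim)
    ts_list <- cohort$timeseries
    manifest_tbl <- cohort$manifest
    truth <- cohort$truth
  } else {
    manifest_path <- file.path(cfg$timeseries, "manifest.tsv")
    if (!file.exists(manifest_path)) {
      abort(paste0("cohort manifest not found: ", manifest_path))
    }
    manifest_tbl <- readr::read_tsv(manifest_path, col_types = readr::cols(
      .default = readr::col_character()))
    ts_list <- purrr::pmap(manifest_tbl[, c("subject_id", "session_id", "file")],
      function(subject_id, session_id, file) {
        read_timeseries(file.path(cfg$timeseries, file), parc,
                        subject_id = subject_id, session_id = session_id)
      })
    names(ts_list) <- sprintf("%s_ses%s", manifest_tbl$subject_id,
                              manifest_tbl$session_id)
    truth <- NULL
  }
  if (is.null(cfg$window) || is.null(cfg$stride)) {
    abort("window and stride must be specified when reading time series")
  }

  per_subject <- purrr::imap(ts_list, function(tsx, key) {
    net <- build_temporal_fcn(tsx, parc, window = cfg$window,
                              stride = cfg$stride, lambda = cfg$lambda)
    m <- richclub_metrics(net, n_core = cfg$n_core,
                          connectivity = cfg$connectivity,
                          ts_mode = cfg$ts_mode)
    mutate(as_tibble(m), subject_id = !!tsx$subject_id,
           session_id = !!tsx$session_id, .before = 1)
  })
  metrics <- bind_rows(per_subject)

  metric_cols <- c("tc", "ts", "ts_prose", "ts_literal", "lf", "jf")
  mrsn_metrics <- metrics |>
    group_by(.data$subject_id, .data$session_id, unit = .data$mrsn) |>
    summarise(tissue = ifelse(.data$unit[1] == "WM", "WM", "GM"),
              across(all_of(metric_cols), mean), .groups = "drop")
  wb_metrics <- metrics |>
    group_by(.data$subject_id, .data$session_id) |>
    summarise(across(all_of(metric_cols), mean), .groups = "drop")

  long_mrsn <- mrsn_metrics |>
    tidyr::pivot_longer(all_of(metric_cols), names_to = "metric",
                        values_to = "value")

  icc_res <- NULL
  if ("icc" %in% cfg$analyses) {
    icc_res <- icc_analysis(long_mrsn)
  }
  gd_res <- NULL
  if ("groupdiff" %in% cfg$analyses) {
    grp <- manifest_tbl[, c("subject_id", "group")] |> dplyr::distinct()
    first_session <- min(metrics$session_id)
    gd_res <- long_mrsn |>
      filter(.data$session_id == first_session) |>
      left_join(grp, by = "subject_id") |>
      group_diff()
  }

  run_manifest <- list(
    package_version = as.character(packageVersion("mlfcn")),
    config = cfg[setdiff(names(cfg), "simulate")],
    n_roi = n_roi(parc),
    n_layers = n_windows(if (is.null(cfg$timeseries))
      sim$L else nrow(ts_list[[1]]$data), cfg$window, cfg$stride),
    n_subject_sessions = length(ts_list),
    truth = truth)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(metrics, file.path(cfg$out_dir, "metrics_roi.tsv"))
    readr::write_tsv(mrsn_metrics, file.path(cfg$out_dir, "metrics_mrsn.tsv"))
    readr::write_tsv(wb_metrics, file.path(cfg$out_dir, "metrics_whole_brain.tsv"))
    readr::write_tsv(manifest_tbl, file.path(cfg$out_dir, "samples.tsv"))
    if (!is.null(icc_res)) {
      readr::write_tsv(icc_res, file.path(cfg$out_dir, "icc.tsv"))
    }
    if (!is.null(gd_res)) {
      readr::write_tsv(gd_res, file.path(cfg$out_dir, "groupdiff.tsv"))
    }
    jsonlite::write_json(run_manifest,
                         file.path(cfg$out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  invisible(list(metrics = metrics, mrsn_metrics = mrsn_metrics,
                 whole_brain_metrics = wb_metrics, icc = icc_res,
                 groupdiff = gd_res, manifest = run_manifest))
}

#' Write a simulated cohort to disk in pipeline-readable layout
#'
#' One headerless TSV per subject-session plus a `manifest.tsv` with
#' `subject_id`, `session_id`, `group` and `file` columns — the layout
#' `run_pipeline()` expects under its `timeseries` field.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- purrr::imap_chr(cohort$timeseries, function(ts, key) {
    f <- paste0(key, ".tsv")
    write_timeseries(ts, file.path(dir, f))
    f
  })
  manifest <- cohort$manifest
  manifest$file <- unname(files)
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(dir)
}
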