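#' Intraclass correlation coefficient (one-way random effects)
#'
#' Test-retest reliability of a per-subject measure across two sessions,
#' via the one-way random-effects analysis-of-variance decomposition:
#' with `MSB` the between-subject and `MSW` the within-subject mean square
#' and `n` repeated measurements per subject (2 here),
#' `ICC = (MSB - MSW) / (MSB + (n - 1) MSW)` — the classic ICC(1,1).
#' Values can be negative (down to `-1/(n-1)`); identical sessions with any
#' between-subject spread give exactly 1.  If every value is identical the
#' coefficient is undefined (0/0) and `NA` is returned with a warning.
#'
#' @param session1,session2 Numeric vectors, one value per subject, equal
#'   length of at least 2.
#' @return A single number in `[-1, 1]`, or `NA` when undefined.
#' @examples
#' icc(c(1, 2, 3, 4), c(1, 2, 3, 4))   # 1
#' icc(c(1, 2), c(2, 1))               # -1
#' @export
icc <- function(session1, session2) {
  if (length(session1) != length(session2)) {
    abort("session vectors must have equal length")
  }
  k <- length(session1)
  if (k < 2) abort("ICC needs at least 2 subjects")
  x <- cbind(session1, session2)
  n <- ncol(x)
  subj_means <- rowMeans(x)
  msb <- n * var(subj_means)
  msw <- sum((x - subj_means)^2) / (k * (n - 1))
  denom <- msb + (n - 1) * msw
  if (denom == 0) {
    warn("ICC undefined: no variance between or within subjects")
    return(NA_real_)
  }
  (msb - msw) / denom
}

#' Classify an ICC value against tissue-specific reliability benchmarks
#'
#' GM regions are considered to reflect individual differences when
#' ICC > 0.6, WM regions when ICC > 0.5 (WM BOLD signals are weaker, so the
#' bar is lower); any region with ICC > 0.8 significantly reflects
#' individual differences.  All comparisons are strict.
#'
#' @param icc Numeric vector of ICC values (NA allowed).
#' @param tissue Character vector, `"GM"` or `"WM"`, recycled.
#' @return Character vector with levels `"none"`, `"individual_difference"`,
#'   `"significant_individual_difference"` (NA in, NA out).
#' @export
classify_icc <- function(icc, tissue) {
  tissue <- rep_len(tissue, length(icc))
  if (!all(tissue %in% c("GM", "WM"))) abort("tissue must be 'GM' or 'WM'")
  lower <- ifelse(tissue == "GM", 0.6, 0.5)
  dplyr::case_when(
    is.na(icc) ~ NA_character_,
    icc > 0.8 ~ "significant_individual_difference",
    icc > lower ~ "individual_difference",
    TRUE ~ "none"
  )
}

#' Test-retest ICC analysis over a metrics table
#'
#' Computes the ICC for every unit x metric combination of a long-format
#' metrics table with paired sessions, and classifies each against the
#' tissue-specific benchmarks.
#'
#' @param df Long tibble with columns `subject_id`, `session_id` (exactly
#'   two distinct values), `unit`, `metric`, `value`, and optionally
#'   `tissue` (defaults to `"GM"`; MRSN-scale rows for the WM unit should
#'   carry `"WM"`).
#' @return A tibble with columns `unit`, `metric`, `tissue`, `n_subjects`,
#'   `icc`, `classification`.
#' @export
icc_analysis <- function(df) {
  df <- as_tibble(df)
  sessions <- sort(unique(df$session_id))
  if (length(sessions) != 2) {
    abort("icc_analysis needs exactly two sessions")
  }
  if (!"tissue" %in% names(df)) df$tissue <- "GM"
  wide <- df |>
    tidyr::pivot_wider(id_cols = c("unit", "metric", "tissue", "subject_id"),
                       names_from = "session_id", values_from = "value")
  wide |>
    group_by(.data$unit, .data$metric, .data$tissue) |>
    summarise(
      n_subjects = dplyr::n(),
      icc = icc(.data[[sessions[1]]], .data[[sessions[2]]]),
      .groups = "drop") |>
    mutate(classification = classify_icc(.data$icc, .data$tissue))
}

#' Independent-samples t-test (pooled variance)
#'
#' Student's two-sample t-test with pooled variance, so the degrees of
#' freedom are exactly `n1 + n2 - 2` (158 for 80 vs 80, 171 for 87 vs 86).
#' A zero pooled variance (both groups constant) yields an NA flag with a
#' warning rather than an error.
#'
#' @param a,b Numeric vectors of per-subject values for the two groups
#'   (each of length >= 2).
#' @return A one-row tibble: `mean_a`, `mean_b`, `t`, `df`, `p`.
#' @export
group_ttest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) abort("each group needs >= 2 subjects")
  df_ <- length(a) + length(b) - 2L
  res <- tryCatch(
    t.test(a, b, var.equal = TRUE),
    error = function(e) {
      warn("t-test undefined (zero pooled variance); returning NA")
      NULL
    })
  if (is.null(res)) {
    return(tibble(mean_a = mean(a), mean_b = mean(b),
                  t = NA_real_, df = df_, p = NA_real_))
  }
  tibble(mean_a = mean(a), mean_b = mean(b),
         t = unname(res$statistic), df = as.integer(unname(res$parameter)),
         p = unname(res$p.value))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`; applied
#' within each metric family by [group_diff()].
#'
#' @param p Numeric vector of p-values.
#' @return Vector of q-values, monotone non-decreasing in `p`.
#' @export
fdr <- function(p) p.adjust(p, method = "BH")

#' Group-difference analysis over a metrics table
#'
#' Runs an independent-samples t-test per unit for every metric, then
#' FDR-adjusts the p-values within each metric family (all units tested for
#' one metric form one family).
#'
#' @param df Long tibble with columns `subject_id`, `group` (exactly two
#'   levels), `unit`, `metric`, `value`.
#' @param alpha Significance level on the adjusted q-values (default 0.05).
#' @return A tibble with columns `metric`, `unit`, `mean_a`, `mean_b`, `t`,
#'   `df`, `p`, `q`, `significant`; group "a" is the first level in sort
#'   order.
#' @export
group_diff <- function(df, alpha = 0.05) {
  df <- as_tibble(df)
  groups <- sort(unique(df$group))
  if (length(groups) != 2) abort("group_diff needs exactly two groups")
  res <- df |>
    group_by(.data$metric, .data$unit) |>
    summarise(group_ttest(.data$value[.data$group == groups[1]],
                          .data$value[.data$group == groups[2]]),
              .groups = "drop")
  res |>
    group_by(.data$metric) |>
    mutate(q = fdr(.data$p)) |>
    ungroup() |>
    mutate(significant = !is.na(.data$q) & .data$q < alpha)
}
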