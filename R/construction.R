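#' Adaptive mean-plus-SD threshold binarisation
#'
#' Binarises a correlation matrix with the adaptive rule used for the simple
#' graph layers: the threshold is the mean plus one standard deviation of the
#' functional-connectivity strengths in the matrix, and an edge is kept only
#' when its correlation strictly exceeds that threshold.  For a symmetric
#' matrix the strengths are the upper-triangle off-diagonal values; for a
#' bipartite (rectangular) matrix, all entries.  FC strength is the signed
#' Pearson r by default; set `abs_corr = TRUE` to threshold on magnitudes.
#'
#' If the strengths have zero spread nothing can strictly exceed
#' mean + SD, so the output is all zeros (with a warning in the degenerate
#' constant case).
#'
#' @param corr Numeric correlation matrix (square symmetric, or rectangular
#'   for the bipartite WM-GM layer).  NA entries (from zero-variance series)
#'   are treated as 0 strength.
#' @param symmetric Is `corr` a symmetric within-set matrix?  Defaults to
#'   `TRUE` for square input.
#' @param abs_corr Threshold absolute correlations instead of signed ones.
#' @return Binary integer matrix of the same shape (zero diagonal when
#'   symmetric), with the threshold in attribute `theta`.
#' @examples
#' set.seed(1)
#' c4 <- cor(matrix(rnorm(80), 20, 4))
#' threshold_adjacency(c4)
#' @export
threshold_adjacency <- function(corr, symmetric = NULL, abs_corr = FALSE) {
  corr <- as.matrix(corr)
  if (is.null(symmetric)) symmetric <- nrow(corr) == ncol(corr)
  corr[is.na(corr)] <- 0
  strength <- if (abs_corr) abs(corr) else corr
  vals <- if (symmetric) strength[upper.tri(strength)] else as.vector(strength)
  out <- matrix(0L, nrow(corr), ncol(corr), dimnames = dimnames(corr))
  if (length(vals) == 0) {
    attr(out, "theta") <- NA_real_
    return(out)
  }
  spread <- if (length(vals) < 2) 0 else sd(vals)
  if (spread == 0 && length(vals) > 1) {
    warn("all FC strengths identical; thresholded adjacency is empty")
  }
  theta <- mean(vals) + spread
  out[strength > theta] <- 1L
  if (symmetric) {
    out[lower.tri(out)] <- t(out)[lower.tri(out)]
    diag(out) <- 0L
  }
  attr(out, "theta") <- theta
  out
}

# Standardize columns to zero mean / unit variance; zero-variance columns are
# returned as all-zero and reported in the "dropped" attribute.
standardize_columns <- function(x) {
  mu <- colMeans(x)
  sds <- apply(x, 2, sd)
  zero <- sds == 0
  sds[zero] <- 1
  out <- sweep(sweep(x, 2, mu, "-"), 2, sds, "/")
  out[, zero] <- 0
  attr(out, "dropped") <- which(zero)
  out
}

#' Hyperedge estimation by lasso sparse regression
#'
#' Builds the binary incidence matrix of the hypergraph layer.  Each node
#' (MRSN representative series) is taken in turn as the central response and
#' regressed on all other nodes under an L1 penalty,
#' `min (1/(2n)) ||X_i - B_i a||^2 + lambda ||a||_1` on column-standardized
#' series.  A node belongs to hyperedge `e_i` exactly when its coefficient is
#' strictly positive; a node is never a member of its own central hyperedge,
#' so the diagonal of `H` is zero.
#'
#' The penalty is expressed on the mean-squared-error scale so that `lambda`
#' is comparable across window lengths; multiply by the number of time points
#' for the unnormalised sum-of-squares convention.
#'
#' @param x Numeric matrix, time points x M node series (M >= 2).
#' @param lambda Positive regularization strength (default 0.1).
#' @return Binary M x M incidence matrix `H`; `H[j, i] = 1` iff node j
#'   belongs to the hyperedge centred on node i.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(300), 100, 3)
#' x[, 2] <- 0.9 * x[, 1] + 0.1 * rnorm(100)
#' lasso_hyperedges(x, lambda = 0.1)
#' @export
lasso_hyperedges <- function(x, lambda = 0.1) {
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) || lambda <= 0) {
    abort("lambda must be a single positive number")
  }
  x <- as.matrix(x)
  m <- ncol(x)
  if (m < 2) abort("hyperedge estimation needs at least 2 node series")
  xs <- standardize_columns(x)
  dropped <- attr(xs, "dropped")
  if (length(dropped) > 0) {
    warn(sprintf("%d zero-variance node series left out of hyperedge estimation",
                 length(dropped)))
  }
  h <- matrix(0L, m, m, dimnames = list(colnames(x), colnames(x)))
  n <- nrow(xs)
  for (i in seq_len(m)) {
    if (i %in% dropped) next
    y <- xs[, i]
    others <- setdiff(seq_len(m), i)
    b <- xs[, others, drop = FALSE]
    coefs <- if (ncol(b) == 1) {
      # glmnet requires >= 2 predictors; the single-predictor lasso has the
      # closed-form soft-threshold solution under the same objective.
      v <- sum(b[, 1]^2) / n
      r <- sum(b[, 1] * y) / n
      if (v == 0) 0 else sign(r) * max(abs(r) - lambda, 0) / v
    } else {
      fit <- glmnet::glmnet(b, y, family = "gaussian", alpha = 1,
                            lambda = lambda * c(8, 4, 2, 1),
                            standardize = FALSE, intercept = FALSE,
                            thresh = 1e-12)
      as.numeric(fit$beta[, ncol(fit$beta)])
    }
    h[others[coefs > 0], i] <- 1L
  }
  h
}

#' Build the spatial three-layer network for one time window
#'
#' Constructs, from one windowed slice of the ROI time series, the three
#' spatial layers: `H`, the M x M hypergraph incidence matrix over MRSN
#' representative series ([lasso_hyperedges()]); `A1`, the within-MRSN GM
#' adjacency, obtained by applying [threshold_adjacency()] independently to
#' each MRSN's internal correlation block (between-network GM pairs are
#' structurally zero); and `A2`, the WM x GM bipartite adjacency from the
#' thresholded WM-GM correlation matrix.  With the default parcellation the
#' shapes are 14 x 14, 90 x 90 and 48 x 90.
#'
#' @param x Numeric matrix (window length x all ROIs) or `mlfcn_timeseries`.
#' @param parc A [parcellation()].
#' @param lambda Lasso penalty for the hypergraph layer.
#' @param abs_corr Threshold absolute correlations in A1/A2.
#' @param mrsn_method Representative-series method, see [mrsn_series()].
#' @param window_index Stored layer index (bookkeeping only).
#' @return An object of class `mlfcn_spatial`: list with `H`, `A1`, `A2`,
#'   `window_index`, and `theta` (named list of realised thresholds).
#' @export
build_spatial_fcn <- function(x, parc, lambda = 0.1, abs_corr = FALSE,
                              mrsn_method = "mean", window_index = 1L) {
  if (inherits(x, "mlfcn_timeseries")) x <- x$data
  if (nrow(x) < 3) abort("a window needs at least 3 time points")
  levs <- attr(parc, "mrsn_levels")
  gm_idx <- parc$roi_index[parc$tissue == "GM"]
  wm_idx <- parc$roi_index[parc$tissue == "WM"]

  h <- lasso_hyperedges(mrsn_series(x, parc, method = mrsn_method), lambda)

  n_g <- length(gm_idx)
  a1 <- matrix(0L, n_g, n_g)
  theta1 <- setNames(rep(NA_real_, length(levs)), levs)
  for (m in seq_along(levs)) {
    pos <- which(parc$mrsn[gm_idx] == levs[m])
    if (length(pos) < 2) next
    cc <- suppressWarnings(cor(x[, gm_idx[pos], drop = FALSE]))
    blk <- threshold_adjacency(cc, symmetric = TRUE, abs_corr = abs_corr)
    a1[pos, pos] <- blk
    theta1[m] <- attr(blk, "theta")
  }

  if (length(wm_idx) > 0) {
    cwg <- suppressWarnings(cor(x[, wm_idx, drop = FALSE],
                                x[, gm_idx, drop = FALSE]))
    a2 <- threshold_adjacency(cwg, symmetric = FALSE, abs_corr = abs_corr)
    theta2 <- attr(a2, "theta")
  } else {
    a2 <- matrix(0L, 0, n_g)
    theta2 <- NA_real_
  }

  structure(
    list(H = h, A1 = a1, A2 = a2, window_index = as.integer(window_index),
         theta = list(A1 = theta1, A2 = theta2)),
    class = "mlfcn_spatial")
}

#' @export
print.mlfcn_spatial <- function(x, ...) {
  cat(sprintf("<mlfcn_spatial layer %d: H %dx%d (%d memberships), A1 %dx%d (%d edges), A2 %dx%d (%d edges)>\n",
              x$window_index, nrow(x$H), ncol(x$H), sum(x$H),
              nrow(x$A1), ncol(x$A1), sum(x$A1) / 2,
              nrow(x$A2), ncol(x$A2), sum(x$A2)))
  invisible(x)
}

#' Build the temporal multilayer network
#'
#' Applies [build_spatial_fcn()] to every sliding window of a subject's time
#' series, producing the ordered sequence of spatial three-layer networks
#' that constitutes the spatio-temporal multilayer FCN.
#'
#' @param ts A `mlfcn_timeseries` (or plain time x ROI matrix).
#' @param parc A [parcellation()].
#' @param window,stride Sliding-window parameters, see [sliding_windows()].
#' @inheritParams build_spatial_fcn
#' @return An object of class `mlfcn_temporal`: list with `layers` (list of
#'   `mlfcn_spatial`), `windows` (the window table), `parcellation`, and
#'   `params`.
#' @examples
#' parc <- toy_parcellation()
#' cfg <- sim_config(parcellation = parc, seed = 7)
#' ts <- simulate_subject(cfg, "s1")
#' net <- build_temporal_fcn(ts, parc, window = 200, stride = 100)
#' net
#' @export
build_temporal_fcn <- function(ts, parc, window, stride, lambda = 0.1,
                               abs_corr = FALSE, mrsn_method = "mean") {
  x <- if (inherits(ts, "mlfcn_timeseries")) ts$data else as.matrix(ts)
  if (ncol(x) != n_roi(parc)) {
    abort("time series column count does not match the parcellation")
  }
  win <- sliding_windows(nrow(x), window, stride)
  layers <- purrr::pmap(win, function(window, start, end) {
    build_spatial_fcn(x[start:end, , drop = FALSE], parc, lambda = lambda,
                      abs_corr = abs_corr, mrsn_method = mrsn_method,
                      window_index = window)
  })
  structure(
    list(layers = layers, windows = win, parcellation = parc,
         params = list(window = as.integer(window), stride = as.integer(stride),
                       lambda = lambda, abs_corr = abs_corr,
                       mrsn_method = mrsn_method),
         subject_id = if (inherits(ts, "mlfcn_timeseries")) ts$subject_id else NA_character_,
         session_id = if (inherits(ts, "mlfcn_timeseries")) ts$session_id else NA_character_),
    class = "mlfcn_temporal")
}

#' @export
print.mlfcn_temporal <- function(x, ...) {
  cat(sprintf("<mlfcn_temporal: %d layers (W=%d, S=%d), %d ROIs, subject %s>\n",
              length(x$layers), x$params$window, x$params$stride,
              n_roi(x$parcellation), x$subject_id))
  invisible(x)
}

#' Write a temporal network as sparse triplet tables
#'
#' Serialises each layer's H/A1/A2 as long-format TSV (layer, matrix, row,
#' col) of nonzero entries, plus a JSON manifest recording shapes and
#' parameters.
#'
#' @param net A `mlfcn_temporal`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_temporal_fcn <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  trip <- purrr::map_dfr(net$layers, function(l) {
    purrr::map_dfr(c("H", "A1", "A2"), function(nm) {
      nz <- which(l[[nm]] != 0, arr.ind = TRUE)
      if (nrow(nz) == 0) return(NULL)
      tibble(layer = l$window_index, matrix = nm,
             row = nz[, 1], col = nz[, 2])
    })
  })
  readr::write_tsv(trip, file.path(dir, "network_edges.tsv"))
  manifest <- list(
    n_layers = length(net$layers),
    shapes = list(H = dim(net$layers[[1]]$H), A1 = dim(net$layers[[1]]$A1),
                  A2 = dim(net$layers[[1]]$A2)),
    params = net$params,
    subject_id = net$subject_id, session_id = net$session_id)
  jsonlite::write_json(manifest, file.path(dir, "network_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
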