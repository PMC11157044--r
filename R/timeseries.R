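#' ROI-level BOLD time series
#'
#' `roi_timeseries()` wraps an `L x N_roi` numeric matrix (time points by
#' regions, column order matching the parcellation) together with subject and
#' session identifiers.  Zero-variance columns are permitted — they arise
#' from empty or constant regions — but are flagged and later excluded from
#' regression/correlation with a warning rather than silently producing NaN.
#'
#' @param data Numeric matrix or data frame, time points in rows, one column
#'   per ROI in parcellation order.
#' @param parc A [parcellation()] whose ROI count must match `ncol(data)`.
#' @param subject_id,session_id Identifier strings carried into outputs.
#' @param tr_seconds Repetition time in seconds (metadata only).
#' @return An object of class `mlfcn_timeseries`: a list with elements
#'   `data` (matrix), `subject_id`, `session_id`, `tr_seconds`, and
#'   `zero_variance` (integer vector of flagged ROI indices).
#' @export
roi_timeseries <- function(data, parc, subject_id = "subject",
                           session_id = "1", tr_seconds = NA_real_) {
  if (is.data.frame(data)) data <- as.matrix(data)
  if (!is.matrix(data) || !is.numeric(data)) {
    abort("time-series data must be a numeric matrix (time x ROI)")
  }
  if (ncol(data) != n_roi(parc)) {
    abort(sprintf("time series has %d columns but the parcellation defines %d ROIs",
                  ncol(data), n_roi(parc)))
  }
  if (anyNA(data) || any(!is.finite(data))) {
    abort("time-series data contains missing or non-finite values")
  }
  sds <- apply(data, 2, sd)
  zv <- which(sds == 0)
  if (length(zv) > 0) {
    warn(sprintf("%d ROI column(s) have zero variance: %s",
                 length(zv), paste(head(zv, 10), collapse = ", ")))
  }
  dimnames(data) <- NULL
  structure(
    list(data = data, subject_id = as.character(subject_id),
         session_id = as.character(session_id),
         tr_seconds = tr_seconds, zero_variance = as.integer(zv)),
    class = "mlfcn_timeseries")
}

#' @export
print.mlfcn_timeseries <- function(x, ...) {
  cat(sprintf("<mlfcn_timeseries: subject %s session %s, %d time points x %d ROIs>\n",
              x$subject_id, x$session_id, nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Read ROI time series from delimited text
#'
#' Reads a TSV/CSV of shape time points x ROIs (no header by default; a
#' header row of non-numeric column names is detected and skipped) and
#' validates it against a parcellation.
#'
#' @param path Path to the delimited file.
#' @param parc A [parcellation()].
#' @param delim Field delimiter, default tab.
#' @inheritParams roi_timeseries
#' @return A `mlfcn_timeseries`.
#' @export
read_timeseries <- function(path, parc, subject_id = NULL, session_id = "1",
                            delim = "\t", tr_seconds = NA_real_) {
  if (!file.exists(path)) abort(paste0("time-series file not found: ", path))
  first <- readLines(path, n = 1)
  fields <- strsplit(first, delim, fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(fields)))
  df <- tryCatch(
    readr::read_delim(path, delim = delim,
                      col_names = has_header,
                      col_types = readr::cols(.default = readr::col_double()),
                      progress = FALSE),
    warning = function(w) abort(paste0("non-numeric value in ", path)))
  if (anyNA(df)) abort(paste0("non-numeric or missing value in ", path))
  if (is.null(subject_id)) {
    subject_id <- sub("\\.(tsv|csv|txt)$", "", basename(path))
  }
  roi_timeseries(as.matrix(df), parc, subject_id = subject_id,
                 session_id = session_id, tr_seconds = tr_seconds)
}

#' @rdname read_timeseries
#' @param ts A `mlfcn_timeseries` to write as headerless TSV.
#' @export
write_timeseries <- function(ts, path, delim = "\t") {
  utils::write.table(ts$data, path, sep = delim, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Extract ROI time series from a 4D NIfTI volume
#'
#' Averages voxel time courses within each labelled atlas region.  Label
#' volumes must already be on the data's voxel grid; no registration or
#' resampling is performed.  Requires the RNifti package.
#'
#' @param bold_path Path to a 4D NIfTI volume (x, y, z, time).
#' @param atlas_paths Character vector of paths to integer label volumes
#'   (e.g. one GM atlas and one WM atlas), applied in order.
#' @param label_map Data frame with columns `atlas` (1-based index into
#'   `atlas_paths`), `label` (integer voxel value) and `roi_index`.
#' @param parc A [parcellation()]; every ROI must appear in `label_map`.
#' @inheritParams roi_timeseries
#' @return A `mlfcn_timeseries`.
#' @export
extract_roi_timeseries <- function(bold_path, atlas_paths, label_map, parc,
                                   subject_id = "subject", session_id = "1") {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("extract_roi_timeseries() requires the RNifti package")
  }
  label_map <- as_tibble(label_map)
  if (!all(parc$roi_index %in% label_map$roi_index)) {
    abort("label_map must cover every ROI in the parcellation")
  }
  bold <- RNifti::asNifti(RNifti::readNifti(bold_path))
  dm <- dim(bold)
  if (length(dm) != 4) abort("BOLD volume must be 4D (x, y, z, time)")
  l_t <- dm[4]
  vox <- matrix(as.numeric(bold), nrow = prod(dm[1:3]), ncol = l_t)
  atlases <- lapply(atlas_paths, function(p) {
    a <- RNifti::readNifti(p)
    if (!identical(dim(a)[1:3], dm[1:3])) {
      abort(paste0("atlas grid does not match BOLD grid: ", p))
    }
    as.integer(round(as.numeric(a)))
  })
  out <- matrix(NA_real_, nrow = l_t, ncol = n_roi(parc))
  for (r in seq_len(nrow(label_map))) {
    idx <- which(atlases[[label_map$atlas[r]]] == label_map$label[r])
    out[, label_map$roi_index[r]] <- if (length(idx) == 0) {
      0
    } else if (length(idx) == 1) {
      vox[idx, ]
    } else {
      colMeans(vox[idx, , drop = FALSE])
    }
  }
  roi_timeseries(out, parc, subject_id = subject_id, session_id = session_id)
}

#' MRSN-level representative series
#'
#' Collapses GM ROI columns to one representative series per macroscale
#' resting-state network, used as the node signals of the hypergraph layer.
#' The default representative is the unweighted mean of the member ROI
#' series; `"pc1"` uses the first principal component (sign-aligned with the
#' mean so the orientation is deterministic).
#'
#' @param x Numeric matrix (time points x all ROIs, parcellation order) or a
#'   `mlfcn_timeseries`.
#' @param parc A [parcellation()].
#' @param method `"mean"` (default) or `"pc1"`.
#' @return Numeric matrix, time points x number of GM MRSNs, columns named
#'   by MRSN.
#' @export
mrsn_series <- function(x, parc, method = c("mean", "pc1")) {
  method <- match.arg(method)
  if (inherits(x, "mlfcn_timeseries")) x <- x$data
  if (nrow(x) < 1) abort("window slice is empty")
  levs <- attr(parc, "mrsn_levels")
  out <- matrix(0, nrow = nrow(x), ncol = length(levs),
                dimnames = list(NULL, levs))
  for (m in seq_along(levs)) {
    cols <- parc$roi_index[parc$mrsn == levs[m]]
    block <- x[, cols, drop = FALSE]
    if (method == "mean" || ncol(block) == 1) {
      out[, m] <- rowMeans(block)
    } else {
      centred <- scale(block, center = TRUE, scale = FALSE)
      pc <- svd(centred, nu = 1, nv = 0)$u[, 1] * svd(centred)$d[1]
      if (sum(pc * rowMeans(block)) < 0) pc <- -pc
      out[, m] <- pc
    }
  }
  out
}
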