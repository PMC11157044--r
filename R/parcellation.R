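#' Multi-scale brain parcellations
#'
#' A parcellation defines the node identities for every layer of the
#' multilayer functional connectivity network: each region of interest (ROI)
#' carries a 1-based index, a label, a tissue class (`"GM"` or `"WM"`), and —
#' for gray-matter ROIs — membership in exactly one macroscale resting-state
#' network (MRSN).  All white-matter ROIs form a single WM group that is
#' excluded from the hypergraph layer.
#'
#' `parcellation()` validates a data frame with columns `roi_index`, `label`,
#' `tissue` and `mrsn` and returns a `mlfcn_parcellation` tibble.
#' ROI indices must be unique and contiguous from 1; every GM ROI must name
#' an MRSN and every MRSN must have at least one member.
#'
#' @param x A data frame with columns `roi_index` (integer), `label`
#'   (character), `tissue` (`"GM"`/`"WM"`) and `mrsn` (character; ignored and
#'   normalised to `"WM"` for WM rows).
#' @param mrsns Optional character vector of expected GM MRSN names; if
#'   given, each must have at least one member ROI (an empty MRSN is a
#'   validation error) and the MRSN ordering follows this vector.
#' @return A tibble of class `mlfcn_parcellation`, one row per ROI, ordered
#'   by `roi_index`, with the GM MRSN names (in order) stored in the
#'   `mrsn_levels` attribute.
#' @examples
#' parc <- toy_parcellation()
#' n_roi(parc)
#' mrsn_table(parc)
#' @export
parcellation <- function(x, mrsns = NULL) {
  x <- as_tibble(x)
  needed <- c("roi_index", "label", "tissue", "mrsn")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("parcellation is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x$roi_index <- as.integer(x$roi_index)
  x$label <- as.character(x$label)
  x$tissue <- as.character(x$tissue)
  x$mrsn <- as.character(x$mrsn)

  if (anyDuplicated(x$roi_index)) {
    dup <- unique(x$roi_index[duplicated(x$roi_index)])
    abort(paste0("duplicate ROI index(es): ", paste(dup, collapse = ", ")))
  }
  x <- arrange(x[, needed], .data$roi_index)
  if (!identical(x$roi_index, seq_len(nrow(x)))) {
    abort("ROI indices must be contiguous from 1 to the number of ROIs")
  }
  if (!all(x$tissue %in% c("GM", "WM"))) {
    abort("tissue must be 'GM' or 'WM' for every ROI")
  }
  gm <- x$tissue == "GM"
  if (any(gm & (is.na(x$mrsn) | x$mrsn == ""))) {
    abort("every GM ROI must be assigned to exactly one MRSN")
  }
  if (any(gm & x$mrsn == "WM")) {
    abort("'WM' is reserved for the white-matter group; GM ROIs may not use it")
  }
  x$mrsn[!gm] <- "WM"

  levels_seen <- unique(x$mrsn[gm])
  if (is.null(mrsns)) {
    mrsns <- levels_seen
  } else {
    empty <- setdiff(mrsns, levels_seen)
    if (length(empty) > 0) {
      abort(paste0("MRSN(s) with no member ROI: ", paste(empty, collapse = ", ")))
    }
    extra <- setdiff(levels_seen, mrsns)
    if (length(extra) > 0) {
      abort(paste0("ROI(s) assigned to undeclared MRSN(s): ",
                   paste(extra, collapse = ", ")))
    }
  }

  structure(x,
            mrsn_levels = mrsns,
            class = c("mlfcn_parcellation", class(tibble())))
}

#' @export
print.mlfcn_parcellation <- function(x, ...) {
  cat(sprintf("<mlfcn_parcellation: %d ROIs (%d GM in %d MRSNs, %d WM)>\n",
              n_roi(x), sum(x$tissue == "GM"), length(attr(x, "mrsn_levels")),
              sum(x$tissue == "WM")))
  NextMethod()
}

#' Parcellation accessors
#'
#' Small query helpers over a [parcellation()]: total ROI count, GM/WM
#' counts, and the per-MRSN membership table whose sizes `n_S` enter the
#' normalised-degree denominators and the local/joint functionality scalings.
#'
#' @param parc A `mlfcn_parcellation`.
#' @return `n_roi()`, `n_gm()`, `n_wm()`: integers.  `mrsn_table()`: a tibble
#'   with one row per GM MRSN plus a final `WM` row, columns `mrsn`,
#'   `n_members`, `roi_indices` (list column).
#' @export
n_roi <- function(parc) nrow(parc)

#' @rdname n_roi
#' @export
n_gm <- function(parc) sum(parc$tissue == "GM")

#' @rdname n_roi
#' @export
n_wm <- function(parc) sum(parc$tissue == "WM")

#' @rdname n_roi
#' @export
mrsn_table <- function(parc) {
  levs <- c(attr(parc, "mrsn_levels"), if (n_wm(parc) > 0) "WM")
  tibble(
    mrsn = levs,
    n_members = vapply(levs, function(m) sum(parc$mrsn == m), integer(1),
                       USE.NAMES = FALSE),
    roi_indices = lapply(levs, function(m) parc$roi_index[parc$mrsn == m])
  )
}

#' Theoretical maximum node degree per layer
#'
#' Returns, for every ROI, the largest degree it can attain in each of the
#' three spatial layers.  A GM ROI in MRSN `S` can at most: belong to every
#' other MRSN's hyperedge (layer 1: `M - 1`, since a node is never a member
#' of its own central hyperedge), connect to every other member of `S`
#' (layer 2: `n_S - 1`), and connect to every WM ROI (layer 3: `N_WM`).  A WM
#' ROI participates only in layer 3, where it can connect to every GM ROI.
#' The layer sums are the denominators of the degree normalisation; under the
#' default parcellation an auditory-network GM node has maxima (13, 2, 48)
#' and every WM node has layer sum 90.
#'
#' @param parc A `mlfcn_parcellation`.
#' @return A tibble with columns `roi_index`, `tissue`, `mrsn`, `dmax1`,
#'   `dmax2`, `dmax3`, `dmax_sum`.
#' @export
max_degrees <- function(parc) {
  m <- length(attr(parc, "mrsn_levels"))
  sizes <- setNames(
    vapply(attr(parc, "mrsn_levels"),
           function(s) sum(parc$mrsn == s), integer(1)),
    attr(parc, "mrsn_levels"))
  gm <- parc$tissue == "GM"
  d1 <- ifelse(gm, m - 1L, 0L)
  d2 <- ifelse(gm, sizes[parc$mrsn] - 1L, 0L)
  d3 <- ifelse(gm, n_wm(parc), n_gm(parc))
  tibble(
    roi_index = parc$roi_index,
    tissue = parc$tissue,
    mrsn = parc$mrsn,
    dmax1 = as.integer(d1),
    dmax2 = as.integer(unname(d2)),
    dmax3 = as.integer(d3),
    dmax_sum = as.integer(d1 + unname(d2) + d3)
  )
}

#' Read and write parcellation tables
#'
#' The on-disk format is a four-column TSV (`roi_index`, `label`, `tissue`,
#' `mrsn`), chosen for diffability.  `read_parcellation()` validates on load;
#' `write_parcellation()` round-trips exactly.
#'
#' @param path Path to a TSV file.
#' @param parc A `mlfcn_parcellation`.
#' @return `read_parcellation()`: a `mlfcn_parcellation`.
#'   `write_parcellation()`: `path`, invisibly.
#' @export
read_parcellation <- function(path) {
  if (!file.exists(path)) abort(paste0("parcellation file not found: ", path))
  df <- readr::read_tsv(path, col_types = readr::cols(
    roi_index = readr::col_integer(),
    label = readr::col_character(),
    tissue = readr::col_character(),
    mrsn = readr::col_character()
  ))
  parcellation(df)
}

#' @rdname read_parcellation
#' @export
write_parcellation <- function(parc, path) {
  readr::write_tsv(as_tibble(parc)[, c("roi_index", "label", "tissue", "mrsn")],
                   path)
  invisible(path)
}

#' Bundled default whole-brain parcellation
#'
#' The default layout has 138 ROIs: 90 GM regions partitioned into 14 named
#' macroscale resting-state networks (anterior/posterior salience, auditory,
#' basal ganglia, dorsal/ventral default mode, primary/higher visual,
#' language, left/right executive control, precuneus, sensorimotor,
#' visuospatial), followed by the 48 white-matter tracts of a standard
#' DTI-based WM atlas.  Network member counts follow the published 90-region
#' functional atlas (the auditory network has 3 members); individual GM
#' member labels are generic placeholders and users mapping their own atlas
#' should supply their own table via [read_parcellation()].
#'
#' @return A `mlfcn_parcellation` with 138 ROIs.
#' @examples
#' parc <- default_parcellation()
#' n_roi(parc)
#' @export
default_parcellation <- function() {
  path <- system.file("extdata", "parcellation_default.tsv",
                      package = "mlfcn", mustWork = TRUE)
  read_parcellation(path)
}

#' Small synthetic parcellation for examples and simulation
#'
#' A deliberately small layout (default 5 MRSNs of 4 GM ROIs each plus 6 WM
#' ROIs, 26 nodes) that keeps exhaustive brute-force computation feasible
#' while exercising every code path of the full-size parcellation.
#'
#' @param n_mrsn Number of GM MRSNs.
#' @param gm_per_mrsn Members per MRSN (recycled to length `n_mrsn`).
#' @param n_wm Number of WM ROIs.
#' @return A `mlfcn_parcellation`.
#' @export
toy_parcellation <- function(n_mrsn = 5, gm_per_mrsn = 4, n_wm = 6) {
  sizes <- rep_len(gm_per_mrsn, n_mrsn)
  mrsn_names <- paste0("NET", seq_len(n_mrsn))
  gm <- tibble(
    label = unlist(lapply(seq_len(n_mrsn), function(i) {
      paste0(mrsn_names[i], "_", seq_len(sizes[i]))
    })),
    tissue = "GM",
    mrsn = rep(mrsn_names, sizes)
  )
  wm <- tibble(
    label = if (n_wm > 0) paste0("TRACT_", seq_len(n_wm)) else character(),
    tissue = rep("WM", n_wm),
    mrsn = rep("WM", n_wm)
  )
  df <- bind_rows(gm, wm)
  df$roi_index <- seq_len(nrow(df))
  parcellation(df, mrsns = mrsn_names)
}
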