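#' Tidy and glance methods
#'
#' Broom-style accessors for the package's result objects.
#' `tidy.mlfcn_richclub()` returns the node-level metrics in long format
#' (one row per ROI x metric); `glance.mlfcn_richclub()` returns a one-row
#' whole-brain summary.  `tidy.mlfcn_temporal()` flattens a temporal
#' network into a long edge/membership table (one row per nonzero entry of
#' H, A1 or A2 per layer).
#'
#' @param x A `mlfcn_richclub` or `mlfcn_temporal` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mlfcn_richclub <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(all_of(c("tc", "ts", "ts_prose", "ts_literal",
                                 "lf", "jf")),
                        names_to = "metric", values_to = "value")
}

#' @rdname tidy.mlfcn_richclub
#' @export
glance.mlfcn_richclub <- function(x, ...) {
  df <- as_tibble(x)
  summarise(df,
            n_roi = dplyr::n(),
            n_core = attr(x, "n_core"),
            across(all_of(c("tc", "ts", "lf", "jf")), mean,
                   .names = "mean_{.col}"))
}

#' @rdname tidy.mlfcn_richclub
#' @export
tidy.mlfcn_temporal <- function(x, ...) {
  purrr::map_dfr(x$layers, function(l) {
    purrr::map_dfr(c("H", "A1", "A2"), function(nm) {
      nz <- which(l[[nm]] != 0, arr.ind = TRUE)
      if (nrow(nz) == 0) return(NULL)
      tibble(layer = l$window_index, matrix = nm,
             row = as.integer(nz[, 1]), col = as.integer(nz[, 2]))
    })
  })
}
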