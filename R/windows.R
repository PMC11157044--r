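#' Sliding time windows over a BOLD series
#'
#' Partitions a series of length `L` into overlapping segments of length
#' `window` advanced by `stride` time points, yielding
#' `T = floor((L - window) / stride) + 1` temporal layers.  When
#' `L - window` is not a multiple of `stride`, the trailing remainder is
#' dropped with a warning (the standard parameter sets divide evenly).
#'
#' @param L Total number of time points.
#' @param window Window length `W` in time points (`1 <= stride <= window <= L`).
#' @param stride Stride `S` in time points.
#' @return A tibble with columns `window` (1-based layer index), `start`,
#'   `end` (1-based, inclusive time-point indices).
#' @examples
#' sliding_windows(1200, 200, 100)   # 11 windows
#' sliding_windows(150, 20, 10)      # 14 windows
#' @export
sliding_windows <- function(L, window, stride) {
  L <- as.integer(L); window <- as.integer(window); stride <- as.integer(stride)
  if (length(L) != 1 || is.na(L) || L < 1) abort("L must be a positive integer")
  if (is.na(window) || window < 1) abort("window length must be >= 1")
  if (is.na(stride) || stride < 1) abort("stride must be >= 1")
  if (window > L) abort(sprintf("window length (%d) exceeds series length (%d)",
                                window, L))
  if (stride > window) abort("stride must not exceed the window length")
  t_n <- n_windows(L, window, stride)
  if ((L - window) %% stride != 0) {
    warn(sprintf(
      "(L - window) is not a multiple of stride; %d trailing time point(s) dropped",
      (L - window) %% stride))
  }
  start <- (seq_len(t_n) - 1L) * stride + 1L
  end <- start + window - 1L
  tibble(window = seq_len(t_n), start = start, end = end)
}

#' @rdname sliding_windows
#' @export
n_windows <- function(L, window, stride) {
  if (window > L) abort("window length exceeds series length")
  as.integer((L - window) %/% stride + 1L)
}
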