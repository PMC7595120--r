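#' Multichannel time-series records
#'
#' `mc_record()` validates a rectangular block of uniformly sampled channels
#' (samples in rows, one column per channel) and returns a `mc_record`, the
#' input container used by all coupling estimators. Channels must be finite
#' numeric series of equal length with unique labels.
#'
#' @param data A data frame, tibble or numeric matrix with one column per
#'   channel and one row per sample.
#' @param labels Optional character vector of channel names; defaults to the
#'   column names of `data` (or `ch1`, `ch2`, ... when absent).
#' @param fs Sampling rate in Hz. Use `1` for unitless simulated series.
#'
#' @return An object of class `mc_record`: a list with elements `data`
#'   (samples x channels numeric matrix), `labels` and `fs`.
#'
#' @examples
#' rec <- mc_record(data.frame(a = rnorm(100), b = rnorm(100)), fs = 4)
#' rec
#' @export
mc_record <- function(data, labels = NULL, fs = 1) {
  if (is.data.frame(data)) data <- as.matrix(data)
  if (!is.matrix(data)) {
    stop_ctds("bad_input", "`data` must be a data frame or matrix (samples x channels).")
  }
  storage.mode(data) <- "double"
  if (is.null(labels)) labels <- colnames(data)
  if (is.null(labels)) labels <- paste0("ch", seq_len(ncol(data)))
  labels <- as.character(labels)
  if (length(labels) != ncol(data)) {
    stop_ctds("bad_input", "`labels` must have one entry per channel.")
  }
  if (anyDuplicated(labels)) {
    stop_ctds("duplicate_labels", "Channel labels must be unique.")
  }
  if (!all(is.finite(data))) {
    stop_ctds("non_finite_data", "Channels contain NaN/Inf/NA values.")
  }
  if (nrow(data) < 4L) {
    stop_ctds("too_short", "Channels must contain at least 4 samples.")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop_ctds("bad_input", "`fs` must be a single positive number.")
  }
  colnames(data) <- labels
  structure(list(data = data, labels = labels, fs = as.numeric(fs)),
            class = "mc_record")
}

as_mc_record <- function(x, fs = 1) {
  if (inherits(x, "mc_record")) return(x)
  mc_record(x, fs = fs)
}

#' @export
print.mc_record <- function(x, ...) {
  cat(sprintf("<mc_record> %d channels x %d samples @ %g Hz\n",
              ncol(x$data), nrow(x$data), x$fs))
  cat("channels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.mc_record <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$data))
}

#' Segmentation plan for overlapping windows
#'
#' Describes how a series of length `n_samples` is cut into half-overlapping
#' windows of length `L`. The overlap is fixed at 50%: window `v` starts at
#' sample `(v - 1) * L / 2` (0-based), so the window count is
#' `floor((n_samples - L) / (L / 2)) + 1`. Trailing samples that do not fill a
#' final window are discarded.
#'
#' @param L Window length in samples; must be an even integer >= 4.
#' @param n_samples Series length in samples.
#' @return A list with `L`, `overlap` (always 0.5), `n_segments` and `starts`
#'   (0-based window start indices).
#' @examples
#' segment_spec(20, 100)$n_segments # 9
#' @export
segment_spec <- function(L, n_samples) {
  if (!is.numeric(L) || length(L) != 1L || L < 4 || L %% 2 != 0) {
    stop_ctds("bad_input", "`L` must be an even integer >= 4.")
  }
  L <- as.integer(L)
  n_samples <- as.integer(n_samples)
  if (n_samples < L) {
    stop_ctds("too_short", sprintf(
      "Series length %d is shorter than window length L = %d.", n_samples, L))
  }
  n_segments <- (n_samples - L) %/% (L %/% 2L) + 1L
  list(L = L, overlap = 0.5, n_segments = n_segments,
       starts = (seq_len(n_segments) - 1L) * (L %/% 2L))
}

# Cut every channel into half-overlapping windows of length L and normalise
# each window to mean 0 and (population) standard deviation 1, so that the
# 1/L lagged product of two windows at full overlap is an ordinary
# correlation. Zero-variance windows are flagged degenerate and their values
# set to NA; downstream delay searches exclude them instead of producing NaN.
#
# Returns a list: segments = array [L, n_segments, n_channels],
# degenerate = matrix [n_segments, n_channels], spec, labels.
segment_channels <- function(record, L) {
  spec <- segment_spec(L, nrow(record$data))
  n_ch <- ncol(record$data)
  segs <- array(NA_real_, dim = c(spec$L, spec$n_segments, n_ch))
  degen <- matrix(FALSE, spec$n_segments, n_ch)
  for (v in seq_len(spec$n_segments)) {
    idx <- spec$starts[v] + seq_len(spec$L)
    w <- record$data[idx, , drop = FALSE]
    m <- colMeans(w)
    w <- sweep(w, 2L, m, "-")
    s <- sqrt(colMeans(w^2))
    bad <- s < 1e-12
    degen[v, ] <- bad
    s[bad] <- NA_real_
    segs[, v, ] <- sweep(w, 2L, s, "/")
  }
  list(segments = segs, degenerate = degen, spec = spec, labels = record$labels)
}

#' Segment and normalise a record
#'
#' Windows every channel of a record into half-overlapping segments of length
#' `L` and normalises each segment to zero mean and unit (population) standard
#' deviation. Constant (zero-variance) segments are flagged degenerate and
#' excluded from later delay searches.
#'
#' @inheritParams build_network
#' @return A tibble with one row per (channel, segment): `channel`, `segment`,
#'   `start` (0-based first sample), `degenerate`, and `values` (list-column of
#'   length-`L` normalised sample vectors).
#' @examples
#' rec <- mc_record(data.frame(a = rnorm(100), b = rnorm(100)))
#' segment_record(rec, L = 20)
#' @export
segment_record <- function(data, L = 20, fs = 1) {
  record <- as_mc_record(data, fs = fs)
  sc <- segment_channels(record, L)
  grid <- expand.grid(segment = seq_len(sc$spec$n_segments),
                      channel = sc$labels, stringsAsFactors = FALSE)
  tibble::tibble(
    channel = grid$channel,
    segment = grid$segment,
    start = sc$spec$starts[grid$segment],
    degenerate = mapply(function(v, ch) sc$degenerate[v, match(ch, sc$labels)],
                        grid$segment, grid$channel),
    values = mapply(function(v, ch) sc$segments[, v, match(ch, sc$labels)],
                    grid$segment, grid$channel, SIMPLIFY = FALSE)
  )
}
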