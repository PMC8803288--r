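#' Acceleration trace container
#'
#' A light data.frame subclass holding a single-axis acceleration time series:
#' columns `time_s` (seconds, GMT epoch, strictly increasing, nominal spacing
#' 1/25 s) and `accel_g` (acceleration in g). The `kind` attribute records the
#' processing stage: `"raw"`, `"smoothed"` or `"dynamic"`.
#'
#' @param time_s Numeric timestamps in seconds (GMT epoch), strictly increasing.
#' @param accel_g Acceleration values in g.
#' @param kind One of `"raw"`, `"smoothed"`, `"dynamic"`.
#' @param sample_rate Nominal sampling rate in Hz (default 25).
#' @return An `accel_trace` data.frame.
#' @export
accel_trace <- function(time_s, accel_g, kind = "raw", sample_rate = 25) {
  stopifnot(length(time_s) == length(accel_g))
  kind <- match.arg(kind, c("raw", "smoothed", "dynamic"))
  if (length(time_s) > 1 && any(diff(time_s) <= 0))
    stop("timestamps must be strictly increasing")
  structure(data.frame(time_s = as.numeric(time_s), accel_g = as.numeric(accel_g)),
            kind = kind, sample_rate = sample_rate,
            class = c("accel_trace", "data.frame"))
}

trace_kind <- function(trace) attr(trace, "kind") %||% "raw"

#' Centered running mean of an acceleration trace
#'
#' Smooths the trace with a centered moving average spanning `window_s`
#' seconds, the estimate of the static (gravity/tag-angle) component. At 25 Hz
#' a 2-s window is 50 samples; for a symmetric zero-phase filter the window is
#' widened to the odd count `2 * floor(window_s * rate / 2) + 1` (51 samples,
#' +/- 1 s inclusive). At segment edges the window shrinks to the available
#' samples rather than padding with fabricated data.
#'
#' @param trace An `accel_trace` (kind `"raw"`).
#' @param window_s Window length in seconds (default 2).
#' @return An `accel_trace` of kind `"smoothed"`, aligned to the input
#'   timestamps (same length).
#' @export
running_mean <- function(trace, window_s = 2) {
  stopifnot(inherits(trace, "accel_trace"), window_s > 0)
  n <- nrow(trace)
  if (n == 0) stop("empty trace")
  rate <- attr(trace, "sample_rate") %||% 25
  h <- max(floor(window_s * rate / 2), 0L)  # half-width in samples
  x <- trace$accel_g
  # O(n) via cumulative sums; lo/hi are the shrunk-window bounds per index
  cs <- c(0, cumsum(x))
  idx <- seq_len(n)
  lo <- pmax(idx - h, 1L)
  hi <- pmin(idx + h, n)
  sm <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  accel_trace(trace$time_s, sm, kind = "smoothed", sample_rate = rate)
}

#' Dynamic body acceleration
#'
#' Movement-induced component of the signal: the raw trace minus its running
#' mean ([running_mean()]), removing the static component due to the tag's
#' angle with respect to gravity. The decomposition is exact:
#' `raw = smoothed + dynamic` at every sample.
#'
#' @inheritParams running_mean
#' @return An `accel_trace` of kind `"dynamic"`.
#' @export
dynamic_acceleration <- function(trace, window_s = 2) {
  sm <- running_mean(trace, window_s = window_s)
  accel_trace(trace$time_s, trace$accel_g - sm$accel_g, kind = "dynamic",
              sample_rate = attr(trace, "sample_rate") %||% 25)
}

#' Split a trace at recording gaps
#'
#' Cuts the trace wherever consecutive timestamps are more than `max_gap_s`
#' apart (e.g., the daytime off period between recording nights). Smoothing
#' should be applied per segment, never across a gap.
#'
#' @param trace An `accel_trace`.
#' @param max_gap_s Maximum allowed spacing within a segment, in seconds.
#' @return List of `accel_trace` segments, in order; concatenating them
#'   restores the input.
#' @export
split_gaps <- function(trace, max_gap_s) {
  stopifnot(inherits(trace, "accel_trace"), max_gap_s > 0)
  n <- nrow(trace)
  if (n == 0) return(list())
  rate <- attr(trace, "sample_rate") %||% 25
  kind <- trace_kind(trace)
  brk <- which(diff(trace$time_s) > max_gap_s)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, n)
  lapply(seq_along(starts), function(i) {
    rows <- starts[i]:ends[i]
    accel_trace(trace$time_s[rows], trace$accel_g[rows], kind = kind,
                sample_rate = rate)
  })
}
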