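#' Specify a digital filter for trace preprocessing
#'
#' The analysis default mirrors the recording pipeline: a 60 Hz high-pass
#' Butterworth, order 4, applied forward-backward (zero phase) so spike
#' times are not shifted. A 50/60 Hz line-noise notch is available but off
#' by default.
#'
#' @param kind `"highpass"` or `"bandpass"`.
#' @param corner_low Lower corner frequency, Hz.
#' @param corner_high Upper corner frequency, Hz (bandpass only).
#' @param order Butterworth order (applied once per direction).
#' @param notch_enabled Apply a narrow band-stop around `notch_freq` first.
#' @param notch_freq Line frequency for the notch, Hz.
#' @return An object of class `"filter_spec"`.
#' @export
filter_spec <- function(kind = c("highpass", "bandpass"), corner_low = 60,
                        corner_high = NULL, order = 4,
                        notch_enabled = FALSE, notch_freq = 60) {
  kind <- match.arg(kind)
  if (corner_low <= 0) stop("corner_low must be positive")
  if (kind == "bandpass") {
    if (is.null(corner_high)) stop("bandpass filter needs corner_high")
    if (corner_high <= corner_low) stop("corner_high must exceed corner_low")
  }
  if (order < 1) stop("order must be >= 1")
  structure(list(kind = kind, corner_low = corner_low,
                 corner_high = corner_high, order = as.integer(order),
                 notch_enabled = isTRUE(notch_enabled),
                 notch_freq = notch_freq),
            class = "filter_spec")
}

reflect_pad <- function(x, npad) {
  n <- length(x)
  npad <- min(npad, n - 1L)
  # odd (point-symmetric) reflection, as used for zero-phase IIR filtering
  left <- 2 * x[1] - x[(npad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - npad)]
  list(x = c(left, x, right), npad = npad)
}

#' Zero-phase Butterworth filtering of a voltage trace
#'
#' Applies the filter forward and backward (`signal::filtfilt`) after odd
#' reflection padding, so the output has zero phase shift and the same
#' length as the input. Corners at or above the Nyquist frequency are
#' rejected.
#'
#' @param trace Numeric voltage trace.
#' @param fs Sampling rate, Hz.
#' @param spec A [filter_spec()].
#' @return Filtered trace, same length as `trace`.
#' @export
filter_trace <- function(trace, fs, spec = filter_spec()) {
  if (!inherits(spec, "filter_spec")) stop("spec must be a filter_spec")
  n <- length(trace)
  if (n <= 3 * spec$order) stop("trace too short for the requested filter order")
  nyq <- fs / 2
  if (spec$corner_low >= nyq ||
      (!is.null(spec$corner_high) && spec$corner_high >= nyq))
    stop("filter corner at or above Nyquist frequency")
  x <- as.numeric(trace)
  if (spec$notch_enabled) {
    half_bw <- 2
    bs <- signal::butter(2, c(spec$notch_freq - half_bw, spec$notch_freq + half_bw) / nyq,
                         type = "stop")
    x <- apply_filtfilt(x, bs, fs, spec$corner_low)
  }
  bf <- if (spec$kind == "highpass") {
    signal::butter(spec$order, spec$corner_low / nyq, type = "high")
  } else {
    signal::butter(spec$order, c(spec$corner_low, spec$corner_high) / nyq,
                   type = "pass")
  }
  apply_filtfilt(x, bf, fs, spec$corner_low, order = spec$order)
}

apply_filtfilt <- function(x, flt, fs, corner_low, order = 4L) {
  # pad long enough to absorb the low-corner transient (>= one corner period)
  npad <- max(3L * order, ceiling(0.1 * fs), ceiling(3 * fs / corner_low))
  p <- reflect_pad(x, npad)
  y <- signal::filtfilt(flt, p$x)
  y[(p$npad + 1):(p$npad + length(x))]
}
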