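#' Define an analysis epoch
#'
#' Epochs partition a recording into the windows compared in the protocol:
#' `control` immediately before a stimulus, `stimulus` during it, and
#' `recover` immediately after, typically 10 or 30 s each.
#'
#' @param name Epoch label (`"control"`, `"stimulus"`, `"recover"` or any
#'   user label).
#' @param start Epoch start, seconds.
#' @param duration Epoch duration, seconds (> 0).
#' @return An object of class `"epoch_spec"`.
#' @export
epoch_spec <- function(name, start, duration) {
  if (duration <= 0) stop("duration must be positive")
  if (start < 0) stop("start must be non-negative")
  structure(list(name = as.character(name), start = start,
                 duration = duration), class = "epoch_spec")
}

#' Build the standard control/stimulus/recover epoch triplet
#' @param stim_start Stimulus onset, seconds.
#' @param duration Epoch duration, seconds (default 10).
#' @return List of three [epoch_spec()]s.
#' @export
standard_epochs <- function(stim_start, duration = 10) {
  list(epoch_spec("control", stim_start - duration, duration),
       epoch_spec("stimulus", stim_start, duration),
       epoch_spec("recover", stim_start + duration, duration))
}

check_epochs <- function(epochs) {
  if (length(epochs) < 2) return(invisible(epochs))
  iv <- t(vapply(epochs, function(e) c(e$start, e$start + e$duration),
                 numeric(2)))
  o <- order(iv[, 1])
  iv <- iv[o, , drop = FALSE]
  if (any(iv[-1, 1] < iv[-nrow(iv), 2] - 1e-12))
    stop("epochs overlap")
  invisible(epochs)
}

#' Mean firing rate within an epoch
#'
#' Counts spikes with `start <= t < start + duration` and divides by the
#' duration, giving Hz.
#'
#' @param times Spike times, seconds.
#' @param epoch An [epoch_spec()].
#' @return Firing rate in Hz.
#' @export
firing_rate <- function(times, epoch) {
  if (!inherits(epoch, "epoch_spec")) stop("epoch must be an epoch_spec")
  sum(times >= epoch$start & times < epoch$start + epoch$duration) /
    epoch$duration
}

#' Instantaneous firing rate on a uniform grid
#'
#' Spike counts are binned at `grid_dt` and convolved with a Gaussian kernel
#' of width `smooth_sigma`, scaled to Hz. The kernel is normalized so the
#' rate integrates to the spike count (mass conservation, up to edge losses
#' for spikes within ~3 sigma of the ends). A reciprocal-ISI estimator is
#' available as an alternative.
#'
#' @param times Spike times, seconds.
#' @param t_end End of the analysis window, seconds (grid runs from 0).
#' @param grid_dt Bin width, seconds (default 0.05).
#' @param smooth_sigma Gaussian kernel SD, seconds (default 0.1).
#' @param method `"gaussian"` (default) or `"isi"` (reciprocal inter-spike
#'   interval, sampled onto the grid).
#' @return An object of class `"rate_series"`: data frame with columns
#'   `time` (bin centers, seconds) and `rate` (Hz).
#' @export
instantaneous_rate <- function(times, t_end, grid_dt = 0.05,
                               smooth_sigma = 0.1,
                               method = c("gaussian", "isi")) {
  method <- match.arg(method)
  if (grid_dt <= 0) stop("grid_dt must be positive")
  edges <- seq(0, t_end + grid_dt, by = grid_dt)
  centers <- edges[-length(edges)] + grid_dt / 2
  counts <- tabulate(findInterval(times[times >= 0 & times < t_end], edges),
                     nbins = length(centers))
  if (method == "isi") {
    rate <- numeric(length(centers))
    if (length(times) >= 2) {
      st <- sort(times)
      mid <- (st[-1] + st[-length(st)]) / 2
      rate <- stats::approx(mid, 1 / diff(st), xout = centers,
                            rule = 2)$y
      rate[centers < st[1] | centers > st[length(st)]] <- 0
    }
  } else {
    half <- ceiling(4 * smooth_sigma / grid_dt)
    k <- stats::dnorm(seq(-half, half) * grid_dt, sd = smooth_sigma)
    k <- k / (sum(k) * grid_dt)            # integrates to 1 -> output in Hz
    npad <- length(k)
    padded <- c(numeric(npad), counts, numeric(npad))
    sm <- stats::filter(padded, k, sides = 2)
    rate <- as.numeric(sm[(npad + 1):(npad + length(counts))])
  }
  structure(data.frame(time = centers, rate = pmax(rate, 0)),
            class = c("rate_series", "data.frame"),
            grid_dt = grid_dt, smooth_sigma = smooth_sigma)
}

#' Resample a trace onto a rate-series grid by linear interpolation
#' @param values Trace samples.
#' @param fs Trace sampling rate, Hz.
#' @param rate A `rate_series` from [instantaneous_rate()].
#' @return Numeric vector aligned with `rate$time`.
#' @export
resample_to_grid <- function(values, fs, rate) {
  t_src <- (seq_along(values) - 1) / fs
  stats::approx(t_src, values, xout = rate$time, rule = 2)$y
}

#' Regress instantaneous firing rate on a stimulus trace
#'
#' Ordinary least squares of the unit's instantaneous rate on the force
#' regressor (grams), the mechanosensitivity measure: slope in Hz per gram
#' and the coefficient of determination r-squared. r-squared is invariant
#' to affine rescaling of the force trace.
#'
#' @param rate A `rate_series` (or numeric rate vector).
#' @param force Force values on the same grid.
#' @param unit_id Optional unit label carried into the result.
#' @return An object of class `"stimulus_regression"`: list with `unit_id`,
#'   `slope` (Hz/g), `intercept` (Hz), `r2`.
#' @export
regress_on_stimulus <- function(rate, force, unit_id = NA) {
  r <- if (inherits(rate, "rate_series") || is.data.frame(rate)) rate$rate else as.numeric(rate)
  if (length(r) != length(force)) stop("rate and force grids differ in length")
  if (stats::sd(force) < 1e-300) stop("degenerate regressor: force has zero variance")
  fit <- ols_fit(force, r)
  structure(list(unit_id = unit_id, slope = fit$slope,
                 intercept = fit$intercept, r2 = fit$r2),
            class = "stimulus_regression")
}

#' Epoch-to-epoch firing rate contrasts
#'
#' Absolute (Hz) and percentage changes of each epoch's rate relative to the
#' control epoch. The percentage is undefined (NA, flagged) when the control
#' rate is zero; absolute changes are always returned.
#'
#' @param rates Named numeric vector of per-epoch rates in Hz; must include
#'   `"control"`.
#' @return Data frame with columns `epoch`, `rate_hz`, `delta_hz`,
#'   `pct_change`, `pct_defined`.
#' @export
epoch_contrast <- function(rates) {
  if (!"control" %in% names(rates)) stop("rates must include a 'control' epoch")
  ctrl <- rates[["control"]]
  data.frame(
    epoch = names(rates),
    rate_hz = as.numeric(rates),
    delta_hz = as.numeric(rates) - ctrl,
    pct_change = if (ctrl > 0) 100 * (as.numeric(rates) - ctrl) / ctrl
                 else rep(NA_real_, length(rates)),
    pct_defined = ctrl > 0,
    stringsAsFactors = FALSE)
}
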