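#' Matching parameters for DR-to-SN spike pairing
#'
#' The tolerance window is derived, never set directly: it is the electrode
#' distance divided by the slowest theoretical fiber conduction velocity
#' (defaults 4 mm / 0.1 m/s = 40 ms), the longest physiologically admissible
#' SN-to-DR latency.
#'
#' @param distance Inter-electrode distance, meters (default 0.004).
#' @param v_min Slowest admissible conduction velocity, m/s (default 0.1).
#' @param v_split A/C fiber boundary velocity, m/s (default 2.0);
#'   slower units are C-type, faster (and exactly at the boundary) A-type.
#' @param exclusive One-to-one matching (default TRUE): an SN spike can be
#'   the origin of at most one DR spike.
#' @return An object of class `"match_params"` with derived field `w`
#'   (tolerance window, seconds).
#' @export
match_params <- function(distance = 0.004, v_min = 0.1, v_split = 2.0,
                         exclusive = TRUE) {
  if (distance <= 0) stop("distance must be positive")
  if (v_min <= 0 || v_min >= v_split) stop("require 0 < v_min < v_split")
  structure(list(distance = distance, v_min = v_min, v_split = v_split,
                 exclusive = isTRUE(exclusive), w = distance / v_min),
            class = "match_params")
}

#' Match dorsal-root spikes to their spinal-nerve origin
#'
#' Each DR spike is paired with the nearest strictly preceding SN spike
#' within the tolerance window `w = distance / v_min` (minimum latency
#' rule). DR spikes are processed in ascending time; with
#' `exclusive = TRUE` an SN spike already claimed by an earlier DR spike is
#' skipped in favor of the next-nearest preceding unclaimed SN spike within
#' the window. DR spikes with no eligible SN partner are reported as
#' orphans; SN spikes with no DR partner are propagation failures.
#' Latencies must be strictly positive: simultaneous timestamps do not
#' match (orthodromic propagation only).
#'
#' @param sn_times SN spike times, seconds, sorted ascending.
#' @param dr_times DR spike times, seconds, sorted ascending.
#' @param params A [match_params()].
#' @param sn_units Optional integer vector of per-SN-spike unit labels
#'   (from [sort_spikes()]); DR spikes inherit the label of their matched
#'   SN spike.
#' @return An object of class `"match_table"`: `pairs` (data frame, one row
#'   per SN spike: `sn_index`, `sn_time`, `unit_id`, `dr_index`, `dr_time`,
#'   `latency`, `velocity`, `fiber_class`, `matched`), `orphan_dr`
#'   (indices of unmatched DR spikes), `params`, `n_sn`, `n_dr`.
#' @export
match_spikes <- function(sn_times, dr_times, params = match_params(),
                         sn_units = NULL) {
  if (!inherits(params, "match_params")) stop("params must be match_params")
  if (is.unsorted(sn_times)) stop("sn_times must be sorted ascending")
  if (is.unsorted(dr_times)) stop("dr_times must be sorted ascending")
  n_sn <- length(sn_times)
  n_dr <- length(dr_times)
  if (!is.null(sn_units) && length(sn_units) != n_sn)
    stop("sn_units must have one label per SN spike")

  w <- params$w
  claimed <- logical(n_sn)
  dr_match <- rep(NA_integer_, n_dr)
  for (j in seq_len(n_dr)) {
    d <- dr_times[j]
    i <- findInterval(d, sn_times)
    while (i >= 1L && sn_times[i] >= d) i <- i - 1L  # strictly preceding
    while (i >= 1L && d - sn_times[i] <= w) {
      if (!params$exclusive || !claimed[i]) {
        dr_match[j] <- i
        claimed[i] <- TRUE
        break
      }
      i <- i - 1L
    }
  }

  pairs <- data.frame(
    sn_index = seq_len(n_sn),
    sn_time = as.numeric(sn_times),
    unit_id = if (is.null(sn_units)) rep(NA_integer_, n_sn) else as.integer(sn_units),
    dr_index = rep(NA_integer_, n_sn),
    dr_time = rep(NA_real_, n_sn),
    latency = rep(NA_real_, n_sn),
    velocity = rep(NA_real_, n_sn),
    fiber_class = rep(NA_character_, n_sn),
    matched = FALSE,
    stringsAsFactors = FALSE)
  hit <- which(!is.na(dr_match))
  if (length(hit) > 0) {
    si <- dr_match[hit]
    pairs$dr_index[si] <- hit
    pairs$dr_time[si] <- dr_times[hit]
    lat <- dr_times[hit] - sn_times[si]
    pairs$latency[si] <- lat
    pairs$velocity[si] <- params$distance / lat
    pairs$fiber_class[si] <- classify_fiber(lat, params)
    pairs$matched[si] <- TRUE
  }
  structure(list(pairs = pairs,
                 orphan_dr = which(is.na(dr_match)),
                 params = params, n_sn = n_sn, n_dr = n_dr),
            class = "match_table")
}

#' @export
print.match_table <- function(x, ...) {
  cat(sprintf("<match_table> %d SN, %d DR spikes: %d matched, %d orphan DR, window %g ms\n",
              x$n_sn, x$n_dr, sum(x$pairs$matched), length(x$orphan_dr),
              1000 * x$params$w))
  invisible(x)
}

#' Classify fiber type from SN-DR conduction latency
#'
#' Conduction velocity is `distance / latency`; units slower than the split
#' velocity (default 2 m/s) are presumed unmyelinated C-fibers, faster ones
#' myelinated A-fibers. A velocity exactly at the boundary is assigned to A
#' (declared convention; the strict inequalities of the field's definition
#' leave it open).
#'
#' @param latency Positive latency or vector of latencies, seconds.
#' @param params A [match_params()].
#' @return Character vector of `"A"` / `"C"`.
#' @export
classify_fiber <- function(latency, params = match_params()) {
  if (any(!is.finite(latency) | latency <= 0))
    stop("latency must be strictly positive")
  velocity <- params$distance / latency
  ifelse(velocity < params$v_split, "C", "A")
}

#' Per-unit propagation success and failure
#'
#' For each sorted unit: the number of SN spikes, the number with a matching
#' DR spike, propagation success (percent matched) and failure
#' (100 - success), mean matched latency, the unit conduction velocity from
#' the median matched latency, and the fiber class of that velocity.
#' Units with zero SN spikes are excluded with a warning. Unlabeled spikes
#' (unit -1 / NA) are summarized under unit id `-1`.
#'
#' @param match A `match_table` from [match_spikes()] whose rows carry
#'   unit ids (pass `sn_units` to [match_spikes()]).
#' @param units Optional `sorted_units`; if given, its labels replace the
#'   unit ids in `match`.
#' @return Data frame of class `"propagation_summary"` with columns
#'   `unit_id`, `n_sn`, `n_matched`, `success_pct`, `failure_pct`,
#'   `mean_latency`, `velocity`, `fiber_class`.
#' @export
summarize_propagation <- function(match, units = NULL) {
  if (!inherits(match, "match_table")) stop("match must be a match_table")
  pairs <- match$pairs
  if (!is.null(units)) {
    if (!inherits(units, "sorted_units")) stop("units must be sorted_units")
    if (length(units$labels) != nrow(pairs))
      stop("unit labels do not cover the SN spikes")
    pairs$unit_id <- units$labels
  }
  uid <- pairs$unit_id
  uid[is.na(uid)] <- -1L
  ids <- sort(unique(uid))
  rows <- lapply(ids, function(u) {
    p <- pairs[uid == u, , drop = FALSE]
    n_sn <- nrow(p)
    if (n_sn == 0) return(NULL)
    n_matched <- sum(p$matched)
    lat <- p$latency[p$matched]
    med_lat <- if (n_matched > 0) stats::median(lat) else NA_real_
    data.frame(
      unit_id = u, n_sn = n_sn, n_matched = n_matched,
      success_pct = 100 * n_matched / n_sn,
      failure_pct = 100 - 100 * n_matched / n_sn,
      mean_latency = if (n_matched > 0) mean(lat) else NA_real_,
      velocity = if (n_matched > 0) match$params$distance / med_lat else NA_real_,
      fiber_class = if (n_matched > 0) classify_fiber(med_lat, match$params)
                    else NA_character_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("propagation_summary", "data.frame")
  out
}

#' Bulk relative spike-count change from SN to DR
#'
#' `(n_sn - n_dr) / n_sn * 100`: the percentage of upstream activity lost
#' (or, when negative, gained) across the ganglion. Accepts counts or rates.
#'
#' @param n_sn SN spike count or rate (must be positive).
#' @param n_dr DR spike count or rate.
#' @return Percentage change.
#' @export
pct_delta_spikes <- function(n_sn, n_dr) {
  if (any(n_sn <= 0)) stop("n_sn must be positive")
  (n_sn - n_dr) / n_sn * 100
}

#' Regress per-unit filtering on spike prominence
#'
#' Ordinary least squares of the per-unit relative SN-to-DR rate change on
#' per-unit spike prominence; tests whether large-amplitude units are
#' filtered more.
#'
#' @param prominence Per-unit prominence values (>= 3 units).
#' @param pct_delta Per-unit percent spike-rate change.
#' @return List with `slope`, `intercept`, `r2`.
#' @export
correlate_prominence_filtering <- function(prominence, pct_delta) {
  if (length(prominence) != length(pct_delta))
    stop("inputs must have equal length")
  ok <- is.finite(prominence) & is.finite(pct_delta)
  if (sum(ok) < 3) stop("insufficient data: need at least 3 units")
  ols_fit(prominence[ok], pct_delta[ok])
}

ols_fit <- function(x, y) {
  ssy <- sum((y - mean(y))^2)
  if (ssy < 1e-300)  # constant response: flat line explains nothing
    return(list(slope = 0, intercept = mean(y), r2 = 0))
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  r2 <- 1 - sum(stats::residuals(fit)^2) / ssy
  list(slope = unname(cf[2]), intercept = unname(cf[1]), r2 = r2)
}
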