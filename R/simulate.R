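#' Specify a simulated firing unit
#'
#' A unit fires as an (optionally force-driven, inhomogeneous) Poisson
#' process on the spinal nerve; each spike propagates to the dorsal root
#' with a fixed conduction delay (`distance / velocity`) unless it fails,
#' a per-spike Bernoulli event whose probability can depend on the epoch
#' (the mechanism used to emulate pharmacological modulation of
#' T-junction filtering).
#'
#' @param unit_id Integer unit label.
#' @param amplitude Template peak amplitude, arbitrary units (sign sets the
#'   leading phase polarity).
#' @param width Template duration, seconds (default 1.2 ms).
#' @param base_rate Baseline Poisson rate, Hz.
#' @param force_gain Rate gain in Hz per gram of applied force (0 for
#'   non-mechanosensitive units).
#' @param velocity Conduction velocity, m/s.
#' @param failure_prob Bernoulli propagation-failure probability: a single
#'   number, or a named vector/list keyed by epoch name (unnamed epochs fall
#'   back to `"control"`, then to the first element).
#' @return An object of class `"unit_spec"`.
#' @export
unit_spec <- function(unit_id, amplitude = 8, width = 1.2e-3, base_rate = 10,
                      force_gain = 0, velocity = 1,
                      failure_prob = 0) {
  if (base_rate < 0) stop("base_rate must be >= 0")
  if (velocity <= 0) stop("velocity must be positive")
  fp <- unlist(failure_prob)
  if (any(fp < 0 | fp > 1)) stop("failure_prob must lie in [0, 1]")
  structure(list(unit_id = as.integer(unit_id), amplitude = amplitude,
                 width = width, base_rate = base_rate,
                 force_gain = force_gain, velocity = velocity,
                 failure_prob = fp),
            class = "unit_spec")
}

failure_at_epoch <- function(fp, epoch_name) {
  if (length(fp) == 1 && is.null(names(fp))) return(unname(fp))
  if (!is.na(epoch_name) && epoch_name %in% names(fp)) return(unname(fp[[epoch_name]]))
  if ("control" %in% names(fp)) return(unname(fp[["control"]]))
  unname(fp[[1]])
}

epoch_of <- function(t, epochs) {
  for (e in epochs)
    if (t >= e$start && t < e$start + e$duration) return(e$name)
  NA_character_
}

#' Ramp-and-hold force stimulus profile
#'
#' Emulates a calibrated paw-pressure stimulus: linear rise to `peak` grams,
#' a hold phase, and a linear release; zero elsewhere.
#'
#' @param onset Ramp start, seconds.
#' @param rise Ramp duration, seconds.
#' @param hold Hold duration, seconds.
#' @param fall Release duration, seconds.
#' @param peak Plateau force, grams.
#' @return A vectorized function of time returning force in grams.
#' @export
ramp_hold_force <- function(onset = 10, rise = 2, hold = 10, fall = 2,
                            peak = 125) {
  function(t) {
    f <- numeric(length(t))
    up <- t >= onset & t < onset + rise
    f[up] <- peak * (t[up] - onset) / rise
    hd <- t >= onset + rise & t < onset + rise + hold
    f[hd] <- peak
    dn <- t >= onset + rise + hold & t < onset + rise + hold + fall
    f[dn] <- peak * (1 - (t[dn] - onset - rise - hold) / fall)
    f
  }
}

#' Simulate ground-truth SN/DR spike trains
#'
#' Per unit, SN spike times are drawn from an inhomogeneous Poisson process
#' with rate `base_rate + force_gain * force(t)` (thinning algorithm),
#' then thinned to enforce a per-unit refractory period. Each SN spike
#' propagates to the DR with probability `1 - failure_prob(epoch)`; its DR
#' time is the SN time plus `distance / velocity` plus truncated Gaussian
#' jitter (the DR time always stays after the SN time). Fully reproducible
#' given `seed`.
#'
#' @param units List of [unit_spec()]s (or a single one).
#' @param duration Simulation length, seconds.
#' @param epochs Optional list of [epoch_spec()]s used to look up
#'   epoch-dependent failure probabilities.
#' @param force Optional force profile: a function of time (seconds ->
#'   grams), e.g. [ramp_hold_force()].
#' @param jitter_sd Conduction jitter SD, seconds (default 0.1 ms).
#' @param distance Electrode distance, meters (default 0.004).
#' @param refractory Per-unit refractory period, seconds (default 1 ms);
#'   set 0 to disable.
#' @param seed Integer seed.
#' @return An object of class `"ground_truth"`: `sn` (data frame `time`,
#'   `unit_id`, `epoch`, `failed`), `dr` (data frame `time`, `unit_id`,
#'   `origin` = row index into `sn`), plus the generating parameters.
#' @export
simulate_trains <- function(units, duration, epochs = NULL, force = NULL,
                            jitter_sd = 1e-4, distance = 0.004,
                            refractory = 1e-3, seed = NULL) {
  if (inherits(units, "unit_spec")) units <- list(units)
  if (duration <= 0) stop("duration must be positive")
  if (!is.null(epochs)) check_epochs(epochs)
  if (!is.null(seed)) set.seed(seed)

  sn_list <- list()
  for (u in units) {
    rate_fun <- if (is.null(force) || u$force_gain == 0) {
      function(t) rep(u$base_rate, length(t))
    } else {
      function(t) u$base_rate + u$force_gain * force(t)
    }
    grid <- seq(0, duration, length.out = max(1000L, ceiling(duration * 100)))
    lam <- rate_fun(grid)
    if (any(lam < 0)) {
      warning("negative instantaneous rate clipped to 0")
      lam <- pmax(lam, 0)
    }
    lam_max <- max(lam)
    times <- numeric(0)
    if (lam_max > 0) {
      n_cand <- stats::rpois(1, lam_max * duration)
      cand <- sort(stats::runif(n_cand, 0, duration))
      acc <- stats::runif(n_cand) < pmax(rate_fun(cand), 0) / lam_max
      times <- cand[acc]
      if (refractory > 0 && length(times) > 1) {
        kept <- times[1]
        last <- times[1]
        for (tt in times[-1]) {
          if (tt - last >= refractory) {
            kept <- c(kept, tt)
            last <- tt
          }
        }
        times <- kept
      }
    }
    if (length(times) == 0) next
    ep <- if (is.null(epochs)) rep(NA_character_, length(times))
          else vapply(times, epoch_of, character(1), epochs = epochs)
    p_fail <- vapply(ep, function(e) failure_at_epoch(u$failure_prob, e),
                     numeric(1))
    failed <- stats::runif(length(times)) < p_fail
    sn_list[[length(sn_list) + 1]] <- data.frame(
      time = times, unit_id = u$unit_id, epoch = ep, failed = failed,
      velocity = u$velocity, stringsAsFactors = FALSE)
  }
  sn <- if (length(sn_list) > 0) do.call(rbind, sn_list) else
    data.frame(time = numeric(0), unit_id = integer(0),
               epoch = character(0), failed = logical(0),
               velocity = numeric(0))
  o <- order(sn$time)
  sn <- sn[o, , drop = FALSE]
  rownames(sn) <- NULL

  prop <- which(!sn$failed)
  dr_time <- numeric(length(prop))
  if (length(prop) > 0) {
    lat <- distance / sn$velocity[prop]
    jit <- if (jitter_sd > 0) stats::rnorm(length(prop), 0, jitter_sd) else 0
    dr_time <- sn$time[prop] + lat + jit
    # truncate jitter: propagation is orthodromic, DR strictly after SN
    bad <- which(dr_time <= sn$time[prop])
    while (length(bad) > 0) {
      dr_time[bad] <- sn$time[prop[bad]] + lat[bad] +
        stats::rnorm(length(bad), 0, jitter_sd)
      bad <- bad[dr_time[bad] <= sn$time[prop[bad]]]
    }
  }
  dr <- data.frame(time = dr_time, unit_id = sn$unit_id[prop],
                   origin = prop)
  dr <- dr[order(dr$time), , drop = FALSE]
  rownames(dr) <- NULL

  structure(list(sn = sn[, c("time", "unit_id", "epoch", "failed")],
                 dr = dr,
                 failed_sn = which(sn$failed),
                 units = units, duration = duration, distance = distance,
                 jitter_sd = jitter_sd, epochs = epochs),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d SN spikes (%d units), %d DR spikes, %d programmed failures over %g s\n",
              nrow(x$sn), length(unique(x$sn$unit_id)), nrow(x$dr),
              length(x$failed_sn), x$duration))
  invisible(x)
}

#' Parametric biphasic spike template
#'
#' Difference of two Gaussians: a main lobe of the requested amplitude
#' followed by a slower opposite-polarity lobe, normalized so the extreme
#' value equals `amplitude`. A negative amplitude flips the polarity.
#'
#' @param amplitude Peak amplitude, arbitrary units.
#' @param width Total template duration, seconds.
#' @param fs Sampling rate, Hz.
#' @return Numeric template vector (`round(width * fs)` samples, >= 8).
#' @export
biphasic_template <- function(amplitude, width, fs) {
  n <- round(width * fs)
  if (n < 8) stop("sampling rate too low to represent the template (< 8 samples)")
  t <- seq_len(n) / n
  s1 <- 0.08
  s2 <- 0.16
  shape <- exp(-(t - 0.3)^2 / (2 * s1^2)) - 0.6 * exp(-(t - 0.55)^2 / (2 * s2^2))
  amplitude * shape / max(abs(shape))
}

#' Render ground-truth events into voltage traces
#'
#' Adds each unit's template at its event times on the SN and DR channels
#' (linear superposition; coincident events sum), plus additive Gaussian
#' noise, yielding a [recording()] that exercises the full
#' detection/sorting/matching chain. The template's alignment extremum is
#' placed at the event sample.
#'
#' @param gt A `ground_truth` from [simulate_trains()].
#' @param fs Sampling rate, Hz (default 30000).
#' @param noise_sd Gaussian noise SD, arbitrary units.
#' @param noise_band Passband of the background noise, Hz: Gaussian noise is
#'   band-limited to the acquisition band (default `c(100, 3000)`, the
#'   hardware filter of the recording chain) and rescaled to exactly
#'   `noise_sd`. `NULL` gives white noise.
#' @param force Optional force profile function; rendered as the force
#'   channel.
#' @param seed Integer seed for the noise.
#' @return A [recording()].
#' @export
render_traces <- function(gt, fs = 30000, noise_sd = 1,
                          noise_band = c(100, 3000), force = NULL,
                          seed = NULL) {
  if (!inherits(gt, "ground_truth")) stop("gt must be a ground_truth")
  if (!is.null(seed)) set.seed(seed)
  n <- ceiling(gt$duration * fs)

  tmpl <- lapply(gt$units, function(u) {
    tp <- biphasic_template(u$amplitude, u$width, fs)
    list(shape = tp, peak = which.max(abs(tp)))
  })
  names(tmpl) <- vapply(gt$units, function(u) as.character(u$unit_id),
                        character(1))

  make_noise <- function() {
    if (noise_sd <= 0) return(numeric(n))
    x <- stats::rnorm(n, 0, noise_sd)
    if (!is.null(noise_band)) {
      hi <- min(noise_band[2], 0.45 * fs)  # keep the band below Nyquist
      x <- filter_trace(x, fs, filter_spec("bandpass",
                                           corner_low = noise_band[1],
                                           corner_high = hi,
                                           order = 2))
      x <- x * noise_sd / stats::sd(x)
    }
    x
  }
  sn_tr <- make_noise()
  dr_tr <- make_noise()
  add_events <- function(trace, times, unit_ids) {
    for (k in seq_along(times)) {
      tp <- tmpl[[as.character(unit_ids[k])]]
      at <- round(times[k] * fs) + 1L
      i0 <- at - tp$peak + 1L
      idx <- seq.int(i0, i0 + length(tp$shape) - 1L)
      ok <- idx >= 1L & idx <= n
      trace[idx[ok]] <- trace[idx[ok]] + tp$shape[ok]
    }
    trace
  }
  sn_tr <- add_events(sn_tr, gt$sn$time, gt$sn$unit_id)
  dr_tr <- add_events(dr_tr, gt$dr$time, gt$dr$unit_id)
  force_tr <- if (!is.null(force)) force((seq_len(n) - 1) / fs) else NULL
  recording(sn_tr, dr_tr, force_trace = force_tr, sampling_rate = fs,
            electrode_distance = gt$distance)
}

#' Score a match table against simulator ground truth
#'
#' Pair accuracy is the percentage of matched DR spikes whose assigned SN
#' spike is their true origin; also reported are the fraction of truly
#' propagated spikes recovered by the matcher, the DR rate error, and the
#' per-unit estimated vs programmed failure percentage.
#'
#' @param gt A `ground_truth` (bare-train mode: the match was computed on
#'   `gt$sn$time` and `gt$dr$time` directly).
#' @param match A `match_table` from [match_spikes()].
#' @return List with `pair_accuracy` (%), `recovered_fraction`,
#'   `rate_error_hz`, `per_unit` (data frame `unit_id`, `true_failure_pct`,
#'   `est_failure_pct`), and `defined` (FALSE when no DR spike was matched).
#' @export
score_matching <- function(gt, match) {
  if (!inherits(gt, "ground_truth")) stop("gt must be a ground_truth")
  if (!inherits(match, "match_table")) stop("match must be a match_table")
  pairs <- match$pairs
  matched <- which(pairs$matched)
  if (length(matched) == 0) {
    return(list(pair_accuracy = NA_real_, recovered_fraction = 0,
                rate_error_hz = nrow(gt$dr) / gt$duration, per_unit = NULL,
                defined = FALSE))
  }
  # truth: DR spike j originates from SN spike gt$dr$origin[j]
  assigned_sn <- pairs$sn_index[matched]
  dr_idx <- pairs$dr_index[matched]
  correct <- assigned_sn == gt$dr$origin[dr_idx]
  n_prop <- nrow(gt$dr)
  per_unit <- do.call(rbind, lapply(unique(gt$sn$unit_id), function(u) {
    in_u <- gt$sn$unit_id == u
    est_matched <- sum(pairs$matched[in_u])
    data.frame(unit_id = u,
               true_failure_pct = 100 * mean(gt$sn$failed[in_u]),
               est_failure_pct = 100 * (1 - est_matched / sum(in_u)))
  }))
  list(pair_accuracy = 100 * mean(correct),
       recovered_fraction = sum(correct) / n_prop,
       rate_error_hz = abs(sum(pairs$matched) - n_prop) / gt$duration,
       per_unit = per_unit,
       defined = TRUE)
}

#' Matching-accuracy benchmark over a rate x failure grid
#'
#' Bare-train benchmark of the minimum-latency matcher: single-unit Poisson
#' SN trains at each firing rate, propagated with fixed conduction latency
#' and per-spike Bernoulli failure, matched, and scored against ground
#' truth. Reports the mean pair accuracy per grid cell across seeds.
#'
#' @param rates Poisson firing rates, Hz (default `c(10, 25, 50, 100)`).
#' @param failures Programmed failure fractions (default
#'   `c(0, 0.25, 0.5, 0.8)`).
#' @param duration Train duration per run, seconds (default 60).
#' @param n_seeds Seeds per grid cell (default 10).
#' @param velocity Unit conduction velocity, m/s (default 2).
#' @param params Matching parameters ([match_params()]).
#' @param jitter_sd Conduction jitter SD, seconds.
#' @param seed Base seed; per-run seeds are derived deterministically.
#' @return List with `cells` (data frame `rate`, `failure`,
#'   `mean_accuracy`, `sd_accuracy`, `n_runs`), `runs` (per-run results)
#'   and `min_cell_mean`.
#' @export
benchmark_matching <- function(rates = c(10, 25, 50, 100),
                               failures = c(0, 0.25, 0.5, 0.8),
                               duration = 60, n_seeds = 10, velocity = 2,
                               params = match_params(), jitter_sd = 1e-4,
                               seed = 1) {
  grid <- expand.grid(rate = rates, failure = failures)
  runs <- list()
  for (g in seq_len(nrow(grid))) {
    for (s in seq_len(n_seeds)) {
      run_seed <- (seed * 7919L + g * 101L + s) %% .Machine$integer.max
      u <- unit_spec(1, base_rate = grid$rate[g], velocity = velocity,
                     failure_prob = grid$failure[g])
      gt <- simulate_trains(u, duration = duration, jitter_sd = jitter_sd,
                            distance = params$distance, seed = run_seed)
      mt <- match_spikes(gt$sn$time, gt$dr$time, params)
      sc <- score_matching(gt, mt)
      runs[[length(runs) + 1]] <- data.frame(
        rate = grid$rate[g], failure = grid$failure[g], seed = run_seed,
        accuracy = sc$pair_accuracy, n_sn = nrow(gt$sn))
    }
  }
  runs <- do.call(rbind, runs)
  cells <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    r <- runs[runs$rate == grid$rate[g] & runs$failure == grid$failure[g], ]
    data.frame(rate = grid$rate[g], failure = grid$failure[g],
               mean_accuracy = mean(r$accuracy, na.rm = TRUE),
               sd_accuracy = stats::sd(r$accuracy),
               n_runs = nrow(r))
  }))
  list(cells = cells, runs = runs,
       min_cell_mean = min(cells$mean_accuracy))
}

#' The three-unit A/C validation scenario
#'
#' One fast myelinated A-unit (10 m/s, 10 Hz, failure 0.1) and two slow
#' unmyelinated C-units (0.5 and 1 m/s, 5 Hz each, failure 0.5), with
#' distinct biphasic templates whose weakest peak sits at about 8 times the
#' noise MAD. This is the end-to-end benchmark scenario: rendered to traces
#' and pushed through filter, detection, sorting and matching.
#'
#' @return List with `units`, `noise_sd`, `duration`.
#' @export
three_unit_scenario <- function() {
  list(units = list(
         unit_spec(1, amplitude = 9, width = 0.7e-3, base_rate = 10,
                   velocity = 10, failure_prob = 0.1),
         unit_spec(2, amplitude = -8, width = 1.4e-3, base_rate = 5,
                   velocity = 0.5, failure_prob = 0.5),
         unit_spec(3, amplitude = 7, width = 2.0e-3, base_rate = 5,
                   velocity = 1, failure_prob = 0.5)),
       noise_sd = 1.3,
       duration = 60)
}
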