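test_that("lossless propagation copies every SN spike to the DR at fixed latency", {
  u <- unit_spec(1, base_rate = 20, velocity = 2, failure_prob = 0)
  gt <- simulate_trains(u, duration = 100, jitter_sd = 0, seed = 1)
  expect_equal(nrow(gt$dr), nrow(gt$sn))
  lat <- gt$dr$time - gt$sn$time[gt$dr$origin]
  expect_true(all(abs(lat - 0.004 / 2) < 1e-12))
  expect_length(gt$failed_sn, 0)
})

test_that("total failure yields zero DR events", {
  u <- unit_spec(1, base_rate = 20, velocity = 2, failure_prob = 1)
  gt <- simulate_trains(u, duration = 50, seed = 2)
  expect_gt(nrow(gt$sn), 0)
  expect_equal(nrow(gt$dr), 0)
})

test_that("the realized failure fraction concentrates on the programmed rate", {
  fr <- vapply(1:50, function(s) {
    gt <- simulate_trains(unit_spec(1, base_rate = 20, velocity = 2,
                                    failure_prob = 0.5),
                          duration = 100, seed = s)
    mean(gt$sn$failed)
  }, numeric(1))
  expect_equal(mean(fr), 0.5, tolerance = 0.04)  # 0.5 +/- 0.02 absolute
})

test_that("simulation is bit-identical given the seed", {
  u <- list(unit_spec(1, base_rate = 15, velocity = 1, failure_prob = 0.3),
            unit_spec(2, base_rate = 5, velocity = 8, failure_prob = 0.1))
  g1 <- simulate_trains(u, duration = 20, seed = 11)
  g2 <- simulate_trains(u, duration = 20, seed = 11)
  expect_identical(g1$sn, g2$sn)
  expect_identical(g1$dr, g2$dr)
  r1 <- render_traces(g1, fs = 30000, noise_sd = 1, seed = 5)
  r2 <- render_traces(g2, fs = 30000, noise_sd = 1, seed = 5)
  expect_identical(r1$sn_trace, r2$sn_trace)
})

test_that("with the refractory period disabled, counts are Poisson-dispersed", {
  gt <- simulate_trains(unit_spec(1, base_rate = 20, velocity = 1),
                        duration = 10000, refractory = 0, seed = 3)
  counts <- tabulate(findInterval(gt$sn$time, 0:9999), nbins = 10000)
  disp <- var(counts) / mean(counts)
  expect_gte(disp, 0.9)
  expect_lte(disp, 1.1)
})

test_that("epoch-dependent failure probabilities apply per epoch", {
  eps <- list(epoch_spec("control", 0, 30), epoch_spec("stimulus", 30, 30))
  u <- unit_spec(1, base_rate = 30, velocity = 1,
                 failure_prob = c(control = 0.1, stimulus = 0.8))
  gt <- simulate_trains(u, duration = 60, epochs = eps, seed = 21)
  f_ctrl <- mean(gt$sn$failed[gt$sn$epoch == "control"])
  f_stim <- mean(gt$sn$failed[gt$sn$epoch == "stimulus"])
  expect_equal(f_ctrl, 0.1, tolerance = 0.5)
  expect_equal(f_stim, 0.8, tolerance = 0.1)
  expect_gt(f_stim, f_ctrl)
})

test_that("rendering places templates exactly and sums coincident events", {
  fs <- 30000
  u <- unit_spec(1, amplitude = 5, width = 1e-3, base_rate = 1, velocity = 1)
  gt <- structure(list(
    sn = data.frame(time = 0.5, unit_id = 1L, epoch = NA, failed = FALSE),
    dr = data.frame(time = numeric(0), unit_id = integer(0), origin = integer(0)),
    failed_sn = integer(0), units = list(u), duration = 1, distance = 0.004,
    jitter_sd = 0, epochs = NULL), class = "ground_truth")
  rec <- render_traces(gt, fs = fs, noise_sd = 0)
  tpl <- biphasic_template(5, 1e-3, fs)
  at <- round(0.5 * fs) + 1
  expect_equal(max(abs(rec$sn_trace)), max(abs(tpl)))
  expect_equal(rec$sn_trace[at], tpl[which.max(abs(tpl))])
  expect_true(all(rec$dr_trace == 0))
  expect_equal(sum(rec$sn_trace != 0), sum(tpl != 0))

  # two coincident events superpose linearly
  gt2 <- gt
  gt2$sn <- data.frame(time = c(0.5, 0.5), unit_id = 1L, epoch = NA,
                       failed = FALSE)
  rec2 <- render_traces(gt2, fs = fs, noise_sd = 0)
  expect_equal(rec2$sn_trace, 2 * rec$sn_trace)
})

test_that("pure rendered noise has the requested scale and band-limits apply", {
  u <- unit_spec(1, base_rate = 0, velocity = 1)
  gt <- simulate_trains(u, duration = 34, seed = 4)
  rec <- render_traces(gt, fs = 30000, noise_sd = 1.5, seed = 4)
  expect_equal(sd(rec$sn_trace), 1.5, tolerance = 0.02)
  recw <- render_traces(gt, fs = 30000, noise_sd = 2, noise_band = NULL, seed = 5)
  expect_equal(sd(recw$sn_trace), 2, tolerance = 0.02)
})

test_that("a sampling rate too low for the template is a parameter error", {
  u <- unit_spec(1, amplitude = 5, width = 1e-3, base_rate = 5, velocity = 1)
  gt <- simulate_trains(u, duration = 2, seed = 5)
  expect_error(render_traces(gt, fs = 4000), "8 samples")
})

test_that("scoring reports perfect accuracy on a lossless, unambiguous scenario", {
  # velocity 4 m/s -> 1 ms latency, inside the refractory period: no
  # same-unit spike can intervene, so every match is unambiguous
  gt <- simulate_trains(unit_spec(1, base_rate = 5, velocity = 4,
                                  failure_prob = 0),
                        duration = 60, jitter_sd = 0, seed = 6)
  mt <- match_spikes(gt$sn$time, gt$dr$time, match_params())
  sc <- score_matching(gt, mt)
  expect_true(sc$defined)
  expect_gte(sc$pair_accuracy, 99)

  # empty match set flagged undefined
  gt0 <- simulate_trains(unit_spec(1, base_rate = 5, velocity = 2,
                                   failure_prob = 1),
                         duration = 20, seed = 7)
  mt0 <- match_spikes(gt0$sn$time, gt0$dr$time, match_params())
  expect_false(score_matching(gt0, mt0)$defined)
})

test_that("negative instantaneous rates are clipped with a warning", {
  force <- function(t) rep(1, length(t))
  u <- unit_spec(1, base_rate = 2, force_gain = -5, velocity = 1)
  expect_warning(simulate_trains(u, duration = 5, force = force, seed = 8),
                 "clipped")
})
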