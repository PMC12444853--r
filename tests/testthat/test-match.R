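test_that("worked matching examples behave as specified", {
  p <- match_params()  # w = 40 ms
  # SN at 0, 10, 20 ms; DR at 5, 25 ms
  mt <- match_spikes(c(0, 0.010, 0.020), c(0.005, 0.025), p)
  expect_equal(mt$pairs$dr_index, c(1L, NA, 2L))
  expect_equal(mt$pairs$latency, c(0.005, NA, 0.005))
  expect_equal(sum(mt$pairs$matched) / mt$n_sn * 100, 66.67, tolerance = 0.01)

  # outside the window: no match, one orphan DR spike
  mt2 <- match_spikes(0, 0.050, p)
  expect_false(any(mt2$pairs$matched))
  expect_equal(mt2$orphan_dr, 1L)

  # minimum-latency rule picks the nearest preceding spike
  mt3 <- match_spikes(c(0, 0.004999), 0.005, p)
  expect_equal(mt3$pairs$dr_index, c(NA, 1L))
  expect_equal(mt3$pairs$velocity[2], 0.004 / 0.000001, tolerance = 1e-6)
  expect_equal(mt3$pairs$fiber_class[2], "A")

  expect_error(match_spikes(c(2, 1), c(3)), "sorted")
})

test_that("matching agrees with the brute-force assignment oracle on micro-instances", {
  set.seed(123)
  for (i in 1:60) {
    n_sn <- sample(1:10, 1)
    n_dr <- sample(1:10, 1)
    sn <- sort(runif(n_sn, 0, 0.3))
    dr <- sort(runif(n_dr, 0, 0.3))
    w <- runif(1, 0.005, 0.06)
    p <- match_params(distance = 0.004, v_min = 0.004 / w)
    got <- match_spikes(sn, dr, p)
    want <- oracle_match(sn, dr, p$w)
    got_assign <- rep(NA_integer_, n_dr)
    hit <- which(got$pairs$matched)
    got_assign[got$pairs$dr_index[hit]] <- hit
    expect_identical(got_assign, as.integer(want))
  }
})

test_that("matching conserves counts and shrinking the window is monotone", {
  set.seed(77)
  sn <- sort(runif(300, 0, 60))
  dr <- sort(runif(200, 0, 60))
  prev <- Inf
  for (v_min in c(0.1, 0.5, 1, 1.9)) {
    mt <- match_spikes(sn, dr, match_params(v_min = v_min))
    n_matched <- sum(mt$pairs$matched)
    expect_lte(n_matched, min(length(sn), length(dr)))
    expect_equal(length(mt$orphan_dr), length(dr) - n_matched)
    expect_lte(n_matched, prev)   # smaller window, fewer matches
    prev <- n_matched
  }
})

test_that("fiber classification splits at 2 m/s with the boundary going to A", {
  p <- match_params(distance = 0.004, v_split = 2)
  expect_equal(classify_fiber(0.004, p), "C")   # 1 m/s
  expect_equal(classify_fiber(0.001, p), "A")   # 4 m/s
  expect_equal(classify_fiber(0.002, p), "A")   # exactly 2 m/s
  expect_error(classify_fiber(0, p), "positive")
  expect_error(classify_fiber(-0.001, p), "positive")
})

test_that("propagation summary computes per-unit success and failure", {
  # unit 1: 10 SN spikes, 7 matched; unit 2: all matched
  sn <- seq(0, by = 0.05, length.out = 15)
  units <- c(rep(1L, 10), rep(2L, 5))
  dr <- c(sn[c(1:7)] + 0.004, sn[11:15] + 0.001)
  mt <- match_spikes(sn, sort(dr), match_params(), sn_units = units)
  s <- summarize_propagation(mt)
  expect_equal(s$success_pct[s$unit_id == 1], 70)
  expect_equal(s$failure_pct[s$unit_id == 1], 30)
  expect_equal(s$success_pct[s$unit_id == 2], 100)
  expect_equal(s$fiber_class, c("C", "A"))
  expect_equal(s$velocity[s$unit_id == 1], 1)
})

test_that("estimated failure matches a programmed Bernoulli rate within binomial error", {
  gt <- simulate_trains(unit_spec(1, base_rate = 20, velocity = 2,
                                  failure_prob = 0.4),
                        duration = 60, seed = 42)
  mt <- match_spikes(gt$sn$time, gt$dr$time, match_params(),
                     sn_units = gt$sn$unit_id)
  s <- summarize_propagation(mt)
  expect_gt(nrow(gt$sn), 1000)
  expect_equal(s$failure_pct, 40, tolerance = 0.1)  # 40 +/- 4 absolute
})

test_that("percent spike-count change follows its defining formula", {
  expect_equal(pct_delta_spikes(100, 50), 50)
  expect_equal(pct_delta_spikes(10, 10), 0)
  expect_equal(pct_delta_spikes(25.4, 10.7), (25.4 - 10.7) / 25.4 * 100)
  expect_equal(pct_delta_spikes(25.4, 10.7), 57.87, tolerance = 0.01)
  expect_error(pct_delta_spikes(0, 5), "positive")
})

test_that("prominence-filtering regression returns exact OLS results", {
  x <- c(1, 2, 3, 4, 5)
  r <- correlate_prominence_filtering(x, 2 * x + 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  expect_equal(r$r2, 1)

  r2 <- correlate_prominence_filtering(x, rep(3, 5))
  expect_equal(r2$slope, 0)
  expect_equal(r2$r2, 0)

  expect_error(correlate_prominence_filtering(1:2, 1:2), "3 units")
})

test_that("a programmed amplitude-failure relation is recovered in sign", {
  hits <- 0
  for (s in 1:20) {
    amps <- c(4, 6, 8, 10, 12)
    units <- lapply(seq_along(amps), function(i)
      unit_spec(i, amplitude = amps[i], base_rate = 8, velocity = 1 + i / 2,
                failure_prob = 0.05 + 0.06 * amps[i]))  # failure rises with amplitude
    gt <- simulate_trains(units, duration = 40, seed = 500 + s)
    mt <- match_spikes(gt$sn$time, gt$dr$time, match_params(),
                       sn_units = gt$sn$unit_id)
    su <- summarize_propagation(mt)
    fit <- correlate_prominence_filtering(amps[su$unit_id], su$failure_pct)
    hits <- hits + (fit$slope > 0)
  }
  expect_gte(hits, 19)
})
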