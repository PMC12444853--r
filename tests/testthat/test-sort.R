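test_that("Haar transform is orthonormal and complete", {
  set.seed(5)
  for (n in c(16, 64, 72)) {
    x <- rnorm(n)
    d <- haar_dwt(x)
    # energy preserved (zero-padding adds none)
    expect_equal(sum(d^2), sum(x^2), tolerance = 1e-12)
  }
  # keeping all coefficients returns a permutation of the full decomposition
  wf <- matrix(rnorm(5 * 32), 5, 32)
  full <- t(apply(wf, 1, haar_dwt))
  feats <- wavelet_features(wf, n_keep = 32)
  idx <- attr(feats, "coef_index")
  expect_setequal(idx, 1:32)
  expect_equal(feats, full[, idx], ignore_attr = TRUE)
})

test_that("wavelet features linearly separate two distinct templates", {
  t1 <- test_template(10, 12)
  t2 <- test_template(-8, 30)
  set.seed(9)
  wf <- rbind(t(replicate(50, t1 + rnorm(72, 0, 0.5))),
              t(replicate(50, t2 + rnorm(72, 0, 0.5))))
  feats <- wavelet_features(wf, n_keep = 10)
  truth <- rep(1:2, each = 50)
  # oracle: exhaustive threshold search over kept coefficients
  separable <- any(apply(feats, 2, function(v) {
    cuts <- sort(v)
    any(vapply(cuts[-length(cuts)] + diff(cuts) / 2, function(cut) {
      g <- (v > cut) + 1
      all(g == truth) || all(g == 3 - truth)
    }, logical(1)))
  }))
  expect_true(separable)
})

test_that("identical waveforms give constant features and one cluster", {
  wf <- matrix(rep(test_template(5, 16), each = 40), nrow = 40, byrow = FALSE)
  wf <- t(replicate(40, test_template(5, 16)))
  feats <- wavelet_features(wf, n_keep = 10)
  expect_true(all(apply(feats, 2, sd) < 1e-10))
  su <- cluster_units(feats, waveforms = wf, min_cluster_size = 20)
  expect_equal(su$n_units, 1)
})

test_that("n_keep beyond the decomposition length is a parameter error", {
  wf <- matrix(rnorm(10 * 32), 10, 32)
  expect_error(wavelet_features(wf, n_keep = 200), "n_keep")
  expect_error(wavelet_features(wf[1, , drop = FALSE]), "at least 2")
  expect_error(wavelet_features(matrix(rnorm(20), 2, 10)), ">= 16")
})

make_sorted_mix <- function(n_units, n_each = 200, noise = 0.8, seed = 1) {
  tpls <- list(test_template(10, 12), test_template(-8, 30),
               test_template(6, 20), test_template(-11, 45))[seq_len(n_units)]
  set.seed(seed)
  wf <- do.call(rbind, lapply(tpls, function(tp)
    t(replicate(n_each, tp + rnorm(72, 0, noise)))))
  list(wf = wf, truth = rep(seq_len(n_units), each = n_each))
}

test_that("three well-separated units are recovered with high label accuracy", {
  mix <- make_sorted_mix(3, 200, noise = 0.8, seed = 2)
  su <- sort_spikes(structure(list(waveforms = mix$wf, align_index = 25L,
                                   channel = "SN", times = seq_len(600) * 1e-2,
                                   prominences = compute_prominence(mix$wf),
                                   fs = 30000,
                                   threshold = list(median = 0, mad = 0.54,
                                                    threshold_low = -3.2,
                                                    threshold_high = 3.2)),
                              class = "spike_train"), seed = 1)
  expect_equal(su$n_units, 3)
  expect_gte(label_accuracy(su$labels, mix$truth), 0.95)
  expect_equal(nrow(su$templates), 3)
})

test_that("the selected unit count tracks the true count", {
  for (u in 1:3) {
    hits <- 0
    for (s in 1:5) {
      mix <- make_sorted_mix(u, 150, noise = 0.8, seed = 10 * u + s)
      feats <- wavelet_features(mix$wf, n_keep = 10)
      su <- cluster_units(feats, waveforms = mix$wf, seed = s)
      hits <- hits + (su$n_units == u)
    }
    expect_gte(hits, 4)
  }
})

test_that("too few spikes leave everything unassigned with a warning", {
  mix <- make_sorted_mix(1, 10, seed = 3)
  feats <- wavelet_features(mix$wf, n_keep = 10)
  expect_warning(su <- cluster_units(feats, waveforms = mix$wf,
                                     min_cluster_size = 20), "unassigned")
  expect_true(all(su$labels == -1L))
  expect_equal(su$n_units, 0)
})

test_that("clustering is permutation invariant and seed-deterministic", {
  mix <- make_sorted_mix(2, 150, seed = 4)
  feats <- wavelet_features(mix$wf, n_keep = 10)
  su1 <- cluster_units(feats, waveforms = mix$wf, seed = 1)
  su2 <- cluster_units(feats, waveforms = mix$wf, seed = 1)
  expect_identical(su1$labels, su2$labels)

  set.seed(99)
  perm <- sample(nrow(feats))
  su3 <- cluster_units(feats[perm, ], waveforms = mix$wf[perm, ], seed = 1)
  # same partition up to label names: co-membership must agree
  same1 <- outer(su1$labels[perm], su1$labels[perm], "==")
  same3 <- outer(su3$labels, su3$labels, "==")
  expect_true(all(same1 == same3))
})
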