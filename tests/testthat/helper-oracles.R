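# Independent oracles used across tests. These deliberately do not share
# code with the package implementation.

# Brute-force matching oracle: enumerate every admissible one-to-one
# assignment of DR spikes to strictly preceding SN spikes within window w,
# then pick the assignment that is lexicographically optimal in DR time
# order, where for each DR spike "matched at smaller latency" beats
# "matched at larger latency" beats "unmatched". Exponential; use only for
# <= 12 spikes per channel.
oracle_match <- function(sn, dr, w) {
  n_dr <- length(dr)
  best <- NULL
  best_key <- NULL
  # key per DR spike: latency if matched, +Inf if unmatched
  assign_key <- function(a) {
    vapply(seq_len(n_dr), function(j)
      if (is.na(a[j])) Inf else dr[j] - sn[a[j]], numeric(1))
  }
  lex_less <- function(k1, k2) {
    for (i in seq_along(k1)) {
      if (k1[i] < k2[i]) return(TRUE)
      if (k1[i] > k2[i]) return(FALSE)
    }
    FALSE
  }
  recurse <- function(j, used, acc) {
    if (j > n_dr) {
      key <- assign_key(acc)
      if (is.null(best_key) || lex_less(key, best_key)) {
        best_key <<- key
        best <<- acc
      }
      return(invisible(NULL))
    }
    cands <- which(sn < dr[j] & dr[j] - sn <= w & !used)
    for (i in c(cands, NA)) {
      acc[j] <- i
      u2 <- used
      if (!is.na(i)) u2[i] <- TRUE
      recurse(j + 1, u2, acc)
    }
  }
  recurse(1L, rep(FALSE, length(sn)), rep(NA_integer_, n_dr))
  best
}

# best label-agreement accuracy over all mappings of found labels onto true
# labels (injective over the smaller set); exact for small unit counts
label_accuracy <- function(found, truth) {
  fu <- sort(unique(found[found > 0]))
  tu <- sort(unique(truth))
  if (length(fu) == 0) return(0)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  base <- if (length(fu) <= length(tu)) tu else c(tu, rep(NA, length(fu) - length(tu)))
  best <- 0
  for (p in perms(base)) {
    map <- p[seq_along(fu)]
    pred <- map[match(found, fu)]
    best <- max(best, mean(!is.na(pred) & pred == truth))
  }
  best
}

# parametric test waveform distinct from the package's template generator
test_template <- function(amplitude, width_samples, total = 72, peak_at = 25) {
  t <- seq_len(total)
  main <- exp(-(t - peak_at)^2 / (2 * (width_samples / 4)^2))
  reb <- exp(-(t - peak_at - width_samples / 2)^2 / (2 * (width_samples / 3)^2))
  amplitude * (main - 0.5 * reb)
}

# trace with copies of a template at given sample indices plus uniform
# background noise whose raw-MAD threshold admits no false crossings
make_spike_trace <- function(n, template, at, noise_half = 1, seed = 1) {
  set.seed(seed)
  x <- stats::runif(n, -noise_half, noise_half)
  for (s in at) {
    idx <- s + seq_along(template) - which.max(abs(template))
    ok <- idx >= 1 & idx <= n
    x[idx[ok]] <- x[idx[ok]] + template[ok]
  }
  x
}
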