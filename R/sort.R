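#' Discrete Haar wavelet decomposition of a waveform
#'
#' Orthonormal multi-level Haar transform. The waveform is zero-padded to a
#' multiple of `2^levels`; the output concatenates the final approximation
#' coefficients with the detail coefficients from coarsest to finest. The
#' transform is orthonormal on the padded signal (energy preserving).
#'
#' @param x Numeric waveform.
#' @param levels Decomposition depth (default 4).
#' @return Numeric coefficient vector (length = padded length).
#' @export
haar_dwt <- function(x, levels = 4) {
  block <- 2^levels
  npad <- (block - length(x) %% block) %% block
  a <- c(as.numeric(x), numeric(npad))
  details <- list()
  for (l in seq_len(levels)) {
    odd <- a[seq(1, length(a), by = 2)]
    even <- a[seq(2, length(a), by = 2)]
    details[[l]] <- (odd - even) / sqrt(2)
    a <- (odd + even) / sqrt(2)
  }
  c(a, unlist(rev(details)))
}

# Kolmogorov-Smirnov distance between a sample and the normal fitted by its
# own mean/sd; 0 for (near-)constant samples.
ks_distance_normal <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s < 1e-12) return(0)
  z <- sort((v - mean(v)) / s)
  n <- length(z)
  p <- stats::pnorm(z)
  max(pmax(seq_len(n) / n - p, p - (seq_len(n) - 1) / n))
}

#' Wavelet features for spike sorting
#'
#' Each waveform is decomposed with a 4-level Haar wavelet transform; the
#' `n_keep` coefficients whose distributions across spikes deviate most from
#' normality (largest Kolmogorov-Smirnov distance to a normal fitted by the
#' sample mean and variance) are retained. Multimodal coefficients — those
#' carrying unit identity — are the least normal, so this selects the most
#' discriminative features. Deterministic given the input.
#'
#' @param waveforms Matrix, one waveform per row (>= 16 columns).
#' @param n_keep Number of coefficients to keep (default 10).
#' @param levels Wavelet decomposition depth (default 4).
#' @return Feature matrix (n_spikes x n_keep) with attribute `coef_index`
#'   giving the retained coefficient positions.
#' @export
wavelet_features <- function(waveforms, n_keep = 10, levels = 4) {
  if (!is.matrix(waveforms) || nrow(waveforms) < 2)
    stop("need a matrix of at least 2 waveforms")
  if (ncol(waveforms) < 16) stop("waveform window must be >= 16 samples")
  coefs <- t(apply(waveforms, 1, haar_dwt, levels = levels))
  if (n_keep > ncol(coefs))
    stop("n_keep exceeds the number of wavelet coefficients (",
         ncol(coefs), ")")
  ks <- apply(coefs, 2, ks_distance_normal)
  keep <- order(ks, decreasing = TRUE)[seq_len(n_keep)]
  feat <- coefs[, keep, drop = FALSE]
  attr(feat, "coef_index") <- keep
  attr(feat, "ks_distance") <- ks[keep]
  feat
}

#' Cluster spike features into putative single units
#'
#' Fits Gaussian mixture models to the feature matrix with the number of
#' components selected by BIC over `1..max_units`. Spikes whose maximum
#' posterior probability falls below `posterior_min` are left unassigned
#' (label -1), clusters smaller than `min_cluster_size` are dissolved into
#' the unassigned pool, and (when waveforms are supplied) units whose mean
#' templates correlate above `merge_correlation` are merged — a guard
#' against BIC oversplitting one unit.
#'
#' @param features Feature matrix from [wavelet_features()].
#' @param waveforms Optional waveform matrix (same row order) used for
#'   templates and template-correlation merging.
#' @param min_cluster_size Minimum spikes per unit (default 20).
#' @param max_units Largest number of mixture components tried (default 8).
#' @param posterior_min Posterior threshold below which a spike is
#'   unassigned (default 0.5).
#' @param merge_correlation Maximum-lag template cross-correlation above
#'   which two units are merged (default 0.9); `NA` disables merging.
#'   Lags up to `merge_lag` samples are searched, so subclusters of one
#'   unit split by alignment jitter or by rebound-lobe alignment flips are reunited.
#' @param merge_lag Maximum alignment lag (samples) searched when comparing
#'   templates (default 18, ~0.6 ms at 30 kHz — wide enough to span the
#'   separation between a spike's main and rebound lobes, so clusters of
#'   rebound-aligned spikes rejoin their unit).
#' @param min_coherence Minimum mean correlation of a unit's waveforms with
#'   its template (default 0.5, needs `waveforms`); clusters below it have
#'   no shared shape and are dissolved into the unassigned pool. `NA`
#'   disables.
#' @param max_residual Maximum ratio of a cluster's median within-cluster
#'   residual energy to the expected noise energy (default 1.5; needs
#'   `noise_sd`). A single unit's waveforms differ from their template by
#'   background noise plus a little alignment jitter; clusters whose
#'   residual clearly exceeds the noise floor are mixtures or
#'   overlapping-spike artifacts and are dissolved. `NA` disables.
#' @param min_amplitude Minimum ratio of a cluster's median aligned-extremum
#'   amplitude to the detection threshold half-width (default 1.2; needs
#'   `threshold_half`). Threshold-crossing noise events hug the threshold
#'   (median ~1.05x); any unit detectable at useful recall sits well above
#'   it. `NA` disables.
#' @param align_index Alignment sample within the waveform window (needed
#'   for the amplitude rule).
#' @param noise_sd Background noise SD estimate, e.g. `mad/0.6745` from
#'   [compute_threshold()] (needed for the residual rule).
#' @param threshold_half Detection threshold half-width in trace units
#'   (needed for the amplitude rule).
#' @param seed Integer seed fixing the (subset) initialization for large
#'   inputs; clustering is deterministic given input and seed.
#' @return An object of class `"sorted_units"`: `labels` (per spike, -1 =
#'   unassigned), `templates` (unit x window matrix), `features`,
#'   `quality` (per-unit spike count and mean waveform correlation to the
#'   template), `n_units`.
#' @export
cluster_units <- function(features, waveforms = NULL, min_cluster_size = 20,
                          max_units = 8, posterior_min = 0.5,
                          merge_correlation = 0.9, merge_lag = 18,
                          min_coherence = 0.5, max_residual = 1.5,
                          min_amplitude = 1.2, align_index = NULL,
                          noise_sd = NULL, threshold_half = NULL,
                          seed = NULL) {
  n <- nrow(features)
  if (n < min_cluster_size) {
    warning("fewer spikes than min_cluster_size; all spikes unassigned")
    return(new_sorted_units(rep(-1L, n), features, waveforms))
  }
  sds <- apply(features, 2, stats::sd)
  if (all(sds < 1e-12)) {
    # identical waveforms: a single unit, no mixture fit needed
    return(new_sorted_units(rep(1L, n), features, waveforms))
  }
  init <- NULL
  if (n > 1500) {
    if (!is.null(seed)) set.seed(seed)
    init <- list(subset = sample.int(n, 1000))
  }
  fit <- mclust::Mclust(features, G = seq_len(max_units),
                        modelNames = c("EII", "VII", "EEI", "VVI", "EEE", "VVV"),
                        initialization = init, verbose = FALSE)
  if (is.null(fit)) stop("mixture model fit failed")
  labels <- as.integer(fit$classification)
  post_max <- apply(fit$z, 1, max)
  labels[post_max < posterior_min] <- -1L

  labels <- enforce_min_size(labels, min_cluster_size)
  if (!is.null(waveforms) && !is.na(merge_correlation))
    labels <- merge_correlated(labels, waveforms, merge_correlation, merge_lag)
  if (!is.null(waveforms) && !is.null(threshold_half) &&
      !is.null(align_index) && !is.na(min_amplitude))
    labels <- drop_low_amplitude(labels, waveforms, align_index,
                                 min_amplitude * threshold_half)
  if (!is.null(waveforms) && !is.null(noise_sd) && !is.na(max_residual))
    labels <- drop_high_residual(labels, waveforms, noise_sd, max_residual)
  if (!is.null(waveforms) && !is.na(min_coherence))
    labels <- drop_incoherent(labels, waveforms, min_coherence)
  labels <- enforce_min_size(labels, min_cluster_size)
  new_sorted_units(labels, features, waveforms)
}

drop_incoherent <- function(labels, waveforms, min_coherence) {
  for (u in unique(labels[labels > 0])) {
    w <- waveforms[labels == u, , drop = FALSE]
    tm <- robust_template(w)
    if (stats::sd(tm) < 1e-12) { labels[labels == u] <- -1L; next }
    cors <- apply(w, 1, function(r)
      if (stats::sd(r) < 1e-12) 0 else stats::cor(r, tm))
    if (mean(cors) < min_coherence) labels[labels == u] <- -1L
  }
  relabel_compact(labels)
}

drop_low_amplitude <- function(labels, waveforms, align_index, floor_amp) {
  for (u in unique(labels[labels > 0])) {
    amp <- abs(waveforms[labels == u, align_index])
    if (stats::median(amp) < floor_amp) labels[labels == u] <- -1L
  }
  relabel_compact(labels)
}

# robust template: per-sample median, insensitive to a minority of
# displaced/contaminating members after merging
robust_template <- function(w) apply(w, 2, stats::median)

drop_high_residual <- function(labels, waveforms, noise_sd, max_ratio) {
  noise_energy <- ncol(waveforms) * noise_sd^2
  for (u in unique(labels[labels > 0])) {
    w <- waveforms[labels == u, , drop = FALSE]
    tm <- robust_template(w)
    resid <- apply(w, 1, function(r) sum((r - tm)^2))
    if (stats::median(resid) / noise_energy > max_ratio)
      labels[labels == u] <- -1L
  }
  relabel_compact(labels)
}

enforce_min_size <- function(labels, min_cluster_size) {
  tab <- table(labels[labels > 0])
  small <- as.integer(names(tab)[tab < min_cluster_size])
  labels[labels %in% small] <- -1L
  relabel_compact(labels)
}

relabel_compact <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  out <- labels
  for (k in seq_along(ids)) out[labels == ids[k]] <- k
  out
}

# maximum normalized cross-correlation of two templates over lags
# -max_lag..max_lag (mean-centered, overlap-normalized)
xcor_max <- function(a, b, max_lag) {
  best <- -1
  for (lag in -max_lag:max_lag) {
    if (lag >= 0) {
      x <- a[(1 + lag):length(a)]
      y <- b[1:(length(b) - lag)]
    } else {
      x <- a[1:(length(a) + lag)]
      y <- b[(1 - lag):length(b)]
    }
    if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) next
    best <- max(best, stats::cor(x, y))
  }
  best
}

# single pass: pairwise template cross-correlations are computed once on
# the un-merged templates, and connected components above rho merge.
# (iterative re-templating can chain distinct units through a smeared
# intermediate template)
merge_correlated <- function(labels, waveforms, rho, max_lag = 18) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) < 2) return(labels)
  tmpl <- vapply(ids, function(u) colMeans(waveforms[labels == u, , drop = FALSE]),
                 numeric(ncol(waveforms)))
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(ids)[-length(ids)]) for (j in (i + 1):length(ids)) {
    if (xcor_max(tmpl[, i], tmpl[, j], max_lag) > rho) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_along(ids), find, integer(1))
  new_lab <- labels
  for (k in seq_along(ids)) new_lab[labels == ids[k]] <- ids[root[k]]
  relabel_compact(new_lab)
}

new_sorted_units <- function(labels, features, waveforms) {
  ids <- sort(unique(labels[labels > 0]))
  templates <- NULL
  quality <- data.frame(unit_id = integer(0), n_spikes = integer(0),
                        mean_waveform_cor = numeric(0))
  if (!is.null(waveforms) && length(ids) > 0) {
    templates <- t(vapply(ids, function(u)
      colMeans(waveforms[labels == u, , drop = FALSE]),
      numeric(ncol(waveforms))))
    rownames(templates) <- ids
    quality <- data.frame(
      unit_id = ids,
      n_spikes = vapply(ids, function(u) sum(labels == u), integer(1)),
      mean_waveform_cor = vapply(ids, function(u) {
        w <- waveforms[labels == u, , drop = FALSE]
        tm <- colMeans(w)
        if (stats::sd(tm) < 1e-12) return(NA_real_)
        mean(apply(w, 1, function(r)
          if (stats::sd(r) < 1e-12) NA_real_ else stats::cor(r, tm)),
          na.rm = TRUE)
      }, numeric(1)))
  }
  structure(list(labels = labels, templates = templates, features = features,
                 quality = quality, n_units = length(ids)),
            class = "sorted_units")
}

#' @export
print.sorted_units <- function(x, ...) {
  cat(sprintf("<sorted_units> %d spikes in %d units (%d unassigned)\n",
              length(x$labels), x$n_units, sum(x$labels < 0)))
  invisible(x)
}

#' Sort a detected spike train into units
#'
#' Convenience wrapper: [wavelet_features()] then [cluster_units()] on the
#' waveforms of a `spike_train` (normally the SN channel; DR spikes inherit
#' unit identity through matching, see [match_spikes()]).
#'
#' @param train A `spike_train` from [detect_spikes()].
#' @param n_keep Number of wavelet features (default 10).
#' @param ... Passed to [cluster_units()].
#' @return A `"sorted_units"` object.
#' @export
sort_spikes <- function(train, n_keep = 10, ...) {
  if (!inherits(train, "spike_train")) stop("train must be a spike_train")
  feats <- wavelet_features(train$waveforms, n_keep = n_keep)
  thr <- train$threshold
  cluster_units(feats, waveforms = train$waveforms,
                align_index = train$align_index,
                noise_sd = thr$mad / 0.6744898,
                threshold_half = (thr$threshold_high - thr$threshold_low) / 2,
                ...)
}
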