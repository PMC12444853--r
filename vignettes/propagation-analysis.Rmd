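---
title: "Quantifying spike propagation failure at the dorsal root ganglion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spike propagation failure at the dorsal root ganglion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drgfilter)
```

## The measurement

Sensory axons bifurcate at a T-junction inside the dorsal root ganglion
(DRG), and action potentials can fail to propagate through it. With hook
electrodes on the spinal nerve (SN, before the ganglion) and the dorsal
root (DR, after it), about 4 mm apart, every afferent spike should appear
first on the SN and then — if it survives the junction — on the DR after
a conduction delay. `drgfilter` turns a pair of such voltage traces into
per-unit propagation failure estimates. The stages and their assumptions:

**Filtering.** Both channels are high-pass filtered at 60 Hz with an
order-4 Butterworth applied forward–backward. Zero-phase application
matters because the entire analysis rests on sub-millisecond latencies
between channels; a causal filter would delay spikes by a
frequency-dependent amount. The filter order is a conventional choice
(the field rarely reports one); it sits in the configuration
(`filter.order`). Edge transients are absorbed by odd-reflection padding
of `max(3 × order, 0.1 s)` samples — a 12-sample pad, while customary for
generic zero-phase filtering, is far too short for a 60 Hz corner at
30 kHz, where the impulse response rings for tens of milliseconds.

**Detection.** The threshold is anchored on the median absolute
deviation, MAD = median(|x − median(x)|), the robust noise scale that is
insensitive to the spikes themselves. `compute_threshold()` reports the
literal `median ± factor × MAD` quantities. For the crossing test,
`detect_spikes()` by default scales the MAD by the Gaussian consistency
factor 1/0.6745, so that `mad_factor = 4` means four standard deviations
of the background — the convention of the standard wavelet spike-sorting
toolchain. The distinction is not cosmetic: a threshold at 4 × raw MAD is
only ~2.7 sigma, and for a Gaussian-like background band-limited to the
100–3000 Hz acquisition band, level crossings at 2.7 sigma occur at
roughly 45 per second (Rice's formula), which would bury genuine spikes
in threshold noise at any realistic firing rate. At ~4 sigma the rate
drops to well under one per second. `mad_consistent = FALSE` restores the
literal convention. Alignment is at the signed extremum of each
supra-threshold excursion, both polarities by default (hook-electrode
spikes can lead with either phase); candidates closer than the 1 ms dead
time merge, keeping the larger. Waveform windows are 0.8 ms before and
1.6 ms after the extremum (72 samples at 30 kHz). Spike *prominence* is
the peak-to-trough amplitude of the snippet.

**Sorting.** Each waveform is decomposed with a 4-level orthonormal Haar
wavelet transform, and the 10 coefficients whose distributions across
spikes deviate most from normality (Kolmogorov–Smirnov distance to a
normal fitted by sample mean and variance) become the feature vector:
coefficients that carry unit identity are multimodal, hence least normal.
Features are clustered with Gaussian mixture models, the number of
components chosen by BIC over 1–8. The superparamagnetic clustering of
the classical toolchain is deliberately replaced here: a mixture model is
deterministic given its initialization, dependency-light, and the
contract being tested is label recovery on synthetic data, not any
particular algorithm. Spikes with maximum posterior below 0.5 stay
unassigned (label −1), as do clusters below the 20-spike floor.

Raw mixture components are not yet units, and the pipeline curates them
with four rules whose parameters come from the physics of the detector
rather than from tuning:

* *Lag-tolerant merging.* Templates whose best cross-correlation over
  lags up to 18 samples (0.6 ms) exceeds 0.9 are the same unit. The lag
  allowance must span the distance between a spike's main and rebound
  lobes: when noise occasionally makes the rebound excursion beat the
  main one, a subcluster of rebound-aligned copies of the unit appears,
  shifted by exactly that distance. Merging is a single pass over the
  original templates (connected components); iteratively re-estimating
  templates while merging lets a smeared intermediate template chain two
  genuinely distinct units together.
* *Amplitude floor.* A cluster whose median aligned amplitude is below
  1.2 × the detection threshold half-width is threshold-crossing noise:
  exceedances of a Gaussian-like background hug the threshold (median
  ≈ 1.05 ×), whereas any unit detectable at useful recall must sit
  clearly above it.
* *Residual ceiling.* A single unit's waveforms differ from their
  template by background noise plus a little alignment jitter, so the
  median within-cluster residual energy should be close to
  `window × noise_sd²`. Clusters exceeding 1.5 × that floor are mixtures
  or overlapping-spike artifacts. The template used here is the
  per-sample median, so a minority of contaminated members cannot inflate
  everyone's residual.
* *Coherence floor.* Clusters whose waveforms correlate with their
  template below 0.5 on average share no waveform shape at all.

Units are sorted on the SN channel only; DR spikes inherit unit identity
through matching.

**Matching.** Each DR spike pairs with the nearest strictly preceding SN
spike within the tolerance window *w* = electrode distance / slowest
admissible conduction velocity = 4 mm / 0.1 m/s = 40 ms. Matching is
one-to-one (a propagating spike has exactly one origin): DR spikes are
processed in ascending time, and an SN spike already claimed is skipped
in favor of the next-nearest preceding unclaimed one inside the window.
Latency must be strictly positive — propagation is orthodromic. Ties at
sample resolution resolve toward the later SN spike (the larger
velocity). A brute-force enumeration oracle over all admissible
assignments verifies this greedy rule exactly on small instances in the
test suite. Conduction velocity = distance / latency classifies fibers:
C below 2 m/s, A above; exactly 2 m/s goes to A by declared convention,
since the strict inequalities of the field's definition leave the
boundary open. A unit's class comes from its *median* matched latency,
robust to occasional mis-matches.

**Quantification.** Per unit: propagation success = 100 × matched SN
spikes / SN spikes, failure = 100 − success. Bulk filtering:
%ΔSpikes = (Spikes_SN − Spikes_DR)/Spikes_SN × 100. Epoch analysis uses
control / stimulus / recover windows (typically 10 or 30 s); rates are
spikes per second within the window, and percentage change from control
is undefined (flagged, not fabricated) when the control rate is zero.
The instantaneous rate is a 50 ms binned count convolved with a Gaussian
kernel (sigma = 100 ms), normalized to integrate to the spike count; a
reciprocal-ISI estimator is available behind `method = "isi"`. The field
never pins down "instantaneous rate"; both the bin width and kernel are
configuration. Mechanosensitivity is the OLS regression of a unit's
instantaneous rate on the force trace (grams), reported as slope
(Hz/g) and r²; r² is invariant to affine rescaling of the force channel.

## The simulator: what it emulates, and what it does not

`simulate_trains()` draws each unit's SN train from an inhomogeneous
Poisson process with rate `base_rate + force_gain × force(t)` (thinning
algorithm), then enforces a 1 ms per-unit refractory period. Each spike
propagates with probability 1 − failure_prob(epoch); its DR time is
offset by distance/velocity plus truncated Gaussian jitter (default
0.1 ms — real fibers conduct at nearly fixed velocity; the jitter is kept
small and configurable to probe robustness). Epoch-dependent failure
probabilities are the mechanism for emulating pharmacological modulation
of the ganglion: e.g., raising a C-unit's failure from 0.55 to 0.77
between epochs while leaving an A-unit unchanged mirrors the direction of
reported GABAergic effects without asserting their magnitudes as ground
truth.

`render_traces()` places parametric biphasic templates (difference of
Gaussians; amplitude and width per unit) at the event times with linear
superposition, adds Gaussian noise band-limited to the 100–3000 Hz
acquisition band and rescaled to exactly `noise_sd`, and copies the force
profile into the third channel. The ramp-and-hold force generator
defaults to a 125 g plateau, a typical noxious pressure threshold.

What the simulator does **not** model: biophysics of the T-junction
(failure is a coin flip, not a cable equation), electrode drift,
non-stationary noise, bursting or serially correlated firing, waveform
changes during high-frequency firing, and overlapping-spike shapes
beyond linear superposition. Passing tests on this generator therefore
demonstrate that the analysis chain recovers the *statistical* structure
it assumes — they do not certify performance on every pathology of real
recordings.

## Study conditions and numerical choices

*Benchmark velocity.* The matching-accuracy benchmark
(`benchmark_matching()`) uses a single unit at 2.0 m/s (2 ms latency over
4 mm). The choice is analytic, made before any benchmark was run: with a
refractory period t_ref, a wrong origin requires another SN spike inside
(latency − t_ref) of the true origin, so expected mis-assignment at rate
λ is ≈ 1 − exp(−λ(L − t_ref)) — about 1% at 10 Hz and 9% at 100 Hz for
L = 2 ms (exclusivity cascades roughly double the latter). That places
the benchmark inside the 80–100% accuracy band reported for this class of
matcher and reproduces its inverse dependence on firing rate. A much
faster unit would make the benchmark trivially perfect (latency inside
the refractory period); a 0.5 m/s unit at 100 Hz would be dominated by
ambiguity no matcher can resolve.

*Three-unit scenario.* The end-to-end benchmark
(`three_unit_scenario()`) fixes one A-unit (10 m/s, failure 0.1) and two
C-units (0.5 and 1 m/s, failure 0.5). Rates are 10/5/5 Hz — consistent
with bulk SN rates of ~25 Hz across a handful of units in this
preparation — and 60 s of recording gives every unit ≥ 300 spikes.
Template amplitudes 9/−8/7 with noise_sd 1.3 put the weakest unit at
peak/MAD ≈ 8. At these settings the main cross-unit biases (a faster
spike intervening inside a C-unit's 8 ms latency window, missed weak
spikes, threshold noise) each contribute a few percentage points to
per-class failure estimates, comfortably inside a ±7 pp budget.

*Problem sizes.* The test suite runs the benchmark grid at 16 cells × 10
seeds × 60 s, failure-recovery at 40 runs × 60 s, and the rendered
three-unit scenario at 20 seeds × 60 s — sizes at which binomial standard
errors on the quantities under test are a fraction of their tolerance.

*Degenerate inputs.* A constant trace (MAD = 0) is a degenerate-signal
error, not a silent zero-threshold. Zero-variance force regressors,
empty match sets, units with no SN spikes and zero-control-rate
percentages are all flagged or excluded with warnings rather than
propagated as numbers.

*Storage.* Time is seconds (double) everywhere outside the detector's
sample indices. Flat-binary recordings store interleaved float32 with a
YAML sidecar; round-trips are bit-exact once values are float32. CSV
event tables carry full double precision (round-trip < 1 ns).

## Known limitations

* Detection precision on *Gaussian-tailed* noise is bounded by the
  threshold's level-crossing rate; at 4 sigma and 30 kHz a ~1-per-second
  false-event rate is unavoidable, which is why downstream curation — not
  the detector — removes noise clusters. Claims of near-perfect detection
  precision only hold for backgrounds whose tails end below threshold.
* Overlapping spikes are not decomposed. Opposite-polarity overlaps
  produce displaced, distorted detections; the residual-ceiling rule
  removes the clusters they form, at the cost of discarding those events
  from per-unit statistics.
* Matching accuracy degrades inherently as firing rate × latency grows;
  above ~100 Hz for slow C-fibers the origin of a DR spike is
  information-theoretically ambiguous, and no assignment rule can fix
  that.
* The A/C split by conduction velocity is a coarse proxy for fiber type;
  units near 2 m/s can flip class with small latency errors.
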