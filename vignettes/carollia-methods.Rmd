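---
title: "Methods: screening, call analysis, and ecotype statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, call analysis, and ecotype statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carollia)
```

This package models the computational chain used to characterize the
mutualism between short-tailed fruit bats (*Carollia*) and *Piper* plants
across forest and gap habitats: semi-automated screening of nightly
ultrasonic recordings, echolocation-call measurement and classification,
camera-trap event analytics, and a battery of ecotype-contrast statistics
applied to diet and fruit-scent (VOC) data. This vignette explains the
models, parameters, and design choices; the worked numbers in the README and
the values written by `scripts/acceptance.R` are all computed by the code
described here.

## Two-pass ultrasonic screening

Field recordings from duty-cycled loggers (10-s clips at 256 kHz) are
dominated by low-frequency clutter — wind, vegetation, rain, other animals.
The screening algorithm classifies each clip as *likely containing bat
calls* or *mainly noise* in two steps:

1. **Band-pass** the clip with a zero-phase Butterworth filter (order 4,
   applied forward and backward) to strip energy below the minimum frequency
   of *Carollia* calls.
2. **Peak frequency**: estimate the Welch power spectral density of the
   filtered clip (1024-sample Hann segments, 50% overlap; about 250 Hz
   resolution at 256 kHz with stable averaging over a 10-s clip) and flag
   the clip when the spectral argmax falls in the *Carollia* search-phase
   peak-frequency window.

The algorithm is run twice: a *specific* run (band 30–110 kHz) tuned against
false positives and a *sensitive* run (band 20–100 kHz) tuned against
misses. Only the band edges of the two runs are fixed by the protocol; the
per-run decision windows are free parameters. We default the specific window
to [60, 80] kHz — the printed range of *Carollia* search-phase peak
frequencies — and widen the sensitive window to [55, 85] kHz so that it
strictly dominates in recall. The review queue is the **union** of the two
runs' positives (tagged by run), because the sensitive run exists precisely
to recover type-II misses of the specific run.

Why this decision rule works on clutter: ambient outdoor noise decays with
frequency, so after high-pass filtering the residual spectrum of a noise
clip peaks at the filter edge (20–40 kHz), outside the decision window. A
clip containing a *Carollia* pass instead concentrates energy near the
main-harmonic center (~65 kHz), which wins the argmax even though the calls
occupy well under 1% of the clip's duration.

The zero-phase filter is implemented as a compiled direct-form-II IIR
(forward–backward with odd-symmetric edge extension); this is numerically
the same operation as the usual `filtfilt` but fast enough for
hundreds of multi-million-sample clips. The Welch estimator packs pairs of
real segments into single complex FFTs, an exact identity.

## Synthetic scenes: what they emulate and what they do not

The generator renders a clip as background noise plus calls:

* **Calls** are sums of harmonics of a fundamental frequency trajectory,
  linear in frequency for FM sweeps (the simplest shape consistent with
  downward search-phase sweeps); `FM_CF_FM`, `FM_CF` and `FM_QCF` use
  piecewise sweep/hold trajectories. Harmonic *k* sweeps *k* times the
  fundamental with phase-locked harmonics. The designated main harmonic is
  0 dB and other harmonics −6 dB by default, so "main harmonic = highest
  relative amplitude" is unambiguous. Calls carry a Hann amplitude envelope,
  which puts the spectral peak at the mid-call instantaneous frequency and
  gives the generator an analytic ground-truth peak.
* A *Carollia*-type scene (`carollia_scene()`) is a train of 12 calls
  (2–3 ms, fundamental ~40→25 kHz, 2–3 harmonics, main harmonic #2, so the
  dominant track sweeps ~80→50 kHz and peaks near 65 kHz) at random onsets
  within the 10-s clip — a bat commuting past the logger. Per-call SNR
  (main-harmonic peak amplitude over noise RMS, dB) defaults to 15–25 dB;
  field SNRs for these comparatively quiet bats are not on record, so this
  is a free parameter chosen to represent a detectable but not pristine
  pass.
* **Noise models**: `white` (flat), `pink` (1/f across the whole band), and
  `low_frequency_clutter` — pink noise low-passed at 20 kHz (wind and
  vegetation movement) over a pink broadband floor 20 dB down. The clutter
  model is the default and represents the tropical-forest regime the
  screening step was built for.

The generator does **not** model atmospheric attenuation, echoes,
directionality, inter-individual call variation, or other species'
vocalizations. Passing the screening criteria on these synthetics
demonstrates that the algorithm implements its decision rule correctly and
behaves sensibly under realistic spectral clutter — not that its error
rates transfer to any particular field dataset.

## Call segmentation, measurement, classification

Spectrograms use the manual-vetting settings: 512-point FFT, Hann window,
95% overlap. The hop `512 × 0.05 = 25.6` samples is **floored to 25** for
bit-reproducibility. One-sided power is energy-preserving (non-DC bins
doubled), so total spectrogram power divided by the FFT length equals the
summed windowed-frame energy exactly (tested to 1%).

`segment_calls()` sums power over a 40–110 kHz band per frame (calls below
40 kHz are not noted — this keeps clutter and most non-*Carollia* species
out) and marks frames exceeding a robust floor, `median + 6·MAD` of the
per-frame band energy; runs separated by under 1 ms merge, and runs
shorter than 0.5 ms are dropped. On clutter-only clips this yields no
intervals in ≥95% of seeded replicates.

`measure_call()` reports the standard parameter set — duration, 90%
duration, minimum/maximum/peak/95% frequency, delta frequency, 90%
bandwidth — plus harmonic structure and SNR. Definitions are
energy-percentile based (Raven-style): the 90% duration is the central
90%-energy time span; the 90% bandwidth spans the 5%→95% energy
frequencies; `fmin`/`fmax` are the edges of the −20 dB spectral support.
Harmonics are per-frame spectral peaks lying within ±10% of integer
multiples of the lowest track; the main harmonic is the track with the
highest amplitude, and **all frequency parameters are measured on the main
harmonic's band**, matching how reference calls are measured on
spectrograms. Percentile frequencies are computed within the support
region, so `bw90 ≤ delta_f` and `duration90 ≤ duration` hold by
construction. Single-frame intervals return a flagged (degenerate)
measurement rather than an error.

Numerical details that matter: per-frame peaks use parabolic (sub-bin)
interpolation on log power; track frames more than 30 dB below the track
maximum are trimmed (their frequency estimates are noise); the harmonic
search starts at 20 kHz, below which clutter would masquerade as a
fundamental.

`classify_call()` is a small decision tree. Calls with `fmax < 40 kHz` are
discarded (`NA`). A call whose inter-call interval is under 6 ms is a
`FEEDING_BUZZ`. Otherwise the main track's instantaneous-frequency slope
(local linear fits over 0.7 ms) labels frames FM (≥2.5 kHz/ms), QCF
(0.25–2.5) or CF (<0.25); a CF run covering ≥30% of the call makes the call
`FM_CF_FM` (FM on both sides) or `FM_CF`, a shallow run covering ≥40% makes
it `FM_QCF`, and plain FM calls split on harmonic structure:
`FM_HARMONIC_CAROLLIA` requires **at least two harmonics**, a main-harmonic
peak in the configured window ([60, 80] kHz), and main-harmonic SNR of at
least 10 dB (the protocol's "high SNR" criterion, made numeric and
configurable); harmonic-bearing calls failing those rules are
`FM_HARMONIC_OTHER`, single-track calls `FM_NO_HARMONIC`. Genus-level
identification is the goal; species-level *Carollia* discrimination is out
of scope.

## Camera-trap events

Events are validated rows (plant, species, ecotype, succession habitat,
visitor taxon, behavior, local timestamp) with a closed behavior set.
Tabulation follows the interaction-table semantics: *bat fruit collections*
are bat `remove_fruit` events; *bat visitations* are bat
`flyby_visit`/`inspect_fruit` events (flying by or inspecting without
removal); *other visitations* are all non-bat events. Activity profiles bin
by hour anchored at sunset (first bin [17:00, 18:00), wrapping to 16:59) or
by month; `species_binary` mode counts distinct species with activity per
bin. Timestamps are naive local times throughout — the sunset-anchored axis
is the analysis frame, and no timezone database is consulted.

The synthetic event generator draws Poisson counts per (ecotype, taxon,
behavior) cell; its default intensities encode the observed qualitative
structure: bats visit and collect at both ecotypes, non-bat frugivory is
confined to gap plants, and bats are nocturnal (17:00–05:00) while other
visitors are diurnal.

## Statistics

* **Monte-Carlo chi-square**: Pearson's statistic with the p-value from
  2000 tables simulated uniformly with both margins fixed (Patefield
  sampling, via `chisq.test`'s simulation option), using the unbiased
  `(1+b)/(B+1)` estimator, which is never exactly zero. Suited to the small
  count tables these surveys produce; `(r−1)(c−1)` df and the asymptotic p
  are reported alongside.
* **Diet chain**: percentages are shifted by `c = 1` and rescaled,
  `y = ln(q/(1−q))` with `q = (pct + c)/100`. The shift-then-rescale
  arithmetic is ambiguous in the protocol, so both a percent-scale and a
  proportion-scale convention are exposed in the configuration. Shapiro-Wilk
  tests are reported faithfully; note that very small W with tiny p-values
  *rejects* normality, and interpretation is left to the user. One-way
  ANOVAs report sums of squares, mean squares, F and p.
* **Wilcoxon + BH**: two-sided rank-sum tests, exact when tie-free with
  pooled n ≤ 20, otherwise midranks with normal approximation and
  continuity correction; Benjamini-Hochberg step-up adjustment across
  compounds. (The BH step-up is monotone and order-preserving but not
  idempotent in general.)
* **Nonparametric multivariate ANOVA-type test**: each variable is
  midranked over the pooled sample; the statistic is
  `tr(H)/tr(G)` (between / within rank mean squares summed over variables).
  Relative effects `(mean rank − ½)/N` are reported per group and variable;
  their sample-size-weighted combination is exactly ½. The asymptotic
  reference is an F distribution with two-moment (Box) degrees of freedom
  `df1 = (a−1)·tr(G)²/tr(G²)`, `df2 = (N−a)·tr(G)²/tr(G²)` — non-integer,
  with df1 shrinking toward the effective (correlation-adjusted) variable
  dimension. At the sample sizes typical here the **permutation analog**
  (whole rows permuted across labels, default 2000) is the p-value to trust;
  it is exactly calibrated by construction and is what the calibration suite
  checks.
* **Blomberg's K**: observed MSE₀/MSE about the phylogenetically corrected
  mean, scaled by its Brownian-motion expectation on the same tree; K = 1
  under Brownian evolution. Permutation p (999 tip shuffles by default,
  `(1+b)/(B+1)`). The implementation is plain matrix algebra on
  `ape::vcv(tree)` and is cross-checked against an independent
  implementation in the test suite.

## Fruit-scent dataset construction

From a species × compound emission-per-weight matrix: compounds present
(emission > 0) in fewer than 5 species are dropped (presence is counted at
the species level — the matrix's analysis unit); each species' compounds
are ranked by descending emission with lexicographic tie-breaks and
truncated at the top 20 (and at the last nonzero entry); compounds are then
ranked by prevalence across those lists. The selection supports both a
prevalence threshold and a target set size (default 15, the documented
outcome); ordering by (prevalence desc, label asc) makes boundary ties
deterministic. Three analysis datasets result: the common-compound
abundance submatrix, total emission per species, and the per-species VOC
count.

The synthetic VOC generator plants 15 ubiquitous high-abundance compounds
(so the selection step has a recoverable truth), 234 sporadic low-abundance
ones, and shifts 6 designated common compounds between ecotypes by a
log-fold-change of 3 (sdlog 1) — a clear chemotype contrast, consistent
with the qualitative finding that a handful of terpenes and long-chain
compounds separate gap from forest fruit scent.

## Problem sizes and calibration checks

The automated checks run, per fresh session: 200 ten-second clips
(100 *Carollia* passes at 15–25 dB SNR, 100 clutter-only) for screening
recall/false-positive rates; 50 clips for peak-frequency oracle agreement;
full conditional enumeration of all ~1800 2×2 tables with total ≤ 12
against the Monte-Carlo p; 1000 null simulations each for the ANOVA-type
test (2×8 observations, 3 variables, 199 permutations) and the Monte-Carlo
chi-square (2×3 multinomial, n = 60); 500 Brownian simulations on a 32-tip
tree for K; and 50 replicate VOC datasets for the detection-power and
exact-selection rates. These sizes give binomial standard errors well below
the margins asserted.

## Known limitations

* The acoustic generator's SNR scale, call rate, and noise decomposition
  are plausible but unvalidated against field recordings; screening error
  rates measured on synthetics are properties of the algorithm under the
  stated model only.
* The ANOVA-type test's asymptotic df approximation is a derived
  two-moment form; small-sample inference should use the permutation p.
* Species-level acoustic identification, GC-MS processing, GIS, and video
  analysis are out of scope; the package starts from their outputs.
* The per-run peak-frequency decision windows are defaults bracketing the
  printed species range, not recovered protocol constants; both are
  configurable in `pipeline_config()`.
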