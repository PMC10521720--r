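---
title: "Raman-SIP single-cell analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Raman-SIP single-cell analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramansip)
```

ramansip implements the computational side of a Raman-activated
cell-sorting workflow for CO₂-fixing bacteria: quantify ¹³C-induced red
shifts of the carotenoid resonance Raman bands in single-cell spectra,
decide which cells to sort, summarize labeling time courses, and bin the
contigs recovered from sorted cells by tetranucleotide composition.
This vignette documents the models, the defaults and why they were
chosen, the numerical details, and what the synthetic data do and do not
establish.

## The band-shift model

Carotenoid spectra carry three resonance-enhanced bands: ν1 (C=C
stretch), ν2 (C–C polyene stretch) and ν3 (CH₃ in-plane rock). When a
cell builds carotenoids from ¹³C, the heavier backbone lowers the
vibrational frequencies. The package models each band center as linear
in the cell's ¹³C fraction $f$:

$$\nu_b(f) = \nu_b^{12} - f\,(\nu_b^{12} - \nu_b^{13}),$$

with default endpoints ν1: 1522 → 1502 cm⁻¹ and ν2: 1158 → 1145 cm⁻¹,
the published positions for unlabeled and fully labeled marine
carotenoid-containing cells. The inverse, `estimate_f()`, recovers $f$
from an observed center and is exactly the identity composed with
`band_center()` (a property the test suite asserts at machine
precision). Two simplifications are deliberate:

* a **single shared $f$ per cell** drives both bands. Reported day-1
  positions correspond to slightly different per-band fractions
  (10/20 = 0.50 for ν1 vs 7/13 ≈ 0.54 for ν2); the package averages the
  two band estimates rather than modeling band-specific response.
* **no isotopologue fine structure**: real partially labeled
  carotenoids are mixtures of isotopologues whose envelope broadens as
  well as shifts; here only the center moves.

ν3 defaults to 1004 → 1000 cm⁻¹. Its position is the literature
convention for carotenoids, not a value this workflow measures; the
classifier never uses ν3.

## The synthetic-data generator

`simulate_spectrum()` builds one spectrum on a 600–1800 cm⁻¹ grid at
1 cm⁻¹ steps (instrument-like resolution covering all three bands) as a
sum of **Lorentzian** bands — the natural Raman line shape — plus a
smooth polynomial fluorescence background, i.i.d. Gaussian noise with
sd = (ν1 amplitude)/snr, and Poisson-count single-channel cosmic-ray
spikes at 10–50× the ν1 amplitude. Defaults: FWHM 12 cm⁻¹, relative
amplitudes ν1:ν2:ν3 = 1.0:0.6:0.3 (typical carotenoid resonance-Raman
profiles — only relative intensities matter downstream), snr 20, spike
rate 0.1/spectrum, baseline comparable in magnitude to the band peaks.

`simulate_timecourse()` draws per-cell fractions around a population
mean

$$f_{\mathrm{mean}}(t) = f_{\max}\left(1 - e^{-(kt)^{h}}\right),$$

a Weibull-type saturation rather than a single exponential. The
sigmoidal form encodes an acclimation lag — cells switch into active
fixation before label accumulates — and is calibrated once to the two
qualitative facts the workflow is built around: the population is
half-labeled after day 1 and effectively at plateau by 48 h. With
$f_{\max} = 1$, $h = 2.5$ and $k = \ln(2)^{1/2.5}$ per day,
$f_{\mathrm{mean}}(1) = 0.5$ and $f_{\mathrm{mean}}(2) = 0.98$. A
single exponential cannot satisfy both facts (through $f(1)=0.5$ it
forces $f(2)=0.75$), which is why the shape parameter exists.
Heterogeneity: per-cell fractions are Normal around the mean with sd
$0.15 \cdot 0.3^{\,t-1}$, clipped to $[0, f_{\max}]$ — strong day-1
cell-to-cell spread that collapses as the population saturates. Day 0
cells are exactly unlabeled.

Class counts use deterministic rounding (`floor`), so population truth
composition never depends on the seed. The mock community mixes an
autotroph (carotenoid, labeled at $f=0.5$), a carotenoid-containing
heterotroph (unlabeled), and a non-carotenoid yeast 1:1:1, with no
cross-feeding term.

**What the generator does not emulate:** wavenumber miscalibration,
detector etaloning, band asymmetry/Fermi resonance, isotopologue
envelopes, photodamage, or non-carotenoid biological bands (protein,
nucleic acid). Passing tests therefore demonstrate correctness of the
estimators under the stated forward model, not robustness to every
artifact of real instruments.

`simulate_contigs()` draws contigs from per-genome Markov chains over
A/C/G/T. Order 0 matches the requested GC exactly in expectation; order
1 gives each genome a random transition matrix tilted (by a 1-D root
search on the stationary distribution) so its stationary GC still equals
the request, adding genome-specific dinucleotide signatures. Real
genomes carry repeats, mobile elements and within-genome composition
heterogeneity that this model omits — synthetic bins are therefore
cleaner than real ones, and binning purity here is an upper bound on
field performance.

## Preprocessing

Order: despike → baseline → smooth → normalize.

* **Despiking** uses the rolling modified z-score
  $0.6745\,(x - \mathrm{med})/\mathrm{MAD}$ over a centered 7-channel
  window; median/MAD are robust to the band peaks themselves. Channels
  above z = 6 are replaced by the window median. A replaced channel
  retains a residual of window-median-vs-point noise (≈1.1 noise sd),
  so despiking removes 10–50× spikes at sub-5-sd cost. With MAD = 0
  (constant window) any deviation is treated as a spike.
* **Baseline**: asymmetric least squares (Whittaker smoother with
  asymmetry $p = 0.01$, roughness $\lambda = 10^5$, 30-iteration cap,
  convergence = stable weights) — fluorescence in pigmented cells is
  smooth and positive, and ALS hugs the lower envelope. Non-convergence
  warns with the cell id. A polynomial option (degree ≤ 6) exists for
  analytic ground truth; on pure polynomial input its residual is below
  1e−6 of the input scale. All-zero spectra pass through unchanged.
  Because ALS leaves residuals riding ≈ +2σ above zero, peak heights
  downstream are always measured above the window median.
* **Smoothing**: Savitzky–Golay, window 7, order 3 — exact on cubic
  structure, mild on 12 cm⁻¹-FWHM Lorentzians. `window = 1` is the
  identity.
* **Normalization**: max-in-ν1-window (default, enables overlays) or
  unit trapezoid area. An all-zero spectrum raises an error rather than
  dividing by zero.
* **Resampling** is linear interpolation; points outside the source
  range become `NA` and are excluded from averages, never zero-filled
  (zero-filling biases mean spectra).

## Band fitting and the sorting decision

Search windows span both the ¹²C and fully shifted positions ±6 cm⁻¹:
ν1 in [1490, 1540], ν2 in [1130, 1170]. Noise is estimated from
1700–1800 cm⁻¹ (no modeled band) after linear detrending. Carotenoid
detection requires peaks (height above window median) ≥ 5× noise sd in
*both* windows. Centers come from a Lorentzian + offset least-squares
fit seeded at the window argmax (Levenberg–Marquardt, bounded), with
3-point parabolic interpolation as fallback; windows with no peak above
3× noise return `ok = FALSE` rather than a spurious center. At snr 20
the fit is unbiased with sd ≈ 0.15 cm⁻¹ for ν1; at snr 10 the ν2 fit
(0.6× amplitude) has sd ≈ 0.5 cm⁻¹, and an exhaustive dense-grid search
errs identically — the limit is information, not the optimizer.

The ν1 **intensity ratio** is $A_{13}/(A_{12}+A_{13})$ with trapezoid
integrals over [1496, 1508] vs [1516, 1528] (the fully shifted and ¹²C
ν1 windows); negative integrals are clipped at 0 so the statistic stays
in [0, 1]. It is monotone in $f$ and unit-free. This is one reasonable
formalization of a "labeled-fraction intensity ratio"; others (peak
heights, fitted areas) would also be monotone.

**Sorting rule**: a carotenoid-positive cell is positive iff
`v1_shift ≥ max(3σ₁, 4)` **and** `v2_shift ≥ max(3σ₂, 4)` cm⁻¹, where
σ are the control-distribution sds from ≥ 5 ¹²C cells. The 3σ term
controls false positives against control spread; the 4 cm⁻¹ floor sits
below the smallest day-1 shift (~7 cm⁻¹ for ν2) and above grid/fit
noise at snr ≥ 10. Requiring both bands is the core specificity
device: single-band excursions (fit glitches, interfering bands) never
sort. Measured on synthetic populations at snr 10, the rule gives 0/1000
false positives and ≥ 97% sensitivity for $f \ge 0.4$. Dark-incubation
controls are ordinary control populations — no special code path.

## Time course and steady state

Per-day summaries average shifts and $\hat f$ (mean of the ν1- and
ν2-derived estimates; inverse-variance weighting was rejected as
needless at these SNRs) over carotenoid-positive cells. The
steady-state detector returns the earliest day $d$ such that every
later day's mean ν1 shift stays within `tol` of the final day's. The
default `tol = 2` cm⁻¹ is about twice the fit sd at snr 10; the
"steady state" of the underlying experiment is a visual judgment, and
this rule is the package's formalization of it. On default kinetics it
fires at day 2 (48 h). A single-cell day reports sd = 0 with an
explicit flag.

## Contig binning

Contigs ≤ 2,000 bp are dropped (strict inequality). Features are
canonical 4-mer frequencies: each window maps to the lexicographic
minimum of itself and its reverse complement (contig strand is
arbitrary), windows containing N are skipped, rows sum to 1, and the
canonical space has exactly 136 tetranucleotides. Clustering is
DBSCAN on the raw 136-dim frequencies — not on the embedding — so bins
never depend on t-SNE randomness; `eps` defaults to 2× the median
distance to the `min_samples`-th neighbour, which on 5 kb contigs sits
between within-genome (~0.018) and between-genome (~0.05 at ΔGC 0.15)
distances. k-means is available as the parametric alternative. Per-bin
GC is length-weighted; purity is the largest single-genome bp fraction
per bin, bp-weighted overall. The t-SNE implementation is exact
(quadratic), adequate for thousands of contigs, and seed-deterministic;
PCA is the fully deterministic default in tests. Genome overlap between
two assemblies is reported as canonical 21-mer containment
$|K_b \cap K_a|/|K_b|$ — an explicit approximation to alignment-based
overlap; at k = 21 random collisions are negligible, but containment
counts shared sequence only once regardless of copy number.

## Problem sizes and determinism

All simulations in the test suite use fixed seeds; the generators
save and restore the caller's RNG state. Typical sizes: 45 cells per
timepoint (a realistic single-cell Raman batch), 6 timepoints,
classifier operating characteristics on 1000 cells per arm, 100-seed
loops for distributional properties (20–25 seeds where a sign test at
p < 0.01 already decides), and 20–50 contigs of 5–10 kb per genome for
binning. These sizes make every property decidable in minutes on one
CPU while keeping estimator noise well inside the asserted tolerances.

## Known limitations

* The linear single-$f$ shift model ignores isotopologue envelopes and
  band-specific response; $\hat f$ is a calibration-free first-order
  estimate.
* The intensity-ratio definition is one of several defensible choices.
* The kinetics form is phenomenological; the package detects steady
  state but deliberately does not fit rate constants.
* Synthetic contigs are compositionally stationary; real-genome
  binning is harder than these tests imply.
* No wavenumber calibration: axes are taken as given.
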