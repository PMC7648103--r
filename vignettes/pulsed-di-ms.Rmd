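---
title: "Pulsed direct-infusion MS metabolomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulsed direct-infusion MS metabolomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsedms)
```

`pulsedms` processes metabolomics data acquired by pulsed nanoelectrospray
direct infusion, where a contactless, pulsed ionization source turns
sub-microliter sample loads into trains of discrete spray pulses. This
vignette is the package's account of the science it implements: the models
and procedures, the parameters that matter, what the synthetic generator does
and does not emulate, and the places where the design was genuinely open.

## The acquisition model

A run is a sequence of analyzer scans (centroided m/z–intensity pairs with a
scan time and a polarity). Spray happens in pulses at roughly 0.8 Hz; each
pulse spans several consecutive scans, so the total ion chronogram (TIC)
looks like a comb of well-separated peaks over a near-zero baseline. Because
pulses are orders of magnitude above the background between them, pulse
detection is plain threshold-crossing segmentation: maximal runs of scans
with TIC at or above `min_height` (default 1% of the chronogram maximum), at
least `min_scans = 3` scans long. No derivative-based peak picking is needed
for signals this well separated, and areas are plain trapezoidal integrals
over the detected segment with a zero baseline — chemical background is dealt
with downstream by the blank filter, not by baseline subtraction.

Pulse-to-pulse spray efficiency varies, and it varies *common-mode*: one
pulse delivers more or less total ion current, scaling every species in that
pulse together. That is what makes an internal standard (IS, an
isotope-labeled compound spiked at fixed concentration, default m/z
183.0879) informative at the pulse level: its extracted-ion-chronogram (EIC)
area per pulse tracks the pulse's yield. Pulses whose IS area falls outside
**±20% of the median** IS area across the run's detected pulses are
discarded. Numerical choices the rule itself leaves open, fixed here for
determinism: the window bounds are inclusive; the median of an even count is
the midpoint of the central pair; the median is computed once over all
detected pulses and not recomputed after removals; detection-threshold
truncation is compensated by padding the integration bounds two scans toward
baseline (never crossing a neighbouring pulse).

From the surviving pulses, `k` are selected uniformly at random under a seed
(`k = 5` for the Q-TOF profile, `k = 3` for the Orbitrap profile) — the point
of the method is that a handful of pulses carries a full spectral
fingerprint. All scans inside the selected pulses are pooled; peaks are
clustered by m/z with single-linkage at 10 ppm; each cluster's m/z is the
intensity-weighted mean and its intensity the **mean over all pooled scans**,
a scan lacking the peak contributing zero. Averaging rather than summing is a
deliberate choice: the downstream IS normalization makes the two equivalent
up to scale, and an average keeps intensities on the per-scan scale that the
instrument abundance thresholds (2e3 for the Q-TOF profile, 1.5e4 for the
Orbitrap profile) are defined on. Peaks below the threshold are removed last.
If fewer than `k` pulses survive the IS window, the replicate is flagged as
failed rather than padded with rejected pulses.

## Feature table and the filter cascade

Representative spectra are aligned across runs by the same single-linkage
ppm clustering (default 10 ppm, matching the annotation tolerance); a
feature's m/z is the intensity-weighted mean of its member peaks and absence
is an explicit missing value. After dividing every run by its own IS value
(and dropping the IS feature), the cascade applies:

* **Blank filter** (factor 3): a feature is removed when its mean abundance
  over biological samples is below 3× its mean in the blank runs. The
  comparison uses group means; a per-sample variant (censoring individual
  sample values below 3× blank) is available behind
  `blank_filter(per_sample = TRUE)` since the rule can be read either way.
  Absence in the blank counts as zero, so blank-absent features are kept.
* **Prevalence filter** (0.8): detected in at least 80% of biological
  samples, boundary inclusive — 16 of 20 qualifies.
* **QC-missingness filter** (0.8): removed when missing in ≥80% of QC
  injections or absent from all of them.
* **Sample outlier rule** (0.2): a biological sample missing strictly more
  than 20% of the retained features is removed. Missingness is evaluated
  after the feature filters and before imputation, matching the order in
  which the rules are stated.
* **Imputation**: every remaining missing value becomes half the minimum
  positive value of the whole table.
* **QC RSD filter** (0.30): per-feature relative SD across QC injections
  (sample SD, n−1 denominator, over the mean), strictly greater than 30%
  removed. `median_rsd_qc()` summarizes platform precision as the median of
  these RSDs.

Boundary semantics ("at least 80%" inclusive, "more than 20%" strict,
"> 30%" strict) are taken literally from how the rules are stated. The four
feature filters commute on complete tables; with missing values their order
can matter, so the package fixes a canonical order (blank → prevalence →
QC-missingness → sample outlier → imputation → RSD) for reproducibility, and
the test suite's order-permutation harness reports divergences across all 24
orders rather than asserting an equality that does not hold in general.
Every applied step is recorded in an append-only provenance log;
`replay_filters()` re-applies a log to reproduce a table exactly.

## Statistics

The split of scales is deliberate and mirrors standard metabolomics
practice: **fold changes** are group-mean ratios (second group over first)
on the un-transformed, IS-normalized, imputed table; **p-values, multivariate
models and correlations** are computed on the generalized-log transformed,
autoscaled matrix of biological samples.

The glog transform is `x -> log2((x + sqrt(x² + λ²))/2)`; λ defaults to the
table's minimum positive value (`"auto"`), is expressed in abundance units,
and the transform tends to `log2(x)` as λ → 0. Autoscaling centers each
feature to mean 0 and scales to unit SD (n−1). Univariate testing is the
two-tailed Welch unequal-variance t-test; no multiple-testing correction is
applied by default because selection is a joint criterion — volcano
(p < 0.05 and FC > 2 or FC < 0.5, strict inequalities) intersected with
PLS-DA VIP > 1.8 (strict).

PLS-DA is PLS1 via NIPALS on ±1-coded classes (second group codes +1):
per component, the weight vector is the normalized covariance `X'y`, scores
`t = Xw`, loadings `p = X't/t't`, y-loading `q = y't/t't`, followed by
deflation of X and y. The algorithm is deterministic — no random
initialization — and the default of 2 components matches the
two-dimensional score plots standard in this field. VIP scores use
`VIP_j = sqrt(p · Σ_a SSY_a (w_ja)² / Σ_a SSY_a)` with unit-norm weights and
`SSY_a = q_a² t_a't_a`, so mean(VIP²) = 1 exactly. VIP is computed on the
plain multi-component PLS-DA model, not on the orthogonal variant.

oPLS-DA uses orthogonal signal correction: `n_ortho` components (default 1,
the standard choice for a two-class design) of X-variation orthogonal to y
are estimated and removed, then a single predictive PLS component is fitted
on the filtered matrix. Class prediction thresholds predicted y at the
midpoint of the training class means. Leave-one-out cross-validation refits
everything per fold, including the autoscaling parameters, so the held-out
sample never leaks into the scaling; sensitivity is reported against the
second group label (the stimulated / post-challenge class) by default. PCA
is an eigendecomposition of the autoscaled matrix via `prcomp`, with the
sign convention that each component's largest-magnitude loading is positive.

## Accurate-mass annotation

Formulas are parsed from condensed notation into element counts (Hill-order
canonical form) and summed over CODATA/IUPAC monoisotopic atomic masses
stored to at least six decimals. Adduct m/z is
`(M + mass_delta)/|charge|` where `mass_delta` includes the electron gained
or lost with the charge: a protonated ion adds 1.007276 Da (proton), not
1.007825 Da (hydrogen atom) — the electron mass matters in the fourth
decimal at these m/z. Only singly charged adducts are supported. Rounding to
the customary 4 printed decimals happens only at report time, half-up.
Annotation compares every candidate × adduct against each feature m/z,
keeps matches within `tol_ppm` (default 10; 5 for high-confidence work), and
sorts by absolute ppm error with lexicographic tie-breaks for determinism.
Fragmentation-based identification (MS/MS spectral matching) is out of
scope; hits are accurate-mass-and-adduct candidates only.

## The synthetic study generator

The generator exists so that every stage has a ground truth. It emulates:

* pulse trains at 0.8 Hz with 6–7 scans per pulse: scan period 0.1 s and a
  mean pulse support of 0.7 s. (The support must be shorter than the 1.25 s
  pulse period: with a coarser scan period the supports needed for 6–7 scans
  per pulse would touch and threshold segmentation could not separate
  pulses.)
* pulse envelopes that are unit-area truncated Gaussians (support ±3σ, so
  the envelope tapers to ~1% of peak at its edges and trapezoidal
  integration recovers the area to well under 1%). The Gaussian shape is the
  simplest unimodal choice; nothing downstream depends on it.
* pulse width jitter at CV 8.9%, and a common-mode per-pulse yield
  multiplier (log-normal, median 1, CV 10%) shared by all species including
  the IS. The multiplier scales the pulse's *area* (total ion yield), not
  its apex height; tying yield to height would convolve the width jitter
  into IS areas and make the ±20% window reject far more than the small
  minority of pulses the 10% default is meant to produce.
* outlier pulses: with probability 0.1 a pulse's yield is scaled 1.5×.
* a spiked IS at fixed nominal area per pulse, in every run including
  blanks.
* two-group designs with planted fold changes (half up, half down among the
  differential features), log-normal between-sample variation
  (mean-preserving, default CV 20%), pooled QCs built from the mean of all
  sample abundance vectors, and blanks with zero feature signal.
* a randomized run order: blanks first, a leading QC triplicate, then
  pairwise-interleaved samples in randomized pair order with QC triplicates
  inserted every 6 samples while QC injections remain.
* additive Gaussian intensity noise plus a sparse random background, and a
  per-run ~2 ppm mass-calibration offset to exercise ppm alignment.

Default study conditions: 100 features, 10 planted at fold change 5, 10
samples per group, 3 QC injections, 1 blank, 40 pulses per run. Missingness
under these defaults arises from left-censoring at the instrument abundance
threshold — the mechanism real DI-MS data shows — rather than from
abundance-independent dropout; uniform random dropout is available through
`detection_probability` for stress-testing the missingness filters, but is
not part of the default conditions, because dropout of high-abundance
features combined with half-minimum imputation produces pathological
log-scale outliers that no real platform generates at random positions.

What the generator does **not** emulate, and what passing tests therefore do
not show: electrospray physics (Taylor-cone dynamics, adduct-formation
chemistry, in-source fragmentation), isotope patterns and isobaric overlap,
intensity-dependent mass error, drift in spray efficiency over a run
sequence (there is no batch or drift structure to correct), polarity
switching, and real biological covariance between metabolites. Recovery
rates on synthetic studies characterize the pipeline's statistical
machinery, not instrument performance on real biofluids.

All randomness flows from a single study seed through documented per-run
sub-seeds, so every fixture is reproducible; reruns are byte-identical,
including the pipeline's provenance manifest.

## Degenerate inputs and numerical tolerances

Errors are raised, rather than silently patched, for: empty runs, mixed
polarities in one chronogram, an IS missing or non-positive in any run
(failed replicate), fewer surviving pulses than `k` (failed replicate), no
blank when blank filtering is requested, fewer than 2 QC injections for RSD
computations, all-missing tables at imputation, non-positive values at glog,
constant columns at autoscaling or correlation, and training folds with a
single class in cross-validation. Algebraic invariants are maintained to
tight tolerances (autoscaled moments to 1e-10, VIP normalization and score
orthogonality to 1e-8) and verified in the test suite. Problem sizes in the
suite — study sizes, seed counts, random-table counts for the oracle
equivalences — are chosen so the whole suite runs in a couple of minutes on
a laptop core while keeping Monte-Carlo assertions comfortably away from
their thresholds.

## Known limitations

* Annotation is accurate-mass only; isomers and isobars within tolerance are
  indistinguishable and all candidates are returned, ranked by ppm error.
* The pulse detector assumes well-separated pulses; acquisitions where the
  spray duty cycle approaches 100% would need a different segmentation.
* The blank filter's group-mean reading is one of two defensible
  interpretations of the rule; the other is available via a flag.
* mzML import handles centroided MS1 spectra only and rejects profile mode.
* Printed theoretical m/z tables in the annotation literature are not always
  computed with a fully consistent mass table; this package's values are
  internally consistent (CODATA masses, electron-corrected adducts), which
  can disagree with a published table in the fourth decimal for a few ions.
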