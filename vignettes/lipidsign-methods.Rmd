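---
title: "Methods: class-level lipid sign tests, isotopologue correction, and growth metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: class-level lipid sign tests, isotopologue correction, and growth metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidsign)
```

# The analysis problem

A preclinical xenograft study compares vehicle-treated and drug-treated
animals carrying the same patient's tumor, across a handful of patients
(PDX models), with about five animals per arm. Direct-infusion FT-MS
lipidomics yields per-sample intensity vectors over hundreds of assigned
lipids; intensities are only relatively quantitative (they depend on
ionization and total load), many lipids are undetected in some samples, and
per-lipid inference at n = 5 is weak. The package's central design response
is to move inference to the lipid **class**: classes contain many lipids,
and a coordinated direction of change across a class is a far more robust
signal than any single lipid's magnitude.

# The lipidomics pipeline

`lipid_diff()` applies, in order:

1. **Total-intensity normalization** (`normalize_total()`): each sample is
   divided by its summed intensity. This removes per-sample load and
   ionization scale; it also closes the composition (see *Known
   limitations*).
2. **Offset log-transform** (`log_transform()`): all values become
   `log(v + delta)`. The offset keeps undetected zeros finite. The default
   rule sets `delta` three orders of magnitude below the smallest strictly
   positive value in the matrix (`delta = min positive x 1e-3`). An
   alternative subtractive reading (`min positive - 1e-3`) is provided for
   completeness but rejected as the default because, after total
   normalization, intensities are typically far below 1e-3 and that rule
   would give a nonpositive offset; the function errors rather than
   proceeding in that case. The rule used and the realized `delta` are
   recorded in the fit's provenance.
3. **Presence filter** (`presence_filter()`): a lipid is kept when it is
   detected (raw value > 0, via a detection mask frozen before the offset)
   in at least a fraction `2/3` of the control samples *or* of the treated
   samples. The comparison is `>=`, so 2 detections out of 3 samples pass.
   By default the rule must hold within **every patient** — the centering
   step needs a trustworthy control mean per patient — with a pooled mode
   (`presence_scope = "pooled"`) that evaluates detection across all
   samples of each arm. Which scope the original study intended is not
   decidable from its description; both are provided and the choice is
   recorded.
4. **Patient centering** (`center_on_controls()`): per patient and lipid,
   the mean control log intensity is subtracted from all of that patient's
   samples. Treated samples then carry log fold-changes versus their own
   model's control; patient-specific baselines cancel exactly.
5. **Per-lipid t-tests** (`lipid_ttest()`): each lipid's treated
   fold-changes (pooled over patients) are tested against zero, two-sided.
   Lipids with a single treated value are excluded with a reason code;
   zero-variance lipids are flagged degenerate (p = 0 for a nonzero mean,
   p = 1 otherwise) rather than dropped silently.
6. **Class sign test** (`class_binomial_test()`): each lipid contributes
   one sign from its **mean** treated fold-change — the grouping unit is
   the lipid, not the sample, because class membership is a property of the
   lipid. Exact zeros are excluded from the trials but reported as ties.
   With `n_up` successes among `n = n_up + n_down` trials, the success
   proportion `p_hat = n_up / n` is tested against 0.5 by an exact
   two-sided binomial test, and the effect statistic is
   `ln(p_hat / 0.5)`.

## The exact binomial p-value

The two-sided p-value uses the minimum-likelihood convention: the sum of
the null probabilities of all outcomes no more likely than the observed
one. At the null proportion 0.5 the Binomial(n, 0.5) pmf is symmetric, so
this coincides with doubling the smaller tail; the test suite verifies
agreement with full pmf enumeration for every (n ≤ 25, k) pair and with
`binom.test()`. No multiple-testing correction is applied across classes by
default — the class test is a small, structured family — but
`storey_qvalues()` can be applied to the class p-values when a panel grows.

## Properties of the statistic

`ln(p_hat / 0.5)` is zero exactly at `p_hat = 0.5`, positive for net
up-regulation, and unbounded below: a class with every lipid down yields
`-Inf`, which is reported as such rather than truncated (the exact p-value
carries the inferential content; the statistic is a descriptive effect
direction and magnitude). The statistic is **not** antisymmetric under
negating all effects — `p_hat` maps to `1 - p_hat`, so 9:1 up/down gives
ln 1.8 ≈ 0.59 while 1:9 gives ln 0.2 ≈ −1.61. Its sign flips, the up/down
counts swap, and the exact p-value is invariant; the tests assert exactly
that.

# Exact-mass peak assignment

`build_mass_table()` precalculates, for every species × adduct, the m/z of
carbon isotopologues M+0 … M+k: `(M + adduct shift + k × 1.0033548378) /
|charge|`, with electron mass included in the adduct shifts. Default
adducts match ammonium-formate electrospray chemistry: [M+H]+, [M+Na]+,
[M+NH4]+ in positive mode; [M−H]−, [M+HCOO]− in negative mode.
`assign_peaks()` matches each observed peak to the entry minimizing |ppm
error| within a tolerance window, default **1.0 ppm** — twice a 0.5 ppm
instrument accuracy, a deliberately conservative window. Exact ppm ties are
broken toward the lower calculated m/z, then the lexicographically first
species, and always flagged ambiguous, so output is deterministic. Several
peaks may share one table entry (profile-mode data can split a species
across peaks); downstream aggregation sums them. The cross-sample
recurrence filter `hpd_filter()` (default: a feature must recur in at least
half the samples of some arm) is an explicit stand-in reproducibility
filter — the filtering criterion used by the original instrument software
is not publicly specified — and is skippable when the input is already a
curated matrix.

# Natural-abundance isotopologue correction

For a metabolite with n carbons, the observed isotopologue vector is the
true tracer-labeling vector mixed by natural ¹³C: a molecule with j labeled
carbons shows i ≥ j total heavy carbons with probability
`dbinom(i - j, n - j, p13C)`. This lower-triangular system is solved
exactly by forward substitution (`na_correction()`); `na_convolve()` is the
forward map, and the pair is verified to round-trip random enrichment
vectors to 1e-8 for n ≤ 60 and p13C ≤ 0.02. Default `p13C = 0.0107`, the
standard terrestrial abundance; the study conditions fix no other value.
Negative corrected components arise from measurement noise: components
below −1e-12 of the total are clipped to zero **with a warning** and the
vector rescaled to preserve total signal, keeping downstream fractions
valid while leaving an audit trail (a `clipped` attribute); rounding-scale
negatives are zeroed silently. Fractional enrichment divides by the total
(scale-invariant, sums to 1); pools such as AXP = ATP + ADP + AMP are
summed over present members with a completeness attribute rather than
erroring on missing species, because real panels routinely miss members
and the pool headline needs only the observed sum. Multi-element correction
(²H, ¹⁵N) and resolution-dependent isotopologue overlap are out of scope.

# Cohort statistics

- **Wilcoxon rank-sum** (`wilcoxon_ranksum()`): exact two-sided p from the
  U distribution when `n_a + n_b <= 20` and the data are tie-free (smaller
  tail doubled, capped at 1); otherwise a normal approximation with
  continuity and tie correction, with the method recorded. The exact path
  refuses ties and falls back to the approximation with a notice, because
  mid-ranks invalidate the tabulated exact distribution.
- **Storey q-values** (`storey_qvalues()`): the null proportion pi0 is
  estimated as `mean(p > lambda) / (1 - lambda)` on the grid 0.05–0.90
  (step 0.05), smoothed with a cubic spline (df = 3) and read off at the
  largest lambda, clamped to (0, 1]. q-values follow the step-up pass
  `q_i = min over p_j >= p_i of pi0 * m * p_j / rank_j`; with `pi0 = 1`
  this is exactly Benjamini–Hochberg, which the tests assert on 1,000
  random p-vectors. Significance is conventionally called at q < 0.05.
- **Growth metrics**: tumor volume is the caliper formula
  `width² × length × 0.52`; fold-change curves divide by each animal's
  baseline. `auc_tgi()` computes, per animal, the trapezoidal AUC of
  **log** fold-change over the week span shared by all animals (linear
  interpolation at the span ends), divided by the span length. This
  "adjusted AUC" (aAUC) reading — baseline-adjusted via the fold-change
  construction, span-adjusted via the division — is an interpretation, as
  the quantity is not publicly defined; a raw-volume AUC can be had by
  passing volumes as fold changes. `TGI = 1 - mean(treated aAUC) /
  mean(control aAUC)` is 0 for identical arms and 1 for a flat treated arm;
  the percentile bootstrap (default 2,000 draws, resampling animals within
  arms under a fixed seed) supplies the confidence interval. TGI is flagged
  undefined when the control mean aAUC is nonpositive (a non-growing
  control arm makes the ratio meaningless).
- **Immunoreactivity score** (`irs_score()`): staining intensity code
  (0–3) times percent-positive category (0: none; 1: up to 10%; 2: 11–50%;
  3: above 50%). Fractional percentages between 10 and 11 stay in category
  1, reading the printed integer bins as "category 2 starts at 11".

# The synthetic-data generators

The generators exist so that every downstream stage has a ground truth. The
lipidomics generator (`simulate_lipidomics()`) draws

```
log intensity = lipid baseline + patient x lipid offset
              + class effect (treated samples only) + per-sample noise
```

exponentiated to lognormal intensities, with cells zeroed independently
with probability `1 - detection_rate`. Defaults define the emulated study
conditions: 3 patients with 5 control + 5 treated samples each (matching a
five-per-arm in vivo design), 10 classes × 15 lipids, baseline log
intensities N(log 1e6, 1.5²) — intensities spanning a few orders of
magnitude, as direct-infusion data do — per-sample noise sd 0.25 on the
natural-log scale, a per-(patient, lipid) baseline offset sd 0.5 that the
centering stage removes exactly, and complete detection (missingness is
opt-in because it is a separate mechanism worth varying deliberately).
Lognormal intensities were chosen because the pipeline log-transforms;
missingness is completely at random because the presence filter only needs
a presence/absence mechanism. These are emulation choices, not claims about
real data: the generator has no correlated lipids within a class beyond the
shared effect, no intensity-dependent detection, no adduct splitting, and
no instrument drift — so passing tests certify the statistics, not
robustness to those realities.

Each generator derives a substream seed from the single global seed and its
stream name, and restores the caller's RNG state, so adding a generator
never shifts existing draws and identical config + seed is bit-identical.
The truth (per-class and per-lipid effects, growth rates) is emitted
alongside the data and never read by analysis code.

`simulate_isotopologues()` forward-convolves a chosen enrichment with
natural abundance and applies multiplicative noise, so zero-noise output is
exactly invertible. `simulate_growth()` uses 100 mm³ × exp(rate × week)
with multiplicative lognormal noise at each weekly visit.

# Verification at scale

The test suite exercises, among others: exact binomial agreement with pmf
enumeration for all n ≤ 25; exact rank-sum agreement with full `combn`
enumeration for every group-size split up to n = 12; the BH identity on
1,000 random p-vectors; NA-correction round trips at n ≤ 60; empirical size
of the class test within [0.03, 0.07] over 500 null cohorts (10 classes ×
15 lipids, 3 patients × 5+5 — the exact-test size is conservative, about
0.035 at n = 15, because the binomial is discrete); and detection of a
−1.0 log-unit class shift (20 lipids, noise sd 0.1) with negative statistic
and p < 0.01 in at least 95% of 200 replicates. These problem sizes keep
the full suite under half a minute while leaving Monte-Carlo margins wide.

# Known limitations

**Compositional closure.** Total-intensity normalization divides by a sum
the treatment itself changes. Centered fold-changes therefore all carry a
common shift equal to the log ratio of control to treated totals; when a
class with intensity share w is suppressed by a log effect of −1, that
shift is about `-log(1 - w(1 - e^-1))` (≈ 0.065 at w = 0.1) applied to
*every* lipid. Consequences: (i) absolute fold-change magnitudes from the
pipeline are biased whenever large classes move, and parameter-recovery
checks are done either on the generator's open-composition estimate or with
`normalization = "none"`; (ii) under strong one-sided shifts, null classes
acquire a common drift that the sign test can flag — visible in the README
example. This is intrinsic to relative-abundance data, not an
implementation artifact; interpreting class calls alongside the sign of the
common drift, or focusing on classes consistent across several PDX models,
mitigates it.

**Offset sensitivity.** Lipids undetected in a patient's controls enter the
centering at `log(delta)`; the presence filter exists precisely to keep
such lipids out, and lowering its fraction re-admits them.

**Small-n exactness.** With 15–20 lipids per class the exact binomial test
is conservative; the class statistic's −∞ at `p_hat = 0` is informative but
unusable for averaging across cohorts — use the p-value or the counts.

**Out of scope.** Raw spectra (profile-mode scans, NMR FIDs), MS/MS
scoring, retention-time modeling, linear mixed models across pooled PDX
models, survival analysis, and PCA plotting are deliberately not provided;
standard tools cover them once this package has produced its tables.
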