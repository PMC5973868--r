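# lipidsign

Quantitative analysis of preclinical control-versus-treated xenograft (PDX)
studies with FT-MS lipidomics and stable-isotope-resolved metabolomics
(SIRM) readouts. The package was written for the setting where a targeted
metabolic inhibitor (e.g. a fatty-acid-synthase inhibitor) is given to
tumor-bearing mice and the question is which lipid **classes** move, how
labeled metabolite pools change, and how much tumor growth is inhibited —
with few animals per arm and intensities that are only relatively
quantitative.

## The core statistic

Per-sample lipid intensities are normalized by the sample's total
intensity, log-transformed after adding an offset three orders of magnitude
below the smallest observed positive intensity, and filtered to lipids
detected in at least 2/3 of either arm's samples. For each patient (PDX
model) the mean log intensity of its control samples is subtracted from all
of that patient's samples, turning every treated sample's value into a log
fold-change versus control. Each lipid is tested against zero with a
two-sided one-sample t-test, and each lipid **class** is summarized by a
sign test: lipids with mean fold-change > 0 are successes, < 0 failures,
and the success proportion p&#770; is tested against 0.5 with an exact two-sided
binomial test. The reported class effect statistic is

    statistic = ln( p_hat / 0.5 )

which is 0 when up- and down-regulated lipids balance, ln 2 ≈ 0.693 when
every lipid moves up, and −∞ when every lipid moves down.

Around this sit: exact-mass assignment of FT-MS peak lists against a
precalculated species × adduct × isotopologue m/z table at ppm tolerance;
natural-abundance ¹³C isotopologue correction by exact lower-triangular
binomial deconvolution, with absolute and fractional enrichments, protein
normalization, pool sums (e.g. AXP = ATP + ADP + AMP) and labeled-ratio
percent changes; Wilcoxon rank-sum tests (exact for small tie-free samples)
with Storey q-values; caliper tumor volume (TV = width² × length × 0.52),
baseline fold-change curves, and AUC-based tumor growth inhibition (TGI)
with a bootstrap confidence interval; and the IHC immunoreactivity score.
Seeded synthetic-data generators emulate the whole study design so every
stage is testable without external data.

## Worked example

```r
library(lipidsign)

# a synthetic 3-PDX study, 5 control + 5 treated samples per model,
# with phosphatidylcholines suppressed and sphingomyelins elevated
sim <- simulate_lipidomics(sim_config(
  class_effects = c(PC = -0.6, SM = 0.6), lipid_noise_sd = 0.3, seed = 42))
fit <- lipid_diff(sim)
summary(fit)
```

```
Class-level binomial sign tests (statistic = ln(p_hat / 0.5)):

  class n_up n_down n_tie  p_hat statistic   p_value
 LacCer    0     15     0 0.0000      -Inf 6.104e-05
     PC    0     15     0 0.0000      -Inf 6.104e-05
     PI    0     15     0 0.0000      -Inf 6.104e-05
     SM   15      0     0 1.0000    0.6931 6.104e-05
     PA    1     14     0 0.0667   -2.0149 9.766e-04
     PE    3     12     0 0.2000   -0.9163 3.516e-02
     PS    3     12     0 0.2000   -0.9163 3.516e-02
     TG    3     12     0 0.2000   -0.9163 3.516e-02
    Cer    5     10     0 0.3333   -0.4055 3.018e-01
 HexCer    5     10     0 0.3333   -0.4055 3.018e-01

Per-lipid t-tests: 150 lipids, 63 with p < 0.05
```

The two configured classes sit at the extremes: every sphingomyelin is up
(p&#770; = 1, statistic ln 2) and every phosphatidylcholine down. The remaining
classes share a common negative shift: total-intensity normalization closes
the composition, so raising one large class (here SM carries a sizable
share of the total signal) depresses every other normalized value. This is
a property of relative-abundance data, not a bug; the methods vignette
(`vignettes/lipidsign-methods.Rmd`) quantifies it.

Growth analysis on the same seed:

```r
g <- simulate_growth(n_per_arm = 5, t_max_weeks = 5,
                     growth_rate_control = 0.35, growth_rate_treated = 0.12,
                     noise_sd = 0.1, seed = 42)
auc_tgi(g, n_boot = 2000, seed = 42)
```

```
Tumor growth inhibition (adjusted AUC of log fold-change)
  aAUC control = 0.908, treated = 0.2971 (weeks 0-5)
  TGI = 0.6728  [95% CI 0.6113, 0.7438; 2000 bootstrap draws]
```

So the treated arm accrued about 33% of the control arm's log-scale growth
area — a TGI of 0.67 with a CI well above zero. Single measurements work
the same way: `tumor_volume(7.2, 10.5)` gives 283.0464 mm³, and
`irs_score(3, 80)` gives the maximal immunoreactivity score 9 (strong
staining, > 50% positive cells).

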