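---
title: "Methods: longitudinal urine NMR metabolic profiling with uromet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal urine NMR metabolic profiling with uromet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

uromet analyzes two-group longitudinal urine studies profiled by 1D ^1^H
NMR: a control group and a study group sampled repeatedly (the default
design uses weeks 1, 3, 5 and 7), with the question being *when* the two
groups' urinary metabolomes become statistically distinguishable and *which*
metabolites drive the difference. This vignette is the package's account of
the statistical machinery, the choices behind it, and its limits.

## From spectra to the bucket matrix

Each spectrum is referenced so the TSP internal standard sits at exactly
0.0 ppm (`reference_to_tsp()` shifts the ppm axis so the intensity argmax in
a ±0.3 ppm window lands on zero; the applied shift is reported). The axis is
then partitioned by a *bucket scheme*: a list of ppm intervals, in the
descending-ppm display convention with a closed-left/open-right rule
(`[left, right)`), so adjacent buckets can share an edge without ambiguity
about which one owns it. `integrate_buckets()` computes the trapezoidal
integral of intensity over each bucket on the native grid, interpolating the
two boundary ordinates; there is no resampling. Trapezoidal integration on
the native grid is the simplest rule whose split-additivity is exact
(integrating two adjacent half-buckets reproduces the whole to 1e-12), which
the tests rely on. Numerically negative integrals — baseline artifacts —
are clipped to zero with a warning because the bucket matrix is defined as
non-negative.

The example scheme shipped with the package excludes three regions as is
standard for urine: water (5.00–4.50 ppm), urea (6.20–5.40 ppm) and the TSP
region (0.20 to −0.20 ppm). These exclusions are illustrative defaults, not
a reconstruction of any particular instrument setup.

Each sample's buckets are then divided by their own total
(`normalize_total_intensity()`), making every row sum to 1. Any positive
normalization constant gives identical downstream statistics (Welch t, AUC
and PLS-DA after column scaling are all scale-invariant per sample), so the
package uses 1 as the cleanest invariant to test. Two consequences of
total-intensity normalization matter for interpretation and are visible in
the synthetic cohorts:

* it can *increase* apparent variance in individual buckets, because each
  bucket inherits the variability of the whole-spectrum total;
* it couples buckets: a genuine increase in some metabolites mechanically
  depresses the normalized values of every other bucket. With a strong
  multi-metabolite effect, unaffected buckets can therefore reach
  significance with negative fold changes. This is a property of
  compositional data, not an artifact of the implementation.

## Univariate screening

For each bucket, `compare_buckets()` tests control vs study with Welch's
unequal-variance two-sided t-test. The per-bucket test family is controlled
by Bonferroni: each of the K buckets is tested at `alpha_total / K`
(0.05/114 ≈ 4.39e-4 for the default 114-bucket scheme), which caps the
family-wise false-positive probability at `alpha_total`. Welch's test was
chosen as the default because the per-bucket test is otherwise unspecified
in this analysis tradition and unequal group variances are the norm after
total-intensity normalization; a Wilcoxon rank-sum alternative sits behind
`method = "wilcoxon"` for heavy-tailed buckets.

Alongside p-values the screen reports the Mann–Whitney AUC — the
probability that a random study sample exceeds a random control sample in
that bucket, ties counted half — computed from ranks, which equals
brute-force pair counting exactly. AUC is flagged when it reaches 0.75 from
either side (`auc >= 0.75` or `<= 0.25`). The 0.75 default is the package's
own cut-off for "useful single-feature discrimination"; AUC thresholds for
biomarker screening are conventionally placed between 0.7 and 0.8 and the
flag is configurable. Log2 fold changes are computed on group means of
normalized intensities, study over control.

## PLS-DA

`fit_plsda()` implements two-class PLS-DA as single-response NIPALS PLS1.
Class labels are coded +1 (study) / −1 (control) and centered; the bucket
matrix is centered and unit-variance scaled by default (`scaling = "uv"`,
with `"pareto"` and `"none"` available). Per component the weight vector is
`w ∝ X'y` normalized to unit length, scores `t = Xw`, X-loadings
`p = X't/t't`, y-loading `c = y't/t't`, followed by deflation of both X and
y. For a single response this is a closed form — no iteration, no
convergence tolerance. Two numerical conventions make fits bit-for-bit
reproducible: the largest-magnitude entry of each weight vector is made
positive, and fold assignment in cross-validation is deterministic (below).
The default of A = 2 components matches the two-dimensional score plots the
separation test operates on.

R²Y(cum) is the fraction of class-label variance captured by the fitted
components. Q²(cum) (`cross_validate_q2()`) is its cross-validated
counterpart, `1 − PRESS/SS`: the data are split into 7 segments (each round
withholds 1/7 of the samples), the model — *including* the centering and
scaling parameters — is refit on the remaining 6/7, and held-out class
responses are predicted. Re-estimating the preprocessing inside each fold
avoids leakage of held-out information through the column means and scales.
Folds are assigned by interleaving within each class (sample *i* of a class
goes to fold `1 + (i−1) mod 7`), the venetian-blind rule: it keeps folds
class-balanced and needs no random seed. If a class has fewer samples than
folds the function refuses and asks for fewer folds rather than silently
producing folds that lose a class.

VIP scores summarize per-bucket influence:
`VIP_k = sqrt(K · Σ_a SS_a w_ak² / Σ_a SS_a)` with `SS_a = c_a² t_a't_a`.
The mean squared VIP is exactly 1, so VIP > 1 marks above-average influence;
the identity is asserted to 1e-9 in the tests.

## The cluster-separation test

Whether the two clouds of points in a score plot are *statistically*
separated is decided by a Mahalanobis-distance F-test
(`assess_separation()`). With group centroids `m1, m2` and pooled
within-group covariance `S`,

* `D = sqrt((m1−m2)' S⁻¹ (m1−m2))`,
* `T² = (n1·n2/(n1+n2)) · D²` (two-sample Hotelling statistic),
* `F = ((n1+n2−p−1)/(p·(n1+n2−2))) · T²` with `p` score dimensions.

Two degrees-of-freedom conventions are offered for the critical value
`critical_f(alpha, df1, df2)` (the upper-tail F quantile, computed to 1e-6):

* `convention = "paper"` (default): `df1 = n1 − 1`, `df2 = n2 − 1` — the
  per-group rule commonly used when this test is reported in published
  metabolic-profiling studies, kept as the default for comparability with
  that literature;
* `convention = "hotelling"`: `df1 = p`, `df2 = n1 + n2 − p − 1` — the
  textbook null distribution of the two-sample Hotelling statistic.

The conventions differ materially: simulation shows the `"hotelling"` rule
rejects at ≈ 5% when both clouds are drawn from one common distribution
(0.043 over 1000 replicates in the test suite), while the per-group rule is
anti-conservative for small `p`. Both are exposed; the calibrated one is
what the package's error-rate claims are stated against.

One caveat the package deliberately documents rather than hides: when the
score clouds come from a PLS-DA fitted *on the same group labels*, the
separation test inherits selection bias — PLS-DA constructs the projection
that maximizes group covariance, so even null data produce well-separated
score clouds and the F-test rejects almost always, under either convention.
Pipeline-level F-values should therefore be read as descriptive summaries
of the achieved projection, not as calibrated hypothesis tests; calibrated
judgments about predictive structure belong to cross-validated Q². The
calibration claim above applies to score clouds that were not chosen to
separate the groups.

Week-level worked examples fixed in the test suite: `D = 6.735` with
`n1 = n2 = 14` and `p = 2` gives `F = 152.65`, and `D = 4.46` with
`n1 = n2 = 19` gives `F = 91.86` (a value printed as 91.72 alongside a
3-significant-figure D is compatible within that rounding). Two further
published-style pairs (`D = 4.46 → F = 59.19` at `n = 14`; `D = 3.863 →
F = 64.964`) are *not* reproducible under the same conversion with the
stated group sizes — the conversion yields 66.93 and 68.9/50.2 respectively
— and are treated as known discrepancies (typos or unstated per-week group
sizes), excluded from regression values.

## Per-week pipeline and the longitudinal summary

`run_timepoint()` chains the stages for one week: normalize → univariate
screen → PLS-DA fit → 7-fold Q² → separation test → annotation. A
metabolite is called significant when *any* of its constituent buckets
passes the Bonferroni screen; with 2–4 resonances per metabolite this
any-bucket rule is the natural aggregation when per-bucket tests are the
primitive, and it is deliberately permissive (one clean resonance
suffices, as in manual spectral review). Degenerate inputs are handled
explicitly: a table with no between-bucket variation left after
normalization (e.g. a single bucket) runs the univariate screen and skips
the multivariate stages with a warning.

`build_trend_matrix()` assembles the longitudinal summary: per metabolite
and week, the log2 fold change of its most-changed significant bucket,
masked to 0 where nothing passes the screen, rows ordered by peak absolute
change. The masked log2 fold change is the package's own heat-map statistic
— it encodes direction, magnitude and significance in one number — and the
matrix is exactly antisymmetric under swapping the group labels, which the
tests assert. `plot_trend_heatmap()` renders it.

## The synthetic cohort generator

`synthetic_design()` + `generate_cohort()` produce cohorts with known
ground truth so that error rates, power and parameter recovery are
assertable without any external data. The generative model:

* **Concentrations.** Each metabolite's concentration is log-normal per
  sample. Urinary concentrations are positive and right-skewed, which the
  log-normal captures with two parameters; no distributional claim beyond
  that is intended. The default within-group spread is
  `baseline_log_sd = 0.12` (≈12% CV). This is the generator's one genuinely
  free parameter and was calibrated once, at design time, so that the
  default effect trajectory is detectable at the default group size — the
  regime the pipeline is built for: with 15 samples per group, a 1.6-fold
  change passes the 0.05/114 Bonferroni threshold with power ≈1, while the
  week-7 1.1-fold residual effect mostly does not. Real urine cohorts often
  show larger inter-animal variation; with wider spread the same pipeline
  simply needs larger folds or groups, and `estimate_power()` maps that
  surface.
* **Effects.** Affected metabolites in the study group are multiplied by a
  per-week fold. The default trajectory `(1.2, 1.6, 1.5, 1.1)` over weeks
  `(1, 3, 5, 7)` encodes rise-to-peak-then-attenuate dynamics: an effect
  that builds through weeks 3–5 and largely resolves by week 7. The
  magnitudes are the package's defaults for a detectable-then-fading
  signal, not measured values.
* **Spectra.** Each resonance line is a unit-area Lorentzian with full
  width 0.0017 ppm (≈1 Hz at 600 MHz, a well-shimmed line) at its library
  position plus per-sample Gaussian jitter (SD 0.002 ppm, small pH/ionic
  shift variation), scaled by concentration × relative intensity. Additive
  Gaussian noise is 1% of the median peak height by default. The spectrum
  path (`generate_spectrum()`, grid of 2^15 points over 0.5–9.5 ppm,
  refused if coarser than 4 points per linewidth) renders full spectra for
  testing the bucketing stage; the table path computes each line's analytic
  Lorentzian mass inside every bucket within 0.2 ppm, which is faster and
  is what the simulation loops use. The two paths agree to ≈2% (the table
  path truncates far tails).
* **The library.** 114 resonance lines: 32 named urine metabolites with
  literature-style shift positions and 57 unassigned singlets (real urine
  bucket tables always carry unassigned resonances). Eight metabolites are
  affected by default. Line positions are spaced ≥0.05 ppm so the derived
  0.04-ppm buckets never overlap, and avoid the water/urea/TSP exclusions.
  The file is plain TSV and explicitly *configuration*: the positions are
  plausible, not measured, and any library with the same columns can be
  substituted.

What the generator does **not** emulate: J-coupling multiplet structure,
pH-dependent shift migration (jitter is i.i.d., not systematic), baseline
distortions, relaxation-weighted intensities, and correlated metabolite
physiology (concentrations are independent across metabolites given the
group). Passing the simulation suite therefore demonstrates that the
statistics behave as designed under the model's assumptions — log-normal
positive data, independent features, shift jitter small relative to bucket
width — not that any particular real cohort will reach the same power.

`estimate_type1_error()` (null design, family-wise rate with binomial SE)
and `estimate_power()` (per-metabolite detection rate) wrap the replicate
loops; both derive every replicate from the design's master seed, so runs
are exactly reproducible.

## Enrichment

`hypergeometric_ora()` tests each user-supplied metabolite set for
over-representation of the significant metabolites: upper-tail
hypergeometric p-value on the observed overlap, after intersecting each set
with the analysis universe, with Holm adjustment across sets. Holm was
preferred over Bonferroni here because the set family is small and Holm is
uniformly more powerful at the same family-wise control. Topology-weighted
pathway-impact scoring is explicitly out of scope: it requires curated
pathway graphs, an external resource; over-representation captures the
ranking use-case with auditable arithmetic (the tests verify it against
brute-force tail enumeration for universes up to 25).

## Problem sizes used by the test suite

The shipped suite runs the full 114-bucket, 15-per-group design for the
family-wise error simulation (500 replicates), the cloud-level separation
calibration (1000 replicates), power at fold 3.0 (100 replicates) and three
full 4-week cohorts for trend recovery; the remaining unit and property
tests use reduced designs (6–20 buckets, 3–12 samples per group). These
sizes give Monte-Carlo standard errors comfortably below the asserted
margins (all simulation assertions carry explicit ±3·SE bands) while the
whole suite completes in well under a minute.

## Known limitations

* Only two groups; no multi-class PLS2/OPLS-DA, no MANOVA-style >2-group
  separation test.
* No peak alignment beyond the global TSP shift; strong pH-driven
  migration would smear intensity across bucket boundaries.
* Bonferroni only (by design): with hundreds of correlated buckets it is
  conservative; there is deliberately no FDR option because family-wise
  control is the contract the screening reports.
* The separation F-test on PLS-fitted scores is descriptive, as discussed
  above.
* Fold changes of near-zero control means are numerically fragile; buckets
  that integrate to ~0 in one group should be reviewed manually.
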