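---
title: "Predicting sake sensory scores from LC-MS peak tables: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting sake sensory scores from LC-MS peak tables: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sakesense)
```

## The problem

Untargeted LC-MS metabolome analysis of sake yields a *peak table*: one row
per injection (each sample is injected in triplicate), one column per
detected feature, with retention time (minutes) and mass-to-charge (Da)
metadata per feature. Trained panels score the same sake samples on defined
attributes (sweetness, body, *ginjo-ka*, ...) by quantitative descriptive
analysis (QDA) on bounded line scales. `sakesense` implements the full
chain that links the two: peak-table quality filtering, sensory-panel QC,
single-response OPLS regression of each attribute on the peak intensities
with replicate-aware cross-validation and permutation validation, signed
VIPpred variable importance, and transfer validation of a model on an
independent year's data.

## Preprocessing

**Peak filters.** Two filters, in a fixed order. First, peaks whose maximum
intensity over all injections is zero are removed (never detected). Second,
for each remaining peak the percent coefficient of variation of the
replicate injections is computed per sample, CV = 100·sd/mean with the
n−1 standard deviation; a peak is removed when its worst sample reaches
CV ≥ 10% (inclusive), or when any sample has a zero replicate mean (the CV
is then undefined; we treat it as infinite and remove the peak, reading an
undetected-in-one-sample peak as unreliable). Both filters are idempotent.
The n−1 convention and the inclusive threshold are exposed as the
documented behaviour; the threshold itself is a parameter
(`threshold_percent`, default 10).

**Annotation.** A library entry is a candidate for a peak when |ΔRT| ≤ 0.1
min and |Δm/z| ≤ 0.007 Da (inclusive; a flag switches to strict). Among
candidates the assignment minimises the normalised combined distance
|ΔRT|/tol_RT + |Δm/z|/tol_mz, with exact ties broken by compound name so
the assignment is deterministic. All candidates are kept in the output.

**Extra variables.** General properties and aroma compounds measured per
sample (acidity, ethyl hexanoate, ...) can be appended as pseudo-peak
columns, broadcast over a sample's injections, giving e.g. 430 peaks + 10
extra variables = 440 columns.

## Sensory QC

Outliers are identified per (sample, attribute) group, pooling panelists
and rounds, with Tukey box-whisker fences: linear-interpolation quartiles
(type 7), fences at Q1 − 1.5·IQR and Q3 + 1.5·IQR, records strictly
outside removed in a **single pass**. Pooling panelists and rounds is an
interpretation: the boxplots are described per attribute and sample, and a
per-round split would leave too few points for quartiles. Groups with
fewer than 4 records pass through untouched.

Attributes are then gated by one-way fixed-effects ANOVA with sample as
the factor on the individual post-QC scores (α = 0.05); attributes whose
samples do not differ are reported but not modelled. Degenerate cases take
their limits: identical score multisets across samples give F = 0, p = 1;
zero within-group variance with non-zero between-group variance gives
F = ∞, p = 0. Sample × attribute mean scores over the remaining records
are the responses used downstream.

## The OPLS model

Each attribute is modelled separately: y is the attribute's sample-mean
score, replicated over a sample's injections, and X is the
injection × peak matrix. Both are UV-scaled (mean 0, unit variance, n−1
sd); scaling y as well as X follows the default of the commercial software
this procedure is usually run in. Zero-variance variables are dropped and
recorded.

The estimator is NIPALS O-PLS for a single response, written
"1 + k + 0": one predictive component, k X-orthogonal components, zero
y-orthogonal components. Each orthogonal round computes the predictive
weight w ∝ X'y, the loading p of the predictive score, extracts the
orthogonal weight w_o ∝ p − (w'p)w, and deflates X by the orthogonal
component t_o p_o'. The final predictive component is computed on the
deflated matrix, so t'T_o = 0 to machine precision. Predictions for new
data replay the stored orthogonal filters and apply the training scaling
parameters.

R² is 1 − SS_res/SS_tot on the scaled response. RMSE is reported on the
original score scale with denominator n (the convention is configurable to
n − a − 1 via `rmse_denominator`, since the printed convention of
commercial software is not documented).

**Cross-validation.** Q² uses 7-fold cross-validation grouped by sample:
whole samples, with all their replicate injections, are dealt to folds
round-robin after a seeded shuffle, so fold sizes differ by at most one
sample and replicates can never leak across folds. Scaling parameters are
re-estimated inside each training fold (no leakage); a
`scale_in_fold = FALSE` switch reproduces the global-scaling convention of
the commercial packages for comparability. PRESS accumulates squared
residuals of the held-out injections on the training fold's y-scale, and
Q² = 1 − PRESS/SS with SS the held-out total sum of squares on that same
scale. Variables that become constant within a training fold are dropped
for that fold only.

**Component selection.** Forward search from k = 0: k + 1 is accepted only
when it strictly increases Q²; the search stops at the first non-increase
(or at `max_a_o`, default 8).

**Permutation validation.** The response is permuted over samples
(replicates keep their sample's permuted value) 100 times; each
permutation is refit with the same component count and folds. A model is
flagged valid when three conditions hold:

1. the R² intercept of the regression of permuted R² on |correlation with
   the original response| (anchored by the unpermuted model at
   correlation 1) is below 0.3;
2. the corresponding Q² intercept is below −0.05;
3. the empirical permutation p-value of Q²,
   (1 + #{Q²_perm ≥ Q²_model})/(n_perm + 1), is below 0.05.

The two intercept rules detect overfitting. They cannot, however, reject a
model with no signal at all: for such a model the permuted cloud and the
unpermuted point coincide, the regression line is flat, and both
intercepts sit comfortably below their thresholds. The p-value condition —
standard practice in chemometrics software such as the `ropls`
Bioconductor package — supplies the missing null rejection. The raw
permutation cloud is always kept in the report so users can apply any
alternative rule. When validation fails, orthogonal components are removed
one at a time and the test repeated until it passes or k = 0; a model that
never validates is returned at k = 0 flagged invalid.

**CV-ANOVA.** Model significance is summarised by
F = ((SS_tot − PRESS)/a) / (PRESS/(n − a − 1)), with a the total number of
latent variables and n the number of injections, referred to
F(a, n − a − 1). The degrees-of-freedom convention of the commercial
implementation is unpublished; this follows the published CV-ANOVA
construction.

**Signed VIPpred.** With a single predictive component the predictive VIP
reduces to vip_j = √p·|w_j|/‖w‖, so mean(vip²) = 1 exactly. Each
variable's VIP is signed by the Pearson correlation between its
sample-mean intensity and the attribute's sample-mean score (correlation
at the sample level, where sensory scores exist). Variables with
vip > 1.5 (strict) are selected; zero-variance variables get sign 0 and
are never selected.

## Transfer validation

Peaks are matched across two independently processed datasets by mutual
nearest match within the annotation tolerances; transfer models are built
on the matched variables. The target matrix is scaled with the **training**
model's parameters — the target year is treated as unknown, no
re-centering — the orthogonal filters are applied, and validation R² is
the coefficient of determination 1 − SS_res/SS_tot on the target response
scaled by the model's y-parameters (it can be negative; the squared
Pearson correlation is reported alongside, since printed values near zero
are consistent with either definition). Variables with |signed VIP| > 1.5
in *both* years are selected; models refit on this common set are
evaluated the same way. Attribute correspondence across years (e.g. a
composite aroma in one year against a single-ester attribute in the other)
is declared by the user, never inferred.

## The synthetic-data generator

Real two-year sake studies deposit no raw data, so the package ships a
generator that emulates the statistical structure the analysis assumes and
records the ground truth needed to verify every stage end-to-end.

**Peak intensities.** Sample-level log-intensities follow a low-rank
factor model: six shared factors with variance shares (0.50, 0.33, 0.08,
0.05, 0.02, 0.02) and per-peak communality 0.8, plus unique variation;
intensities are exp-transformed log-normals with per-peak location
log(10³)–log(10⁵) and log-scale 0.2–0.6, so marginals are positive and
right-skewed as LC-MS intensities are. The communality and shares were
chosen so a PCA of the sample-mean peak matrix explains roughly 30% / 20%
on the first two components at the 26-sample design — the level such
studies report — and were fixed before the validation simulations were
run. A 15% "independent" pool of peaks couples only weakly to the shared
factors (communality 0.25), standing for compounds on dedicated pathways.

**Drivers and neighbours.** Each attribute's 10 driver peaks are disjoint
draws from the independent pool; they share one latent *driver factor* (a
common biosynthetic activity), loading it with communality 0.7 and with
the sign of their planted weight, so the attribute genuinely tracks a
coherent compound group and each driver is individually a strong
correlate. Sixty further "pathway neighbour" peaks per attribute draw 40%
of their variance from the same factor — precursors and byproducts that
co-vary with, without driving, the attribute. This mirrors how e.g.
ester-related attributes correlate with whole families of fermentation
products, and it is what makes a one-component model predictive while
keeping driver recovery meaningful.

**Replicates.** Replicate multipliers are constructed with an *exact*
empirical CV: deviations are centred (so the replicate mean equals the
sample value) and rescaled to a target CV drawn in 1–5% for retained
peaks, ≥ 12% in at least one sample for the planted high-CV peaks, and
all-zero columns for the planted zero-max peaks. The filters therefore
recover the planted partition exactly, by construction, not
probabilistically.

**Panel scores.** A panelist's score is the sample's expected score plus a
bounded (uniform) panelist bias (sd 0.2) and bounded round noise (sd 0.3),
clipped to the attribute scale. The expected score is a scale-clipped
affine map of the standardized driver signal, with slope
effect_size·range/6 and the clip kept inside the scale by the noise
half-width — trained panels anchor their standards away from the line-scale
endpoints, and endpoint pile-ups would make box-whisker behaviour
degenerate. Because empirical Tukey fences on ~57 draws flag a natural
record with small but non-negligible probability under any continuous
noise, the generator redraws a group's round noise until single-pass Tukey
removal on the finished group flags exactly the injected outliers; the
conditioning is deterministic given the seed and affects a small minority
of groups. Injected outliers are placed at the group extreme ±(3·IQR + 1),
guaranteeing they fall beyond the whiskers of the contaminated group.

**Seeding.** One master integer seed drives named substreams per module
(peak metadata, intensities, library, panel, drivers, ...), so changing
the number of draws in one module does not shift any other module's
stream, and identical configurations are bit-reproducible.

**Year splits.** `split_years()` partitions the samples, keeps the
sample-level expected scores (hence the driver weights) identical, and
re-draws panel noise, biases and outliers independently per year — two
panels, one underlying composition-to-flavour relationship.

**What the generator does not emulate.** No chromatographic drift,
ionization suppression, batch or injection-order effects, no missing-value
mechanism beyond all-zero peaks, no cross-year shift in the peak
metadata, and no panel scale drift between years (the emulated studies
also did not standardize scales across years). Passing tests therefore
demonstrate the correctness and calibration of the *analysis chain* under
the stated statistical structure, not robustness to instrumental
artefacts.

## Numerical and design choices

- **In-fold re-scaling** for CV is the default (no leakage);
  `scale_in_fold = FALSE` reproduces the global-scaling convention.
- **Quantile convention** for whiskers is linear interpolation (type 7),
  configurable, as conventions differ between packages.
- **Tie-breaks** in annotation are by normalised distance then compound
  name; exact distance ties across datasets are reported by
  `align_variables()`.
- **Degenerate inputs**: constant responses, zero-variance variables,
  single-replicate samples, empty selections and rank-deficient requests
  all raise informative errors or documented limit behaviour rather than
  propagating NaNs.
- **Permutations** permute y over samples, never over injections, so the
  replicate structure is preserved under the null.

## Problem sizes used by the test suite

Module tests run on small designs (12 samples, 60–67 peaks, 8 panelists).
The end-to-end property checks use the study-scale design — 26 or 40
samples in triplicate, 455 peaks before filtering, 430 after, 19 panelists,
7-fold grouped CV, 100 permutations — with 10 seeds for the exact-recovery
contracts and 50–100 seeds for the calibration properties (null Q²,
validation flags, driver recovery, transfer R²). `scripts/acceptance.R`
recomputes the headline quantities on 5 seeds per block.

## Known limitations

- Single-response OPLS only: no multi-response variant, no OPLS-DA, no
  kernel variants.
- The permutation R²-intercept rule interacts badly with p ≫ n when
  orthogonal components are present (permuted refits reach high R²), so
  validated models on data with strong orthogonal variation tend to end at
  "1 + 0 + 0"; the component-search trace preserves what the Q² search
  found. At small sample counts the effect bites even at k = 0: with 26
  samples and 430 peaks the permuted R² level sits near 0.35, above the
  0.3 intercept rule, so strong models at that design can still be flagged
  invalid by the intercept conditions alone — the permutation p-value on
  Q² is the more informative output there.
- Under strongly factor-correlated peak data, a permuted response can align
  with a dominant intensity factor by chance, and grouped CV only partly
  discounts that alignment; the null Q² distribution then has a heavier
  upper tail than independent-variable intuition suggests. The permutation
  p-value on Q², not the point null Q², is the reliable null-rejection
  device.
- No multiple-testing correction across attributes is applied (matching
  the emulated studies); users comparing many attributes should correct
  externally.
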