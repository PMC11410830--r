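---
title: "Methods: null models, dissimilarity and hierarchical analysis of multi-factor experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: null models, dissimilarity and hierarchical analysis of multi-factor experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcfmix)
```

# The problem

When several global change factors (GCFs) act on a soil system at once,
the joint response is shaped by three things that are easy to conflate:
*which* factors are present (factor identity), *how many* act
simultaneously, and *how dissimilar* the factors are in the way they
affect the system. `gcfmix` implements an analysis chain that separates
these: a randomized factor-pool design, bootstrap effect sizes,
an effect-based dissimilarity index, null-model predictions of joint
responses, classification of net interactions from deviations, and a
seven-model hierarchy that partitions explained variance among identity,
number and dissimilarity.

This vignette documents the statistical model behind each stage, the
tunable parameters and their defaults, the synthetic-data generator used
for validation, the numerical choices made where the design was open,
and known limitations.

# Experimental design

A design is a table of treatments: a control group, an optional solvent
(water) control, one single-factor treatment per pool member, and, per
number-of-factors level $k$, $n$ distinct combinations sampled without
replacement from the complete enumerated set of $\binom{p}{k}$ subsets.
Sampling is a seeded shuffle of the complete set followed by taking the
first $n$: exact, reproducible, and free of rejection loops. The default
configuration has $p = 12$ factors, levels $k \in \{2, 5, 8\}$ with
$n = 50$ each, 20 controls, 10 water controls and 8 replicates per single
factor — 276 units in total. Water-control units are carried through the
design but excluded from all statistics by default; they exist only as a
solvent check.

The pool's declaration order is fixed and defines composition-column
order and all lexicographic tie-breaking.

# Bootstrap effect sizes

For a treatment group $T$ and control $C$, `bootstrap_effect_size()`
draws $B$ independent resamples of each group and forms
$\Delta_b = \overline{T^*_b} - \overline{C^*_b}$. The reported effect is
$\overline{\Delta}$, the interval the $\alpha/2$ and $1-\alpha/2$
percentiles, and the two-sided p-value
$2\min\{\Pr(\Delta \le 0), \Pr(\Delta \ge 0)\}$ clipped to $[2/B, 1]$.
The sign-based bootstrap p is one of several reasonable conventions; it
is isolated in one function and easy to swap. Benjamini–Hochberg
adjustment is applied within each response family across treatments
(the family choice is a convention; adjusting across all responses at
once is possible by calling `adjust_pvalues_bh()` on the pooled vector).
Default $B = 10000$, $\alpha = 0.05$.

# Factor dissimilarity

Single-factor effect profiles (one effect per response) are standardized
per response column — centered and scaled to unit variance across the
factors — so that responses measured on different scales contribute
equally. The standardization choice (z-score across factors, rather than
scaling by the control standard deviation) is a design decision; it makes
the distance matrix independent of measurement units. Euclidean distances
between standardized profiles give the factor distance matrix $d$, and a
combination's dissimilarity index is the sum over its member pairs
$DI_i = \sum_{j \in N_i} d_j$.

$DI$ grows mechanically with the number of pairs ($1$ at level 2, $28$
at level 8), which is exactly why indices are range-normalized *within*
each level: $DI^{norm} = (DI - \min)/(\max - \min) \in [0, 1]$. A level
with zero range is mapped to all zeros with a warning.

Views of the factor space use classical multidimensional scaling
(`pcoa()`, Torgerson double-centering; negative eigenvalues are reported
and excluded from the variance denominator) and agglomerative clustering
(`hierarchical_cluster()`, default UPGMA linkage — the linkage is not
dictated by the method, average linkage is the common default for
effect-profile clustering). Dendrograms serialize to Newick via `ape`.

# Null models of joint effects

Three assumptions predict the joint effect size of a combination from
its members' single-factor effect sizes $ES_1, \dots, ES_N$ and the
control level $CT$:

* **additive**: $P = \sum_i ES_i$;
* **multiplicative**: $P = CT \prod_i (1 + ES_i/CT) - CT$, i.e. effects
  combine as proportional changes (undefined at $CT = 0$; a bracket
  $1 + ES_i/CT \le 0$ flips the sign of the product and is flagged);
* **dominative**: the signed effect of largest magnitude, ties to the
  first occurrence in pool order.

All three coincide on a single factor, and the additive–multiplicative
gap for two factors is exactly $ES_1 ES_2 / CT$.

The bootstrap prediction distribution (`bootstrap_null_distribution()`)
repeats $K$ times: resample the control group once (shared across
members within an iteration) and each member's single-factor group;
compute resampled group means; form signed effect sizes
$Z_i = \bar{t}_i - \bar{c}$ (signed, not absolute — the dominative rule
and the direction-dependent classification need signs); combine under
the model, with $CT := \bar{c}$ for the multiplicative rule; add
$\bar{c}$ back to get a predicted joint response. Default $K = 1000$
with a 95% percentile interval. Multiplicative iterations with
$\bar{c} = 0$ exactly are redrawn and counted. The per-treatment
bootstrap seed is shared across models, so model comparisons see
identical resamples.

# Net interaction classification

The observed joint response (treatment group mean) is compared with the
prediction interval. Inside: no net interaction. Outside: the rescaled
deviation

$$DN = \frac{\text{observed} - \text{mean(draws)}}{\text{sd(draws)}}$$

is a dimensionless, z-like quantity comparable across responses — the
scaling by the prediction distribution's spread is the design choice
here; dividing by the interval half-width is an alternative with the
same sign structure. For positive-direction responses (pH, the four
enzyme activities) $DN > 0$ outside the interval is synergistic and
$DN < 0$ antagonistic; for negative-direction responses (decomposition
rate, water-stable aggregates) the rule is mirrored. Directions are
declared in configuration; `gcf_directions()` holds the defaults.

Per response, the null model with the smallest sum of squared deviations
of observations from prediction means (SSD) across all multi-factor
treatments is selected as best-fitting, with deterministic tie-break in
the order additive, multiplicative, dominative. Downstream summaries
(per-level one-sample t-tests on $DN$, BH-adjusted; Spearman
correlations of $DN$ against $DI^{norm}$) are typically run on the best
model's calls.

Within-level Spearman trends of the raw responses against $DI^{norm}$
(`spearman_trend()`) are descriptive companions; a correlation alone
cannot separate a dissimilarity effect from factor identity, which is
why the hierarchy below is the inferential surface.

# The seven-model hierarchy

One row per non-control unit and response carries the response value and
the predictors: the three null predictions, the number of factors, the
normalized dissimilarity index (single-factor treatments have no pairs;
their $DI^{norm}$ is set to 0 by convention — a sensitivity check can
simply drop singles), and the binary factor-composition vector.

Model 1 regresses the response on the three null predictions and absorbs
the factor-identity contribution. Models 2 and 3 use number of factors
or dissimilarity alone; Models 4 and 5 add each to the baseline, Model 6
both, and Model 7 adds the composition matrix. Reported comparisons are
4 vs 1, 5 vs 1, 6 vs 1 and 7 vs 6. The GLM backend is a Gaussian
identity-link linear model (responses are continuous) reporting
in-sample $R^2$, AIC and nested ANOVA F-tests; in Model 7 the
composition columns are collinear with the number of factors (their row
sum), so aliased columns are dropped with a warning — for the GLM,
Model 7 is reported only for comparability with the forest. The forest
backend (`ranger`) reports out-of-bag $R^2$, because in-sample forest
fits are optimistically biased; OOB was chosen as the default since the
forest's $R^2$ definition is otherwise ambiguous.

Permutation importance follows the response-permutation (Altmann-style)
scheme: the observed importance is the mean out-of-bag loss increase
under predictor permutation; the null distribution refits the forest
with a permuted response $n_{perm}$ times (default 1000), giving
$p = (1 + \#\{I^{null} \ge I^{obs}\})/(1 + n_{perm})$, BH-adjusted
across predictors. Importances are floored at zero for reporting.

# The synthetic-data generator

`make_ground_truth()` + `simulate_experiment()` generate experiments
with known truth: per response, a control mean, homoscedastic Gaussian
unit noise $\sigma$, a factors × responses matrix of true single-factor
effects (supplied or drawn $N(\mu_r, \tau_r^2)$), a combination rule
("world": additive, multiplicative or dominative — exactly the rules the
null models assume), and an optional injected interaction. The
interaction is a sum over member pairs: a fixed amount per pair, or
proportional to the true pairwise factor distance
($s \cdot \gamma \cdot d_{ij}$), emulating the hypothesis that
dissimilar factors interact more strongly. Higher-order interactions are
not separately injected — a pairwise sum suffices to exercise the
classifier, whose "net interaction" aggregates all orders anyway.
Negative-direction responses are given negative effect means in the
default pipeline so the mirrored classification branch is exercised.

What the generator does *not* emulate: temporal dynamics within an
incubation, heteroscedastic or correlated measurement error across
responses, and mechanistic soil biogeochemistry. Passing validation on
this generator shows the statistical machinery is correct and calibrated
under its assumptions, not that those assumptions hold for any real
dataset.

# Validation studies and their conditions

The studies in `R/studies.R` (run by `tests/testthat/test-acceptance.R`
and `scripts/acceptance.R`) use these problem sizes, chosen as the
package's own simulation conditions:

* **Calibration** (`null_calibration()`): 500 simulated experiments per
  world; group sizes follow the reference design (20 controls, 8
  replicates per single factor); 10 combinations per level (30
  multi-factor treatments per experiment, 15 000 cases per world);
  $\sigma = 1$, effect spread 2, $K = 1000$. The observed multi-factor
  mean uses 400 replicates so that its own sampling noise is under 1% of
  the narrowest null-prediction variance: the study measures the
  calibration of the null interval, not observation noise.
* **Synergy recovery** (`interaction_recovery()`): 100 experiments, 50
  combinations per level, additive world, injected
  distance-proportional synergy with $\gamma$ set so the mean pairwise
  term equals $3\sigma$ (three standard errors of a single-replicate
  joint observation); observed means from 8 replicates; the estimation
  path (bootstrap effects, estimated distances, estimated $DI$) is run
  in full. Reported: fraction labeled synergistic, and both the pooled
  and the within-level $DN$–$DI^{norm}$ Spearman correlations. The
  within-level statistics are the primary readout: the injected
  deviation scale grows with the number of pairs, so pooled rank
  correlations are structurally diluted by between-level differences
  carrying no dissimilarity information.
* **Best-null recovery** (`best_null_recovery()`): 99 experiments
  cycling the three worlds, $\sigma = 0.1$, effect spread 2 against a
  control mean of 10 (large enough that additive and multiplicative
  separate through the $ES_i ES_j / CT$ cross terms).
* **Hierarchy recovery** (`hierarchy_recovery()`): additive-world
  experiments with a term $\beta \cdot k$ (or
  $\beta \cdot DI^{norm}$) added to multi-factor units only — added to
  all units it would be absorbed into the single-factor effects and
  cancel out of the comparison by construction; 15 combinations per
  level, $\beta = 1$ (number) or $3$ (dissimilarity) against
  $\sigma = 1$.

# Numerical choices and degenerate inputs

* Percentile intervals use `quantile()` type 7 on the bootstrap draws.
* Zero-variance groups are legal everywhere and collapse to degenerate
  (width-zero) intervals; a zero-spread prediction distribution yields
  $DN = 0$ when the observation equals its mean and an error otherwise.
* All-zero deviations in a level give $t = 0, p = 1$; other
  zero-variance deviation sets report `NA`.
* Constant vectors in correlations report `NA` with a warning.
* Every stochastic stage draws its seed from the master seed by a stable
  hash of the stage name, so changing one stage's depth never perturbs
  another stage's stream.
* Spearman p-values use the t approximation (`exact = FALSE`),
  appropriate at $n = 50$ per level.

# Known limitations

* **Small-sample bootstrap undercoverage.** With 8 replicates per
  single-factor group, the percentile bootstrap underestimates the
  estimator variance by roughly a factor $(n-1)/n$ per group, so the
  95% null interval covers about 92–93% rather than 95% in the additive
  and multiplicative worlds; for the dominative world the bootstrap of a
  maximum-magnitude statistic is additionally biased by selection at the
  max, and coverage is nearer 91%. Consequently the classifier flags
  7–9% of truly non-interacting treatments at the 95% level, not 5%,
  symmetrically split between labels. This is a property of the
  percentile-bootstrap procedure at these group sizes, not an
  implementation artifact (the same rates arise from an independent
  simulation of the algorithm), and it should be kept in mind when
  interpreting interaction frequencies from real data with similar
  replication.
* **Estimated null predictions as regressors.** The hierarchy's
  baseline uses estimated, not true, null predictions; with finite
  single-factor groups the multiplicative prediction carries a small
  level-dependent bias (cross terms of estimation noise), which can
  leave an $R^2$ increment of order 0.02 for Model 4 even when no
  number-of-factors effect exists. Increments of that size should not be
  over-interpreted.
* **One replicate per combination** in the reference design means
  single observed joint responses carry full unit noise; the validation
  studies use replicated multi-factor groups to isolate classifier
  calibration, so real single-replicate designs will show more "false"
  interaction calls than the calibration numbers suggest.
* The multiplicative rule is undefined at $CT = 0$ and unstable when
  $|ES_i|$ approaches $CT$; such cases are flagged, not hidden.
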