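---
title: "Pathway-informed penalized Cox models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-informed penalized Cox models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathsurv)
```

## What the package does

High-dimensional transcriptomic prognosis models built gene-by-gene are hard
to interpret and unstable: correlated genes enter or leave the model almost
at random. `pathsurv` builds overall-survival models that incorporate
pathway (gene-set) knowledge in two ways:

1. **Pathway-score models** — convert the gene × sample expression matrix
   into pathway × sample activity scores (ssGSEA, GSVA, or z-score), then
   fit a lasso-penalized Cox model on the scores.
2. **Group-lasso models** — keep genes as predictors but penalize them in
   pathway-defined groups, so whole pathways enter or leave the model
   together.

Around this core the package provides censoring-aware evaluation (IPCW
Brier score, integrated Brier score, concordance index), a repeated
train/test internal-validation harness with corrected resampled t-tests,
external validation with batch alignment, K-nearest-gene imputation so a
fitted model can be applied to new patients with missing genes, and a
synthetic cohort generator with known pathway-level ground truth.

## Pathway scoring

All three methods consume a gene-level matrix on a log2 microarray-like
scale and a gene-set collection restricted to the measured universe
(`restrict_to_universe`, default size filter 5–500 genes — the common
practice bounds; sets outside them carry too little or too diffuse signal).

**z-score.** Each gene is standardized across samples; the score of sample
$i$ for set $J$ is $Z_{iJ} = \sum_{j \in J} z_{ij} / \sqrt{|J|}$. The
$\sqrt{|J|}$ denominator is the combined z-score convention (it keeps the
score variance constant in $|J|$ under independence); a `count` switch
divides by $|J|$ instead for a per-gene mean. Zero-variance genes carry no
information about the sample distribution and are dropped from all sets
with a warning.

**ssGSEA.** Within one sample, genes are ranked by expression (descending)
and given rank scores $s_g = N - \mathrm{pos}(g) + 1$. Walking down the
ranked list, the enrichment score is
$\sum_i [P^w_{in}(i) - P_{out}(i)]$, where $P^w_{in}$ accumulates
$s_g^{\alpha}$ over in-set genes (normalized by the in-set total) and
$P_{out}$ steps uniformly over out-of-set genes. Defaults follow the
method's original description: $\alpha = 0.25$ and normalization of the
score matrix by its range. Because only within-sample ranks enter, scores
are invariant to any per-sample strictly increasing transform and a single
patient can be scored without a background cohort — the property that makes
ssGSEA models easy to deploy. The normalization constant is computed on the
training matrix and stored with the model, so scoring one new patient never
depends on other new patients.

**GSVA.** Each gene's expression is first transformed to an empirical
kernel CDF across the background samples (Gaussian kernel, bandwidth
$\mathrm{sd}_g/4$; zero-variance genes sit at 0.5); per sample, genes are
ranked by the CDF value and the rank is symmetrized to
$r_g = |N/2 - \rho_g|$. A Kolmogorov–Smirnov-like walk with in-set steps
$\propto r_g^{\tau}$ ($\tau = 1$) and uniform out-of-set steps yields the
enrichment score, by default the sum of the largest positive and largest
negative deviations (`max_diff`), which shrinks noise sets toward zero.
GSVA and z-score both need a background cohort; models store the training
matrix as that reference, which is what makes their external application
well-defined.

Ties in every rank step are broken by lexicographic gene id, so results are
identical across runs and platforms. Whether the original study ran the
scorers with non-default parameters is not stated anywhere we could verify;
the defaults above are declared, recorded in `method_params`, and
configurable.

## Distinct-pathway selection

Collections overlap heavily; the group penalty needs groups that are as
close to disjoint as possible. `select_distinct_pathways` reduces a
collection to its `n_select` (default 100) most distinct members:
average-linkage hierarchical clustering on the Jaccard distance
$1 - |A \cap B| / |A \cup B|$, the tree cut into `n_select` clusters, one
representative per cluster — the medoid, ties broken by name. Collections
already at or below `n_select` pass through unchanged (a 50-set hallmark
collection is used in full). Distance, linkage, and the representative rule
are the minimal standard completions of "hierarchical clustering"; all are
deliberate package choices, not reverse-engineered ones, and alternatives
plug in trivially.

Because a partition is still not guaranteed, `grouped_gene_features`
assigns a gene shared by several selected pathways to the lexicographically
first one. This keeps the penalty's all-in/all-out semantics exact at the
price of slightly diluting the later groups; with distinct pathways
selected first the clashes are rare.

## Penalized Cox models

Both penalties minimize
$\frac{1}{n}\,\ell(\beta) + \lambda P(\beta)$, where $\ell$ is the negative
log partial likelihood with Breslow tie handling and
$P(\beta) = \sum_j |\beta_j|$ (lasso) or
$P(\beta) = \sum_g m_g \lVert \beta_g \rVert_2$ (group lasso,
$m_g = \sqrt{T_g}$ by default so larger pathways are not favoured; a
`cardinality` rule and the unit rule — under which the group penalty is
exactly the lasso for singleton groups — are exposed). A Cox model has no
intercept; the intercept of the literal squared-error objective
(`fit_penalized_lm`, provided for continuous outcomes) is handled by
centering.

The solver is accelerated proximal gradient descent (FISTA with a
function-value restart that also makes the reported objective path strictly
non-increasing) with backtracking line search, in C++ via RcppArmadillo.
Convergence is declared when the relative objective change falls below
`tol` (default 1e-7) on a momentum-free step; the iteration cap is 1e5 and
non-convergence is an error, not a silent result. Predictors are
standardized internally and coefficients returned on the original scale.
$\lambda_{\max}$ — the smallest penalty with an all-zero solution — is
computed in closed form from the null-model gradient.

$\lambda$ is chosen by 10-fold cross-validation, folds stratified by the
event indicator so every fold contains events. The criterion is the
Verweij–van Houwelingen cross-validated partial-likelihood deviance, and
the chosen $\lambda$ minimizes it (no 1-SE rule: the models exist to
predict, and the minimum is the prediction-optimal choice). The default
grid is 100 log-spaced values down to $0.01\,\lambda_{\max}$; the
large-scale experiments below pass a 30-value grid, which changes selected
models negligibly while keeping repeated cross-validation affordable.

Absolute survival probabilities use the Breslow baseline cumulative hazard
stored at fit time: $\pi(x, t) = \exp(-H_0(t)\,e^{lp(x)})$. Beyond the last
training event time the baseline is extrapolated flat with a warning —
transporting a baseline hazard to another population is exactly the caveat
that applies to the integrated Brier score in external validation.

## Evaluation under censoring

**IPCW Brier score.** $BS(t^*) = \frac{1}{n}\sum_i W_i\,(I(T_i > t^*) -
\pi_i)^2$ with weights $1/\hat G(T_i^-)$ for events at or before $t^*$,
$1/\hat G(t^*)$ for subjects still at risk, and 0 for subjects censored by
$t^*$; $\hat G$ is the Kaplan–Meier estimate of the censoring distribution
on the evaluation set. The left limit $\hat G(T_i^-)$ avoids weighting a
subject by its own censoring step; the plain convention is a switch. The
integrated Brier score averages $BS(t)$ over $(0, t_{\max}]$ by the
trapezoidal rule on the unique event times, with $t_{\max}$ defaulting to
the largest observed event time — the integration range is otherwise
arbitrary and is reported with the result.

**Concordance index.** $C = P(\mathrm{Risk}(i) > \mathrm{Risk}(j) \mid T_i
< T_j)$ over pairs whose order is established: a pair is usable iff the
smaller observed time belongs to an event; a subject censored at another
subject's event time counts as surviving longer; two events at the same
time are excluded (their order is unknown); risk ties count 0.5 (Harrell
convention). Small-sample C-index bias is real but affects all compared
models equally; no correction is applied.

**Corrected resampled t-test.** Repeated random splits reuse subjects, so
per-split metric differences are positively correlated and the naive
resampled t-test is badly anti-conservative. The corrected statistic
inflates the variance by $(1/J + n_{test}/n_{train})$; under the package's
70/30 design with $J = 100$ that multiplies the naive variance by about 44.
A 200-cohort null simulation in the test suite keeps the empirical size at
$\alpha = 0.05$ inside $[0.01, 0.10]$.

**Bootstrap CIs** are percentile intervals over resampled evaluation
subjects (default $B = 1000$), deterministic under a seed; resamples on
which a metric is undefined are redrawn and counted.

## Validation harnesses

`internal_validation` repeats (default 100×) a stratified 70/30 split and,
per configuration, constructs features, selects $\lambda$, and fits on the
training split only. Everything that uses background samples — the z-score
standardization, the GSVA kernel CDF, the ssGSEA normalization constant,
distinct-pathway selection, predictor standardization — is estimated on the
training split and replayed on the validation split, so a held-out sample's
features depend only on its own values plus training statistics. The test
suite audits this directly: a deliberately leaked construction changes
results, while perturbing a held-out sample's companions does not.

`external_validation` replays feature construction from the stored training
reference (an error, not a guess, if a background-dependent model lacks
one), optionally after `reference_align` — a per-gene location/scale
adjustment to the training cohort. That alignment is deliberately simple:
it matches each gene's mean and SD exactly and ignores the covariance
structure an empirical-Bayes batch correction would model; it is the
contract the synthetic experiments need, not a general batch-effect
remover.

## Missing genes at prediction time

A single missing gene would otherwise make a high-dimensional model
unusable. `knn_impute_new_samples` computes gene–gene Euclidean distances
on the training reference once, and imputes each missing gene from its
`K = 10` nearest reference neighbours that are observed in that sample,
weighted $1/(d + 10^{-6})$ — `K = 10` being the long-standing default of
nearest-neighbour expression imputation, and inverse distance the simplest
concrete reading of "distance-weighted average". The per-sample missing
fraction is checked up front and more than 5% triggers a warning: the
robustness experiment (`missing_robustness_experiment`) shows prediction
essentially unchanged at 5% masking and degrading beyond, which is where
the 5% allowance comes from. Masking draws a fresh gene set per sample by
default (`shared_mask` switches to one draw for all samples; the
alternative readings are both defensible, so both exist).

## Synthetic cohorts

The generator emulates the structure of a log2-microarray myeloma cohort
without reproducing any real dataset: latent pathway activities
$A_p \sim N(0,1)$ drive member-gene expression
($x_{gj} = \mu_g + \sum_p \lambda_{gp} A_{pj} + \varepsilon$,
$\mu_g \sim N(8, 2)$, loadings $\sim N(1, 0.2)$, noise SD 1) and, through
the first `n_active` pathways ($\gamma = \pm 1$), a Weibull
proportional-hazards survival outcome (shape 1.5, scale set so baseline
median survival is 90 months — months-scale follow-up with a median in the
low nineties, as in the motivating cohort). Censoring is uniform with its
upper bound calibrated by bisection so the realized event rate lands within
±3 points of the 44% target. Sets are drawn with sizes uniform in a range
(default 10–40) and 20% of each set re-drawn from previously used genes,
producing the overlap that motivates distinct-pathway selection; preset
universes include pathway-free genes so gene-level models face realistic
noise dimensions.

What the generator does **not** emulate: probe-level artifacts, real
correlation structure beyond one-factor-per-pathway, batch effects beyond a
location/scale shift, informative censoring, or clinical covariates.
Passing tests therefore demonstrate correctness of the machinery and
recoverability under a known truth — not clinical performance on real
cohorts.

Presets: `tiny` (50 genes × 30 samples × 6 sets) backs the fast unit
tests; `default` (2000 genes × 400 samples × 60 sets, 3 active pathways,
$|\gamma| = 1$, 44% events) backs the parameter-recovery and
missing-value experiments. At those sizes the full acceptance experiments
(20-seed recovery with 10-fold CV, 200-cohort t-test calibration, 20-rep
masking) complete on one CPU in minutes; the sizes are the package's
documented study conditions and are configurable.

## Numerical and degenerate-input choices

- Rank ties anywhere: lexicographic gene id, deterministic everywhere.
- Zero-variance genes: dropped with a warning (z-score), CDF pinned at 0.5
  (GSVA), standardization scale forced to 1 (penalized fits — a constant,
  centered predictor is all-zero and its coefficient stays 0).
- Exactly at $\lambda_{\max}$ the zero/non-zero boundary is a last-ulp
  float question; the guarantees are stated for $\lambda > \lambda_{\max}$
  and $\lambda < \lambda_{\max}$.
- All randomized procedures (fold assignment, splits, bootstrap, masking,
  simulation) take explicit integer seeds and restore the caller's RNG
  state; a fixed master seed makes the whole pipeline bitwise-reproducible,
  which the test suite checks through the command-line interface.
- Models serialize to JSON at 17 significant digits so a re-loaded model
  predicts bit-identically.

## Known limitations

- The group penalty requires disjoint groups; overlapping-group and
  sparse-group penalties are out of scope, and the first-pathway assignment
  of shared genes is a pragmatic tie-break, not a modelling claim.
- `reference_align` is not a substitute for a full batch-correction model
  when arrays come from genuinely different platforms.
- The IBS transports the training baseline hazard; across populations with
  different baseline hazards it conflates calibration with baseline
  mismatch — the harness says so whenever it computes an external IBS.
- GSVA scoring is O(genes × samples × reference) in plain R; it is intended
  for the pathway-collection sizes used here, not genome-scale single-cell
  matrices.
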