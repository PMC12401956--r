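---
title: "wolfscreen: models, design choices and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wolfscreen: models, design choices and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`wolfscreen` implements a complete case-control classification workflow on
routine blood parameters: cohort simulation from group summary statistics,
leakage-safe preprocessing, binary Grey Wolf Optimization (GWO) wrapper
feature selection, five reference classifiers, repeated stratified
cross-validation, and group-comparison statistics. This vignette records
the modelling assumptions, the tunable parameters and their defaults, the
design decisions taken where the problem was genuinely open, and the
limits of what a passing test suite establishes.

## The synthetic cohort: a stated world

No patient-level data exist in the package. The generator's builtin world
is defined by published-style group summaries: 192 controls (130 male,
ages 28.3 ± 10.7 years) versus 203 cases (154 male, ages 28.7 ± 3.9
years), and 45 analytes each described only by a per-group mean and SD.

**Gaussian marginals.** With only means and SDs available, each analyte is
drawn from a per-group Gaussian. Lab analytes cannot be negative, so draws
below the physiological floor (default 0) are redrawn; ages use the same
rule. This is the simplest distributional completion of the summaries,
and it has one important consequence: for analytes whose case SD is of the
order of the mean (GGT 30.2 ± 37.4 U/L, triglyceride 142 ± 154 mg/dL, the
near-zero NRBC counts), redrawing the sub-zero mass inflates the realized
case mean well above the configured one. In the builtin world these
heavy-tailed analytes therefore top the Welch comparison table ahead of
the planted moderate effects (calcium, iron, glucose). That is a property
of the floor-truncated Gaussian model, not a bug, and it is why the
marginal-recovery property (sample mean/SD within 3 standard errors of the
configured values at n ≥ 10,000) is only claimed — and only tested — where
the floor is several SDs below the mean. A skew family (e.g. log-normal)
would avoid the artifact but cannot be parameterised from a mean/SD pair
without further assumptions, so it is out of scope.

**Correlation.** Real lab panels are strongly cross-correlated (HGB/HCT/
RBC near-collinear, derived indices deterministic in their parents). The
summaries carry no covariance information, so the generator offers a
single shared standard-normal latent factor per subject: with loading
`sqrt(correlation)` on every standardized draw, any two analytes correlate
at `correlation` within group. The default is 0 (independent analytes).
Independence makes classification *easier* than reality in one sense
(45 weakly informative, independent features aggregate well) and harder in
another (no redundant near-copies of strong markers), so accuracy on this
world must not be read as an estimate of accuracy on real data — only as
evidence the pipeline recovers signal that is genuinely there.

**Sex and age** are Bernoulli and truncated-Gaussian per group with the
fractions above; the age floor (0 years) is ≥ 2.6 SD below both group
means, so the induced bias is negligible relative to the 3-standard-error
acceptance band used for the simulated case-arm age mean.

**Missingness** is MCAR by design: each cell of a targeted analyte is
blanked independently with its configured rate, never the label, sex or
age. Informative missingness (sicker patients measured more often) is
explicitly not modelled; the missingness machinery exists to exercise the
elimination/imputation contracts.

## Preprocessing

- **Elimination threshold 0.50** (drop an analyte iff its missing fraction
  strictly exceeds the threshold). Such studies have been described with
  both a 50% and an 85% rule in different places; the Methods-style value
  is the default and the threshold is a config knob, so either regime is
  one line away.
- **Median imputation**, even-count median = mean of the two central order
  statistics; **mode** for sex with ties broken lexicographically
  (determinism). Imputers and z-scalers are *always* fitted on training
  rows and applied to held-out rows; the test suite asserts that fold
  medians cannot be moved by arbitrary perturbation of the held-out fold.
- **Scaling scope.** Standardization matters for the distance (KNN),
  margin (SVM) and penalty (ridge LR) models and is applied exactly there;
  tree ensembles are split-point invariant to monotone rescaling and
  receive raw features. A constant training column gets SD 1, mapping to
  zeros rather than NaN.
- **Sex encoding** is the fixed map female = 0, male = 1.

## Binary GWO wrapper selection

Each wolf is a continuous position in `[0,1]^d` over the d = 45 + 2
design columns (analytes, age, sex). Open choices and their resolutions:

- **Transfer function.** How a continuous position becomes a bit is left
  open in most descriptions of binary GWO. Default:
  `sigmoid_stochastic`, include feature j with probability
  `1/(1 + exp(-10 (pos_j - 0.5)))` — the standard S-shaped transfer, slope
  10 making the map decisive outside a narrow band around 0.5. A
  deterministic `threshold_half` (include iff `pos_j > 0.5`) is provided
  for testability and exact reproducibility studies.
- **Empty masks** are repaired by switching on the `min_features`
  largest-position components (preserving the optimizer's ranking signal);
  at all-equal positions the tie falls to the lowest index via stable
  ordering.
- **Fitness** is the mean stratified 5-fold CV accuracy of a
  random-forest classifier on the masked columns. Five folds balances
  variance against the cost of the inner loop; the fold count, wrapper
  classifier and its hyperparameters are all configurable. The fitness is
  a pure function of the mask given its seed (the evaluator restores the
  caller's RNG state), so `run_gwo()` memoizes it; caching changes no
  trajectory, it only collapses re-evaluations of revisited masks.
- **Accuracy vs parsimony.** The printed fitness is pure accuracy. The
  stated goal of also minimizing feature count is honoured without
  altering that formula: among equal-fitness masks the one with fewer
  selected features wins (then the earlier-encountered one), and an
  optional `penalty_weight` subtracts `weight * popcount/d` for users who
  want explicit pressure. Default weight 0 reproduces the pure formula.
- **Schedule.** `a` decays linearly from 2 to 0 across iterations
  (canonical); per wolf and leader, `A = 2 a r1 - a`, `C = 2 r2`,
  attraction `X_L - A |C X_L - X|`, new position = mean of the three
  attractions, clamped to `[0,1]`.
- **Selection scope.** Default `"global"`: GWO runs once on the fully
  preprocessed data and the mask is reused in every fold — this mirrors
  the common select-once-then-cross-validate workflow and is what the
  before/after comparison reports. Because the selector has seen the
  evaluation data, fold metrics under the global scope carry selection
  bias; `scope = "per_fold"` nests selection inside each training fold for
  an unbiased (and ~k-fold costlier) estimate. Both are first-class.

## The classifier zoo

The surrounding R installation provides no random forest, boosting, SVM or
CART package, so the ensembles are implemented in the package (Rcpp), and
that is deliberate: the wrapper loop re-fits forests thousands of times.

- **Random forest**: 100 Gini CART trees grown to purity on bootstrap
  samples, `mtry = floor(sqrt(d))` features per node; scores are averaged
  leaf class fractions; importances are per-tree-normalized mean impurity
  decreases.
- **Gradient boosting**: 100 rounds of depth-6 trees fitted to the
  second-order logistic objective with L2 penalty `lambda = 1` (gain
  `(G_L^2/(H_L+λ) + G_R^2/(H_R+λ) - G^2/(H+λ))/2`), learning rate 0.3,
  base score 0.5 — the widely published defaults of the regularised
  boosting family. Importances are normalized total split gains.
- **SVM (RBF)**: the dual soft-margin QP solved with `quadprog`
  (`C = 1`, `gamma = 1/(d · Var(X))`); a tiny, escalating ridge keeps the
  kernel matrix numerically positive definite in the presence of
  near-duplicate rows. Raw decision values (threshold 0) feed the ROC —
  AUC is rank-based, so no probability calibration is needed.
- **KNN**: `k = 5`, Euclidean, exact neighbour search via FNN; on
  degenerate folds `k` clips to `n - 1` with a warning rather than
  failing.
- **Logistic regression**: ridge penalty at inverse strength `C = 1`
  (intercept unpenalized), Newton/IRLS with a 1e-10 jitter on the
  intercept block; the penalty keeps separable problems finite.

Score orientation is uniform: higher = more case-like; hard labels
threshold probabilities at 0.5 and SVM decision values at 0.

A caveat recorded by the tests: *exact* permutation-equivariance of tree
importances holds only while split gains are untied. Deep trees on small
pure nodes do tie, and any deterministic tie-break (here: first feature in
column order, as in the reference implementations) breaks equivariance at
those knife-edges; the property test therefore uses depth-1 trees, where
ties on continuous data are measure-zero.

## Evaluation

Stratified k-fold (default 10) × repeats (default 5): within each class,
subjects are shuffled and dealt round-robin, so per-fold class counts
deviate by at most one from perfect stratification. Metrics use the
confusion-matrix formulas verbatim with case as the positive class;
division by zero returns 0 with the metric named in an `undefined` flag
(stable tabular reports rather than NaN). Aggregation is the unweighted
mean over all k × repeats folds — fold sizes differ by at most one
subject, so weighting is immaterial. ROC curves are built two ways,
because curve aggregation across folds is genuinely underdetermined: the
reported per-model AUC is the mean of per-fold AUCs, and a single smooth
curve (plus its AUC) comes from pooling the out-of-fold scores of the last
repeat. Both numbers appear in the metrics table (`auc`, `auc_pooled`).
The AUC computation sweeps thresholds with tie groups collapsed, which
makes the trapezoidal area identical to the normalized Mann–Whitney U —
an identity the acceptance suite checks against an independent rank
oracle.

## Group statistics

Welch's unequal-variance t-test is the default for the comparison table —
the group SDs of the builtin analytes differ up to several-fold, exactly
the regime where the pooled test is anticonservative — with the pooled
variant one flag away. Both a raw-data and a summary-statistic entry point
exist and agree exactly on matching inputs. The sex table uses Pearson's
chi-square without continuity correction (df = 1); Yates is available as
an option. p-values display at four decimals floored at 0.0001, full
precision retained internally. No multiplicity correction is applied, by
design; the table is descriptive.

## Numerical and reproducibility choices

- One global seed fans out to per-stage seeds through a fixed affine hash
  of the stage label (`derive_seed()`), all below 2^31.
- Cohort CSVs serialise numbers as `%.17g`, so write → read round-trips
  reproduce the doubles bit-exactly and repeated runs are byte-identical.
- Truncation redraws are capped (1000 rounds) with a final clamp, so a
  pathological spec cannot hang the generator; `sd = 0` short-circuits to
  a constant column.
- All stochastic helpers restore the caller's RNG state, so composing
  stages never silently shifts downstream draws.

## What a green suite does and does not establish

The acceptance suite checks printed-count arithmetic, recovery of
configured generator parameters, equivalence of the optimizer with an
exhaustive subset oracle on a d = 8 planted problem (sized so each
informative feature's marginal gain exceeds fold noise, making "recover
all informative features" well-posed), metric/AUC identities against
independent oracles, null calibration (chance-level accuracy and a ~5%
false-flag rate on separation-free cohorts), qualitative signal recovery
on the builtin world, and leakage-freedom of fold-fitted imputation. None
of this validates clinical performance: the synthetic world has Gaussian,
(by default) independent marginals, MCAR missingness, no medication,
stage or site effects, and its headline accuracies quantify the pipeline
on that world only. External, patient-level validation is the only way to
establish diagnostic utility.
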