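---
title: "Ensemble learning with active sampling: model, conventions, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble learning with active sampling: model, conventions, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elas)
```

## The problem

Postoperative prognosis in oncology cohorts is a sharply imbalanced binary
classification problem: at a one-year horizon only a few percent of patients
have recurred or died, and classifiers trained on the raw class distribution
drift towards the majority class. `elas` implements a meta-classifier that
attacks the imbalance through its *training curriculum* rather than through
resampling: every base classifier starts from a perfectly balanced seed, and
the curriculum then grows the training set by querying the pool samples the
current classifier is least sure about.

## The training algorithm

Write $D_\text{train}$ for the training set. The algorithm has three levels:

1. **Internal validation folds.** $D_\text{train}$ is split into $n_\text{folds}$
   stratified folds (default 5). Each fold in turn is the *internal validation
   set* used only to rank base classifiers; the other folds form the training
   pool $D_\text{trainPool}$. This is distinct from hyperparameter-tuning CV:
   hyperparameters are tuned once by a separate grid-search CV and frozen
   before any of this starts.
2. **Balanced seeding and active sampling.** From the pool, $N_\text{seed}/2$
   samples per class are drawn without replacement as the balanced seed. A
   base classifier is fitted; while at least $N_\text{batch}$ samples remain
   in the pool, ranked batch-mode sampling (below) selects $N_\text{batch}$
   samples, which join the training data *with their true labels* — the pool
   is fully labeled, so "active sampling" is a curriculum device, not
   human-in-the-loop annotation. Every iteration's classifier is kept. No
   early stopping is applied; a pool of size $N_\text{trainPool}$ (counted
   before seed removal) yields exactly
   $\lfloor (N_\text{trainPool} - N_\text{seed}) / N_\text{batch} \rfloor + 1$
   records. This is repeated with $T_\text{seed}$ independent seeds per fold.
3. **Selection and averaging.** Each run's classifiers are scored on the
   fold's internal validation set (AUROC by default, AUPRC optionally) and
   the top $K$ are kept, ties going to the earlier iteration — the smaller,
   more balanced training set. The ensemble holds
   $n_\text{folds} \times T_\text{seed} \times K$ members and predicts the
   unweighted mean of their probability outputs.

## Ranked batch-mode sampling and its two printed ambiguities

Candidates are scored by

$$S_\text{final} = \alpha\,(1 - S_\text{similarity}) + (1 - \alpha)\,S_\text{uncertainty},$$

with $S_\text{uncertainty} = 1 - \max_j p_j$ (least confident) and
$S_\text{similarity}$ the maximum similarity of the candidate to the
*estimated set* (current training data plus the samples already picked this
round). Selection is greedy within the batch: after each pick the estimated
set grows, so a near-duplicate of a picked sample loses its appeal — the
mechanism that avoids the redundant batches plain uncertainty sampling
produces.

Two parts of the printed formulation are internally inconsistent, and both
are resolved here behind flags:

- **The mixing weight.** The printed rule
  $\alpha = N_\text{trainData} / (N_\text{trainPool} + N_\text{trainData})$
  is *small* when the pool dwarfs the training data, which would put low
  weight on diversity exactly when the stated intent is for diversity to
  dominate. The default is
  therefore the diversity-first form
  $\alpha = N_\text{trainPool} / (N_\text{trainPool} + N_\text{trainData})$,
  the convention of the ranked batch-mode method the design follows;
  `alpha_convention = "literal"` restores the printed form. Both are tested.
- **The similarity map.** The printed similarity is the maximum Euclidean
  *distance*, which is unbounded and grows with dissimilarity — it would make
  $(1 - S_\text{similarity})$ negative and reward *similar* candidates.
  Distance is therefore mapped onto $(0, 1]$ by $\mathrm{sim} = 1/(1+d)$
  (default) or $\mathrm{sim} = e^{-d}$ (`similarity_map = "exp"`).

Within a batch, $\alpha$ is recomputed after every pick (the picked sample
moves from the pool count to the training-data count); `alpha_update =
"frozen"` keeps the round-start value. Ties in the argmax break towards the
lowest pool index, for reproducibility. Distances are computed on the
standardized feature matrix, since Euclidean similarity is scale-sensitive
and bin indices and one-hot indicators live on different scales.

## Base learners

Three families, with the published grids: RBF-kernel SVM
($C \in \{0.1, 1, 10\}$), L2-regularized logistic regression
($C \in \{1, 10, 100\}$), and CART with Gini impurity
($\texttt{max\_depth} \in \{\text{none}, 5, 10\}$,
$\texttt{min\_samples\_leaf} \in \{1, 3, 5\}$). The offline toolchain has no
packaged SVM or CART, so both are implemented in-package: the SVM as the
standard C-SVC dual quadratic program (solved with `quadprog`, probabilities
by Platt sigmoid calibration on the training decision values — documented
because the uncertainty score consumes probabilities), CART as an exact
greedy Gini tree whose splits must strictly reduce impurity and break ties
towards the lowest feature index, then the lowest threshold. Logistic
regression delegates to `glmnet` ridge with $\lambda = 1/(Cn)$, preserving
the usual inverse-regularization meaning of $C$.

Hyperparameters are tuned **once** on the full training set by stratified
CV and frozen for all base classifiers. Per-iteration retuning is neither
described by the protocol nor affordable (it would multiply the grid cost
into every one of the $\approx 100$ iterations per run). For the same
reason `n_seed` is an explicit configuration field (default 50, even, with
$n_\text{seed}/2$ bounded by the minority class) rather than a value chosen
by a nested CV over $\{50, 100\}$: selecting it by CV would require full
ensemble fits per candidate. The tuning scorer is AUROC by default
(the protocol's primary metric; it does not name a tuning scorer),
configurable to AUPRC.

Standardization (per-column center/scale, stored on the model) is applied to
the feature matrix once inside `fit_elas()` and used for *all* families, not
only the SVM and the distance computations: the tree is invariant to
monotone per-column maps, and applying one transform everywhere keeps the
query-strategy geometry and the classifiers' view of the data identical.

## Preprocessing defaults

- Rows with any missing feature value are excluded at fit time; no
  imputation (by design).
- Categorical features are one-hot encoded from the fitted level maps; a
  level unseen at fit time becomes an all-zero block with a warning, keeping
  the transform total.
- Continuous features are discretized into equal-frequency (quantile) bins,
  default `n_bins = 4` — the source protocol states only that continuous
  features were discretized into intervals, so both the scheme and the count
  are configuration with documented defaults. The bin is stored as an
  ordinal index `0..n_bins-1` so Euclidean distances respect interval order;
  one-hot bins are available. Out-of-range values clip to the end bins.
- The 1%-variance filter is applied to *post-encoding* columns with
  threshold 0.01 on the sample variance. The source does not say whether the
  filter precedes or follows encoding; filtering after encoding also prunes
  near-constant one-hot columns, which is the stronger reading.
- Horizon labeling treats the boundary as closed: an event at exactly the
  horizon is within the period, and a last contact at exactly the horizon
  counts as followed through it. Event-free patients whose last contact
  precedes the horizon are excluded as lost to follow-up.

## The synthetic cohort generator

Real cohorts of this kind are not publicly deposited, so the package ships a
generator whose defaults state the world the tests run in: cohorts with
categorical and continuous features at a configurable prevalence (named
presets reproduce the six published task prevalences of 7.6/29.1/51.9%
recurrence and 4.6/21.8/43.7% death at their task sizes), class-conditional
Gaussian shifts on informative continuous features and tilted multinomials
on informative categorical ones, with `effect_size` the log-odds scale. This
signal model is deliberately simple because it buys a closed-form
Bayes-optimal score (`bayes_score()`) used as an oracle: zero effect size
must give chance-level AUROC, and discrimination must rise monotonically
with effect size.

What the generator does **not** emulate: correlated features, non-linear
interactions, informative censoring, or realistic survival-time
distributions — follow-up times are placed uniformly within the horizon bins
implied by `horizon_rates`, and the overall-survival columns mirror the
disease-free columns. A green test therefore establishes that the machinery
is correct on a cohort with the stated marginal structure, not that the
published real-data metric values are reproduced; those were computed on a
non-deposited hospital dataset and are out of reach by construction.

## Evaluation protocol

`repeated_holdout()` reproduces the published protocol: stratified 80/20
splits repeated (default 10 times) with derived seeds, every method fitted
on the same training split and scored on the same test split; AUROC, AUPRC
(step-wise, non-interpolated precision-recall integral — the interpolation
convention is not specified in the source, and the step integral is the
conservative standard), sensitivity and specificity at threshold 0.5 (no
threshold is stated; configurable), means and SDs over completed repeats,
and two-sided paired t-tests pairing by repeat. Zero-variance differences
return p = 1 with a warning rather than erroring. Pooling repeats *across
tasks* — the published "all tasks" rows — changes what the pairs mean, so it
is a separate explicit helper (`pooled_t_test()`), not a default.

The published comparison baselines (AdaBoost, Bagging, SMOTE, TomekLinks)
must by design be delegated to established implementations; none exist in
the offline R toolchain, so those roster names raise a structured
`elas_baseline_unavailable` error instead of a bespoke re-implementation.
The supported roster covers the three tuned base families and the ensemble
itself.

## Numerical choices worth knowing

- All model archives are JSON with 17 significant digits: 15 digits (R's
  default print precision) can perturb a CART threshold that coincides
  exactly with a data value and flip a comparison after a round-trip.
- Randomness derives from one master seed through a fixed spawning scheme
  (`(master %% 1e5) * 16384 + fold * 128 + t`, kept below $2^{31}$), so runs
  are reproducible and independent of execution order.
- The SVM dual adds a tiny ridge ($10^{-8}$, escalating on failure) to keep
  the kernel matrix positive definite for the QP solver; the bias is
  averaged over free support vectors.
- Infeasible configurations fail fast with the constraint that was violated
  ($n_\text{seed}/2$ vs the pool minority class; $K$ vs the record count a
  pool can yield) rather than silently shrinking.

## Known limitations

- The in-package SVM solves a dense QP; it is exact but $O(n^3)$-ish, so
  SVM-family ensembles are practical at cohort scale ($n \lesssim 2000$),
  not biobank scale.
- The single-split internal validation mode (`internal_split = "single"`)
  exists for pedagogy; the fold scheme supersedes it and is the tested path.
- Probability averaging is unweighted by design; weighted ensembling and
  classifier-subset resampling are explicitly out of scope.

## A minimal run

```{r example, eval = FALSE}
spec <- sim_preset("1y-death", seed = 1)
co <- generate_cohort(spec)
state <- fit_preprocess(co)
X <- apply_preprocess(co, state)
cfg <- elas_config(n_seed = 50, t_seed = 3, k = 20, n_folds = 5,
                   learner = learner_spec("logreg_l2"))
model <- fit_elas(X, co$labels, cfg, preprocess = state)
predict_proba(model, co)[1:5, ]
```
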