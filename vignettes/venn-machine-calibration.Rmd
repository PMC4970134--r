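---
title: "Valid multiprobability prediction for sensor arrays: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valid multiprobability prediction for sensor arrays: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

An electronic nose — an array of cross-sensitive metal-oxide gas sensors —
fingerprints a volatile sample by the joint response pattern of its sensors.
Classifying such fingerprints is routine; attaching an *honest probability*
to each classification is not. Classical probabilistic classifiers (naive
Bayes, softmax regression, Platt-scaled SVMs) each lean on a parametric
model of the data, and when that model is wrong — the default situation for
real sensor data — their stated probabilities drift away from the
frequencies with which they are actually right.

The Venn machine addresses this with a transductive construction whose only
assumption is that the examples are drawn i.i.d. It outputs, for each test
object, a predicted class plus a *probability interval* `[P_l, P_u]`, and
under i.i.d. sampling the long-run frequency of correct predictions is
guaranteed to be tracked by these intervals — whatever classifier is used
underneath.

## The Venn construction

Given training examples `z_1, ..., z_{n-1}` with labels from an alphabet of
size `K`, and a new object `x`:

1. **Hypothesize** each label `y` in turn and form the augmented set with
   `z_n = (x, y)`.
2. **Assign categories** with a *taxonomy*: a function that gives each
   example a category from the multiset of the others and itself. Here the
   taxonomy is the label an underlying classifier predicts for that example
   — the only requirement is symmetry in the example set, which keeps the
   construction exchangeable.
3. **Tabulate** the empirical label frequencies of the category containing
   `z_n`; this row vector (summing to 1) is row `y` of a `K x K` matrix `P`.
4. **Select**: each column's *quality* is its minimum entry; the column with
   the highest quality names the prediction, and its minimum and maximum are
   the interval bounds. Ties go to the first label in alphabet order (the
   construction itself does not break ties; a fixed deterministic rule makes
   runs reproducible).

`select_from_matrix()` exposes step 4 as a pure function; on the canonical
three-class example matrix

```{r, eval = FALSE}
p <- matrix(c(0.11, 0.78, 0.11,
              0.00, 0.91, 0.09,
              0.10, 0.70, 0.20), 3, byrow = TRUE,
            dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
select_from_matrix(p)
#> label "B", interval [0.70, 0.91]
```

the second column's minimum (0.70) beats both others, so the prediction is
B with interval [0.70, 0.91].

### Taxonomy modes

The exact construction ("loo") recategorizes every example by a classifier
trained on the other `n - 1` examples — `K * n` classifier fits per test
object. `venn_predict()` also offers an inductive shortcut ("induct"): one
fit per hypothesized label on the full augmented set, applied to every
example. This is still a symmetric function of the example multiset, so the
validity guarantee is unaffected; what changes is the granularity of the
categories. We default to "loo" for fidelity to the construction and use
"induct" in large simulations; for softmax taxonomies the inductive path
warm-starts each hypothesis fit from the training-set optimum.

## Underlying classifiers

* **Gaussian naive Bayes** (`nb_fit()`): per-class, per-feature Gaussians
  with empirical priors. Variances are floored at `1e-9` times the mean
  feature variance (and never below machine epsilon) so single-example
  classes and constant features remain defined.
* **Softmax regression** (`softmax_fit()`): multinomial logistic regression
  minimizing the negative log-likelihood plus a ridge term
  (default `l2 = 1e-4`), which makes the objective strictly convex and fixes
  the additive-shift unidentifiability of the class score vectors. The
  optimizer is L-BFGS with analytic gradients, run in short restarts so the
  recorded objective trace is non-increasing; hitting the iteration cap with
  a large gradient raises an error that reports the gradient norm.
* **SVM + Platt + coupling** (`platt_fit()`): one-vs-one RBF SVMs (via
  e1071/libsvm) supply pairwise decision values `f_ij = -f_ji`; each pair's
  values are calibrated by a sigmoid `r_ij = 1 / (1 + exp(A f + B))` fitted
  by regularized maximum likelihood with prior-smoothed targets
  (`(N+ + 1)/(N+ + 2)`, `1/(N- + 2)`) and a damped Newton iteration; the
  pairwise probabilities are then coupled into one distribution by
  minimizing `½ Σ_{i≠j} (r_ji p_i − r_ij p_j)²` on the simplex
  (`pairwise_couple()`), using the standard Gauss–Seidel fixed point on the
  KKT system with renormalization (tolerance `1e-10`, cap 1000 sweeps; the
  unit tests check it against a brute-force grid minimization). Sigmoids
  are fitted on 5-fold cross-validated decision values per pair, mirroring
  the usual libsvm procedure; tiny pairs fall back to training-set margins.
* Hyperparameters: `tune_svm()` grid-searches
  `C = 2^2, 2^4, ..., 2^14` and `gamma = 2^-9, ..., 2^-1` by stratified
  5-fold CV with deterministic tie-breaks (smallest `C`, then smallest
  `gamma`). Tuning is done once per experiment on the full training set and
  frozen across Venn and leave-one-out refits; nesting it inside every fold
  is possible in principle but multiplies cost by the grid size for little
  insight at these sample sizes. In online runs an optional re-tune every
  25 steps is available.

## Measuring validity

For a point predictor stating probability `p` for its prediction, with
`q = 1` when correct:

* mean log loss `d_ln` — average of `-log p` / `-log(1-p)`; a single
  certainly-wrong prediction makes it infinite, and we propagate that
  infinity rather than clipping it (an epsilon-clip would hide exactly the
  failure this loss exists to flag);
* root mean square loss `d_sq` — `sqrt(mean((p - q)^2))`;
* cumulative deviation `d1` — `|CN/N − ΣP/N|`, the gap between empirical
  accuracy and mean claimed probability.

A Venn predictor states an interval, so each loss first collapses the
interval to its *minimax* point — the value minimizing worst-case regret
for that loss: `p = P_u / (1 − P_l + P_u)` for log loss and
`p = P_u + P_l²/2 − P_u²/2` for square loss. Both lie inside `[P_l, P_u]`
for every valid interval (verified by a 10,000-interval sweep in the
tests), and each loss uses its own conversion. For intervals `d1` becomes
`max(d11, d12)` with `d11`/`d12` the deviations from the cumulative lower
and upper bounds.

## The synthetic generator

No public E-nose dataset accompanies the method, so the package carries a
two-level generator, and all statistical tests run on it.

* `generate_feature_table()` draws class-conditional Gaussian features:
  means on a circle (2-d) or on axes (higher dimensions), unit noise by
  default. This is i.i.d. — and hence exchangeable — by construction, which
  is precisely the hypothesis under which Venn validity is stated. A
  `correlation` parameter adds an equicorrelated noise component shared
  across features: marginals stay Gaussian, but the independence the naive
  Bayes model assumes is broken. This is the package's misspecification
  knob: it reliably produces the overconfident NB probabilities against
  which the Venn wrapper's repair is demonstrated.
* `generate_recordings()` emulates a measurement cycle: 20 s flat baseline
  (plus a constant 0.5 V per-sensor offset that calibration must remove), a
  saturating-exponential rise toward a class- and sensor-specific amplitude
  over a 180 s response phase, exponential recovery, additive Gaussian
  noise; 340 s at 2 Hz by default, matching a typical recording protocol.
  The sampling rate is metadata, not a constant: the EMA smoothing factors
  `1/(100·SR), 1/(10·SR), 1/SR` derive from whatever rate the recording
  declares.

What the generator does *not* emulate: sensor drift, humidity/temperature
covariates, inter-sample carry-over, non-Gaussian sensor noise. Passing
tests therefore certify the algorithms under the i.i.d. conditions the
theory assumes, not robustness to the full messiness of lab data.

### Problem sizes used in the checks

The statistical checks run at sizes chosen to make their conclusions
meaningful while keeping a full run on one CPU comfortable: online validity
runs use `K = 3`, `n = 500`, the inductive taxonomy and five seeds per
taxonomy; calibration comparisons use `n = 1000`; the brute-force oracle
comparison uses 50 datasets of at most 15 examples, where exact equality
with an explicit-loop reimplementation is checkable.

## Numerical and design choices

* **Baseline estimate**: the per-sensor *mean* over a configurable
  pre-injection window (default first 20 s), rather than a single reading —
  averaging is standard practice and halves the variance of the estimate at
  no cost.
* **Integration rule**: trapezoid on the uniform time grid.
* **Feature scaling**: per-feature min/max learned on training rows only;
  test values clipped to `[0, 1]`; constant columns map to 0. This is the
  only reading of min-max normalization that both lands in `[0, 1]` per
  feature and cannot leak test information; the scaler is refitted inside
  every evaluation fold for the same reason.
* **EMA features** are taken over the full trace, not just the response
  phase; the recursion is bounded and the baseline phase contributes ~0.
* **No smoothing of category rows**: the matrix rows are raw frequencies;
  a hypothesized example always belongs to its own category, so rows are
  never 0/0.
* **Coupling degeneracies**: hard 0/1 pairwise probabilities are clipped to
  `1e-12` from the boundary so the fixed point's diagonal terms stay
  positive; the iteration is deterministic.
* **Infinities**: `d_ln = Inf` is a value, not an error; report printers and
  JSON writers carry it through as the string `"Inf"`.

## Known limitations

* The exact ("loo") Venn taxonomy costs `K * n` classifier fits per test
  object — quadratic in `n` over a leave-one-out evaluation. The inductive
  mode is the practical default beyond a few hundred examples.
* Validity is guaranteed *on average over i.i.d. draws*; any single finite
  run can exceed the interval bounds by sampling fluctuation, which is why
  the checks allow a `3·sqrt(N)` binomial band around the cumulative counts.
* The Platt sigmoid is fitted per pair independently; with very few
  examples per pair the cross-validated decision values fall back to
  training margins and the calibration inherits their optimism.
* Softmax regression penalizes the intercept along with the slopes — a
  simplification that keeps the objective strictly convex; at the default
  `l2 = 1e-4` its effect is far below the statistical noise of the
  experiments run here.
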