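# vennmachine

Calibrated multiprobability classification for electronic-nose (gas-sensor
array) data — or any multi-class problem where you need the stated
probability of a prediction to mean what it says.

## The problem and the method

Classical probabilistic classifiers attach a probability to each predicted
class, but that probability is only as honest as the parametric assumptions
behind it: Gaussian naive Bayes assumes independent Gaussian features,
softmax regression assumes a log-linear posterior, Platt-scaled SVMs assume
a sigmoidal link from margins to probabilities. On real sensor-array data
those assumptions routinely fail, and the stated probabilities drift away
from the frequency with which the classifier is actually correct.

The **Venn machine** wraps any such classifier as a *taxonomy* and makes a
transductive, distribution-free prediction instead. For a new object
`x` with label alphabet of size `K`:

1. hypothesize each label `y`, augment the training set with `(x, y)`;
2. categorize every example in the augmented set by the label the
   underlying classifier predicts for it from the other examples;
3. the label frequencies of the category containing `(x, y)` form row `y`
   of a `K × K` matrix `P`;
4. each column's **quality** is its minimum entry; the best column names
   the predicted class and its minimum/maximum give the probability
   interval `[P_l, P_u]`.

Under the sole assumption that examples are i.i.d., the cumulative count of
correct predictions provably tracks the cumulative interval bounds —
regardless of how wrong the underlying classifier's own probability model
is. The package implements the construction with three taxonomies (naive
Bayes, softmax regression, RBF-SVM), the underlying point predictors
themselves (including Platt scaling with pairwise coupling), calibration
diagnostics (`d_ln`, `d_sq`, `d1`, cumulative curves, minimax
interval-to-point conversions), leave-one-out and online evaluation
protocols, transient feature extraction for raw sensor recordings
(`V_max`, curve integral, EMA-derivative features; 8 features per sensor),
and a synthetic generator for both feature tables and full sensor-array
recordings.

## Worked example

Three-class Gaussian-mixture features, one held-out sample predicted by a
Venn machine over a naive Bayes taxonomy:

```r
library(vennmachine)

ds <- generate_feature_table(c(20, 20, 20), default_class_means(3),
                             noise_sd = 1, seed = 7)
venn_predict(subset_dataset(ds, 1:59), ds$x[60, ],
             classifier_spec("nb"), mode = "loo")
#> <venn_prediction> label C, probability interval [0.9500, 0.9524] (nb taxonomy, loo mode)
#>      A      B      C
#> A 0.05 0.0000 0.9500
#> B 0.00 0.0500 0.9500
#> C 0.00 0.0476 0.9524
```

Row `y` of the matrix is the label distribution of the test point's
category under hypothesis `y`; the third column wins with quality 0.95, so
the prediction is class C and the probability of being correct is bracketed
by [0.950, 0.952] — a tight interval because the classes are well
separated. A full leave-one-out evaluation with validity diagnostics:

```r
offline_loo(ds, predictor_spec("vm-nb", venn_mode = "induct"))
#> <offline_result> vm-nb, leave-one-out over 60 samples: 95.00% correct
#> <validity_report> n = 60 (interval predictor)
#>   d_ln = 0.1273   d_sq = 0.1542   d1 = 0.0472 (d11 = 0.0472, d12 = 0.0190)
```

`d1` is the gap between mean stated probability and empirical accuracy —
the headline calibration number. `online_run()` evaluates the incremental
protocol (predict, reveal the label, refit), and
`sensitivity_specificity()` summarizes the per-class confusion.

For raw recordings, `generate_recordings()` + `extract_feature_table()`
(or `read_recording_csv()` + `extract_features()` for your own CSVs) turn
voltage traces into the per-sensor feature vectors, and `fit_scaler()` /
`apply_scaler()` handle leakage-free min-max scaling — the evaluation
protocols do this per fold automatically.

A thin CLI over the same functions ships in `inst/cli/vennmachine.R`
(subcommands `simulate`, `extract-features`, `predict-offline`,
`predict-online`, `evaluate-validity`, `run-experiment`).

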