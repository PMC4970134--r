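# The Venn machine. For a new object x and every hypothesized label y, the
# augmented set {training examples, (x, y)} is partitioned into categories by
# a taxonomy — here, the label an underlying classifier predicts for each
# example given the others. The empirical label distribution of x's category
# forms one row of a K x K matrix P; the column whose minimum entry (its
# "quality") is largest names the prediction, and that column's min and max
# bound the probability that the prediction is correct. Under i.i.d. sampling
# this interval is valid whatever the taxonomy classifier does.

#' Assign taxonomy categories to an augmented example set
#'
#' Categories are the labels an underlying classifier predicts for each
#' example. In `"loo"` mode (the exact transductive construction) the
#' classifier is refitted n times, each time on the other n - 1 examples; in
#' `"induct"` mode it is fitted once on all n examples and applied to each —
#' still a symmetric function of the example set, so Venn validity is
#' preserved, at 1/n of the cost.
#'
#' @param x feature matrix of the augmented set (hypothesized example last).
#' @param y factor of labels for the augmented set (levels = alphabet).
#' @param taxonomy a [classifier_spec()].
#' @param mode `"loo"` or `"induct"`.
#' @param init optional warm-start parameters (softmax taxonomies only).
#' @return Factor of category identifiers (the label alphabet), length n.
#' @export
assign_categories <- function(x, y, taxonomy, mode = c("loo", "induct"), init = NULL) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  y <- as.factor(y)
  n <- nrow(x)
  spec <- taxonomy
  if (!is.null(init) && spec$method == "softmax") {
    spec$params$init <- init
  }
  if (mode == "induct") {
    model <- clf_fit(spec, x, y)
    cats <- clf_predict(model, x)
  } else {
    cats <- character(n)
    for (i in seq_len(n)) {
      model <- tryCatch(
        clf_fit(spec, x[-i, , drop = FALSE], y[-i]),
        error = function(e) {
          stop(sprintf("taxonomy training failed at leave-one-out fold %d: %s",
                       i, conditionMessage(e)))
        }
      )
      cats[i] <- as.character(clf_predict(model, x[i, , drop = FALSE]))
    }
    cats <- factor(cats, levels = levels(y))
  }
  cats
}

#' Empirical label distribution of a category
#'
#' The row vector `p_y`: label frequencies among the examples sharing the
#' target category (by default the category of the last, hypothesized
#' example — which always makes the category nonempty).
#'
#' @param categories factor of category assignments, one per example.
#' @param labels factor of example labels; its levels define the alphabet
#'   (the hypothesized example carries its hypothesized label).
#' @param target_category category whose label distribution is wanted;
#'   defaults to the last example's category.
#' @return Named numeric vector over the alphabet, summing to 1.
#' @export
empirical_distribution <- function(categories, labels,
                                   target_category = categories[length(categories)]) {
  labels <- as.factor(labels)
  in_tau <- which(categories == target_category)
  if (length(in_tau) == 0L) stop_input("target category is empty")
  counts <- table(labels[in_tau])
  stats::setNames(as.numeric(counts) / length(in_tau), names(counts))
}

#' Column-selection rule on a Venn probability matrix
#'
#' Each column's quality is its minimum entry; the predicted label is the
#' column with the highest quality (ties broken towards the first label in
#' alphabet order), and the probability interval is that column's minimum
#' and maximum. Exposed as a pure function so printed matrices can be fed
#' straight in.
#'
#' @param p `K x K` numeric matrix: row y is the label distribution obtained
#'   under hypothesis y; rows must sum to 1 (tolerance `1e-9`) with entries
#'   in \[0, 1\]. Column names, if present, name the labels.
#' @return List with `label`, `p_lower`, `p_upper`, `quality` (the selected
#'   column's minimum) and `index` (the selected column).
#' @examples
#' p <- matrix(c(0.11, 0.78, 0.11,
#'               0.00, 0.91, 0.09,
#'               0.10, 0.70, 0.20), 3, byrow = TRUE,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' select_from_matrix(p) # label "B", interval [0.70, 0.91]
#' @export
select_from_matrix <- function(p) {
  p <- as.matrix(p)
  if (nrow(p) != ncol(p)) stop_input("probability matrix must be square")
  if (any(p < -1e-9) || any(p > 1 + 1e-9)) stop_input("entries must lie in [0, 1]")
  if (any(abs(rowSums(p) - 1) > 1e-9)) stop_input("every row must sum to 1")
  quality <- apply(p, 2L, min)
  j <- argmax_first(quality)
  label <- if (!is.null(colnames(p))) colnames(p)[j] else j
  list(label = label, p_lower = min(p[, j]), p_upper = max(p[, j]),
       quality = quality[[j]], index = j)
}

#' Venn machine prediction for one object
#'
#' Runs the full multiprobability construction: for every label in the
#' alphabet, augment the training set with the hypothesized example, assign
#' taxonomy categories, and record the label distribution of the test
#' example's category as one row of `P`; then select the best column.
#'
#' @param train a [labeled_dataset()] (n >= 2 classes in the alphabet).
#' @param xnew feature vector (or 1-row matrix) of the object to predict.
#' @param taxonomy a [classifier_spec()]; default Gaussian naive Bayes.
#' @param mode taxonomy mode, `"loo"` (exact, K*n classifier fits) or
#'   `"induct"` (K fits); see [assign_categories()].
#' @return An object of class `venn_prediction`: list with `label`,
#'   `p_lower`, `p_upper`, `quality` and the `K x K` matrix `P` (rows =
#'   hypothesized labels).
#' @export
venn_predict <- function(train, xnew, taxonomy = classifier_spec("nb"),
                         mode = c("loo", "induct")) {
  stopifnot(inherits(train, "labeled_dataset"))
  mode <- match.arg(mode)
  lv <- levels(train$y)
  if (length(lv) < 2L) stop_input("need an alphabet of at least two labels")
  xnew <- if (is.null(dim(xnew))) matrix(xnew, nrow = 1L) else as.matrix(xnew)
  if (ncol(xnew) != ncol(train$x)) {
    stop_input("xnew has %d features, training data has %d", ncol(xnew), ncol(train$x))
  }
  init <- NULL
  if (taxonomy$method == "softmax" && mode == "induct") {
    # warm start every hypothesis fit from the training-set optimum
    base <- tryCatch(clf_fit(taxonomy, train$x, train$y), error = function(e) NULL)
    if (!is.null(base$theta)) init <- base$theta
  }
  xa <- rbind(train$x, xnew)
  n <- nrow(xa)
  p <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  for (k in seq_along(lv)) {
    ya <- factor(c(as.character(train$y), lv[k]), levels = lv)
    cats <- tryCatch(
      assign_categories(xa, ya, taxonomy, mode, init = init),
      error = function(e) {
        stop(sprintf("taxonomy failed under hypothesis '%s': %s",
                     lv[k], conditionMessage(e)))
      }
    )
    in_tau <- cats == cats[n]
    counts <- table(ya[in_tau])
    p[k, ] <- as.numeric(counts) / sum(in_tau)
  }
  sel <- select_from_matrix(p)
  structure(
    list(label = sel$label, p_lower = sel$p_lower, p_upper = sel$p_upper,
         quality = sel$quality, matrix = p, mode = mode,
         taxonomy = taxonomy$method),
    class = "venn_prediction"
  )
}

#' @export
print.venn_prediction <- function(x, ...) {
  cat(sprintf(
    "<venn_prediction> label %s, probability interval [%.4f, %.4f] (%s taxonomy, %s mode)\n",
    x$label, x$p_lower, x$p_upper, x$taxonomy, x$mode
  ))
  print(round(x$matrix, 4))
  invisible(x)
}
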