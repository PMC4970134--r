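# Uniform classifier interface. A classifier_spec names a method plus its
# hyperparameters; clf_fit/clf_predict/clf_predict_proba dispatch on the
# fitted model. All models keep the full label alphabet so probability
# vectors stay aligned even when a class is absent from a training split
# (absent classes get probability 0). A training split with a single class
# present yields a constant model rather than an error — leave-one-out Venn
# taxonomies routinely create such splits on tiny data.

#' Specify an underlying classifier
#'
#' @param method one of `"nb"` (Gaussian naive Bayes), `"softmax"`
#'   (multinomial logistic regression), `"svm"` (RBF one-vs-one SVM, labels
#'   only), `"platt"` (SVM + Platt scaling + pairwise coupling).
#' @param ... hyperparameters forwarded to the matching fit function
#'   ([nb_fit()], [softmax_fit()], [svm_fit()], [platt_fit()]).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(method = c("nb", "softmax", "svm", "platt"), ...) {
  method <- match.arg(method)
  structure(list(method = method, params = list(...)), class = "classifier_spec")
}

#' Fit / predict through a classifier specification
#'
#' @param spec a [classifier_spec()].
#' @param x numeric feature matrix.
#' @param y factor of class labels (levels = alphabet).
#' @return `clf_fit()`: a fitted model. `clf_predict()`: a factor of
#'   predicted labels on the full alphabet. `clf_predict_proba()`: a matrix
#'   of class probabilities, columns = alphabet, rows summing to 1.
#' @export
clf_fit <- function(spec, x, y) {
  stopifnot(inherits(spec, "classifier_spec"))
  y <- as.factor(y)
  present <- levels(droplevels(y))
  if (length(present) == 1L) {
    return(structure(list(levels = levels(y), class = present),
                     class = c("constant_model", "vennmachine_model")))
  }
  fitter <- switch(spec$method,
    nb = nb_fit, softmax = softmax_fit, svm = svm_fit, platt = platt_fit
  )
  do.call(fitter, c(list(x = x, y = y), spec$params))
}

#' @rdname clf_fit
#' @param model a model fitted by `clf_fit()`.
#' @param newx feature matrix (or single feature vector) to score.
#' @export
clf_predict_proba <- function(model, newx) UseMethod("clf_predict_proba")

#' @export
clf_predict_proba.nb_model <- function(model, newx) nb_predict_proba(model, newx)

#' @export
clf_predict_proba.softmax_model <- function(model, newx) softmax_predict_proba(model, newx)

#' @export
clf_predict_proba.platt_model <- function(model, newx) platt_predict_proba(model, newx)

#' @export
clf_predict_proba.svm_model <- function(model, newx) {
  stop_input("a plain svm emits margins, not probabilities; use method = 'platt'")
}

#' @export
clf_predict_proba.constant_model <- function(model, newx) {
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1L)
  out <- matrix(0, nrow(newx), length(model$levels),
                dimnames = list(rownames(newx), model$levels))
  out[, model$class] <- 1
  out
}

#' @rdname clf_fit
#' @export
clf_predict <- function(model, newx) UseMethod("clf_predict")

#' @export
clf_predict.svm_model <- function(model, newx) svm_predict_label(model, newx)

#' @export
clf_predict.default <- function(model, newx) {
  pr <- clf_predict_proba(model, newx)
  factor(colnames(pr)[apply(pr, 1L, argmax_first)], levels = model$levels)
}
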