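# RBF support vector machine wrapper. The margin classifier itself is
# delegated to e1071/libsvm (one-vs-one C-classification); this file owns the
# parts the rest of the package contracts on: the antisymmetric pairwise
# decision-value matrix and grid-search hyperparameter tuning.

#' Fit a multiclass RBF support vector machine
#'
#' One-vs-one C-classification with a radial basis kernel, via
#' [e1071::svm()]. Feature scaling is left off here because the package
#' pipeline applies its own min-max scaler. Class labels must not contain
#' `"/"` (used by libsvm to name class pairs).
#'
#' @param x numeric feature matrix.
#' @param y factor of class labels (levels = alphabet; at least two classes
#'   must be present).
#' @param cost soft-margin cost C.
#' @param gamma RBF kernel width; default `1/ncol(x)`.
#' @param ... passed on to [e1071::svm()].
#' @return An object of class `svm_model` wrapping the e1071 fit.
#' @export
svm_fit <- function(x, y, cost = 1, gamma = NULL, ...) {
  x <- as.matrix(x)
  y <- as.factor(y)
  yp <- droplevels(y)
  if (nlevels(yp) < 2L) stop_input("svm needs at least two classes present")
  if (any(grepl("/", levels(yp), fixed = TRUE))) {
    stop_input("class labels must not contain '/'")
  }
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  fit <- e1071::svm(x, yp, type = "C-classification", kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE, ...)
  structure(
    list(fit = fit, levels = levels(y), present = levels(yp),
         cost = cost, gamma = gamma),
    class = c("svm_model", "vennmachine_model")
  )
}

#' Pairwise decision values of a fitted SVM
#'
#' Returns, per sample, the full antisymmetric matrix of one-vs-one decision
#' values: `f[i, j] > 0` means the pair classifier for classes `(i, j)`
#' favours class `i`, and `f[j, i] = -f[i, j]` by construction.
#'
#' @param model a fitted `svm_model`.
#' @param newx matrix (or single vector) of feature values.
#' @return 3-d array `n_samples x K_present x K_present` with zero diagonal.
#' @export
svm_decision_values <- function(model, newx) {
  stopifnot(inherits(model, "svm_model"))
  if (is.null(model$fit)) stop_input("unfitted svm model")
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1L)
  newx <- as.matrix(newx)
  pred <- predict(model$fit, newx, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  kp <- length(model$present)
  f <- array(0, dim = c(nrow(newx), kp, kp),
             dimnames = list(rownames(newx), model$present, model$present))
  for (col in colnames(dv)) {
    pair <- strsplit(col, "/", fixed = TRUE)[[1L]]
    f[, pair[1L], pair[2L]] <- dv[, col]
    f[, pair[2L], pair[1L]] <- -dv[, col]
  }
  f
}

# Predicted labels on the full alphabet (internal; the public route is
# clf_predict()).
svm_predict_label <- function(model, newx) {
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1L)
  factor(as.character(predict(model$fit, as.matrix(newx))), levels = model$levels)
}

#' Grid-search SVM hyperparameters by stratified cross-validation
#'
#' Evaluates every `(cost, gamma)` grid point by k-fold stratified
#' cross-validated accuracy and returns the best one. Ties are broken
#' deterministically towards the smallest cost, then the smallest gamma.
#' The default grids are `C = 2^2, 2^4, ..., 2^14` and
#' `gamma = 2^-9, 2^-7, ..., 2^-1`.
#'
#' @param x numeric feature matrix.
#' @param y factor of class labels; every class must have at least `folds`
#'   examples so each fold contains every class.
#' @param cost_grid,gamma_grid candidate values.
#' @param folds number of cross-validation folds (default 5).
#' @param seed seed for the fold assignment.
#' @return List with `cost`, `gamma`, `cv_accuracy` and the full `grid` of
#'   per-point accuracies.
#' @export
tune_svm <- function(x, y, cost_grid = 2^seq(2, 14, by = 2),
                     gamma_grid = 2^seq(-9, -1, by = 2), folds = 5L, seed = 1L) {
  x <- as.matrix(x)
  y <- as.factor(y)
  counts <- table(droplevels(y))
  if (min(counts) < folds) {
    stop_input("stratified %d-fold CV needs >= %d examples per class (smallest class has %d)",
               folds, folds, min(counts))
  }
  fold <- stratified_folds(y, folds, seed)
  grid <- expand.grid(cost = sort(cost_grid), gamma = sort(gamma_grid))
  grid$accuracy <- NA_real_
  best <- NULL
  for (g in sort(unique(gamma_grid))) {
    for (co in sort(unique(cost_grid))) {
      acc <- vapply(seq_len(folds), function(fo) {
        m <- svm_fit(x[fold != fo, , drop = FALSE], y[fold != fo], cost = co, gamma = g)
        mean(svm_predict_label(m, x[fold == fo, , drop = FALSE]) == y[fold == fo])
      }, numeric(1L))
      grid$accuracy[grid$cost == co & grid$gamma == g] <- mean(acc)
    }
  }
  # deterministic tie-break: smallest cost first, then smallest gamma
  ord <- order(-grid$accuracy, grid$cost, grid$gamma)
  best <- grid[ord[1L], ]
  list(cost = best$cost, gamma = best$gamma, cv_accuracy = best$accuracy, grid = grid)
}
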