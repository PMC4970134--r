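# Evaluation protocols: leave-one-out (offline) and incremental (online)
# prediction, plus per-class sensitivity/specificity. Six predictor
# configurations are supported: the three Venn predictors (vm-nb, vm-sr,
# vm-svm) and their underlying point-probability methods (nb, sr, platt).

#' Specify a probabilistic predictor
#'
#' @param method one of `"vm-nb"`, `"vm-sr"`, `"vm-svm"` (Venn machines
#'   over the naive Bayes, softmax and SVM taxonomies) or `"nb"`, `"sr"`,
#'   `"platt"` (the underlying point-probability methods).
#' @param venn_mode taxonomy mode for Venn predictors, `"loo"` (exact) or
#'   `"induct"` (one classifier fit per hypothesis); ignored for point
#'   methods.
#' @param ... hyperparameters forwarded to the underlying classifier.
#' @return An object of class `predictor_spec`.
#' @export
predictor_spec <- function(method = c("vm-nb", "vm-sr", "vm-svm", "nb", "sr", "platt"),
                           venn_mode = c("loo", "induct"), ...) {
  method <- tryCatch(match.arg(method), error = function(e) {
    stop_input("unknown method '%s'; valid methods: vm-nb, vm-sr, vm-svm, nb, sr, platt",
               as.character(method)[1L])
  })
  venn_mode <- match.arg(venn_mode)
  base <- switch(method,
    "vm-nb" = "nb", "nb" = "nb",
    "vm-sr" = "softmax", "sr" = "softmax",
    "vm-svm" = "svm", "platt" = "platt"
  )
  structure(
    list(method = method, venn = grepl("^vm-", method),
         taxonomy = classifier_spec(base, ...), venn_mode = venn_mode),
    class = "predictor_spec"
  )
}

# One prediction record: label plus probability bounds (equal for point
# predictors: the probability attached to the predicted label).
predict_example <- function(spec, train, xnew) {
  if (spec$venn) {
    vp <- venn_predict(train, xnew, spec$taxonomy, spec$venn_mode)
    list(label = vp$label, p_lower = vp$p_lower, p_upper = vp$p_upper)
  } else {
    model <- clf_fit(spec$taxonomy, train$x, train$y)
    pr <- clf_predict_proba(model, xnew)[1L, ]
    j <- argmax_first(pr)
    list(label = names(pr)[j], p_lower = pr[[j]], p_upper = pr[[j]])
  }
}

#' Leave-one-out offline evaluation
#'
#' Every sample is predicted once by a model trained on the remaining
#' n - 1 samples. The min-max feature scaler is refitted inside each fold
#' on the training portion only, so no information about the held-out
#' sample leaks into the model.
#'
#' @param dataset a [labeled_dataset()] with at least K + 1 samples.
#' @param spec a [predictor_spec()].
#' @param scale refit and apply the min-max scaler per fold (default TRUE).
#' @return An object of class `offline_result`: list with the prediction
#'   `records` data frame, `classification_rate`, the [validity_report()],
#'   and the `confusion` table (rows = true labels).
#' @export
offline_loo <- function(dataset, spec, scale = TRUE) {
  stopifnot(inherits(dataset, "labeled_dataset"), inherits(spec, "predictor_spec"))
  n <- nrow(dataset$x)
  if (n < nlevels(dataset$y) + 1L) {
    stop_input("leave-one-out needs at least K + 1 = %d samples", nlevels(dataset$y) + 1L)
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    train <- subset_dataset(dataset, -i)
    xt <- dataset$x[i, ]
    if (scale) {
      sc <- fit_scaler(train$x)
      train <- apply_scaler(train, sc)
      xt <- apply_scaler(xt, sc)
    }
    pred <- predict_example(spec, train, xt)
    rows[[i]] <- data.frame(
      sample_id = rownames(dataset$x)[i],
      true_label = as.character(dataset$y[i]),
      predicted_label = as.character(pred$label),
      p_lower = pred$p_lower, p_upper = pred$p_upper,
      correct = as.character(pred$label) == as.character(dataset$y[i]),
      stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, rows)
  confusion <- confusion_table(dataset$y, factor(records$predicted_label,
                                                 levels = levels(dataset$y)))
  structure(
    list(records = records,
         classification_rate = mean(records$correct),
         validity = validity_report(records),
         confusion = confusion, method = spec$method),
    class = "offline_result"
  )
}

#' @export
print.offline_result <- function(x, ...) {
  cat(sprintf("<offline_result> %s, leave-one-out over %d samples: %.2f%% correct\n",
              x$method, nrow(x$records), 100 * x$classification_rate))
  print(x$validity)
  invisible(x)
}

#' Online (incremental) evaluation
#'
#' Seeds an initial training set with `init_per_class` randomly chosen
#' samples per class, then consumes the remaining samples in seeded random
#' order: each is predicted with the current model, then joined (with its
#' true label) to the training set before the next prediction. This is the
#' transductive setting in which the Venn validity guarantee is stated.
#'
#' @inheritParams offline_loo
#' @param init_per_class initial training samples per class (default 3).
#' @param seed seed controlling the initial set and the test order.
#' @param tune optional list enabling periodic SVM hyperparameter re-tuning:
#'   `list(every = 25, cost_grid = ..., gamma_grid = ..., folds = 5)`. The
#'   grid search runs on the current training set at steps
#'   `1, every + 1, 2 * every + 1, ...` and the chosen `(cost, gamma)` are
#'   frozen in between. `NULL` (default) keeps the spec's hyperparameters
#'   throughout.
#' @return An object of class `online_result`: list with per-step `records`
#'   (including cumulative columns), the [validity_report()], `seed`, and
#'   `final_train_size`.
#' @export
online_run <- function(dataset, spec, init_per_class = 3L, seed = 1L,
                       scale = TRUE, tune = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"), inherits(spec, "predictor_spec"))
  if (init_per_class < 1L) stop_input("init_per_class must be >= 1")
  counts <- table(dataset$y)
  if (any(counts <= init_per_class)) {
    stop_input("every class needs more than init_per_class = %d samples", init_per_class)
  }
  y <- dataset$y
  withr::with_seed(seed, {
    init_idx <- unlist(lapply(levels(y), function(l) resample(which(y == l), init_per_class)))
    test_order <- resample(setdiff(seq_along(y), init_idx), length(y) - length(init_idx))
  })
  train_idx <- init_idx
  rows <- vector("list", length(test_order))
  for (s in seq_along(test_order)) {
    if (!is.null(tune) && spec$taxonomy$method %in% c("svm", "platt") &&
        (s - 1L) %% (tune$every %||% 25L) == 0L) {
      cur <- subset_dataset(dataset, train_idx)
      xs <- if (scale) apply_scaler(cur$x, fit_scaler(cur$x)) else cur$x
      tuned <- tune_svm(xs, cur$y,
                        cost_grid = tune$cost_grid %||% 2^seq(2, 14, by = 2),
                        gamma_grid = tune$gamma_grid %||% 2^seq(-9, -1, by = 2),
                        folds = tune$folds %||% 5L, seed = seed)
      spec$taxonomy$params$cost <- tuned$cost
      spec$taxonomy$params$gamma <- tuned$gamma
    }
    i <- test_order[s]
    train <- subset_dataset(dataset, train_idx)
    xt <- dataset$x[i, ]
    if (scale) {
      sc <- fit_scaler(train$x)
      train <- apply_scaler(train, sc)
      xt <- apply_scaler(xt, sc)
    }
    pred <- predict_example(spec, train, xt)
    rows[[s]] <- data.frame(
      step = s, sample_id = rownames(dataset$x)[i],
      true_label = as.character(y[i]),
      predicted_label = as.character(pred$label),
      p_lower = pred$p_lower, p_upper = pred$p_upper,
      correct = as.character(pred$label) == as.character(y[i]),
      stringsAsFactors = FALSE
    )
    train_idx <- c(train_idx, i)
  }
  records <- do.call(rbind, rows)
  records$cum_correct <- cumsum(records$correct)
  records$cum_p_lower <- cumsum(records$p_lower)
  records$cum_p_upper <- cumsum(records$p_upper)
  structure(
    list(records = records, validity = validity_report(records),
         seed = seed, init_per_class = init_per_class,
         final_train_size = length(train_idx), method = spec$method),
    class = "online_result"
  )
}

#' @export
print.online_result <- function(x, ...) {
  cat(sprintf(
    "<online_result> %s, %d online steps (seed %d, %d/class initial): %.2f%% correct\n",
    x$method, nrow(x$records), x$seed, x$init_per_class, 100 * mean(x$records$correct)
  ))
  print(x$validity)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Confusion table
#'
#' @param true,predicted factors on a shared alphabet.
#' @return Integer matrix, rows = true labels, columns = predicted labels.
#' @export
confusion_table <- function(true, predicted) {
  true <- as.factor(true)
  predicted <- factor(as.character(predicted), levels = levels(true))
  as.matrix(table(true = true, predicted = predicted))
}

#' Per-class sensitivity and specificity
#'
#' For class k, sensitivity is the fraction of class-k samples classified
#' as k; specificity is one minus the fraction of all other-class samples
#' wrongly classified as k. A class with no true samples gets `NA`
#' sensitivity (undefined, not silently zero).
#'
#' @param confusion a [confusion_table()] (rows = true labels).
#' @return Data frame with columns `class`, `sensitivity`, `specificity`.
#' @export
sensitivity_specificity <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stop_input("confusion table must be square")
  rs <- rowSums(confusion)
  k <- nrow(confusion)
  sens <- ifelse(rs > 0, diag(confusion) / rs, NA_real_)
  spec <- vapply(seq_len(k), function(j) {
    other <- sum(rs[-j])
    if (other == 0) return(NA_real_)
    1 - sum(confusion[-j, j]) / other
  }, numeric(1L))
  data.frame(class = rownames(confusion), sensitivity = as.numeric(sens),
             specificity = spec, row.names = NULL, stringsAsFactors = FALSE)
}
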