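#' Gaussian naive Bayes classifier
#'
#' Class-conditional densities are products of per-feature Gaussians with
#' class-specific means and variances estimated from the training rows;
#' priors are the empirical class frequencies. The posterior is
#' `P(y = k | x) ∝ P(y = k) * prod_j N(x_j; mu_kj, var_kj)`, normalized over
#' the classes present in the training set (absent alphabet classes get
#' probability 0).
#'
#' Variances are floored at `var_floor` times the mean overall feature
#' variance (never below machine epsilon), so single-example classes and
#' constant features stay well defined instead of erroring.
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y factor of class labels; its levels define the alphabet.
#' @param var_floor relative variance floor (default `1e-9`).
#' @return An object of class `nb_model`.
#' @export
nb_fit <- function(x, y, var_floor = 1e-9) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nrow(x) != length(y)) stop_input("x and y disagree on sample count")
  counts <- tabulate(y, nbins = nlevels(y))
  present <- levels(y)[counts > 0L]
  if (length(present) < 1L) stop_input("no training examples")
  d <- ncol(x)
  mu <- sig2 <- matrix(NA_real_, length(present), d,
                       dimnames = list(present, colnames(x)))
  for (k in seq_along(present)) {
    xk <- x[y == present[k], , drop = FALSE]
    mu[k, ] <- colMeans(xk)
    if (nrow(xk) >= 2L) sig2[k, ] <- apply(xk, 2L, var)
  }
  pooled <- if (nrow(x) >= 2L) mean(apply(x, 2L, var)) else 0
  floor_val <- max(var_floor * pooled, .Machine$double.eps)
  sig2[!is.finite(sig2) | sig2 < floor_val] <- floor_val
  structure(
    list(
      levels = levels(y), present = present, mean = mu, var = sig2,
      log_prior = log(counts[counts > 0L] / sum(counts))
    ),
    class = c("nb_model", "vennmachine_model")
  )
}

#' @rdname nb_fit
#' @param model a fitted `nb_model`.
#' @param newx matrix (or single vector) of feature values to score.
#' @return `nb_predict_proba()`: matrix of posterior class probabilities,
#'   one row per sample, columns aligned with the full label alphabet.
#' @export
nb_predict_proba <- function(model, newx) {
  stopifnot(inherits(model, "nb_model"))
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1L)
  newx <- as.matrix(newx)
  n <- nrow(newx)
  kp <- length(model$present)
  ll <- matrix(0, n, kp)
  tx <- t(newx) # features x samples; dnorm recycles per-feature parameters
  for (k in seq_len(kp)) {
    ll[, k] <- model$log_prior[k] +
      colSums(dnorm(tx, mean = model$mean[k, ], sd = sqrt(model$var[k, ]), log = TRUE))
  }
  p <- row_softmax(ll)
  out <- matrix(0, n, length(model$levels), dimnames = list(rownames(newx), model$levels))
  out[, match(model$present, model$levels)] <- p
  out
}
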