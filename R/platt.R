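# Platt scaling and pairwise coupling: sigmoid calibration of SVM decision
# values into pairwise class probabilities r_ij = 1 / (1 + exp(A f + B)),
# then coupling of all pairs into a single multiclass distribution by
# minimizing sum_{i != j} (r_ji p_i - r_ij p_j)^2 on the simplex.

#' Fit Platt's sigmoid to decision values
#'
#' Maximum-likelihood fit of `r = 1 / (1 + exp(A f + B))` to binary pair
#' outcomes, with the prior-smoothed targets `(N+ + 1)/(N+ + 2)` and
#' `1/(N- + 2)` that regularize the fit and keep it defined for separable
#' data. The optimizer is a damped Newton iteration on the (convex) negative
#' log-likelihood, numerically stabilized against sigmoid saturation.
#'
#' @param f numeric vector of decision values; positive values favour the
#'   pair's first class.
#' @param target logical/0-1 vector, `1` = the pair's first class.
#' @param max_iter Newton iteration cap.
#' @return Named numeric vector `c(A, B)`.
#' @export
platt_fit_sigmoid <- function(f, target, max_iter = 200L) {
  f <- as.numeric(f)
  target <- as.integer(as.logical(target))
  if (length(f) != length(target)) stop_input("f and target lengths differ")
  n1 <- sum(target == 1L)
  n0 <- sum(target == 0L)
  if (n1 == 0L || n0 == 0L) stop_input("both pair classes must be represented")
  hi <- (n1 + 1) / (n1 + 2)
  lo <- 1 / (n0 + 2)
  t <- ifelse(target == 1L, hi, lo)

  nll <- function(a, b) {
    z <- a * f + b
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  a <- 0
  b <- log((n0 + 1) / (n1 + 1))
  fval <- nll(a, b)
  sigma <- 1e-12
  for (it in seq_len(max_iter)) {
    z <- a * f + b
    p <- ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
    d1 <- t - p
    g1 <- sum(f * d1)
    g2 <- sum(d1)
    if (max(abs(g1), abs(g2)) < 1e-10) break
    d2 <- p * (1 - p)
    h11 <- sum(f * f * d2) + sigma
    h22 <- sum(d2) + sigma
    h21 <- sum(f * d2)
    det <- h11 * h22 - h21 * h21
    da <- -(h22 * g1 - h21 * g2) / det
    db <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * da + g2 * db
    step <- 1
    accepted <- FALSE
    while (step >= 1e-10) {
      cand <- nll(a + step * da, b + step * db)
      if (cand < fval + 1e-4 * step * gd) {
        a <- a + step * da
        b <- b + step * db
        fval <- cand
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
  }
  c(A = a, B = b)
}

#' @rdname platt_fit_sigmoid
#' @param ab fitted coefficients, `c(A, B)`.
#' @return `platt_sigmoid()`: the calibrated probability
#'   `1 / (1 + exp(A f + B))` for each decision value.
#' @export
platt_sigmoid <- function(f, ab) {
  z <- ab[[1L]] * f + ab[[2L]]
  ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
}

#' Couple pairwise probabilities into a class distribution
#'
#' Solves the constrained least-squares problem
#' \deqn{\min_p \frac12 \sum_i \sum_{j \ne i} (r_{ji} p_i - r_{ij} p_j)^2,
#'   \quad p_i \ge 0, \ \sum_i p_i = 1}
#' by the standard damped Gauss–Seidel fixed-point iteration on its KKT
#' system with simplex renormalization after every coordinate update. The
#' iteration is deterministic; non-convergence within the cap raises a
#' diagnostic error carrying the KKT residual.
#'
#' @param r `K x K` matrix with `r[i, j]` the estimated probability of class
#'   `i` against class `j` (`r[i, j] + r[j, i] = 1` off the diagonal; the
#'   diagonal is ignored).
#' @param tol KKT residual tolerance (default `1e-10`).
#' @param max_iter sweep cap (default 1000).
#' @return Numeric probability vector of length `K` (named from `r`'s rows).
#' @export
pairwise_couple <- function(r, tol = 1e-10, max_iter = 1000L) {
  r <- as.matrix(r)
  k <- nrow(r)
  if (k != ncol(r)) stop_input("r must be square")
  if (k < 2L) stop_input("need at least two classes")
  off <- r[row(r) != col(r)]
  if (any(off < -1e-9 | off > 1 + 1e-9)) stop_input("pairwise probabilities must lie in [0, 1]")
  s <- r + t(r)
  if (any(abs(s[row(s) != col(s)] - 1) > 1e-6)) {
    stop_input("r[i, j] + r[j, i] must equal 1 for i != j")
  }
  # clip hard 0/1 pairs so every diagonal Q entry stays positive
  r <- pmin(pmax(r, 1e-12), 1 - 1e-12)
  diag(r) <- 0
  q <- matrix(0, k, k)
  for (tt in seq_len(k)) {
    q[tt, tt] <- sum(r[-tt, tt]^2)
    q[tt, -tt] <- -r[-tt, tt] * r[tt, -tt]
  }
  p <- rep(1 / k, k)
  converged <- FALSE
  resid <- NA_real_
  for (it in seq_len(max_iter)) {
    for (tt in seq_len(k)) {
      pqp <- drop(crossprod(p, q %*% p))
      p[tt] <- (-sum(q[tt, -tt] * p[-tt]) + pqp) / q[tt, tt]
      p <- p / sum(p)
    }
    qp <- drop(q %*% p)
    resid <- max(abs(qp - drop(crossprod(p, qp))))
    if (resid < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop(sprintf("pairwise coupling did not converge: KKT residual %.3g after %d sweeps",
                 resid, max_iter))
  }
  stats::setNames(p, rownames(r))
}

#' Platt's method: probabilistic multiclass SVM
#'
#' Fits a one-vs-one RBF SVM, calibrates every class pair's decision values
#' with [platt_fit_sigmoid()], and at prediction time couples the pairwise
#' probabilities into a multiclass distribution with [pairwise_couple()].
#' Sigmoids are fitted on cross-validated decision values (default 5 folds
#' per pair, mirroring the usual libsvm procedure) to avoid the optimistic
#' bias of training-set margins; pairs too small to split fall back to
#' training-set decision values.
#'
#' @inheritParams svm_fit
#' @param sigmoid_folds folds for per-pair CV decision values; `0` disables
#'   CV and uses training-set decision values.
#' @param seed seed for the sigmoid CV fold assignment.
#' @return An object of class `platt_model`.
#' @export
platt_fit <- function(x, y, cost = 1, gamma = NULL, sigmoid_folds = 5L, seed = 1L) {
  x <- as.matrix(x)
  y <- as.factor(y)
  model <- svm_fit(x, y, cost = cost, gamma = gamma)
  yp <- droplevels(y)
  present <- levels(yp)
  full_f <- svm_decision_values(model, x)
  sigmoids <- list()
  for (i in seq_along(present)) {
    for (j in seq_along(present)) {
      if (j <= i) next
      li <- present[i]
      lj <- present[j]
      idx <- which(yp %in% c(li, lj))
      tgt <- yp[idx] == li
      use_cv <- sigmoid_folds >= 2L && min(sum(tgt), sum(!tgt)) >= sigmoid_folds
      if (use_cv) {
        fold <- stratified_folds(factor(tgt), sigmoid_folds, seed)
        fvals <- numeric(length(idx))
        for (fo in seq_len(sigmoid_folds)) {
          tr <- idx[fold != fo]
          te <- idx[fold == fo]
          m2 <- svm_fit(x[tr, , drop = FALSE],
                        factor(as.character(yp[tr]), levels = c(li, lj)),
                        cost = cost, gamma = gamma)
          fvals[fold == fo] <- svm_decision_values(m2, x[te, , drop = FALSE])[, li, lj]
        }
      } else {
        fvals <- full_f[idx, li, lj]
      }
      sigmoids[[paste(li, lj, sep = "/")]] <- platt_fit_sigmoid(fvals, tgt)
    }
  }
  structure(
    list(svm = model, sigmoids = sigmoids, levels = levels(y), present = present),
    class = c("platt_model", "vennmachine_model")
  )
}

#' @rdname platt_fit
#' @param model a fitted `platt_model`.
#' @param newx matrix (or single vector) of feature values to score.
#' @export
platt_predict_proba <- function(model, newx) {
  stopifnot(inherits(model, "platt_model"))
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1L)
  newx <- as.matrix(newx)
  f <- svm_decision_values(model$svm, newx)
  kp <- length(model$present)
  out <- matrix(0, nrow(newx), length(model$levels),
                dimnames = list(rownames(newx), model$levels))
  cols <- match(model$present, model$levels)
  for (s in seq_len(nrow(newx))) {
    r <- matrix(0.5, kp, kp, dimnames = list(model$present, model$present))
    for (pair in names(model$sigmoids)) {
      lab <- strsplit(pair, "/", fixed = TRUE)[[1L]]
      rij <- platt_sigmoid(f[s, lab[1L], lab[2L]], model$sigmoids[[pair]])
      r[lab[1L], lab[2L]] <- rij
      r[lab[2L], lab[1L]] <- 1 - rij
    }
    out[s, cols] <- pairwise_couple(r)
  }
  out
}
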