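#' Softmax (multinomial logistic) regression
#'
#' Fits class score vectors `theta_k` (with intercept) by minimizing the
#' multinomial negative log-likelihood
#' \deqn{J(\theta) = -\sum_i \log \frac{e^{\theta_{y_i}^T x_i}}
#'   {\sum_j e^{\theta_j^T x_i}} + \frac{\lambda}{2} \|\theta\|^2}
#' The ridge term (`l2`) makes the objective strictly convex and pins down
#' the otherwise unidentified common shift of the `theta_k`. Optimization is
#' L-BFGS with analytic gradients, run in short restarts so the recorded
#' objective trace is non-increasing; if the gradient norm is still large at
#' the iteration cap a diagnostic error reporting it is raised.
#'
#' @param x numeric feature matrix.
#' @param y factor of class labels (levels = alphabet).
#' @param l2 ridge penalty weight (default `1e-4`).
#' @param max_iter total L-BFGS iteration cap (default 1000). `max_iter = 0`
#'   returns the initial parameters unchanged (all-zero scores give the
#'   uniform distribution).
#' @param tol gradient tolerance, scaled by the sample count.
#' @param init optional warm-start coefficient matrix `(d+1) x K` with
#'   columns named by class; unnamed classes start at zero.
#' @param chunk iterations per L-BFGS restart.
#' @return An object of class `softmax_model` with a `trace` of objective
#'   values (initial value, then one per restart).
#' @export
softmax_fit <- function(x, y, l2 = 1e-4, max_iter = 1000L, tol = 1e-7,
                        init = NULL, chunk = 50L) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nrow(x) < 1L) stop_input("empty training set")
  if (l2 < 0) stop_input("l2 must be >= 0")
  yp <- droplevels(y)
  present <- levels(yp)
  n <- nrow(x)
  kp <- length(present)
  xa <- cbind(1, x)
  p <- ncol(xa)
  ymat <- matrix(0, n, kp)
  ymat[cbind(seq_len(n), as.integer(yp))] <- 1

  theta0 <- matrix(0, p, kp, dimnames = list(NULL, present))
  if (!is.null(init)) {
    init <- as.matrix(init)
    if (nrow(init) != p) stop_input("init has %d rows, expected %d", nrow(init), p)
    hit <- intersect(colnames(init), present)
    theta0[, hit] <- init[, hit]
  }

  fn <- function(th) {
    s <- xa %*% matrix(th, p, kp)
    m <- row_max(s)
    lse <- m + log(rowSums(exp(s - m)))
    -(sum(s * ymat) - sum(lse)) + 0.5 * l2 * sum(th^2)
  }
  gr <- function(th) {
    thm <- matrix(th, p, kp)
    s <- xa %*% thm
    pr <- exp(s - row_max(s))
    pr <- pr / rowSums(pr)
    as.vector(crossprod(xa, pr - ymat) + l2 * thm)
  }

  th <- as.vector(theta0)
  trace <- fn(th)
  iters <- 0L
  converged <- max_iter == 0L
  while (iters < max_iter) {
    res <- optim(th, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = min(chunk, max_iter - iters)))
    th <- res$par
    trace <- c(trace, res$value)
    iters <- iters + min(chunk, max_iter - iters)
    gmax <- max(abs(gr(th)))
    if (gmax <= tol * max(1, n) || res$convergence == 0L) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    gmax <- max(abs(gr(th)))
    if (gmax > 1e-3 * max(1, n)) {
      stop(sprintf(
        "softmax optimisation did not converge: max |gradient| = %.4g after %d iterations",
        gmax, iters
      ))
    }
  }
  structure(
    list(
      levels = levels(y), present = present,
      theta = matrix(th, p, kp, dimnames = list(c("(intercept)", colnames(x)), present)),
      l2 = l2, trace = trace, iterations = iters
    ),
    class = c("softmax_model", "vennmachine_model")
  )
}

#' @rdname softmax_fit
#' @param model a fitted `softmax_model`.
#' @param newx matrix (or single vector) of feature values to score.
#' @export
softmax_predict_proba <- function(model, newx) {
  stopifnot(inherits(model, "softmax_model"))
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1L)
  newx <- as.matrix(newx)
  s <- cbind(1, newx) %*% model$theta
  p <- row_softmax(s)
  out <- matrix(0, nrow(newx), length(model$levels),
                dimnames = list(rownames(newx), model$levels))
  out[, match(model$present, model$levels)] <- p
  out
}
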