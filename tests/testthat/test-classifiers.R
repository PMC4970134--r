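test_that("Gaussian NB posterior matches direct Bayes arithmetic", {
  # symmetric two-class problem, query at the origin -> posterior 1/2
  set.seed(1)
  x <- rbind(matrix(rnorm(20, -3), 20), matrix(rnorm(20, 3), 20))
  y <- factor(rep(c("A", "B"), each = 20))
  m <- nb_fit(x, y)
  # force exact symmetry through the model parameters
  m$mean[] <- c(-3, 3)
  m$var[] <- 1
  expect_equal(unname(nb_predict_proba(m, c(0))[1, ]), c(0.5, 0.5))

  # identical class-conditional densities -> posterior equals the priors
  m$mean[] <- 0
  m$log_prior <- log(c(0.7, 0.3))
  expect_equal(unname(nb_predict_proba(m, c(1.3))[1, ]), c(0.7, 0.3))

  # hand-computed posterior on a tiny 1-d fit
  x1 <- matrix(c(0, 2, 10, 12), ncol = 1)
  y1 <- factor(c("A", "A", "B", "B"))
  fit <- nb_fit(x1, y1)
  lik <- function(q, mu, s2) dnorm(q, mu, sqrt(s2))
  q <- 4
  la <- 0.5 * lik(q, 1, 2)  # mean 1, var 2 (n-1 denominator)
  lb <- 0.5 * lik(q, 11, 2)
  expect_equal(unname(nb_predict_proba(fit, q)[1, ]), c(la, lb) / (la + lb))
})

test_that("NB estimates class means consistently at n = 1000", {
  ds <- generate_feature_table(1000, matrix(c(0, 3), 2, 1), noise_sd = 1, seed = 4)
  m <- nb_fit(ds$x, ds$y)
  expect_lt(abs(m$mean["A", 1] - 0), 0.15)
  expect_lt(abs(m$mean["B", 1] - 3), 0.15)
})

test_that("NB handles degenerate classes and is feature-order invariant", {
  # single-example class: variance floor applies instead of erroring
  x <- matrix(c(0, 0.1, 5), ncol = 1)
  y <- factor(c("A", "A", "B"))
  m <- nb_fit(x, y)
  expect_true(all(is.finite(nb_predict_proba(m, 2)[1, ])))

  ds <- overlap_dataset(20, dims = 4, seed = 9)
  perm <- c(3, 1, 4, 2)
  p1 <- nb_predict_proba(nb_fit(ds$x, ds$y), ds$x[1:5, ])
  p2 <- nb_predict_proba(nb_fit(ds$x[, perm], ds$y), ds$x[1:5, perm])
  expect_equal(p1, p2)
})

test_that("probability outputs are simplex vectors for all classifiers", {
  ds <- overlap_dataset(15, seed = 12)
  specs <- list(classifier_spec("nb"), classifier_spec("softmax"),
                classifier_spec("platt", sigmoid_folds = 0))
  for (spec in specs) {
    p <- clf_predict_proba(clf_fit(spec, ds$x, ds$y), ds$x[1:8, ])
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(unname(rowSums(p)), rep(1, 8), tolerance = 1e-9)
  }
})

test_that("softmax with zero coefficients is uniform; K = 2 matches glm", {
  ds <- overlap_dataset(10, seed = 2)
  m0 <- softmax_fit(ds$x, ds$y, max_iter = 0)
  expect_equal(unname(softmax_predict_proba(m0, ds$x[1:3, ])),
               matrix(1 / 3, 3, 3))

  # binary softmax reduces to logistic regression on coefficient differences
  ds2 <- generate_feature_table(40, matrix(c(0, 1.5, 0, 0), 2, 2), seed = 3)
  m <- softmax_fit(ds2$x, ds2$y, l2 = 1e-8, max_iter = 4000, tol = 1e-9)
  glm_fit <- glm(I(y == "B") ~ x1 + x2,
                 data = data.frame(y = ds2$y, x1 = ds2$x[, 1], x2 = ds2$x[, 2]),
                 family = binomial())
  p_glm <- predict(glm_fit, type = "response")
  p_sm <- softmax_predict_proba(m, ds2$x)[, "B"]
  expect_equal(unname(p_sm), unname(p_glm), tolerance = 5e-3)
})

test_that("softmax separates a separable set and its objective trace decreases", {
  ds <- separable_dataset(10, seed = 5)
  m <- softmax_fit(ds$x, ds$y, l2 = 1e-3)
  pred <- colnames(softmax_predict_proba(m, ds$x))[
    apply(softmax_predict_proba(m, ds$x), 1, which.max)]
  expect_equal(mean(pred == as.character(ds$y)), 1)
  expect_true(all(is.finite(m$theta)))
  expect_true(all(diff(m$trace) <= 1e-10)) # non-increasing objective
})

test_that("svm decision values are antisymmetric and sign-consistent", {
  ds <- separable_dataset(10, K = 2, seed = 6)
  m <- svm_fit(ds$x, ds$y)
  f <- svm_decision_values(m, ds$x)
  expect_equal(f[, "A", "B"], -f[, "B", "A"])
  expect_equal(unname(f[, "A", "A"]), rep(0, 20))
  pred <- clf_predict(m, ds$x)
  expect_equal(as.character(pred), unname(ifelse(f[, "A", "B"] > 0, "A", "B")))
})

test_that("Platt sigmoid fitting recovers symmetry, intercept and flatness", {
  # balanced, symmetric decision values -> B ~ 0
  f <- c(-3, -2, -1, -0.5, 0.5, 1, 2, 3)
  tgt <- f > 0
  ab <- platt_fit_sigmoid(f, tgt)
  expect_lt(abs(ab["B"]), 1e-6)
  expect_equal(unname(platt_sigmoid(0, ab)), 1 / (1 + exp(ab[["B"]])))

  # labels independent of f -> flat sigmoid near the class prior
  set.seed(8)
  f2 <- rnorm(400)
  tgt2 <- rep(c(TRUE, FALSE), c(120, 280)) # prior 0.3, shuffled against f
  tgt2 <- sample(tgt2)
  ab2 <- platt_fit_sigmoid(f2, tgt2)
  expect_lt(abs(ab2["A"]), 0.2)
  expect_equal(unname(platt_sigmoid(0, ab2)), 0.3, tolerance = 0.05)

  expect_error(platt_fit_sigmoid(f, rep(TRUE, 8)), "both pair classes")
})

test_that("Platt sigmoid matches an independent optimizer of the same likelihood", {
  set.seed(13)
  f <- rnorm(200)
  tgt <- runif(200) < plogis(-2 * f + 0.4)
  ab <- platt_fit_sigmoid(f, tgt)
  n1 <- sum(tgt)
  n0 <- sum(!tgt)
  t <- ifelse(tgt, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  nll <- function(par) {
    z <- par[1] * f + par[2]
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  ref <- optim(c(0, 0), nll, method = "BFGS")$par
  expect_equal(unname(ab), ref, tolerance = 1e-4)
})

test_that("pairwise coupling solves the simplex least-squares problem", {
  # symmetric input -> uniform output
  r <- matrix(0.5, 3, 3)
  expect_equal(unname(pairwise_couple(r)), rep(1 / 3, 3))

  # K = 2: the minimizer is (r12, r21) exactly
  r2 <- matrix(c(0.5, 0.2, 0.8, 0.5), 2, 2)
  expect_equal(unname(pairwise_couple(r2)), c(0.8, 0.2), tolerance = 1e-6)

  # consistency: r built from a known p is recovered
  p0 <- c(0.55, 0.3, 0.15)
  r3 <- outer(p0, p0, function(a, b) a / (a + b))
  expect_equal(unname(pairwise_couple(r3)), p0, tolerance = 1e-6)

  expect_error(pairwise_couple(matrix(c(0.5, 0.9, 0.9, 0.5), 2, 2)), "equal 1")
})

test_that("coupling matches a brute-force grid search of the objective", {
  objective <- function(p, r) {
    K <- length(p)
    s <- 0
    for (i in 1:K) for (j in (1:K)[-i]) s <- s + (r[j, i] * p[i] - r[i, j] * p[j])^2
    s / 2
  }
  set.seed(21)
  for (case in 1:5) {
    r <- matrix(0.5, 3, 3)
    for (i in 1:2) for (j in (i + 1):3) {
      r[i, j] <- runif(1, 0.05, 0.95)
      r[j, i] <- 1 - r[i, j]
    }
    # grid over the simplex, step 1e-3
    step <- 1e-3
    g1 <- seq(0, 1, by = step)
    best <- c(1, 0, 0)
    best_val <- Inf
    for (p1 in g1) {
      p2 <- seq(0, 1 - p1, by = step)
      p3 <- 1 - p1 - p2
      vals <- (r[2, 1] * p1 - r[1, 2] * p2)^2 + (r[3, 1] * p1 - r[1, 3] * p3)^2 +
        (r[1, 2] * p2 - r[2, 1] * p1)^2 + (r[3, 2] * p2 - r[2, 3] * p3)^2 +
        (r[1, 3] * p3 - r[3, 1] * p1)^2 + (r[2, 3] * p3 - r[3, 2] * p2)^2
      jm <- which.min(vals)
      if (vals[jm] / 2 < best_val) {
        best_val <- vals[jm] / 2
        best <- c(p1, p2[jm], p3[jm])
      }
    }
    sol <- pairwise_couple(r)
    expect_equal(unname(sol), best, tolerance = 2e-3)
    expect_lte(objective(sol, r), best_val + 1e-9)
  }
})

test_that("SVM grid tuning returns the best point with deterministic ties", {
  ds <- separable_dataset(10, K = 2, seed = 14)
  one <- tune_svm(ds$x, ds$y, cost_grid = 4, gamma_grid = 0.5, folds = 5, seed = 1)
  expect_equal(one$cost, 4)
  expect_equal(one$gamma, 0.5)

  # a gamma so large the RBF kernel memorizes nothing vs a sane one
  two <- tune_svm(ds$x, ds$y, cost_grid = 4, gamma_grid = c(0.5, 1e6),
                  folds = 5, seed = 1)
  expect_equal(two$gamma, 0.5)
  expect_gt(max(two$grid$accuracy), min(two$grid$accuracy))

  # same seed -> identical selection
  a <- tune_svm(ds$x, ds$y, cost_grid = c(4, 16), gamma_grid = c(0.1, 0.5),
                folds = 3, seed = 7)
  b <- tune_svm(ds$x, ds$y, cost_grid = c(4, 16), gamma_grid = c(0.1, 0.5),
                folds = 3, seed = 7)
  expect_identical(a[c("cost", "gamma", "cv_accuracy")],
                   b[c("cost", "gamma", "cv_accuracy")])

  idx <- c(1:3, 11:13) # three per class, fewer than the fold count
  expect_error(tune_svm(ds$x[idx, ], ds$y[idx], folds = 5), "per class")
})
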