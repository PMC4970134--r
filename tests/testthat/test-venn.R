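worked_matrix <- matrix(
  c(0.11, 0.78, 0.11,
    0.00, 0.91, 0.09,
    0.10, 0.70, 0.20),
  nrow = 3, byrow = TRUE, dimnames = list(c("A", "B", "C"), c("A", "B", "C"))
)

test_that("column selection picks the highest-quality column", {
  sel <- select_from_matrix(worked_matrix)
  expect_equal(sel$label, "B")
  expect_equal(sel$p_lower, 0.70)
  expect_equal(sel$p_upper, 0.91)
  expect_equal(sel$quality, 0.70)

  # uniform matrix: tie on quality 1/K -> first label, degenerate interval
  u <- matrix(1 / 3, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  sel_u <- select_from_matrix(u)
  expect_equal(sel_u$label, "A")
  expect_equal(c(sel_u$p_lower, sel_u$p_upper), c(1 / 3, 1 / 3))

  # identity matrix: all qualities 0, tie-break to the first label
  sel_i <- select_from_matrix(diag(3))
  expect_equal(sel_i$index, 1L)
  expect_equal(c(sel_i$p_lower, sel_i$p_upper), c(0, 1))

  # 2x2 case checked by enumerating both columns by hand
  p2 <- matrix(c(0.9, 0.1, 0.8, 0.2), 2, byrow = TRUE,
               dimnames = list(c("x", "y"), c("x", "y")))
  sel_2 <- select_from_matrix(p2)
  expect_equal(sel_2$label, "x")
  expect_equal(c(sel_2$p_lower, sel_2$p_upper), c(0.8, 0.9))

  # a column of ones (others zero) is certain
  c1 <- matrix(c(0, 1, 0, 0, 1, 0, 0, 1, 0), 3, byrow = TRUE)
  sel_c <- select_from_matrix(c1)
  expect_equal(sel_c$index, 2L)
  expect_equal(c(sel_c$p_lower, sel_c$p_upper), c(1, 1))

  expect_error(select_from_matrix(matrix(0.4, 2, 2)), "sum to 1")
  expect_error(select_from_matrix(matrix(c(1.2, -0.2, 0, 1), 2, byrow = TRUE)),
               "\\[0, 1\\]")
})

test_that("empirical category distributions are label frequencies", {
  cats <- factor(rep("t1", 10))
  labs <- factor(c(rep("A", 2), rep("B", 7), "C"), levels = c("A", "B", "C"))
  expect_equal(unname(empirical_distribution(cats, labs)), c(0.2, 0.7, 0.1))

  # singleton category containing only the hypothesized example
  cats2 <- factor(c("a", "a", "b"))
  labs2 <- factor(c("A", "A", "B"), levels = c("A", "B"))
  expect_equal(unname(empirical_distribution(cats2, labs2)), c(0, 1))

  # all labels equal -> a single 1
  labs3 <- factor(rep("A", 5), levels = c("A", "B"))
  expect_equal(unname(empirical_distribution(factor(rep("t", 5)), labs3)), c(1, 0))
})

test_that("taxonomy categories behave on degenerate and separable sets", {
  # identical copies of one example, one label -> one shared category
  x <- matrix(1, 5, 2)
  y <- factor(rep("A", 5), levels = c("A", "B"))
  cats <- assign_categories(x, y, classifier_spec("nb"), mode = "loo")
  expect_equal(length(unique(cats)), 1L)

  # n = K, one well-separated example per class (inductive taxonomy):
  # every example is categorized as its own label
  x3 <- matrix(c(0, 0, 100, 0, 0, 100), 3, 2, byrow = TRUE)
  y3 <- factor(c("A", "B", "C"))
  cats3 <- assign_categories(x3, y3, classifier_spec("nb"), mode = "induct")
  expect_equal(as.character(cats3), c("A", "B", "C"))

  # the augmented set of the worked setting yields one category per example
  ds <- overlap_dataset(10, seed = 3)
  xa <- rbind(ds$x, colMeans(ds$x))
  ya <- factor(c(as.character(ds$y), "A"), levels = levels(ds$y))
  expect_length(assign_categories(xa, ya, classifier_spec("nb"), "loo"), 31L)
})

test_that("venn predictions have valid row-stochastic matrices and intervals", {
  set.seed(30)
  for (rep_i in 1:8) {
    ds <- overlap_dataset(sample(4:8, 1), K = sample(2:3, 1), seed = rep_i)
    vp <- venn_predict(ds, rnorm(2), classifier_spec("nb"),
                       mode = sample(c("loo", "induct"), 1))
    expect_equal(unname(rowSums(vp$matrix)), rep(1, nlevels(ds$y)), tolerance = 1e-9)
    expect_true(all(vp$matrix >= 0 & vp$matrix <= 1))
    expect_true(vp$p_lower >= 0 && vp$p_lower <= vp$p_upper && vp$p_upper <= 1)
    expect_true(vp$label %in% levels(ds$y))
  }
})

test_that("venn prediction is invariant to training-set row order", {
  ds <- overlap_dataset(8, seed = 17)
  xnew <- c(0.5, -0.2)
  vp1 <- venn_predict(ds, xnew, classifier_spec("nb"), mode = "loo")
  set.seed(99)
  perm <- sample(nrow(ds$x))
  vp2 <- venn_predict(subset_dataset(ds, perm), xnew, classifier_spec("nb"),
                      mode = "loo")
  expect_equal(vp1$label, vp2$label)
  expect_equal(vp1$matrix, vp2$matrix)
})

test_that("venn machine agrees exactly with the brute-force construction", {
  set.seed(55)
  for (rep_i in 1:10) {
    K <- sample(2:3, 1)
    n <- sample(6:12, 1)
    ds <- generate_feature_table(
      rep(ceiling(n / K), K)[1:K], default_class_means(K, 2, radius = 3),
      seed = 1000 + rep_i
    )
    xnew <- rnorm(2)
    mine <- venn_predict(ds, xnew, classifier_spec("nb"), mode = "loo")
    ref <- oracle_venn_loo(ds$x, ds$y, xnew,
                           fit_fun = nb_fit,
                           predict_fun = function(m, x) clf_predict(m, x))
    expect_identical(mine$label, ref$label)
    expect_identical(unname(mine$matrix), unname(ref$matrix))
    expect_identical(c(mine$p_lower, mine$p_upper), c(ref$p_lower, ref$p_upper))
  }
})

test_that("venn validity holds on a small online run", {
  ds <- overlap_dataset(50, seed = 41)
  run <- online_run(ds, predictor_spec("vm-nb", venn_mode = "induct"), seed = 41)
  r <- run$records
  n_steps <- seq_len(nrow(r))
  expect_true(all(r$cum_correct >= r$cum_p_lower - 3 * sqrt(n_steps)))
  expect_true(all(r$cum_correct <= r$cum_p_upper + 3 * sqrt(n_steps)))
})
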