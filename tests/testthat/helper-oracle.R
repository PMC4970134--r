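# Brute-force reimplementation of the Venn multiprobability construction,
# written with explicit loops and no code shared with the package's
# venn_predict()/assign_categories()/select_from_matrix() path. The
# underlying classifier is passed in as opaque fit/predict functions (the
# contract boundary); everything above it — augmentation, leave-one-out
# category assignment, category frequency rows, column selection and
# tie-breaking — is redone from scratch here.
oracle_venn_loo <- function(x, y, xnew, fit_fun, predict_fun) {
  lv <- levels(y)
  K <- length(lv)
  n <- nrow(x) + 1L
  P <- matrix(NA_real_, K, K, dimnames = list(lv, lv))
  for (ki in seq_len(K)) {
    xa <- rbind(x, matrix(xnew, nrow = 1))
    ya <- c(as.character(y), lv[ki])
    cats <- character(n)
    for (i in seq_len(n)) {
      model <- fit_fun(xa[-i, , drop = FALSE], factor(ya[-i], levels = lv))
      cats[i] <- as.character(predict_fun(model, xa[i, , drop = FALSE]))
    }
    tau <- which(cats == cats[n])
    for (kj in seq_len(K)) {
      P[ki, kj] <- sum(ya[tau] == lv[kj]) / length(tau)
    }
  }
  best_j <- 1L
  best_q <- min(P[, 1L])
  if (K >= 2L) {
    for (j in 2:K) {
      qj <- min(P[, j])
      if (qj > best_q) {
        best_j <- j
        best_q <- qj
      }
    }
  }
  list(label = lv[best_j], p_lower = min(P[, best_j]), p_upper = max(P[, best_j]),
       matrix = P)
}
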