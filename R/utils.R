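# Internal helpers shared across the package.

# Signal a user-input error with a condition class the CLI maps to exit code 1.
stop_input <- function(msg, ...) {
  if (length(list(...)) > 0L) msg <- sprintf(msg, ...)
  stop(errorCondition(msg, class = c("vennmachine_input_error", "vennmachine_error")))
}

# sample() with the surprising length-1 behaviour removed
resample <- function(x, k) x[sample.int(length(x), k)]

# Row-wise maxima without apply(); matters inside optimizer loops.
row_max <- function(m) {
  out <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) out <- pmax(out, m[, j])
  out
}

# Row-wise softmax of a matrix of log-weights, numerically stable.
row_softmax <- function(ll) {
  w <- exp(ll - row_max(ll))
  w / rowSums(w)
}

# which.max with the documented first-index tie-break, named for intent.
argmax_first <- function(v) which.max(v)

# Serialize doubles so that write-then-read round-trips exactly.
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  out
}

# Stratified fold assignment; every class is shuffled independently and dealt
# round-robin so each fold sees each class (requires >= nfolds per class).
stratified_folds <- function(y, nfolds, seed = 1L) {
  y <- as.factor(y)
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (lev in levels(droplevels(y))) {
      idx <- which(y == lev)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(nfolds), length(idx))
    }
  })
  fold
}
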