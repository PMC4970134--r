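# Calibration diagnostics. A probabilistic predictor is valid when its
# stated probabilities match the frequencies with which it is right. Point
# predictors are scored directly; interval (multiprobability) predictors are
# first collapsed to the minimax point inside the interval for the loss at
# hand, and their cumulative bounds are compared with the cumulative count
# of correct predictions.

#' Log loss of a point probability
#'
#' `-log p` when the prediction was correct, `-log(1 - p)` otherwise.
#' Degenerate certainty on the wrong side yields `+Inf`, which is
#' propagated, not clipped: an average that blows up is exactly the signal
#' this loss is meant to give.
#'
#' @param p probability claimed for the predicted label, in \[0, 1\].
#' @param q 1 if the prediction was correct, 0 otherwise.
#' @export
log_loss <- function(p, q) {
  stopifnot(all(p >= 0 & p <= 1), all(q %in% c(0, 1)))
  ifelse(q == 1, -log(p), -log1p(-p))
}

#' Square loss of a point probability
#'
#' @inheritParams log_loss
#' @export
square_loss <- function(p, q) {
  stopifnot(all(p >= 0 & p <= 1), all(q %in% c(0, 1)))
  (p - q)^2
}

#' Minimax point probability of an interval, log loss
#'
#' The single probability whose worst-case log-loss regret over
#' `[p_l, p_u]` is smallest: `p = p_u / (1 - p_l + p_u)`. Always lies inside
#' the interval.
#'
#' @param p_lower,p_upper interval bounds, `0 <= p_lower <= p_upper <= 1`
#'   (vectorized).
#' @export
minimax_log <- function(p_lower, p_upper) {
  check_interval(p_lower, p_upper)
  p_upper / (1 - p_lower + p_upper)
}

#' Minimax point probability of an interval, square loss
#'
#' `p = p_u + p_l^2/2 - p_u^2/2`; always lies inside `[p_l, p_u]`.
#'
#' @inheritParams minimax_log
#' @export
minimax_square <- function(p_lower, p_upper) {
  check_interval(p_lower, p_upper)
  p_upper + p_lower^2 / 2 - p_upper^2 / 2
}

check_interval <- function(p_lower, p_upper) {
  if (any(p_lower < 0 | p_upper > 1 | p_lower > p_upper)) {
    stop_input("need 0 <= p_lower <= p_upper <= 1")
  }
  invisible(NULL)
}

# Coerce prediction records (data frame with p_lower, p_upper, correct)
check_records <- function(records) {
  need <- c("p_lower", "p_upper", "correct")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop_input("records must be a data frame with columns %s", paste(need, collapse = ", "))
  }
  if (nrow(records) == 0L) stop_input("no prediction records")
  records
}

#' Mean log and root-mean-square losses of a prediction sequence
#'
#' Interval records are converted per loss with the matching minimax rule
#' ([minimax_log()] feeds the mean log loss, [minimax_square()] feeds the
#' root mean square loss); point records (`p_lower == p_upper`) pass
#' through unchanged. A single infinite log loss makes `d_ln` infinite.
#'
#' @param records data frame with columns `p_lower`, `p_upper`, `correct`.
#' @return List with `d_ln` (mean log loss) and `d_sq` (root mean square
#'   loss).
#' @export
mean_losses <- function(records) {
  records <- check_records(records)
  q <- as.integer(records$correct)
  list(
    d_ln = mean(log_loss(minimax_log(records$p_lower, records$p_upper), q)),
    d_sq = sqrt(mean(square_loss(minimax_square(records$p_lower, records$p_upper), q)))
  )
}

#' Cumulative probability bounds versus cumulative correct predictions
#'
#' Tracks, in test order, the cumulative count of correct predictions `CN`
#' and the cumulative lower/upper probability bounds, and summarizes the
#' final deviation: `d11 = |CN/N - sum(P_l)/N|`, `d12 = |CN/N - sum(P_u)/N|`
#' and `d1 = max(d11, d12)`. For point predictors the two bounds coincide
#' and `d1` reduces to the absolute difference between mean claimed
#' probability and empirical accuracy.
#'
#' @inheritParams mean_losses
#' @return List with the `series` data frame (`step`, `cum_correct`,
#'   `cum_p_lower`, `cum_p_upper`) and `d11`, `d12`, `d1`.
#' @export
cumulative_validity <- function(records) {
  records <- check_records(records)
  q <- as.integer(records$correct)
  n <- length(q)
  cn <- cumsum(q)
  cpl <- cumsum(records$p_lower)
  cpu <- cumsum(records$p_upper)
  d11 <- abs(cn[n] / n - cpl[n] / n)
  d12 <- abs(cn[n] / n - cpu[n] / n)
  list(
    series = data.frame(step = seq_len(n), cum_correct = cn,
                        cum_p_lower = cpl, cum_p_upper = cpu),
    d11 = d11, d12 = d12, d1 = max(d11, d12)
  )
}

#' Full validity report of a prediction sequence
#'
#' Combines [mean_losses()] and [cumulative_validity()] into one object.
#'
#' @inheritParams mean_losses
#' @return An object of class `validity_report` with elements `d_ln`,
#'   `d_sq`, `d1`, `d11`, `d12`, `n` and the cumulative `series`.
#' @export
validity_report <- function(records) {
  records <- check_records(records)
  losses <- mean_losses(records)
  cum <- cumulative_validity(records)
  structure(
    list(d_ln = losses$d_ln, d_sq = losses$d_sq, d1 = cum$d1,
         d11 = cum$d11, d12 = cum$d12, n = nrow(records),
         series = cum$series,
         interval = any(records$p_upper > records$p_lower)),
    class = "validity_report"
  )
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf(
    "<validity_report> n = %d (%s predictor)\n  d_ln = %s   d_sq = %.4f   d1 = %.4f (d11 = %.4f, d12 = %.4f)\n",
    x$n, if (x$interval) "interval" else "point",
    if (is.finite(x$d_ln)) sprintf("%.4f", x$d_ln) else "Inf",
    x$d_sq, x$d1, x$d11, x$d12
  ))
  invisible(x)
}

#' Plot cumulative correct predictions against cumulative bounds
#'
#' @param report a [validity_report()] (or any object with its `series`).
#' @param ... passed to [graphics::matplot()].
#' @export
plot_validity <- function(report, ...) {
  s <- report$series
  graphics::matplot(
    s$step, cbind(s$cum_correct, s$cum_p_lower, s$cum_p_upper),
    type = "l", lty = c(1, 2, 2), col = c("black", "grey40", "grey40"),
    xlab = "test examples", ylab = "cumulative value", ...
  )
  graphics::legend("topleft", c("correct predictions", "probability bounds"),
                   lty = c(1, 2), col = c("black", "grey40"), bty = "n")
  invisible(report)
}
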