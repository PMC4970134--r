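# Feature extraction for metal-oxide sensor transients: per sensor, two
# steady-state features (peak magnitude, curve integral) and six transient
# features (min/max of the exponentially smoothed derivative at three
# smoothing factors tied to the sampling rate).

#' Maximal absolute response of one calibrated sensor trace
#'
#' @param v numeric vector, calibrated signal of a single sensor.
#' @return `max(|v|)`.
#' @export
feature_vmax <- function(v) {
  if (length(v) < 1L) stop_input("empty signal")
  max(abs(v))
}

#' Area under one calibrated sensor trace
#'
#' Trapezoidal approximation of the integral of `v` over the full measurement
#' time, with a uniform time step `dt` seconds.
#'
#' @param v numeric vector, calibrated signal of a single sensor.
#' @param dt time step in seconds (> 0).
#' @export
feature_vint <- function(v, dt) {
  if (length(v) < 1L) stop_input("empty signal")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop_input("dt must be positive")
  if (length(v) == 1L) return(0)
  pracma::trapz(seq(0, by = dt, length.out = length(v)), v)
}

#' Exponential-moving-average derivative features
#'
#' Smoothed first-derivative transient features. For each smoothing factor
#' `a` in `1/(100*SR), 1/(10*SR), 1/SR` (`SR` = sampling rate in Hz) the
#' recursion
#' \deqn{y(1) = a V(1), \quad y(k) = (1-a) y(k-1) + a (V(k)-V(k-1))}
#' is run over the calibrated trace and its minimum and maximum are kept, so
#' each sensor contributes six transient features. The three factors probe
#' slow, medium and fast dynamics of the response onset and recovery.
#'
#' @param v numeric vector with at least 2 points.
#' @param sampling_rate samples per second; must be >= 1 Hz so that all
#'   smoothing factors stay in (0, 1].
#' @return Named numeric vector of length 6, ordered
#'   `(min, max)` for `a = 1/(100 SR)`, then `1/(10 SR)`, then `1/SR`.
#' @export
ema_derivative_features <- function(v, sampling_rate) {
  if (length(v) < 2L) stop_input("need at least 2 points for derivative features")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0) {
    stop_input("sampling_rate must be a single positive number")
  }
  a_all <- c(1 / (100 * sampling_rate), 1 / (10 * sampling_rate), 1 / sampling_rate)
  if (any(a_all > 1)) {
    stop_input("sampling_rate below 1 Hz would give a smoothing factor above 1")
  }
  d <- c(v[1L], diff(v)) # so that y(1) = a * V(1)
  out <- numeric(0)
  for (a in a_all) {
    y <- stats::filter(a * d, filter = 1 - a, method = "recursive")
    out <- c(out, min(y), max(y))
  }
  names(out) <- as.vector(t(outer(
    c("ema_a100", "ema_a10", "ema_a1"), c("min", "max"), paste, sep = "_"
  )))
  out
}

#' Extract the per-sensor feature vector of a recording
#'
#' Calibrates the recording (baseline subtraction) and concatenates, for each
#' sensor in column order: the maximal absolute response, the area under the
#' response curve, and the six exponential-moving-average derivative
#' features. A 16-sensor array therefore yields 16 x 8 = 128 features. Names
#' are `"<sensor>_<feature>"` and are byte-stable across runs.
#'
#' @param recording a [sensor_recording()].
#' @return Named numeric vector of length `n_sensors * 8`.
#' @export
extract_features <- function(recording) {
  v <- calibrate(recording)
  sr <- recording$sampling_rate
  dt <- 1 / sr
  per_sensor <- lapply(seq_len(ncol(v)), function(j) {
    vj <- v[, j]
    c(vmax = feature_vmax(vj), vint = feature_vint(vj, dt),
      ema_derivative_features(vj, sr))
  })
  out <- unlist(per_sensor, use.names = FALSE)
  names(out) <- as.vector(vapply(
    seq_len(ncol(v)),
    function(j) paste(colnames(v)[j], names(per_sensor[[j]]), sep = "_"),
    character(8L)
  ))
  out
}

#' Turn a list of recordings into a feature table
#'
#' @param recordings list of [sensor_recording()] objects with identical
#'   sensor layouts.
#' @return A [labeled_dataset()] when every recording carries a label,
#'   otherwise a bare feature matrix (rows named by `sample_id`).
#' @export
extract_feature_table <- function(recordings) {
  if (length(recordings) == 0L) stop_input("no recordings given")
  feats <- t(vapply(recordings, extract_features,
                    numeric(ncol(recordings[[1L]]$readings) * 8L)))
  rownames(feats) <- vapply(recordings, function(r) r$sample_id, character(1L))
  labels <- lapply(recordings, function(r) r$label)
  if (any(vapply(labels, is.null, logical(1L)))) return(feats)
  labeled_dataset(feats, unlist(labels))
}

#' Min-max feature scaling learned on training data
#'
#' `fit_scaler()` records the per-feature minimum and maximum over the
#' training rows; `apply_scaler()` maps each feature to
#' `(x - min) / (max - min)`. Training values land exactly in \[0, 1\];
#' values outside the training range (test data) are clipped to \[0, 1\];
#' constant training columns map to 0. Fitting on the training portion only
#' and freezing the ranges avoids test-set leakage.
#'
#' @param x numeric feature matrix or [labeled_dataset()].
#' @return `fit_scaler()`: an object of class `feature_scaler`;
#'   `apply_scaler()`: the scaled features, same container as the input.
#' @export
fit_scaler <- function(x) {
  if (inherits(x, "labeled_dataset")) x <- x$x
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop_input("scaler needs at least one training row")
  structure(
    list(min = apply(x, 2L, min), max = apply(x, 2L, max)),
    class = "feature_scaler"
  )
}

#' @rdname fit_scaler
#' @param scaler a fitted `feature_scaler`.
#' @export
apply_scaler <- function(x, scaler) {
  stopifnot(inherits(scaler, "feature_scaler"))
  if (inherits(x, "labeled_dataset")) {
    return(labeled_dataset(apply_scaler(x$x, scaler), x$y, labels = levels(x$y)))
  }
  one_row <- is.null(dim(x))
  x <- if (one_row) matrix(x, nrow = 1L, dimnames = list(NULL, names(x))) else as.matrix(x)
  if (ncol(x) != length(scaler$min)) {
    stop_input("scaler was fitted on %d features, data has %d", length(scaler$min), ncol(x))
  }
  rng <- scaler$max - scaler$min
  out <- sweep(x, 2L, scaler$min)
  out <- sweep(out, 2L, ifelse(rng > 0, rng, 1), "/")
  out[, rng == 0] <- 0
  out <- pmin(pmax(out, 0), 1)
  if (one_row) out[1L, ] else out
}
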