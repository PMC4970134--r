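#' Raw sensor-array recording
#'
#' One electronic-nose measurement: a matrix of voltage readings, one row per
#' time step and one column per gas sensor, sampled uniformly. The baseline
#' window indexes the pre-injection segment used to estimate each sensor's
#' baseline voltage; by default it covers the first 20 s of the trace, the
#' usual clean-carrier-gas settling period before the sample gas is injected.
#'
#' @param readings numeric matrix, time steps x sensors, in volts.
#' @param sampling_rate samples per second (> 0).
#' @param baseline_window integer indices of the rows used to estimate the
#'   baseline; default: all rows within the first 20 s.
#' @param sample_id identifier carried through feature extraction.
#' @param label optional class label.
#' @return An object of class `sensor_recording`.
#' @export
sensor_recording <- function(readings, sampling_rate, baseline_window = NULL,
                             sample_id = "sample", label = NULL) {
  readings <- as.matrix(readings)
  storage.mode(readings) <- "double"
  if (nrow(readings) < 2L || ncol(readings) < 1L) {
    stop_input("a recording needs at least 2 time steps and 1 sensor")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0) {
    stop_input("sampling_rate must be a single positive number")
  }
  if (is.null(baseline_window)) {
    baseline_window <- seq_len(max(1L, min(nrow(readings), floor(20 * sampling_rate))))
  }
  baseline_window <- as.integer(baseline_window)
  if (length(baseline_window) == 0L || anyNA(baseline_window) ||
      any(baseline_window < 1L) || any(baseline_window > nrow(readings))) {
    stop_input("baseline_window must be a nonempty set of valid row indices")
  }
  if (is.null(colnames(readings))) {
    colnames(readings) <- paste0("sensor_", seq_len(ncol(readings)))
  }
  structure(
    list(
      readings = readings, sampling_rate = sampling_rate,
      baseline_window = baseline_window, sample_id = as.character(sample_id),
      label = if (is.null(label)) NULL else as.character(label)
    ),
    class = "sensor_recording"
  )
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf(
    "<sensor_recording> '%s'%s: %d steps x %d sensors @ %g Hz (%.1f s), baseline %d steps\n",
    x$sample_id,
    if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
    nrow(x$readings), ncol(x$readings), x$sampling_rate,
    nrow(x$readings) / x$sampling_rate, length(x$baseline_window)
  ))
  invisible(x)
}

#' Baseline-correct a recording
#'
#' Subtracts each sensor's baseline voltage from its raw trace,
#' `V = V_s - V_o`, where `V_o` is the per-sensor mean over the recording's
#' baseline window. All downstream features are computed on the calibrated
#' signal, which makes them invariant to constant per-sensor offsets.
#'
#' @param recording a [sensor_recording()].
#' @return Numeric matrix of calibrated voltages, same shape as the readings.
#' @export
calibrate <- function(recording) {
  stopifnot(inherits(recording, "sensor_recording"))
  v0 <- colMeans(recording$readings[recording$baseline_window, , drop = FALSE])
  sweep(recording$readings, 2L, v0)
}
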