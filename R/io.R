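# CSV interchange. Recordings: one file per measurement with a leading
# `time` column (seconds, uniform) and one column per sensor. Feature
# tables: one row per sample, feature columns plus a trailing `label`
# column. All floats are written with 17 significant digits so a
# write-then-read round trip reproduces the doubles exactly.

write_csv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Read / write a sensor recording CSV
#'
#' The file must have a strictly increasing, uniformly spaced `time` first
#' column (seconds) and at least one sensor column; malformed files raise
#' errors naming the offending line.
#'
#' @param path file path.
#' @param baseline_s length of the pre-injection baseline window in seconds
#'   (default 20): rows with `time < time[1] + baseline_s`.
#' @param sample_id,label passed to [sensor_recording()]; `sample_id`
#'   defaults to the file name.
#' @return A [sensor_recording()].
#' @export
read_recording_csv <- function(path, baseline_s = 20, sample_id = NULL, label = NULL) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L || names(df)[1L] != "time") {
    stop_input("%s: header must be 'time,<sensor_1>,...' (line 1)", path)
  }
  if (any(!vapply(df, is.numeric, logical(1L)))) {
    bad <- names(df)[!vapply(df, is.numeric, logical(1L))][1L]
    stop_input("%s: column '%s' is not numeric", path, bad)
  }
  tm <- df$time
  dt <- diff(tm)
  if (any(dt <= 0)) {
    stop_input("%s: time not strictly increasing at line %d",
               path, which(dt <= 0)[1L] + 2L)
  }
  if (any(abs(dt - dt[1L]) > 1e-6 * dt[1L])) {
    stop_input("%s: time not uniformly spaced at line %d",
               path, which(abs(dt - dt[1L]) > 1e-6 * dt[1L])[1L] + 2L)
  }
  sr <- 1 / dt[1L]
  readings <- as.matrix(df[, -1L, drop = FALSE])
  bw <- which(tm < tm[1L] + baseline_s)
  sensor_recording(readings, sampling_rate = sr, baseline_window = bw,
                   sample_id = sample_id %||% basename(path), label = label)
}

#' @rdname read_recording_csv
#' @param recording a [sensor_recording()].
#' @export
write_recording_csv <- function(recording, path) {
  stopifnot(inherits(recording, "sensor_recording"))
  t <- (seq_len(nrow(recording$readings)) - 1L) / recording$sampling_rate
  df <- data.frame(time = t, recording$readings, check.names = FALSE)
  write_csv_exact(df, path)
  invisible(path)
}

#' Read / write a feature table CSV
#'
#' Feature columns plus a `label` column (required unless
#' `require_label = FALSE`).
#'
#' @param path file path.
#' @param require_label error when the `label` column is missing.
#' @return A [labeled_dataset()] (or a bare matrix when labels are absent
#'   and not required).
#' @export
read_feature_table <- function(path, require_label = TRUE) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df)) {
    if (require_label) stop_input("%s: feature table is missing a 'label' column", path)
    return(as.matrix(df))
  }
  y <- as.character(df$label)
  x <- df[, setdiff(names(df), "label"), drop = FALSE]
  bad <- !vapply(x, is.numeric, logical(1L))
  if (any(bad)) stop_input("%s: non-numeric feature column '%s'", path, names(x)[bad][1L])
  labeled_dataset(as.matrix(x), y)
}

#' @rdname read_feature_table
#' @param dataset a [labeled_dataset()].
#' @export
write_feature_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  write_csv_exact(as.data.frame(dataset), path)
  invisible(path)
}

#' Read / write prediction records
#'
#' @param records prediction records data frame (from [offline_loo()] or
#'   [online_run()]).
#' @param path file path.
#' @export
write_predictions <- function(records, path) {
  write_csv_exact(records, path)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("p_lower", "p_upper", "correct")
  if (!all(need %in% names(df))) {
    stop_input("%s: prediction file needs columns %s", path, paste(need, collapse = ", "))
  }
  df$correct <- as.logical(df$correct)
  df
}
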