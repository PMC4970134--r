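# Synthetic data: (i) Gaussian-mixture feature tables for fast statistical
# tests of the predictors, and (ii) raw sensor-array recordings with the
# baseline / response / recovery phase structure of a metal-oxide E-nose
# measurement, for end-to-end pipeline tests. Both draw i.i.d. within class
# from a fixed seed — exchangeability by construction, which is exactly the
# assumption under which the Venn validity guarantee is stated.

#' Equally separated class means
#'
#' Convenience layout for Gaussian-mixture fixtures: for 2-d features the
#' class means sit on a circle of the given radius; for higher dimensions
#' each class mean is `radius` along its own axis (requires `K <= dims`).
#'
#' @param n_classes number of classes K.
#' @param dims feature dimension.
#' @param radius distance of each mean from the origin, in units of the
#'   (unit) noise standard deviation.
#' @return `K x dims` matrix of class means.
#' @export
default_class_means <- function(n_classes, dims = 2L, radius = 2) {
  if (dims == 2L) {
    ang <- 2 * pi * (seq_len(n_classes) - 1L) / n_classes
    cbind(radius * cos(ang), radius * sin(ang))
  } else {
    if (n_classes > dims) stop_input("need dims >= n_classes for the axis layout")
    radius * diag(1, n_classes, dims)
  }
}

#' Generate a Gaussian-mixture feature table
#'
#' Class-conditional Gaussian features with common noise scale: class k's
#' samples are `mean_k + noise`. With `correlation = 0` the noise is
#' spherical — the model Gaussian naive Bayes assumes. A positive
#' `correlation` adds an equicorrelated component shared across features,
#' which deliberately violates the per-feature independence assumption while
#' leaving each marginal Gaussian; it is the package's misspecification
#' knob for calibration experiments.
#'
#' @param n_per_class samples per class (scalar or length-K vector).
#' @param class_means `K x dims` matrix of class means (one row per class).
#' @param noise_sd noise standard deviation (default 1).
#' @param correlation equicorrelation of the noise across features, in
#'   \[0, 1) (default 0 = independent).
#' @param labels class labels (default `"A"`, `"B"`, ...).
#' @param seed RNG seed; the generator is deterministic given it.
#' @return A [labeled_dataset()].
#' @export
generate_feature_table <- function(n_per_class, class_means, noise_sd = 1,
                                   correlation = 0, labels = NULL, seed = 1L) {
  class_means <- as.matrix(class_means)
  k <- nrow(class_means)
  d <- ncol(class_means)
  if (length(n_per_class) == 1L) n_per_class <- rep(n_per_class, k)
  if (length(n_per_class) != k) stop_input("n_per_class must have one entry per class")
  if (any(n_per_class < 1L)) stop_input("n_per_class must be positive")
  if (correlation < 0 || correlation >= 1) stop_input("correlation must lie in [0, 1)")
  if (is.null(labels)) labels <- LETTERS[seq_len(k)]
  withr::with_seed(seed, {
    xs <- vector("list", k)
    for (ki in seq_len(k)) {
      n <- n_per_class[ki]
      noise <- matrix(rnorm(n * d), n, d)
      if (correlation > 0) {
        shared <- rnorm(n)
        noise <- sqrt(correlation) * shared + sqrt(1 - correlation) * noise
      }
      xs[[ki]] <- sweep(noise_sd * noise, 2L, class_means[ki, ], "+")
    }
  })
  x <- do.call(rbind, xs)
  y <- rep(labels, n_per_class)
  rownames(x) <- paste0(y, "_", unlist(lapply(n_per_class, seq_len)))
  labeled_dataset(x, y, labels = labels)
}

#' Specification of a synthetic sensor-array experiment
#'
#' Describes a multi-class E-nose measurement campaign: each recording has a
#' flat pre-injection baseline, a saturating-exponential rise toward a
#' class- and sensor-specific amplitude during the response phase, and an
#' exponential recovery once clean air returns, plus additive Gaussian
#' noise and a constant per-sensor offset voltage (removed by calibration).
#' Defaults mirror a typical measurement cycle: 340 s at 2 Hz, with 20 s of
#' baseline and a 180 s response phase.
#'
#' @param n_classes,n_sensors,n_per_class campaign shape (defaults 3, 16, 10).
#' @param amplitudes `K x n_sensors` matrix of response amplitudes (volts);
#'   default: drawn once from Unif(0.5, 3) under `seed`.
#' @param rise_tau,decay_tau response and recovery time constants (s).
#' @param noise_sd additive noise standard deviation (volts).
#' @param offset constant baseline voltage per sensor (volts).
#' @param sampling_rate samples per second.
#' @param baseline_s,response_s,total_s phase durations (s).
#' @param labels class labels.
#' @param seed RNG seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 3L, n_sensors = 16L, n_per_class = 10L,
                           amplitudes = NULL, rise_tau = 20, decay_tau = 30,
                           noise_sd = 0.01, offset = 0.5, sampling_rate = 2,
                           baseline_s = 20, response_s = 180, total_s = 340,
                           labels = NULL, seed = 1L) {
  if (any(c(n_classes, n_sensors, n_per_class, rise_tau, decay_tau,
            sampling_rate, baseline_s, response_s, total_s) <= 0)) {
    stop_input("all synthetic_spec sizes and durations must be positive")
  }
  if (is.null(labels)) labels <- LETTERS[seq_len(n_classes)]
  if (is.null(amplitudes)) {
    amplitudes <- withr::with_seed(seed,
      matrix(runif(n_classes * n_sensors, 0.5, 3), n_classes, n_sensors))
  }
  amplitudes <- as.matrix(amplitudes)
  if (!all(dim(amplitudes) == c(n_classes, n_sensors))) {
    stop_input("amplitudes must be a %d x %d matrix", n_classes, n_sensors)
  }
  structure(
    list(n_classes = n_classes, n_sensors = n_sensors, n_per_class = n_per_class,
         amplitudes = amplitudes, rise_tau = rise_tau, decay_tau = decay_tau,
         noise_sd = noise_sd, offset = offset, sampling_rate = sampling_rate,
         baseline_s = baseline_s, response_s = response_s, total_s = total_s,
         labels = labels, seed = seed),
    class = "synthetic_spec"
  )
}

#' Generate labelled sensor-array recordings
#'
#' @param spec a [synthetic_spec()].
#' @return List of [sensor_recording()] objects (length
#'   `n_classes * n_per_class`), each labelled and named
#'   `"<class>_<replicate>"`.
#' @export
generate_recordings <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sr <- spec$sampling_rate
  nt <- round(spec$total_s * sr)
  t <- (seq_len(nt) - 1L) / sr
  resp_end <- spec$baseline_s + spec$response_s
  shape_for <- function(amp) {
    v <- numeric(nt)
    rising <- t >= spec$baseline_s & t < resp_end
    v[rising] <- amp * (1 - exp(-(t[rising] - spec$baseline_s) / spec$rise_tau))
    peak <- amp * (1 - exp(-spec$response_s / spec$rise_tau))
    after <- t >= resp_end
    v[after] <- peak * exp(-(t[after] - resp_end) / spec$decay_tau)
    v
  }
  out <- vector("list", spec$n_classes * spec$n_per_class)
  idx <- 0L
  withr::with_seed(spec$seed, {
    for (ki in seq_len(spec$n_classes)) {
      clean <- vapply(seq_len(spec$n_sensors),
                      function(s) shape_for(spec$amplitudes[ki, s]), numeric(nt))
      for (rep_i in seq_len(spec$n_per_class)) {
        noisy <- clean + spec$offset +
          matrix(rnorm(nt * spec$n_sensors, sd = spec$noise_sd), nt, spec$n_sensors)
        colnames(noisy) <- paste0("sensor_", seq_len(spec$n_sensors))
        idx <- idx + 1L
        out[[idx]] <- sensor_recording(
          noisy, sampling_rate = sr,
          baseline_window = which(t < spec$baseline_s),
          sample_id = paste0(spec$labels[ki], "_", rep_i),
          label = spec$labels[ki]
        )
      }
    }
  })
  names(out) <- vapply(out, function(r) r$sample_id, character(1L))
  out
}
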