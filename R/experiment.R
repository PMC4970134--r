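#' Run a full offline or online experiment from a configuration
#'
#' Orchestrates one evaluation of any of the six predictors on a feature
#' table: loads the data, optionally tunes SVM hyperparameters once on the
#' full (scaled) dataset and freezes them, runs [offline_loo()] or
#' [online_run()], and writes `predictions.csv`, `report.json`,
#' `confusion.csv` and a reproducibility `manifest.json` to the output
#' directory. Reruns with an identical manifest reproduce the outputs.
#'
#' @param config a named list (or path to a JSON/YAML file) with fields:
#'   `data` (feature-table CSV path) or `dataset` (a [labeled_dataset()]);
#'   `method` (one of vm-nb, vm-sr, vm-svm, nb, sr, platt); `experiment`
#'   (`"offline"` or `"online"`); `out_dir`; and optionally `seed` (default
#'   1), `scale` (default TRUE), `venn_mode` (default `"loo"`),
#'   `init_per_class` (default 3, online only), `tune_svm` (logical,
#'   default FALSE), and `params` (classifier hyperparameters).
#' @return Invisibly, the `offline_result` / `online_result`.
#' @export
run_experiment <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_config(config)
  }
  if (!is.list(config)) stop_input("config must be a list or a config file path")
  for (field in c("method", "experiment", "out_dir")) {
    if (is.null(config[[field]])) stop_input("config is missing '%s'", field)
  }
  experiment <- match.arg(config$experiment, c("offline", "online"))
  seed <- as.integer(config$seed %||% 1L)
  scale <- isTRUE(config$scale %||% TRUE)
  params <- config$params %||% list()

  dataset <- if (!is.null(config$dataset)) {
    config$dataset
  } else if (!is.null(config$data)) {
    read_feature_table(config$data)
  } else {
    stop_input("config needs either 'data' (csv path) or 'dataset'")
  }

  if (isTRUE(config$tune_svm) && config$method %in% c("vm-svm", "platt")) {
    xs <- if (scale) apply_scaler(dataset$x, fit_scaler(dataset$x)) else dataset$x
    tuned <- tune_svm(xs, dataset$y, folds = as.integer(config$tune_folds %||% 5L),
                      seed = seed)
    params$cost <- tuned$cost
    params$gamma <- tuned$gamma
  }

  spec <- do.call(predictor_spec, c(
    list(method = config$method, venn_mode = config$venn_mode %||% "loo"), params
  ))
  result <- if (experiment == "offline") {
    offline_loo(dataset, spec, scale = scale)
  } else {
    online_run(dataset, spec, init_per_class = as.integer(config$init_per_class %||% 3L),
               seed = seed, scale = scale)
  }

  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_predictions(result$records, file.path(out_dir, "predictions.csv"))
  rep <- result$validity
  report <- list(
    method = config$method, experiment = experiment, n = rep$n,
    d_ln = if (is.finite(rep$d_ln)) rep$d_ln else "Inf",
    d_sq = rep$d_sq, d1 = rep$d1, d11 = rep$d11, d12 = rep$d12
  )
  if (experiment == "offline") {
    report$classification_rate <- result$classification_rate
    utils::write.csv(as.data.frame.matrix(result$confusion),
                     file.path(out_dir, "confusion.csv"))
    ss <- sensitivity_specificity(result$confusion)
    report$sensitivity <- ss$sensitivity
    report$specificity <- ss$specificity
  } else {
    report$classification_rate <- mean(result$records$correct)
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    package = "vennmachine",
    version = as.character(utils::packageVersion("vennmachine")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed, method = config$method, experiment = experiment,
    venn_mode = config$venn_mode %||% "loo", scale = scale,
    init_per_class = if (experiment == "online") as.integer(config$init_per_class %||% 3L) else NULL,
    params = params,
    data = if (!is.null(config$data)) {
      list(path = config$data, md5 = unname(tools::md5sum(config$data)))
    } else {
      list(inline = TRUE, n = nrow(dataset$x))
    },
    outputs = c("predictions.csv", "report.json",
                if (experiment == "offline") "confusion.csv")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}

read_config <- function(path) {
  if (!file.exists(path)) stop_input("no such config file: %s", path)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_input("yaml package required to read %s", path)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
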