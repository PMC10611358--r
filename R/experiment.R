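# End-to-end experiment orchestration and run configuration: simulate
# (optional) -> preprocess per band -> cross-validate per architecture,
# with every artifact written under one run directory and replayable from
# the saved configuration alone.

#' Experiment run configuration
#'
#' Bundles a cohort source (a [cohort_spec()] to simulate, or a directory of
#' recordings), the preprocessing parameters, the bands and architectures to
#' evaluate, and the training configuration.
#'
#' @param cohort a [cohort_spec()], or a path to a cohort directory written
#'   by [write_cohort()].
#' @param pipeline a [pipeline_config()] (its `band` field is ignored; the
#'   `bands` argument drives the band loop).
#' @param bands character vector of band tokens to evaluate.
#' @param architectures model architectures to evaluate.
#' @param model arguments for [model_spec()] beyond the architecture.
#' @param train a [train_config()].
#' @param n_epochs training epochs per fold.
#' @param seed master seed for the run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(n_group_a = 6, n_group_b = 6,
                                            duration_s = 60, artifact_rate = 0),
                       pipeline = pipeline_config(ica = FALSE),
                       bands = c("theta", "beta"),
                       architectures = "mrcnn_rse",
                       model = list(conv_filters = c(4, 4, 4), se_reduction = 4),
                       train = train_config(max_epochs = 10, warmup_epochs = 3,
                                            n_folds = 3),
                       n_epochs = train$max_epochs,
                       seed = 1) {
  bands <- vapply(bands, function(b) {
    parse_band(b); as.character(b)
  }, character(1))
  architectures <- match.arg(architectures, c("mrcnn_rse", "mrcnn_lstm"),
                             several.ok = TRUE)
  structure(list(cohort = cohort, pipeline = pipeline, bands = bands,
                 architectures = architectures, model = model, train = train,
                 n_epochs = n_epochs, seed = as.integer(seed)),
            class = "run_config")
}

.config_to_list <- function(x) {
  strip <- function(v) {
    if (inherits(v, "band_spec")) list(low_hz = v$low_hz, high_hz = v$high_hz,
                                       order = v$order)
    else if (is.list(v)) lapply(v, strip)
    else v
  }
  lapply(unclass(x), strip)
}

#' Write a run configuration as YAML
#' @param config a [run_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(.config_to_list(config), path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML file written by [write_run_config()].
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- if (is.character(y$cohort)) y$cohort
            else do.call(cohort_spec, c(
              y$cohort[setdiff(names(y$cohort), "band_effects")],
              list(band_effects = lapply(y$cohort$band_effects, function(e)
                do.call(band_effect, e)))))
  pl <- y$pipeline
  if (is.list(pl$band)) pl$band <- do.call(band_spec, pl$band)
  run_config(cohort = cohort,
             pipeline = do.call(pipeline_config, pl),
             bands = unlist(y$bands),
             architectures = unlist(y$architectures),
             model = y$model,
             train = do.call(train_config, y$train),
             n_epochs = y$n_epochs,
             seed = y$seed)
}

#' Run an experiment end to end
#'
#' Simulates (or loads) the cohort, preprocesses it once per requested band,
#' cross-validates each architecture on each band, and writes everything to
#' `out_dir`: the config (YAML), the preprocessing manifest of the first
#' subject, one metrics report (JSON) per band x architecture, and a summary
#' table. Replaying from the saved config reproduces the summary.
#'
#' @param config a [run_config()].
#' @param out_dir output directory, created if needed.
#' @param verbose print progress.
#' @return Named list of `cv_report`s (invisibly); names are
#'   `<architecture>/<band>`.
#' @export
run_experiment <- function(config, out_dir = tempfile("eegdep_run"),
                           verbose = FALSE) {
  if (!inherits(config, "run_config")) stopf("`config` must be a run_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_run_config(config, file.path(out_dir, "config.yaml"))

  cohort <- if (is.character(config$cohort)) read_cohort(config$cohort)
            else {
              cs <- config$cohort
              cs$seed <- derive_seed(config$seed, 1)
              generate_cohort(cs)
            }
  reports <- list()
  summary_rows <- list()
  for (band in config$bands) {
    pl <- config$pipeline
    pl$band <- parse_band(band)
    ep <- preprocess_cohort(cohort, pl)
    if (!is.null(ep$manifest) && band == config$bands[1])
      jsonlite::write_json(ep$manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (arch in config$architectures) {
      spec <- do.call(model_spec, c(list(architecture = arch,
                                         in_channels = dim(ep$data)[2],
                                         in_samples = dim(ep$data)[3]),
                                    config$model))
      tc <- config$train
      tc$seed <- derive_seed(config$seed, 2)
      rep <- cross_validate(ep, spec, tc, n_epochs = config$n_epochs)
      key <- paste(arch, band, sep = "/")
      reports[[key]] <- rep
      summary_rows[[key]] <- c(list(architecture = arch, band = band),
                               as.list(rep$mean), sd = as.list(rep$sd))
      jsonlite::write_json(
        list(architecture = arch, band = band, per_fold = rep$per_fold,
             mean = as.list(rep$mean), sd = as.list(rep$sd),
             n = rep$n, seed = config$seed),
        file.path(out_dir, sprintf("report_%s_%s.json", arch,
                                   gsub("[^0-9A-Za-z]+", "-", band))),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      if (verbose)
        message(sprintf("%s %s: acc %.3f", arch, band, rep$mean["accuracy"]))
    }
  }
  tab <- report_table(reports)
  utils::write.csv(tab, file.path(out_dir, "summary.csv"))
  writeLines(c(utils::capture.output(print(tab))),
             file.path(out_dir, "summary.txt"))
  attr(reports, "out_dir") <- out_dir
  invisible(reports)
}
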