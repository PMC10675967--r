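#' Configure an end-to-end run
#'
#' Bundles everything [run_pipeline()] needs: the input (a scenario to
#' simulate or a CSV to read), the model variants and tuning criteria, the
#' estimator, and the seeds. A single top-level `seed` expands
#' deterministically into the data, split, and cross-validation seeds unless
#' these are given explicitly.
#'
#' @param input An [scenario_config()] object, or a path to a clustered CSV
#'   (see [read_clustered_csv()]).
#' @param outcome_family `"gaussian"` or `"binomial"`; ignored (taken from
#'   the scenario) when `input` is a scenario.
#' @param variants,criteria Passed to [run_experiment()].
#' @param estimator `"classic"` or `"post"`.
#' @param alpha Elastic-net mixing for the fixed-effects variants.
#' @param R Number of outer sub-sampling replicates.
#' @param seed Top-level seed.
#' @param data_seed,split_seed,cv_seed Explicit sub-seeds (optional).
#' @param population_subsample_fraction Optionally reduce the input to a
#'   random row fraction before splitting (as done for the largest study
#'   population when the binary outcome made some procedures expensive).
#' @param output_dir Where [run_pipeline()] writes its artifact tree; `NULL`
#'   keeps everything in memory.
#' @param cor_threshold,iterative Collinearity-filter settings
#'   (see [drop_collinear()]).
#' @param allow_cv1se_random Passed to [run_experiment()].
#' @return A validated `hl_run_config`.
#' @export
run_config <- function(input,
                       outcome_family = c("gaussian", "binomial"),
                       variants = c("no_hosps", "hosps_fixed", "hosps_random"),
                       criteria = c("cv_min", "cv_1se", "aic", "bic"),
                       estimator = c("classic", "post"),
                       alpha = 1, R = 20L, seed = 1L,
                       data_seed = NULL, split_seed = NULL, cv_seed = NULL,
                       population_subsample_fraction = NULL,
                       output_dir = NULL,
                       cor_threshold = 0.95, iterative = TRUE,
                       allow_cv1se_random = FALSE) {
  estimator <- match.arg(estimator)
  ok_var <- c("no_hosps", "hosps_fixed", "hosps_random")
  ok_crit <- c("cv_min", "cv_1se", "aic", "bic")
  if (!length(variants) || !all(variants %in% ok_var)) {
    abort(paste0("variants must be a non-empty subset of: ", paste(ok_var, collapse = ", ")))
  }
  if (!length(criteria) || !all(criteria %in% ok_crit)) {
    abort(paste0("criteria must be a non-empty subset of: ", paste(ok_crit, collapse = ", ")))
  }
  if (inherits(input, "hl_scenario")) {
    outcome_family <- if (input$outcome_family == "binomial") "binomial" else "gaussian"
  } else {
    outcome_family <- match.arg(outcome_family)
    if (!is.character(input) || length(input) != 1L) {
      abort("input must be a scenario_config() or a CSV path")
    }
  }
  if (!is.null(population_subsample_fraction) &&
      (population_subsample_fraction <= 0 || population_subsample_fraction > 1)) {
    abort("population_subsample_fraction must be in (0, 1]")
  }
  structure(
    list(
      input = input, outcome_family = outcome_family,
      variants = variants, criteria = criteria, estimator = estimator,
      alpha = alpha, R = as.integer(R), seed = as.integer(seed),
      data_seed = as.integer(data_seed %||% (seed * 3L + 11L)),
      split_seed = as.integer(split_seed %||% (seed * 3L + 12L)),
      cv_seed = as.integer(cv_seed %||% (seed * 3L + 13L)),
      population_subsample_fraction = population_subsample_fraction,
      output_dir = output_dir,
      cor_threshold = cor_threshold, iterative = iterative,
      allow_cv1se_random = allow_cv1se_random
    ),
    class = "hl_run_config"
  )
}

#' Run the whole pipeline
#'
#' Simulates or reads the data, applies the global preparation rules, draws
#' the sub-sampling splits once, runs the full variant-by-criterion
#' comparison, and (if `output_dir` is set) writes the artifact tree:
#' `config.yaml`, `manifest.json`, `data/` (the prepared dataset and the
#' preprocessing report), `metrics/` (per-replicate and aggregated CSVs),
#' `importance/`, and `logs/`. Two runs with the same configuration produce
#' bit-identical CSV outputs.
#'
#' @param config An [run_config()].
#' @return The [run_experiment()] result, invisibly, with the prepared data,
#'   splits and output paths attached as attributes.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "hl_run_config"))

  data <- if (inherits(config$input, "hl_scenario")) {
    cfg <- config$input
    cfg$seed <- config$data_seed
    simulate_hospital_data(cfg)
  } else {
    read_clustered_csv(config$input, family = config$outcome_family)
  }

  if (!is.null(config$population_subsample_fraction)) {
    set.seed(config$data_seed + 1L)
    keep <- sort(sample.int(length(data$y),
                            round(length(data$y) * config$population_subsample_fraction)))
    data <- subset_dataset(data, keep)
  }

  prep <- preprocess_global(data, cor_threshold = config$cor_threshold,
                            iterative = config$iterative)
  splits <- make_subsamples(prep$data, R = config$R, seed = config$split_seed)
  result <- run_experiment(
    prep$data, splits,
    variants = config$variants, criteria = config$criteria,
    estimator = config$estimator, alpha = config$alpha,
    cv_seed = config$cv_seed,
    allow_cv1se_random = config$allow_cv1se_random
  )

  if (!is.null(config$output_dir)) {
    write_artifacts(config, prep, splits, result)
  }
  attr(result, "data") <- prep$data
  attr(result, "splits") <- splits
  attr(result, "output_dir") <- config$output_dir
  invisible(result)
}

write_artifacts <- function(config, prep, splits, result) {
  out <- config$output_dir
  for (d in c("", "data", "metrics", "importance", "logs")) {
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  }

  cfg_list <- unclass(config)
  cfg_list$output_dir <- NULL
  if (inherits(cfg_list$input, "hl_scenario")) {
    sc <- unclass(cfg_list$input)
    sc$beta_true <- as.list(sc$beta_true)
    cfg_list$input <- sc
  }
  yaml::write_yaml(cfg_list, file.path(out, "config.yaml"))

  manifest <- list(
    config_checksum = index_checksum(utf8ToInt(paste(
      capture.output(utils::str(cfg_list)), collapse = ""))),
    seeds = list(data = config$data_seed, split = config$split_seed,
                 cv = config$cv_seed),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    package_version = as.character(utils::packageVersion("hosplasso")),
    split_checksums = splits$checksums$checksum
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  write_clustered_csv(prep$data, file.path(out, "data", "dataset.csv"))
  report_to_json(prep$report, file.path(out, "data", "preprocess_report.json"))
  readr::write_csv(result$metrics, file.path(out, "metrics", "metrics.csv"),
                   progress = FALSE)
  readr::write_csv(result$aggregate, file.path(out, "metrics", "aggregate.csv"),
                   progress = FALSE)
  if (!is.null(result$importance) && nrow(result$importance)) {
    readr::write_csv(result$importance,
                     file.path(out, "importance", "importance.csv"),
                     progress = FALSE)
  }
  readr::write_csv(result$log, file.path(out, "logs", "fit_log.csv"),
                   progress = FALSE)
  invisible(out)
}
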