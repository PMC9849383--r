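#' Assemble a pipeline run configuration
#'
#' @param input Path to a delimited records file, or `NULL` when
#'   simulating.
#' @param simulate A [cohort_spec()] (or the string `"four_typology"`)
#'   to generate the input instead of reading it.
#' @param column_map Column mapping for [read_records()].
#' @param age_bounds Inclusive age retention bounds.
#' @param sampler List of sampler settings: `chains`, `iter`, `warmup`,
#'   `target_accept`.
#' @param levels List with quantile pairs `population` and `individual`.
#' @param K Candidate mixture sizes.
#' @param parameterizations Covariance structures (default all 14).
#' @param scoring_ages Raw ages for the overlap score.
#' @param seed Integer seed recorded in every artifact.
#' @return A validated list of class `"run_config"`.
#' @export
run_config <- function(input = NULL, simulate = NULL,
                       column_map = list(id = "id", age = "age",
                                         score = "points"),
                       age_bounds = c(10, 25),
                       sampler = list(chains = 4, iter = 200, warmup = 500,
                                      target_accept = 0.9),
                       levels = list(population = c(0.025, 0.975),
                                     individual = c(0.05, 0.95)),
                       K = 2:8, parameterizations = NULL,
                       scoring_ages = 10:20, seed = 1) {
  if (is.null(input) && is.null(simulate))
    stop("config invalid: either 'input' or 'simulate' is required")
  if (!is.null(input) && !file.exists(input))
    stop("config invalid: input file not found: ", input)
  if (identical(simulate, "four_typology")) simulate <- four_typology_preset()
  if (!is.null(simulate)) stopifnot(inherits(simulate, "cohort_spec"))
  defaults <- list(chains = 4, iter = 200, warmup = 500, target_accept = 0.9)
  sampler <- utils::modifyList(defaults, sampler)
  structure(list(input = input, simulate = simulate,
                 column_map = column_map, age_bounds = age_bounds,
                 sampler = sampler, levels = levels, K = K,
                 parameterizations = parameterizations,
                 scoring_ages = scoring_ages, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; `simulate:
#' four_typology` selects the preset.
#'
#' @param path YAML file path.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package")
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

# stable FNV-1a hash of the JSON form of the config, for artifact
# provenance stamps
config_hash <- function(config) {
  s <- jsonlite::toJSON(lapply(unclass(config), function(x)
    if (inherits(x, "cohort_spec")) unclass(x) else x),
    auto_unbox = TRUE, digits = 10, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full potential-estimation pipeline
#'
#' Stages, in order: simulate or read records; best-per-age filtering
#' and standardization; hierarchical Bayesian fit; population potential
#' curve and peak summary; progression-typology clustering; membership
#' profiles; JSON run report. Every stage writes its artifact under
#' `output_dir`; identical config and seed give an identical report.
#'
#' @param config A [run_config()] (or a YAML path).
#' @param output_dir Directory for artifacts (created if missing).
#' @param quiet Suppress progress messages (default `TRUE`).
#' @return The run report, invisibly (also written to
#'   `<output_dir>/report.json`).
#' @export
run_pipeline <- function(config, output_dir, quiet = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- list(schema_version = "1.0", config_hash = config_hash(config),
                seed = config$seed)
  say <- function(...) if (!quiet) message(...)

  # stage: input
  if (!is.null(config$simulate)) {
    say("stage simulate: ", config$simulate$n_individuals, " individuals")
    cohort <- simulate_cohort(config$simulate, seed = config$seed)
    write_cohort(cohort, file.path(output_dir, "cohort.csv"))
    records <- cohort$records
  } else {
    say("stage read: ", config$input)
    records <- read_records(config$input, config$column_map)
    cohort <- NULL
  }
  n_raw <- nrow(records)

  # stage: preprocess
  training <- best_per_age(records, config$age_bounds)
  spec <- fit_standardization(training)
  std <- standardize_records(spec, training)
  write_training_table(std, spec, file.path(output_dir, "training_std.csv"))
  say("stage preprocess: ", n_raw, " records in, ", nrow(training),
      " best-per-age records out")

  # stage: fit
  s <- config$sampler
  fit <- fit_potential(training, age_bounds = config$age_bounds,
                       chains = s$chains, iter = s$iter, warmup = s$warmup,
                       target_accept = s$target_accept,
                       seed = config$seed, best_filter = FALSE,
                       quiet = quiet)
  utils::write.csv(
    data.frame(fit$draws$fixed, fit$draws$tau, sigma = fit$draws$sigma),
    file.path(output_dir, "fixed_draws.csv"), row.names = FALSE)
  jsonlite::write_json(
    c(stamp, list(table = fit$diagnostics$table,
                  n_divergent = fit$diagnostics$n_divergent)),
    file.path(output_dir, "diagnostics.json"), auto_unbox = TRUE,
    digits = NA)
  say("stage fit: ", nrow(fit$draws$fixed), " draws, max R-hat ",
      round(max(fit$diagnostics$table$rhat, na.rm = TRUE), 3))

  # stage: curves
  pop_curve <- potential_curve(fit, level = config$levels$population)
  write_potential_curve(pop_curve, file.path(output_dir,
                                             "population_curve.csv"))
  pk <- attr(pop_curve, "peak")

  # stage: cluster
  clusters <- cluster_progressions(fit, K = config$K,
                                   parameterizations =
                                     config$parameterizations,
                                   ages = config$scoring_ages)
  write_cluster_report(clusters, file.path(output_dir, "clusters.csv"))
  say("stage cluster: ", clusters$selected$parameterization, " K=",
      clusters$selected$K)

  # stage: membership
  prof <- membership_profile(clusters, fit)
  write_membership(prof, file.path(output_dir, "membership.csv"))

  report <- c(stamp, list(
    n_records = n_raw,
    n_training = nrow(training),
    n_individuals = length(fit$individuals),
    r_squared = r_squared(fit, random_effects = TRUE),
    r_squared_fixed_only = r_squared(fit, random_effects = FALSE),
    peak = pk,
    mixture = list(parameterization = clusters$selected$parameterization,
                   K = clusters$selected$K,
                   overlap_score = clusters$selected$overlap_score,
                   cluster_sizes = as.integer(
                     tabulate(clusters$classification,
                              nbins = clusters$selected$K))),
    diagnostics = list(
      max_rhat = max(fit$diagnostics$table$rhat, na.rm = TRUE),
      min_ess = min(fit$diagnostics$table$ess, na.rm = TRUE),
      n_divergent = fit$diagnostics$n_divergent)))
  jsonlite::write_json(report, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
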