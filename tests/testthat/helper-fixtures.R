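# Shared fixtures, built once per test run and cached.

# mclust's low-level entry points (me, estep) dispatch by name in the
# caller's search path, so the oracle calls in the tests need it attached
suppressPackageStartupMessages(library(mclust))

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) assign(key, builder(), envir = .fixtures)
  get(key, envir = .fixtures)
}

table1_params <- function() moore(0.5206276, 2.3244675, 0.8705898, 0.1825503)

# a small clean cohort + hierarchical fit, reused across test files
small_fit <- function() memo("small_fit", function() {
  spec <- cohort_spec(n_individuals = 12, results_per_age = 1,
                      counter_performance = list(prob = 0, mean = 0.5),
                      residual_sd = 0.1)
  cohort <- simulate_cohort(spec, seed = 401)
  fit <- fit_potential(cohort$records,
                       standardization = cohort$truth$standardization,
                       chains = 2, iter = 60, warmup = 200, seed = 402,
                       quiet = TRUE)
  list(cohort = cohort, fit = fit)
})

# four-typology truth (no model fit): quadruplets + labels + spec
typology_truth <- function() memo("typology_truth", function() {
  spec <- four_typology_preset(n_individuals = 200)
  simulate_cohort(spec, seed = 403)
})

# minimal object that quacks like a potential_fit, for method-level tests
fake_fit <- function(individual_draws, ids = NULL,
                     fixed = NULL) {
  if (is.null(ids)) ids <- dimnames(individual_draws)[[2]]
  if (is.null(ids)) {
    ids <- sprintf("f%02d", seq_len(dim(individual_draws)[2]))
    dimnames(individual_draws) <- list(NULL, ids, c("a", "b", "c", "d"))
  }
  structure(list(individuals = ids,
                 draws = list(individual = individual_draws, fixed = fixed)),
            class = "potential_fit")
}

# hand-built well-separated two-component mixture in quadruplet space
toy_mixture <- function(delta = 5) {
  means <- cbind(c(0, 0, 0, 0), c(delta, delta, delta, delta))
  sigma <- array(0, dim = c(4, 4, 2))
  sigma[, , 1] <- diag(4) * 0.2
  sigma[, , 2] <- diag(4) * 0.2
  list(weights = c(0.5, 0.5), means = means, sigma = sigma, K = 2)
}

write_temp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
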