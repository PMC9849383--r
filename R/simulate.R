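#' Specification of a synthetic performance cohort
#'
#' Defines the generative conditions the pipeline assumes: individuals
#' follow Moore-type U-shaped curves on a standardized scale, with
#' per-individual parameter perturbations, Gaussian residual noise, and
#' one-sided counter-performance contamination (atypically *bad*
#' results only — the phenomenon the best-per-age filter neutralizes).
#' Raw units come from a fixed "true" standardization so that unit
#' handling is exercised: ages centered at 17.5 (sd 4.6 years), scores
#' scaled by 20 points with the population curve's minimum landing at
#' 141.37 points.
#'
#' @param n_individuals Cohort size (default 60).
#' @param age_range Integer ages generated, inclusive (default
#'   `c(10, 25)`).
#' @param results_per_age Results per individual per age (default 3).
#' @param fixed_truth Population [moore()] parameters; default the
#'   reference quadruplet `(0.5206276, 2.3244675, 0.8705898, 0.1825503)`.
#' @param random_effect_sds Length-4 sds of individual perturbations
#'   `(a, b, c, d)`: additive for the amplitudes a and c, multiplicative
#'   log-normal for the rates b and d (so every individual curve stays
#'   U-shaped). Ignored when `typology_mixture` is given.
#' @param residual_sd Gaussian residual sd on the standardized score
#'   scale (default 0.1).
#' @param counter_performance List `prob` (contamination probability per
#'   result, default 0.3) and `mean` (mean of the exponential
#'   worse-score shift in standardized units, default 0.5).
#' @param typology_mixture Optional list of components, each
#'   `list(weight, mean = c(a, b, c, d), sd = c(...))` (diagonal
#'   covariance), defining progression clusters on the natural
#'   parameter scale.
#' @param standardization Optional `"standardization"` override for the
#'   raw-units mapping.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_individuals = 60,
                        age_range = c(10, 25),
                        results_per_age = 3,
                        fixed_truth = moore(0.5206276, 2.3244675,
                                            0.8705898, 0.1825503),
                        random_effect_sds = c(a = 0.05, b = 0.10,
                                              c = 0.08, d = 0.10),
                        residual_sd = 0.1,
                        counter_performance = list(prob = 0.3, mean = 0.5),
                        typology_mixture = NULL,
                        standardization = NULL) {
  fixed_truth <- as_moore(fixed_truth)
  if (fixed_truth$a <= 0 || fixed_truth$c <= 0)
    stop("fixed_truth has no interior peak: amplitudes must be positive")
  if (is.null(standardization)) {
    pk <- moore_peak(fixed_truth)
    standardization <- standardization(
      age_mean = 17.5, age_sd = 4.6,
      score_mean = 141.37 - 20 * pk[["p"]], score_sd = 20,
      positivity_shift = 0)
  }
  if (!is.null(typology_mixture)) {
    w <- vapply(typology_mixture, `[[`, 0, "weight")
    stopifnot(all(w > 0))
    for (k in seq_along(typology_mixture)) {
      m <- typology_mixture[[k]]$mean
      if (length(m) != 4L || any(m <= 0))
        stop("typology_mixture component ", k,
             " mean must be a positive quadruplet (U-shape requirement)")
    }
  }
  structure(list(n_individuals = n_individuals, age_range = age_range,
                 results_per_age = results_per_age,
                 fixed_truth = fixed_truth,
                 random_effect_sds = rep_len(random_effect_sds, 4L),
                 residual_sd = residual_sd,
                 counter_performance = counter_performance,
                 typology_mixture = typology_mixture,
                 standardization = standardization),
            class = "cohort_spec")
}

draw_quadruplet <- function(spec) {
  ft <- spec$fixed_truth
  sds <- spec$random_effect_sds
  for (tries in 1:100) {
    q <- c(a = ft$a + stats::rnorm(1, 0, sds[1L]),
           b = ft$b * exp(stats::rnorm(1, 0, sds[2L])),
           c = ft$c + stats::rnorm(1, 0, sds[3L]),
           d = ft$d * exp(stats::rnorm(1, 0, sds[4L])))
    if (all(q > 0)) return(q)
  }
  stop("could not draw a valid quadruplet: random_effect_sds too large ",
       "relative to fixed_truth amplitudes")
}

draw_typology_quadruplet <- function(comp, k) {
  for (tries in 1:100) {
    q <- comp$mean + stats::rnorm(4L, 0, rep_len(comp$sd, 4L))
    if (all(q > 0)) return(q)
  }
  stop("typology_mixture component ", k,
       " keeps producing non-positive quadruplets")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws per-individual quadruplets (from the random-effect law or the
#' typology mixture), then one record per (individual, age, replicate):
#' curve value plus Gaussian residual, plus — with the configured
#' probability — an exponential counter-performance shift on the
#' worse-score side only. Scores and ages are returned in raw units.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; fully determines the output.
#' @return List with `records` (data frame `individual_id`, `age`,
#'   `score`) and `truth`: `quadruplets` (individuals x 4, standardized
#'   scale), `cluster` (integer labels or `NULL`), `peak_age` /
#'   `peak_score` (raw units per individual), `standardization`,
#'   `fixed_truth`, and the cohort specification itself.
#' @export
simulate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  N <- spec$n_individuals
  ids <- sprintf("ind%04d", seq_len(N))
  mix <- spec$typology_mixture
  cluster <- NULL
  quads <- matrix(NA_real_, N, 4L, dimnames = list(ids, c("a", "b", "c", "d")))
  if (!is.null(mix)) {
    w <- vapply(mix, `[[`, 0, "weight")
    cluster <- sample.int(length(mix), N, replace = TRUE, prob = w)
    for (i in seq_len(N))
      quads[i, ] <- draw_typology_quadruplet(mix[[cluster[i]]], cluster[i])
  } else {
    for (i in seq_len(N)) quads[i, ] <- draw_quadruplet(spec)
  }

  ages <- seq(spec$age_range[1L], spec$age_range[2L])
  sspec <- spec$standardization
  t_std <- standardize_age(sspec, ages)
  R <- spec$results_per_age
  cp <- spec$counter_performance

  n_rec <- N * length(ages) * R
  rec_id <- rep(ids, each = length(ages) * R)
  rec_age <- rep(rep(ages, each = R), times = N)
  rec_t <- rep(rep(t_std, each = R), times = N)
  mu <- numeric(n_rec)
  for (i in seq_len(N)) {
    rows <- ((i - 1L) * length(ages) * R + 1L):(i * length(ages) * R)
    q <- quads[i, ]
    mu[rows] <- q[1L] * exp(-q[2L] * rec_t[rows]) +
                q[3L] * exp(q[4L] * rec_t[rows])
  }
  y <- mu + stats::rnorm(n_rec, 0, spec$residual_sd)
  contaminated <- stats::runif(n_rec) < cp$prob
  y[contaminated] <- y[contaminated] +
    stats::rexp(sum(contaminated), rate = 1 / cp$mean)
  score <- destandardize_score(sspec, y)
  if (any(score <= 0))
    stop("generated non-positive raw scores; check the standardization ",
         "and residual settings")

  peaks <- t(apply(quads, 1L, function(q) moore_peak(as_moore(q))))
  list(records = data.frame(individual_id = rec_id, age = rec_age,
                            score = score, stringsAsFactors = FALSE),
       truth = list(quadruplets = quads, cluster = cluster,
                    peak_age = destandardize_age(sspec, peaks[, "t"]),
                    peak_score = destandardize_score(sspec, peaks[, "p"]),
                    standardization = sspec,
                    fixed_truth = spec$fixed_truth,
                    spec = spec))
}

#' Four-typology cohort preset
#'
#' A mixture of four progression archetypes mirroring the typologies a
#' national-federation cohort exhibits, with highly unequal weights
#' (one dominant "average" group):
#'
#' 1. **average** — the reference quadruplet (85% of individuals);
#' 2. **high young level, low progression** — small early amplitude, so
#'    scores start low (good) and the progression slope is the
#'    flattest;
#' 3. **low young level, strong progression** — large early amplitude:
#'    weak start, steep improvement through the early ages;
#' 4. **lower performance** — the weakest start (largest early
#'    amplitude, hence the steepest raw progression) combined with an
#'    inflated late amplitude, so scores stay worse throughout.
#'
#' The components differ mainly along the early-amplitude direction
#' (with a late-amplitude shift for the fourth), which keeps their
#' slope densities strictly ordered and widely separated at every
#' scoring age from 10 to 20 — many within-cluster standard deviations
#' apart, so EM and BIC recover the partition even for the small
#' components and the progression slopes barely overlap. The minority
#' components get 5% weight each.
#'
#' @param n_individuals Cohort size (default 400).
#' @param ... Further arguments passed to [cohort_spec()].
#' @return A `"cohort_spec"` with `typology_mixture` set.
#' @export
four_typology_preset <- function(n_individuals = 400, ...) {
  mix <- list(
    list(weight = 0.85, mean = c(0.5206276, 2.3244675, 0.8705898, 0.1825503),
         sd = c(0.02, 0.01, 0.01, 0.004)),
    list(weight = 0.05, mean = c(0.2806276, 2.3244675, 0.8705898, 0.1825503),
         sd = c(0.02, 0.01, 0.01, 0.004)),
    list(weight = 0.05, mean = c(0.7606276, 2.3244675, 0.8705898, 0.1825503),
         sd = c(0.02, 0.01, 0.01, 0.004)),
    list(weight = 0.05, mean = c(1.0006276, 2.3244675, 1.0000000, 0.1825503),
         sd = c(0.02, 0.01, 0.01, 0.004)))
  cohort_spec(n_individuals = n_individuals, typology_mixture = mix, ...)
}

#' Write simulated records in the CSV dialect [read_records()] reads
#'
#' @param cohort Result of [simulate_cohort()].
#' @param path Output CSV path (`id, age, points` columns); ground truth
#'   is written alongside as `<path>.truth.json`.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  df <- data.frame(id = cohort$records$individual_id,
                   age = cohort$records$age,
                   points = cohort$records$score)
  utils::write.csv(df, path, row.names = FALSE)
  tr <- cohort$truth
  jsonlite::write_json(
    list(quadruplets = tr$quadruplets, cluster = tr$cluster,
         peak_age = tr$peak_age, peak_score = tr$peak_score,
         standardization = unclass(tr$standardization)),
    paste0(path, ".truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
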