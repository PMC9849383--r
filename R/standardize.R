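#' Fit the standardization transform for ages and scores
#'
#' The hierarchical curve model is trained on a standardized scale: ages
#' are centered and reduced (mean 0, sd 1); scores are centered and
#' reduced and then shifted by a constant so every training score is
#' strictly positive, as the double-exponential curve never crosses zero.
#' The shift is \eqn{-\min(z) + \epsilon} where \eqn{z} are the centered
#' and reduced scores.
#'
#' @param records Data frame with numeric columns `age` and `score`.
#' @param eps Strict-positivity margin added on the standardized score
#'   scale (default `1e-3`).
#' @return An object of class `"standardization"`: a list with
#'   `age_mean`, `age_sd`, `score_mean`, `score_sd`, `positivity_shift`.
#' @export
fit_standardization <- function(records, eps = 1e-3) {
  stopifnot(is.data.frame(records), all(c("age", "score") %in% names(records)))
  age <- records$age; score <- records$score
  if (length(unique(age)) < 2L || length(unique(score)) < 2L)
    stop("degenerate data: need at least 2 distinct ages and 2 distinct scores")
  age_sd <- stats::sd(age); score_sd <- stats::sd(score)
  if (age_sd <= 0 || score_sd <= 0)
    stop("degenerate data: zero variance in age or score")
  score_mean <- mean(score)
  z <- (score - score_mean) / score_sd
  structure(list(age_mean = mean(age), age_sd = age_sd,
                 score_mean = score_mean, score_sd = score_sd,
                 positivity_shift = -min(z) + eps),
            class = "standardization")
}

#' Manually construct a standardization transform
#'
#' Used by the synthetic-cohort generator (which owns a fixed "true"
#' transform) and when refitting on a scale fixed elsewhere.
#'
#' @param age_mean,age_sd Age location/scale in years (`age_sd > 0`).
#' @param score_mean,score_sd Score location/scale in points (`score_sd > 0`).
#' @param positivity_shift Constant added on the standardized score scale.
#' @return A `"standardization"` object; see [fit_standardization()].
#' @export
standardization <- function(age_mean, age_sd, score_mean, score_sd,
                            positivity_shift = 0) {
  stopifnot(age_sd > 0, score_sd > 0)
  structure(list(age_mean = age_mean, age_sd = age_sd,
                 score_mean = score_mean, score_sd = score_sd,
                 positivity_shift = positivity_shift),
            class = "standardization")
}

#' @export
print.standardization <- function(x, ...) {
  cat(sprintf(
    "standardization: age ~ (x - %.4g)/%.4g, score ~ (x - %.4g)/%.4g + %.4g\n",
    x$age_mean, x$age_sd, x$score_mean, x$score_sd, x$positivity_shift))
  invisible(x)
}

#' Standardize / destandardize ages and scores
#'
#' Forward and inverse affine transforms defined by a
#' `"standardization"` object. `standardize_score()` includes the
#' positivity shift; both directions round-trip to machine precision.
#'
#' @param spec A `"standardization"` object.
#' @param age,score Numeric vectors in raw units (years, points).
#' @param t,p Numeric vectors on the standardized scale.
#' @return Numeric vector of transformed values.
#' @name standardize
NULL

#' @rdname standardize
#' @export
standardize_age <- function(spec, age) (age - spec$age_mean) / spec$age_sd

#' @rdname standardize
#' @export
destandardize_age <- function(spec, t) t * spec$age_sd + spec$age_mean

#' @rdname standardize
#' @export
standardize_score <- function(spec, score)
  (score - spec$score_mean) / spec$score_sd + spec$positivity_shift

#' @rdname standardize
#' @export
destandardize_score <- function(spec, p)
  (p - spec$positivity_shift) * spec$score_sd + spec$score_mean

#' Standardize a table of performance records
#'
#' @param spec A `"standardization"` object.
#' @param records Data frame with `individual_id`, `age`, `score`.
#' @return Data frame with columns `individual_id`, `age_std`,
#'   `score_std` (rows in input order).
#' @export
standardize_records <- function(spec, records) {
  data.frame(individual_id = records$individual_id,
             age_std = standardize_age(spec, records$age),
             score_std = standardize_score(spec, records$score),
             stringsAsFactors = FALSE)
}
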