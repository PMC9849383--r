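#' Evaluate an ensemble of posterior curves in raw units
#'
#' One curve per posterior quadruplet, evaluated on a raw-age grid and
#' destandardized back to points.
#'
#' @param draws Matrix (draws x 4) of quadruplets (a, b, c, d) on the
#'   standardized scale.
#' @param spec A `"standardization"` object.
#' @param ages Numeric vector of raw ages.
#' @return Matrix (draws x length(ages)) of raw scores.
#' @export
curve_ensemble <- function(draws, spec, ages) {
  draws <- as.matrix(draws)
  stopifnot(ncol(draws) == 4L, nrow(draws) >= 1L)
  t <- standardize_age(spec, ages)
  # outer products: draws x grid
  std <- draws[, 1L] * exp(-draws[, 2L] %o% t) +
         draws[, 3L] * exp(draws[, 4L] %o% t)
  destandardize_score(spec, std)
}

#' Median curve and quantile envelope from a curve ensemble
#'
#' @param curves Matrix (draws x grid) of raw scores, e.g. from
#'   [curve_ensemble()].
#' @param ages Raw-age grid matching `ncol(curves)`.
#' @param level Quantile pair for the envelope, e.g. `c(0.025, 0.975)`.
#' @return Data frame `age`, `median`, `lower`, `upper`.
#' @export
summarize_curve <- function(curves, ages, level = c(0.025, 0.975)) {
  stopifnot(nrow(curves) >= 2L, length(ages) == ncol(curves),
            length(level) == 2L, level[1L] < level[2L])
  data.frame(age = ages,
             median = apply(curves, 2, stats::median),
             lower = apply(curves, 2, stats::quantile, probs = level[1L],
                           names = FALSE),
             upper = apply(curves, 2, stats::quantile, probs = level[2L],
                           names = FALSE))
}

draws_for <- function(fit, individual = NULL) {
  if (is.null(individual)) return(fit$draws$fixed)
  i <- match(individual, fit$individuals)
  if (is.na(i)) stop("unknown individual: ", individual)
  fit$draws$individual[, i, , drop = TRUE]
}

#' Potential curve with estimate interval
#'
#' The per-age median and quantile envelope of the ensemble of posterior
#' Moore curves, in raw units, with the peak summary attached. The
#' envelope is an estimate interval for the individual's potential, not
#' a prediction interval for single race results.
#'
#' @param fit A `"potential_fit"`.
#' @param individual `NULL` for the population fixed-effect curve, else
#'   one individual id.
#' @param ages Raw-age grid; default 0.1-year steps over the configured
#'   age bounds.
#' @param level Quantile pair; defaults to `c(0.025, 0.975)` for the
#'   population and `c(0.05, 0.95)` for an individual.
#' @return An object of class `"potential_curve"`: data frame `age`,
#'   `median`, `lower`, `upper` with attributes `peak` (see
#'   [peak_summary()]), `level`, `individual`.
#' @export
potential_curve <- function(fit, individual = NULL, ages = NULL,
                            level = NULL) {
  stopifnot(inherits(fit, "potential_fit"))
  if (is.null(level))
    level <- if (is.null(individual)) c(0.025, 0.975) else c(0.05, 0.95)
  if (is.null(ages)) {
    b <- fit$config$age_bounds
    ages <- seq(b[1L], b[2L], by = 0.1)
  }
  draws <- draws_for(fit, individual)
  curves <- curve_ensemble(draws, fit$standardization, ages)
  out <- summarize_curve(curves, ages, level)
  attr(out, "peak") <- peak_summary(fit, individual = individual)
  attr(out, "level") <- level
  attr(out, "individual") <- individual
  class(out) <- c("potential_curve", "data.frame")
  out
}

#' @export
print.potential_curve <- function(x, ...) {
  ind <- attr(x, "individual")
  cat(sprintf("Potential curve (%s), %d grid ages, envelope (%.3g, %.3g)\n",
              if (is.null(ind)) "population" else paste("individual", ind),
              nrow(x), attr(x, "level")[1L], attr(x, "level")[2L]))
  pk <- attr(x, "peak")
  cat(sprintf("  peak age %.2f +/- %.2f, peak score %.2f +/- %.2f\n",
              pk$peak_age, pk$peak_age_pm, pk$peak_score, pk$peak_score_pm))
  invisible(x)
}

#' @export
plot.potential_curve <- function(x, main = NULL, xlab = "age (years)",
                                 ylab = "points (lower is better)", ...) {
  ind <- attr(x, "individual")
  if (is.null(main))
    main <- if (is.null(ind)) "Population potential curve"
            else paste("Potential curve, individual", ind)
  graphics::plot(x$age, x$median, type = "n", ylim = range(x$lower, x$upper),
                 main = main, xlab = xlab, ylab = ylab, ...)
  graphics::polygon(c(x$age, rev(x$age)), c(x$lower, rev(x$upper)),
                    col = grDevices::adjustcolor("goldenrod1", 0.5),
                    border = NA)
  graphics::lines(x$age, x$median, col = "steelblue4", lwd = 2)
  invisible(x)
}

#' Peak age and peak performance with uncertainty
#'
#' The closed-form peak of each posterior curve is destandardized to raw
#' years and points; the summary is the median and the half-width of the
#' central 95% interval of the per-draw peaks (set
#' `method = "sd"` for posterior standard deviations instead). Draws
#' without an interior peak are excluded and counted; more than 50%
#' excluded is an error.
#'
#' @param fit A `"potential_fit"` (or a draws x 4 quadruplet matrix, in
#'   which case `spec` must be given).
#' @param individual `NULL` for the population, else one id.
#' @param method `"interval"` (half-width of the central 95% interval)
#'   or `"sd"`.
#' @param spec Standardization, only when `fit` is a plain matrix.
#' @return List: `peak_age`, `peak_age_pm`, `peak_score`,
#'   `peak_score_pm`, `n_draws`, `n_excluded`.
#' @export
peak_summary <- function(fit, individual = NULL, method = c("interval", "sd"),
                         spec = NULL) {
  method <- match.arg(method)
  if (inherits(fit, "potential_fit")) {
    draws <- draws_for(fit, individual)
    spec <- fit$standardization
  } else {
    draws <- as.matrix(fit)
    stopifnot(!is.null(spec))
  }
  ok <- draws[, 1L] * draws[, 2L] > 0 & draws[, 3L] * draws[, 4L] > 0
  n_exc <- sum(!ok)
  if (n_exc > 0.5 * nrow(draws))
    stop("more than 50% of draws admit no interior peak")
  d <- draws[ok, , drop = FALSE]
  tstar <- log((d[, 1L] * d[, 2L]) / (d[, 3L] * d[, 4L])) / (d[, 2L] + d[, 4L])
  pstar <- d[, 1L] * exp(-d[, 2L] * tstar) + d[, 3L] * exp(d[, 4L] * tstar)
  age <- destandardize_age(spec, tstar)
  score <- destandardize_score(spec, pstar)
  half <- function(x) {
    if (method == "sd") return(stats::sd(x))
    q <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
    (q[2L] - q[1L]) / 2
  }
  list(peak_age = stats::median(age), peak_age_pm = half(age),
       peak_score = stats::median(score), peak_score_pm = half(score),
       n_draws = nrow(d), n_excluded = n_exc)
}

#' Write a potential curve and its peak summary to disk
#'
#' @param curve A `"potential_curve"`.
#' @param path Output CSV path (`age, median, lower, upper`); the peak
#'   summary is written alongside as `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_potential_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve)[, c("age", "median", "lower", "upper")],
                   path, row.names = FALSE)
  jsonlite::write_json(attr(curve, "peak"), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
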