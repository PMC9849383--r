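#' Fit the Bayesian hierarchical age-performance potential model
#'
#' Fits the hierarchical Moore-type curve
#' \deqn{p_i(t) = (a + a_i) e^{-(b + b_i) t} + (c + c_i) e^{(d + d_i) t}}
#' to longitudinal lower-is-better performance records: population fixed
#' effects (a, b, c, d) plus per-individual random offsets, Gaussian
#' residuals on the standardized score scale. Sampling uses a No-U-Turn
#' Hamiltonian Monte Carlo sampler with dual-averaging step-size
#' adaptation and diagonal mass-matrix estimation; rates b and d (and
#' their individual perturbations) are sampled on the log scale so every
#' retained quadruplet defines a U-shaped curve.
#'
#' The pipeline is: best-score-per-age filtering (counter-performance
#' removal), standardization (ages centered/reduced; scores
#' centered/reduced plus a positivity shift), pooled nonlinear OLS
#' prefit (prior centers and the fixed-only baseline), then NUTS.
#' Priors: Normal(OLS, `prior_scale`) on the fixed effects (log scale
#' for rates), standard-normal non-centered individual offsets,
#' half-Normal on random-effect scales and the residual scale.
#'
#' @param records Data frame of raw performance records with columns
#'   `individual_id`, `age` (years), `score` (points, lower is better).
#' @param age_bounds Inclusive integer-age retention bounds
#'   (default `c(10, 25)`).
#' @param standardization Optional `"standardization"` object fixing the
#'   training scale; fitted from the filtered records when `NULL`.
#' @param prior_scale Length-4 (or scalar) prior sd for the fixed
#'   effects on the sampling scale (a, log b, c, log d); default 1.
#' @param tau_prior_scale Half-Normal scale for the four random-effect
#'   sds (default 1).
#' @param sigma_prior_scale Half-Normal scale for the residual sd
#'   (default 1).
#' @param chains Number of MCMC chains (default 4).
#' @param iter Retained draws per chain (default 200; 4 x 200 = 800
#'   quadruplets per individual).
#' @param warmup Adaptation iterations per chain, discarded (default 500).
#' @param target_accept NUTS dual-averaging target (default 0.9).
#' @param max_treedepth Maximum NUTS tree depth (default 10).
#' @param seed Integer seed; fully determines the output.
#' @param best_filter If `FALSE`, skip the best-per-age filter (records
#'   are assumed already filtered). Ages are still bounds-checked.
#' @param quiet Suppress progress messages.
#' @return An object of class `"potential_fit"`; see Details. Key
#'   components: `draws$fixed` (draws x 4 matrix, natural scale),
#'   `draws$individual` (draws x individuals x 4 array of effective
#'   quadruplets), `draws$tau`, `draws$sigma`, `standardization`, `ols`,
#'   `diagnostics` (R-hat / effective sample size per global parameter,
#'   divergence counts), `individuals`, `training` (the filtered raw
#'   table) and `std_table`.
#' @seealso [potential_curve()], [peak_summary()], [r_squared()],
#'   [summarize_fixed()], [cluster_progressions()], [membership_profile()]
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_individuals = 8), seed = 1)
#' fit <- fit_potential(cohort$records, chains = 2, iter = 50,
#'                      warmup = 150, seed = 1, quiet = TRUE)
#' summarize_fixed(fit)
#' @export
fit_potential <- function(records,
                          age_bounds = c(10, 25),
                          standardization = NULL,
                          prior_scale = 1,
                          tau_prior_scale = 1,
                          sigma_prior_scale = 1,
                          chains = 4,
                          iter = 200,
                          warmup = 500,
                          target_accept = 0.9,
                          max_treedepth = 10,
                          seed = NULL,
                          best_filter = TRUE,
                          quiet = FALSE) {
  stopifnot(chains >= 1, iter >= 1, warmup >= 10)
  training <- if (best_filter) best_per_age(records, age_bounds) else {
    r <- records; r$age_bin <- floor(r$age)
    r[r$age_bin >= age_bounds[1L] & r$age_bin <= age_bounds[2L], ,
      drop = FALSE]
  }
  spec <- if (is.null(standardization)) fit_standardization(training)
          else standardization
  std <- standardize_records(spec, training)

  ids <- sort(unique(std$individual_id))
  N <- length(ids)
  idx <- match(std$individual_id, ids) - 1L
  ols <- ols_prefit(std)
  prior_mean <- c(ols$params$a, log(ols$params$b),
                  ols$params$c, log(ols$params$d))
  prior_scale <- rep_len(prior_scale, 4L)

  if (!is.null(seed)) set.seed(seed)
  dim_theta <- 9L + 4L * N
  chain_res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    init <- numeric(dim_theta)
    init[1:4] <- prior_mean + stats::rnorm(4, 0, 0.05)
    init[5:(4 + 4 * N)] <- stats::rnorm(4 * N, 0, 0.1)
    init[(5 + 4 * N):(8 + 4 * N)] <- log(0.1) + stats::rnorm(4, 0, 0.1)
    init[9 + 4 * N] <- log(max(ols$sigma, 1e-3)) + stats::rnorm(1, 0, 0.1)
    if (!quiet) message("chain ", ch, "/", chains, " (", warmup, " warmup + ",
                        iter, " draws)")
    chain_res[[ch]] <- .nuts_chain(init, std$score_std, std$age_std,
                                   as.integer(idx), N,
                                   prior_mean, prior_scale,
                                   tau_prior_scale, sigma_prior_scale,
                                   as.integer(warmup), as.integer(iter),
                                   target_accept, as.integer(max_treedepth))
  }

  global_cols <- c(1:4, (5 + 4 * N):(9 + 4 * N))
  global_names <- c("a", "log_b", "c", "log_d",
                    "log_tau_a", "log_tau_b", "log_tau_c", "log_tau_d",
                    "log_sigma")
  chain_globals <- lapply(chain_res, function(r)
    r$draws[, global_cols, drop = FALSE])
  diag_tab <- fit_diagnostics(chain_globals, global_names)
  n_div <- sum(vapply(chain_res, function(r) r$n_divergent, 0L))
  div_frac <- n_div / (chains * iter)
  if (div_frac > 0.02)
    warning(sprintf("%d divergent transitions (%.1f%% of draws)",
                    n_div, 100 * div_frac))
  bad_rhat <- diag_tab$parameter[is.finite(diag_tab$rhat) &
                                 diag_tab$rhat > 1.05]

  all_draws <- do.call(rbind, lapply(chain_res, `[[`, "draws"))
  S <- nrow(all_draws)
  fixed <- cbind(a = all_draws[, 1L], b = exp(all_draws[, 2L]),
                 c = all_draws[, 3L], d = exp(all_draws[, 4L]))
  tau <- exp(all_draws[, (5 + 4 * N):(8 + 4 * N), drop = FALSE])
  colnames(tau) <- c("tau_a", "tau_b", "tau_c", "tau_d")
  sigma <- exp(all_draws[, 9 + 4 * N])

  z_a <- all_draws[, 4L + seq_len(N), drop = FALSE]
  z_b <- all_draws[, 4L + N + seq_len(N), drop = FALSE]
  z_c <- all_draws[, 4L + 2L * N + seq_len(N), drop = FALSE]
  z_d <- all_draws[, 4L + 3L * N + seq_len(N), drop = FALSE]
  eff <- array(NA_real_, dim = c(S, N, 4L),
               dimnames = list(NULL, ids, c("a", "b", "c", "d")))
  eff[, , 1L] <- fixed[, "a"] + tau[, "tau_a"] * z_a
  eff[, , 2L] <- exp(all_draws[, 2L] + tau[, "tau_b"] * z_b)
  eff[, , 3L] <- fixed[, "c"] + tau[, "tau_c"] * z_c
  eff[, , 4L] <- exp(all_draws[, 4L] + tau[, "tau_d"] * z_d)

  structure(list(
    training = training,
    std_table = std,
    standardization = spec,
    ols = ols,
    individuals = ids,
    draws = list(fixed = fixed, tau = tau, sigma = sigma, individual = eff),
    chain_globals = chain_globals,
    diagnostics = list(table = diag_tab, n_divergent = n_div,
                       divergent_fraction = div_frac,
                       flagged_rhat = bad_rhat,
                       mean_accept = mean(vapply(chain_res,
                                                 `[[`, 0, "mean_accept")),
                       step_size = vapply(chain_res, `[[`, 0, "step_size")),
    config = list(chains = chains, iter = iter, warmup = warmup,
                  target_accept = target_accept,
                  max_treedepth = max_treedepth, seed = seed,
                  age_bounds = age_bounds, prior_scale = prior_scale,
                  tau_prior_scale = tau_prior_scale,
                  sigma_prior_scale = sigma_prior_scale),
    call = match.call()
  ), class = "potential_fit")
}

#' @export
print.potential_fit <- function(x, ...) {
  cat("Hierarchical age-performance potential fit\n")
  cat(sprintf("  %d individuals, %d training records, %d x %d = %d draws\n",
              length(x$individuals), nrow(x$training),
              x$config$chains, x$config$iter,
              nrow(x$draws$fixed)))
  cat("  fixed effects (posterior medians, standardized scale):\n")
  med <- apply(x$draws$fixed, 2, stats::median)
  cat(sprintf("    a = %.4f, b = %.4f, c = %.4f, d = %.4f\n",
              med[1], med[2], med[3], med[4]))
  if (x$diagnostics$n_divergent > 0)
    cat(sprintf("  %d divergent transitions\n", x$diagnostics$n_divergent))
  invisible(x)
}

#' Population fixed-effect summary table
#'
#' Posterior median, posterior sd and central 95% quantiles for the four
#' fixed parameters on the natural (standardized-score) scale, in the
#' conventional reporting layout.
#'
#' @param fit A `"potential_fit"` object.
#' @return Data frame with rows `a_Intercept` .. `d_Intercept` and
#'   columns `Estimate`, `Est.Error`, `Q2.5`, `Q97.5`.
#' @export
summarize_fixed <- function(fit) {
  stopifnot(inherits(fit, "potential_fit"))
  f <- fit$draws$fixed
  out <- data.frame(
    Estimate = apply(f, 2, stats::median),
    Est.Error = apply(f, 2, stats::sd),
    Q2.5 = apply(f, 2, stats::quantile, probs = 0.025, names = FALSE),
    Q97.5 = apply(f, 2, stats::quantile, probs = 0.975, names = FALSE))
  rownames(out) <- paste0(c("a", "b", "c", "d"), "_Intercept")
  out
}

#' @export
summary.potential_fit <- function(object, ...) {
  out <- list(fixed = summarize_fixed(object),
              diagnostics = object$diagnostics,
              r2 = r_squared(object, random_effects = TRUE),
              r2_fixed = r_squared(object, random_effects = FALSE),
              n_individuals = length(object$individuals),
              n_records = nrow(object$training),
              config = object$config)
  class(out) <- "summary.potential_fit"
  out
}

#' @export
print.summary.potential_fit <- function(x, ...) {
  cat("Hierarchical age-performance potential fit\n")
  cat(sprintf("  %d individuals, %d best-per-age records\n",
              x$n_individuals, x$n_records))
  cat(sprintf("  %d chains x %d draws (warmup %d)\n\n",
              x$config$chains, x$config$iter, x$config$warmup))
  print(round(x$fixed, 7))
  cat(sprintf("\nR-squared: %.3f with random effects, %.3f fixed-only (OLS)\n",
              x$r2, x$r2_fixed))
  dt <- x$diagnostics$table
  cat(sprintf("max R-hat %.3f, min ESS %.0f, %d divergent\n",
              max(dt$rhat, na.rm = TRUE), min(dt$ess, na.rm = TRUE),
              x$diagnostics$n_divergent))
  if (length(x$diagnostics$flagged_rhat))
    cat("R-hat > 1.05 flagged for:",
        paste(x$diagnostics$flagged_rhat, collapse = ", "), "\n")
  invisible(x)
}

#' Extract coefficients from a potential fit
#'
#' @param object A `"potential_fit"`.
#' @param type `"fixed"` (posterior medians of a, b, c, d) or
#'   `"individual"` (matrix of per-individual median effective
#'   quadruplets, the clustering input).
#' @param ... Ignored.
#' @export
coef.potential_fit <- function(object, type = c("fixed", "individual"), ...) {
  type <- match.arg(type)
  if (type == "fixed") apply(object$draws$fixed, 2, stats::median)
  else median_params(object)
}

#' Coefficient of determination of the potential model
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} on the standardized best-per-age
#' training table. With random effects, each individual's own posterior
#' median quadruplet predicts their records; without, the pooled OLS
#' prefit predicts everyone.
#'
#' @param fit A `"potential_fit"`.
#' @param random_effects Use per-individual parameters (default) or the
#'   fixed-only OLS baseline.
#' @param adjusted Penalize by the number of free curve parameters.
#' @return A single numeric value.
#' @export
r_squared <- function(fit, random_effects = TRUE, adjusted = FALSE) {
  stopifnot(inherits(fit, "potential_fit"))
  y <- fit$std_table$score_std
  pred <- predict_std(fit, random_effects)
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  if (adjusted) {
    n <- length(y)
    p <- if (random_effects) 4L * (1L + length(fit$individuals)) else 4L
    r2 <- 1 - (1 - r2) * (n - 1) / max(1L, n - p - 1L)
  }
  r2
}

predict_std <- function(fit, random_effects = TRUE) {
  t <- fit$std_table$age_std
  if (!random_effects) return(moore_eval(fit$ols$params, t))
  med <- median_params(fit)
  i <- match(fit$std_table$individual_id, rownames(med))
  med[i, "a"] * exp(-med[i, "b"] * t) + med[i, "c"] * exp(med[i, "d"] * t)
}

#' Predicted potential scores
#'
#' Posterior-median potential (raw points) at given raw ages, for the
#' population curve or one individual.
#'
#' @param object A `"potential_fit"`.
#' @param ages Numeric vector of raw ages; defaults to the training span
#'   in 0.1-year steps.
#' @param individual `NULL` for the population, else one individual id.
#' @param ... Ignored.
#' @return Data frame with columns `age` and `score`.
#' @export
predict.potential_fit <- function(object, ages = NULL, individual = NULL,
                                  ...) {
  pc <- potential_curve(object, individual = individual, ages = ages)
  data.frame(age = pc$age, score = pc$median)
}

#' @export
fitted.potential_fit <- function(object, ...) {
  destandardize_score(object$standardization, predict_std(object, TRUE))
}

#' Residuals of a potential fit
#'
#' Observed minus posterior-median predicted best-per-age score.
#'
#' @param object A `"potential_fit"`.
#' @param scale `"raw"` (points) or `"standardized"`.
#' @param ... Ignored.
#' @export
residuals.potential_fit <- function(object,
                                    scale = c("raw", "standardized"), ...) {
  scale <- match.arg(scale)
  res_std <- object$std_table$score_std - predict_std(object, TRUE)
  if (scale == "standardized") res_std
  else res_std * object$standardization$score_sd
}

#' Posterior-predictive simulation of training scores
#'
#' For each simulation one posterior draw is chosen and new scores are
#' generated at the training ages from that draw's individual curves
#' plus Gaussian residual noise, then destandardized.
#'
#' @param object A `"potential_fit"`.
#' @param nsim Number of replicate datasets.
#' @param seed Optional seed.
#' @param ... Ignored.
#' @return Data frame: `individual_id`, `age`, one column `sim_k` per
#'   replicate (raw points).
#' @export
simulate.potential_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  eff <- object$draws$individual
  S <- dim(eff)[1L]
  t <- object$std_table$age_std
  i <- match(object$std_table$individual_id, object$individuals)
  out <- data.frame(individual_id = object$std_table$individual_id,
                    age = object$training$age)
  for (k in seq_len(nsim)) {
    s <- sample.int(S, 1L)
    mu <- eff[s, i, 1L] * exp(-eff[s, i, 2L] * t) +
          eff[s, i, 3L] * exp(eff[s, i, 4L] * t)
    y <- mu + stats::rnorm(length(t), 0, object$draws$sigma[s])
    out[[paste0("sim_", k)]] <-
      destandardize_score(object$standardization, y)
  }
  out
}

#' Plot a potential fit
#'
#' Median potential curve with its estimate interval, overlaid on the
#' best-per-age training records.
#'
#' @param x A `"potential_fit"`.
#' @param individual `NULL` for the population curve, else one id.
#' @param ... Passed to [plot.potential_curve()].
#' @export
plot.potential_fit <- function(x, individual = NULL, ...) {
  pc <- potential_curve(x, individual = individual)
  plot(pc, ...)
  tr <- x$training
  if (!is.null(individual)) tr <- tr[tr$individual_id == individual, ]
  graphics::points(tr$age, tr$score, pch = 16, cex = 0.5,
                   col = grDevices::adjustcolor("black", 0.6))
  invisible(x)
}
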