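test_that("OLS prefit recovers true parameters from noise-free data", {
  m <- table1_params()
  tab <- expand.grid(age_std = seq(-1.63, 1.63, length.out = 16),
                     rep = 1:3)
  tab$score_std <- moore_eval(m, tab$age_std)
  fit <- ols_prefit(tab)
  expect_equal(fit$params$a, m$a, tolerance = 1e-3)
  expect_equal(fit$params$b, m$b, tolerance = 1e-3)
  expect_equal(fit$params$c, m$c, tolerance = 1e-3)
  expect_equal(fit$params$d, m$d, tolerance = 1e-3)
  expect_lt(fit$rss, 1e-10)
})

test_that("OLS prefit beats random parameter draws and flags degeneracy", {
  set.seed(21)
  tab <- data.frame(age_std = rep(seq(-1.5, 1.5, length.out = 12), 2))
  tab$score_std <- moore_eval(table1_params(), tab$age_std) +
    rnorm(nrow(tab), 0, 0.05)
  fit <- ols_prefit(tab)
  rss_random <- replicate(100, {
    p <- moore(runif(1, 0.05, 2), runif(1, 0.1, 4),
               runif(1, 0.05, 2), runif(1, 0.05, 2))
    sum((tab$score_std - moore_eval(p, tab$age_std))^2)
  })
  expect_lte(fit$rss, min(rss_random))

  flat <- data.frame(age_std = seq(-1.5, 1.5, length.out = 12),
                     score_std = 1)
  expect_warning(ols_prefit(flat), "degenerate")
  expect_error(ols_prefit(data.frame(age_std = c(0, 1),
                                     score_std = c(1, 2))),
               "under-determined")
})

test_that("analytic log-posterior gradient matches finite differences", {
  set.seed(31)
  N <- 4; M <- 30
  idx <- sample.int(N, M, replace = TRUE) - 1L
  t <- runif(M, -1.6, 1.6)
  y <- moore_eval(table1_params(), t) + rnorm(M, 0, 0.1)
  pm <- c(0.5, log(2.3), 0.9, log(0.18)); ps <- rep(1, 4)
  theta <- rnorm(9 + 4 * N, 0, 0.3)
  res <- skipotential:::.logpost_grad(theta, y, t, as.integer(idx), N,
                                      pm, ps, 1, 1)
  h <- 1e-6
  for (j in seq_along(theta)) {
    e <- numeric(length(theta)); e[j] <- h
    up <- skipotential:::.logpost_grad(theta + e, y, t, as.integer(idx), N,
                                       pm, ps, 1, 1)$lp
    dn <- skipotential:::.logpost_grad(theta - e, y, t, as.integer(idx), N,
                                       pm, ps, 1, 1)$lp
    expect_equal(res$grad[j], (up - dn) / (2 * h),
                 tolerance = 1e-4, label = paste("gradient component", j))
  }
})

test_that("the sampler is deterministic given the seed and keeps draw counts", {
  sf <- small_fit()
  fit <- sf$fit
  S <- fit$config$chains * fit$config$iter
  expect_equal(nrow(fit$draws$fixed), S)
  expect_equal(dim(fit$draws$individual),
               c(S, length(fit$individuals), 4L))
  # every retained quadruplet defines a U-shaped curve
  expect_true(all(fit$draws$individual[, , 2] > 0))
  expect_true(all(fit$draws$individual[, , 4] > 0))

  refit <- fit_potential(sf$cohort$records,
                         standardization = sf$cohort$truth$standardization,
                         chains = 2, iter = 60, warmup = 200, seed = 402,
                         quiet = TRUE)
  expect_identical(summarize_fixed(refit), summarize_fixed(fit))
  expect_identical(refit$draws$sigma, fit$draws$sigma)
})

test_that("summarize_fixed reports median, sd and 95% quantiles in the
           conventional layout", {
  f1 <- fake_fit(array(1, dim = c(10, 2, 4)),
                 fixed = matrix(2, 10, 4,
                                dimnames = list(NULL, c("a", "b", "c", "d"))))
  tab <- summarize_fixed(f1)
  expect_identical(rownames(tab), c("a_Intercept", "b_Intercept",
                                    "c_Intercept", "d_Intercept"))
  expect_identical(colnames(tab), c("Estimate", "Est.Error", "Q2.5", "Q97.5"))
  expect_equal(tab$Est.Error, rep(0, 4))
  expect_true(all(tab$Estimate == 2 & tab$Q2.5 == 2 & tab$Q97.5 == 2))

  set.seed(41)
  fx <- matrix(rep(c(1, 2, 1, 1), each = 800), 800, 4)
  fx[, 2] <- rnorm(800)
  f2 <- fake_fit(array(1, dim = c(800, 1, 4)), fixed = fx)
  tab2 <- summarize_fixed(f2)
  expect_equal(tab2["b_Intercept", "Q2.5"], -1.96, tolerance = 0.15)
  expect_equal(tab2["b_Intercept", "Q97.5"], 1.96, tolerance = 0.15)
  expect_equal(tab2["b_Intercept", "Est.Error"], 1, tolerance = 0.1)
})

test_that("hierarchical R-squared exceeds the fixed-only baseline on a
           heterogeneous cohort", {
  sf <- small_fit()
  r2_re <- r_squared(sf$fit, random_effects = TRUE)
  r2_fix <- r_squared(sf$fit, random_effects = FALSE)
  expect_gt(r2_re, r2_fix)
  expect_lte(r2_re, 1)
  expect_lt(r_squared(sf$fit, adjusted = TRUE), r2_re)
})

test_that("random-effect scales shrink toward zero on a pooled cohort", {
  # rich per-individual data (four clean results per age, no filtering)
  # so the individual amplitudes are well identified
  spec <- cohort_spec(n_individuals = 30, results_per_age = 4,
                      random_effect_sds = c(0, 0, 0, 0),
                      counter_performance = list(prob = 0, mean = 0.5),
                      residual_sd = 0.1)
  cohort <- simulate_cohort(spec, seed = 51)
  fit <- fit_potential(cohort$records,
                       standardization = cohort$truth$standardization,
                       chains = 2, iter = 80, warmup = 250, seed = 52,
                       best_filter = FALSE, quiet = TRUE)
  tau_q95 <- apply(fit$draws$tau, 2, stats::quantile, probs = 0.95)
  sigma_med <- stats::median(fit$draws$sigma)
  # the early-amplitude scale is sharply identified (its regressor
  # e^{-bt} is large over the age span) and collapses below a tenth of
  # the residual scale
  expect_lt(tau_q95[["tau_a"]], 0.1 * sigma_med)
  # the late-amplitude regressor is O(1), so tau_c can only shrink to
  # the per-individual standard-error floor; it must still end far
  # below the heterogeneity a realistic cohort carries (sd 0.08)
  expect_lt(tau_q95[["tau_c"]], 0.02)
  expect_lt(tau_q95[["tau_b"]], 0.05)
})

test_that("diagnostics expose split R-hat near 1 for well-mixed chains and
           detect disagreement", {
  set.seed(61)
  good <- lapply(1:4, function(i) rnorm(500))
  expect_lt(skipotential:::split_rhat(good), 1.02)
  bad <- list(rnorm(500), rnorm(500) + 5)
  expect_gt(skipotential:::split_rhat(bad), 1.5)
  expect_gt(skipotential:::ess_basic(good), 500)
})
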