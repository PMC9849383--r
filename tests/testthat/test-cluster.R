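test_that("median_params takes component-wise medians of the effective
           quadruplets", {
  arr <- array(1.5, dim = c(5, 3, 4))
  f <- fake_fit(arr)
  expect_true(all(median_params(f) == 1.5))

  arr2 <- array(rep(c(1, 2, 3), each = 1), dim = c(3, 2, 4))
  arr2[, , ] <- c(1, 2, 3)  # draws {1,2,3} for every component
  expect_true(all(median_params(fake_fit(arr2)) == 2))

  set.seed(81)
  for (r in 1:50) {
    n_draw <- sample(5:20, 1)
    arr3 <- array(rnorm(n_draw * 2 * 4), dim = c(n_draw, 2, 4))
    m <- median_params(fake_fit(arr3))
    naive <- apply(arr3, c(2, 3), function(x) {
      s <- sort(x); n <- length(s)
      if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
    })
    expect_equal(unname(m), unname(naive), tolerance = 1e-12)
  }
})

test_that("the covariance family has 14 members", {
  expect_length(covariance_family(), 14L)
})

test_that("mixture family fits recover well-separated blobs", {
  set.seed(82)
  mix <- toy_mixture(delta = 6)
  lab <- rep(1:2, each = 60)
  x <- t(mix$means[, lab]) + matrix(rnorm(120 * 4, 0, sqrt(0.2)), 120)
  cands <- fit_mixture_family(x, K = 2, parameterizations = c("EII", "VVV"))
  expect_gte(length(cands), 1L)
  for (cand in cands) {
    expect_gte(mclust::adjustedRandIndex(cand$classification, lab), 0.95)
    expect_equal(sum(cand$weights), 1, tolerance = 1e-9)
    for (k in 1:2)
      expect_true(all(eigen(cand$sigma[, , k])$values > 0))
  }
})

test_that("K = 1 reduces to the pooled Gaussian and constrained models are
           nested in likelihood", {
  set.seed(83)
  x <- matrix(rnorm(200 * 4), 200)
  x[, 1] <- x[, 1] * 3  # anisotropic
  one <- fit_mixture_family(x, K = 1, parameterizations = "VVV")[[1]]
  expect_equal(drop(one$means), colMeans(x), tolerance = 1e-6)
  expect_equal(one$sigma[, , 1], cov(x) * (200 - 1) / 200,
               tolerance = 1e-4, ignore_attr = TRUE)

  both <- fit_mixture_family(x, K = 2, parameterizations = c("EII", "VVV"))
  ll <- vapply(both, `[[`, 0, "loglik")
  names(ll) <- vapply(both, `[[`, "", "parameterization")
  expect_lt(ll[["EII"]], ll[["VVV"]])
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  set.seed(84)
  x <- rbind(matrix(rnorm(80, 0, 1), 20), matrix(rnorm(80, 3, 1), 20))
  z0 <- cbind(runif(40, 0.3, 0.7))
  z0 <- cbind(z0, 1 - z0)
  ll <- vapply(1:6, function(it) {
    mclust::me(data = x, modelName = "EII", z = z0,
               control = mclust::emControl(itmax = it, tol = 0))$loglik
  }, 0)
  expect_true(all(diff(ll) >= -1e-8))
})

test_that("raw slopes apply the chain rule through the standardization", {
  spec <- standardization(17.5, 4.6, 120, 20, 0)
  m <- table1_params()
  age <- 15
  s <- raw_slopes(matrix(unlist(m[1:4]), 1), spec, age)
  expect_equal(drop(s),
               moore_deriv(m, standardize_age(spec, age)) *
                 spec$score_sd / spec$age_sd,
               tolerance = 1e-12)
})

test_that("slope densities integrate to one and track known distributions", {
  spec <- standardization(17.5, 4.6, 120, 20, 0)
  cohort <- typology_truth()
  dens <- slope_densities(cohort$truth$quadruplets, cohort$truth$cluster,
                          cohort$truth$standardization, ages = c(12, 15))
  for (da in dens) for (d in da) {
    area <- overlap_coefficient(d$grid, d$density, d$density)
    expect_equal(area, 1, tolerance = 1e-3)
  }

  # a cluster of identical members is handled by the bandwidth floor
  ident <- matrix(rep(unlist(table1_params()[1:4]), each = 6), 6)
  dens2 <- slope_densities(rbind(ident, ident + 0.3),
                           rep(1:2, each = 6), spec, ages = 15)
  expect_true(all(is.finite(dens2[[1]][["1"]]$density)))

  # KDE of normal slopes recovers the mean within 3 standard errors
  set.seed(85)
  n <- 400
  target <- rnorm(n, -2, 0.5)
  d <- skipotential:::kde_on_grid(target, seq(-5, 1, length.out = 2048), 1)
  kde_mean <- sum(d$grid * d$density) * diff(d$grid)[1]
  expect_lt(abs(kde_mean - (-2)), 3 * 0.5 / sqrt(n))
})

test_that("overlap coefficient matches the closed form for Gaussian pairs", {
  grid <- seq(-10, 12, length.out = 4001)
  f0 <- dnorm(grid, 0, 1)
  expect_equal(overlap_coefficient(grid, f0, f0), 1, tolerance = 1e-3)
  expect_equal(overlap_coefficient(grid, dnorm(grid, -6, 0.3),
                                   dnorm(grid, 8, 0.3)), 0,
               tolerance = 1e-6)
  set.seed(86)
  for (i in 1:20) {
    delta <- runif(1, 0.2, 4); sd <- runif(1, 0.3, 2)
    ovl <- overlap_coefficient(grid, dnorm(grid, 0, sd),
                               dnorm(grid, delta, sd))
    expect_equal(ovl, 2 * pnorm(-delta / (2 * sd)), tolerance = 1e-3)
  }
})

test_that("overlap integral agrees with a Monte-Carlo estimate", {
  set.seed(87)
  for (i in 1:10) {
    m1 <- runif(1, -1, 1); s1 <- runif(1, 0.5, 1.5)
    m2 <- runif(1, -1, 1); s2 <- runif(1, 0.5, 1.5)
    grid <- seq(min(m1, m2) - 6 * max(s1, s2),
                max(m1, m2) + 6 * max(s1, s2), length.out = 4001)
    ovl <- overlap_coefficient(grid, dnorm(grid, m1, s1),
                               dnorm(grid, m2, s2))
    # int min(f, g) = E_f[ min(1, g/f) ]
    n <- 20000
    x1 <- rnorm(n, m1, s1)
    ratio <- pmin(1, dnorm(x1, m2, s2) / dnorm(x1, m1, s1))
    est <- mean(ratio)
    se <- stats::sd(ratio) / sqrt(n)
    expect_lt(abs(ovl - est), 3 * se + 1e-3)
  }
})

test_that("overlap score is symmetric under relabeling and bounded", {
  cohort <- typology_truth()
  q <- cohort$truth$quadruplets
  cl <- cohort$truth$cluster
  spec <- cohort$truth$standardization
  s1 <- overlap_score(q, cl, spec, ages = c(12, 15, 18))
  perm <- c(3, 1, 4, 2)[cl]
  s2 <- overlap_score(q, perm, spec, ages = c(12, 15, 18))
  expect_equal(s1, s2, tolerance = 1e-12)
  expect_gte(s1, 0); expect_lte(s1, 1 + 1e-9)
  expect_error(overlap_score(q, rep(1, nrow(q)), spec), "single cluster")
})

test_that("select_model prefers low overlap, then parsimony", {
  c1 <- list(parameterization = "VVV", K = 3, n_params = 40,
             overlap_score = 0.3)
  c2 <- list(parameterization = "EII", K = 3, n_params = 20,
             overlap_score = 0.1)
  c3 <- list(parameterization = "EEE", K = 2, n_params = 25,
             overlap_score = 0.1)
  expect_identical(select_model(list(c1)), c1)
  expect_identical(select_model(list(c1, c2, c3))$parameterization, "EII")
  # ties at equal parameters break to smaller K
  c4 <- list(parameterization = "EII", K = 2, n_params = 20,
             overlap_score = 0.1)
  expect_identical(select_model(list(c2, c4))$K, 2)
  # duplicating the winner does not change the selected score
  expect_equal(select_model(list(c1, c2, c2))$overlap_score, 0.1)
})

test_that("cluster_progressions recovers generative typologies from true
           quadruplets", {
  cohort <- typology_truth()
  cl <- cluster_progressions(cohort$truth$quadruplets, K = 2:6,
                             parameterizations = c("EII", "EEI", "EEE",
                                                   "VVI", "VVV"),
                             spec = cohort$truth$standardization)
  expect_equal(cl$selected$K, 4L)
  expect_gte(mclust::adjustedRandIndex(cl$classification,
                                       cohort$truth$cluster), 0.9)
  sizes <- tabulate(cl$classification, 4)
  expect_gt(max(sizes) / sum(sizes), 0.7)
})
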