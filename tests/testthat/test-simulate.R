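test_that("record counts follow the cohort design", {
  spec <- cohort_spec(n_individuals = 100, results_per_age = 3)
  cohort <- simulate_cohort(spec, seed = 101)
  expect_equal(nrow(cohort$records), 100 * 16 * 3)
  expect_equal(length(unique(cohort$records$individual_id)), 100L)
})

test_that("a noise-free pooled cohort lies exactly on the fixed-truth curve", {
  spec <- cohort_spec(n_individuals = 5, results_per_age = 2,
                      random_effect_sds = c(0, 0, 0, 0), residual_sd = 0,
                      counter_performance = list(prob = 0, mean = 0.5))
  cohort <- simulate_cohort(spec, seed = 102)
  best <- best_per_age(cohort$records)
  sspec <- cohort$truth$standardization
  expected <- destandardize_score(
    sspec, moore_eval(spec$fixed_truth, standardize_age(sspec, best$age)))
  expect_equal(best$score, expected, tolerance = 1e-9)
})

test_that("the default mean trajectory is U-shaped with an interior minimum", {
  spec <- cohort_spec()
  sspec <- spec$standardization
  ages <- seq(10, 25, by = 0.1)
  mean_curve <- destandardize_score(
    sspec, moore_eval(spec$fixed_truth, standardize_age(sspec, ages)))
  i <- which.min(mean_curve)
  expect_gt(i, 1); expect_lt(i, length(ages))
  expect_true(all(diff(mean_curve[1:i]) < 0))
  expect_true(all(diff(mean_curve[i:length(ages)]) > 0))
  # the minimum lands at the reference peak score by construction
  expect_equal(min(mean_curve), 141.37, tolerance = 0.02)
})

test_that("counter-performances only worsen scores and best-per-age filters
           them", {
  spec <- cohort_spec(n_individuals = 10, results_per_age = 4,
                      random_effect_sds = c(0, 0, 0, 0), residual_sd = 0,
                      counter_performance = list(prob = 1, mean = 0.5))
  cohort <- simulate_cohort(spec, seed = 103)
  sspec <- cohort$truth$standardization
  clean <- destandardize_score(
    sspec,
    moore_eval(spec$fixed_truth, standardize_age(sspec, cohort$records$age)))
  expect_true(all(cohort$records$score >= clean - 1e-9))

  # with contamination probability 0 and one result per age, best-per-age
  # returns the noisy sample unchanged
  spec2 <- cohort_spec(n_individuals = 6, results_per_age = 1,
                       counter_performance = list(prob = 0, mean = 0.5))
  cohort2 <- simulate_cohort(spec2, seed = 104)
  best2 <- best_per_age(cohort2$records)
  expect_equal(nrow(best2), nrow(cohort2$records))
  expect_equal(sort(best2$score), sort(cohort2$records$score))
})

test_that("generation is deterministic under a fixed seed", {
  spec <- four_typology_preset(n_individuals = 50)
  c1 <- simulate_cohort(spec, seed = 105)
  c2 <- simulate_cohort(spec, seed = 105)
  expect_identical(c1$records, c2$records)
  expect_identical(c1$truth$quadruplets, c2$truth$quadruplets)
})

test_that("four-typology preset has a dominant cluster and distinct slopes", {
  spec <- four_typology_preset(n_individuals = 1000)
  cohort <- simulate_cohort(spec, seed = 106)
  sizes <- tabulate(cohort$truth$cluster, 4)
  expect_gt(sizes[1] / 1000, 0.7)

  # low-progression vs strong-progression slope densities barely overlap
  # at age 15 (computed on the generative truth)
  sel <- cohort$truth$cluster %in% c(2, 3)
  dens <- slope_densities(cohort$truth$quadruplets[sel, ],
                          cohort$truth$cluster[sel],
                          cohort$truth$standardization, ages = 15)
  ovl <- overlap_coefficient(dens[[1]][["2"]]$grid,
                             dens[[1]][["2"]]$density,
                             dens[[1]][["3"]]$density)
  expect_lt(ovl, 0.2)

  # every generated quadruplet supports an interior peak inside the range
  expect_true(all(cohort$truth$quadruplets > 0))
  expect_true(all(cohort$truth$peak_age > 10 & cohort$truth$peak_age < 25))
})

test_that("invalid typology components are rejected by name", {
  bad <- list(list(weight = 1, mean = c(0.5, -1, 0.8, 0.2),
                   sd = rep(0.01, 4)))
  expect_error(cohort_spec(typology_mixture = bad), "component 1")
})

test_that("cohorts round-trip through the CSV dialect read_records expects", {
  spec <- cohort_spec(n_individuals = 4, results_per_age = 1)
  cohort <- simulate_cohort(spec, seed = 107)
  path <- tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_records(path)
  expect_equal(nrow(back), nrow(cohort$records))
  expect_equal(back$score, cohort$records$score, tolerance = 1e-9)
})
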