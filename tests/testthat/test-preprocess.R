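test_that("read_records parses delimited text and preserves ids verbatim", {
  path <- write_temp_csv(c("id,age,points",
                           "A-01,15,120.5",
                           "A-01,16,95",
                           "B 2,14.5,210"))
  rec <- read_records(path)
  expect_equal(nrow(rec), 3L)
  expect_identical(rec$individual_id, c("A-01", "A-01", "B 2"))
  expect_equal(rec$score, c(120.5, 95, 210))
  expect_equal(attr(rec, "n_dropped"), 0L)
})

test_that("unparseable and non-positive rows are dropped with a count", {
  path <- write_temp_csv(c("id,age,points",
                           "A,15,120",
                           "A,16,",          # empty score
                           "B,abc,100",      # bad age
                           "C,14,-5"))       # non-positive score
  expect_message(rec <- read_records(path), "3 record")
  expect_equal(nrow(rec), 1L)
  expect_equal(attr(rec, "n_dropped"), 3L)
})

test_that("duplicate rows pass through and missing columns are named", {
  path <- write_temp_csv(c("id,age,points", "A,15,120", "A,15,120"))
  expect_equal(nrow(read_records(path)), 2L)
  path2 <- write_temp_csv(c("id,age", "A,15"))
  expect_error(read_records(path2), "points")
})

test_that("best_per_age keeps the minimum score per individual-age bin", {
  rec <- data.frame(individual_id = "X", age = c(15.1, 15.6, 15.9),
                    score = c(120, 95, 130))
  out <- best_per_age(rec)
  expect_equal(nrow(out), 1L)
  expect_equal(out$score, 95)

  two <- data.frame(individual_id = c("A", "B"), age = c(12, 14),
                    score = c(50, 60))
  expect_equal(best_per_age(two)$score, c(50, 60))
})

test_that("best_per_age ties break to the first-seen record", {
  rec <- data.frame(individual_id = "X", age = c(15.2, 15.8),
                    score = c(100, 100), season = c("s1", "s2"))
  expect_identical(best_per_age(rec)$season, "s1")
})

test_that("best_per_age yields one record per (individual, age-bin) on a
           10 x 5 x 3 cohort and bounds ages", {
  set.seed(1)
  rec <- expand.grid(individual_id = sprintf("s%02d", 1:10),
                     age = 11:15, rep = 1:3)
  rec$score <- runif(nrow(rec), 50, 300)
  out <- best_per_age(rec)
  expect_equal(nrow(out), 50L)
  # per-bin output score <= every input score in that bin
  for (i in sample(nrow(out), 10)) {
    bin <- rec[rec$individual_id == out$individual_id[i] &
               floor(rec$age) == out$age_bin[i], ]
    expect_true(all(out$score[i] <= bin$score))
  }
  # bounds: ages outside [10, 25] dropped
  rec2 <- data.frame(individual_id = "Y", age = c(9.9, 10, 25.4, 26),
                     score = c(1, 2, 3, 4))
  expect_equal(best_per_age(rec2)$age_bin, c(10L, 25L))
})

test_that("standardization centers, reduces and keeps scores positive", {
  rec <- data.frame(age = 10:25, score = runif(16, 80, 400))
  spec <- fit_standardization(rec)
  t <- standardize_age(spec, rec$age)
  expect_equal(mean(t), 0, tolerance = 1e-12)
  expect_equal(stats::sd(t), 1, tolerance = 1e-12)
  p <- standardize_score(spec, rec$score)
  expect_true(all(p > 0))
  # the minimum lands exactly at the epsilon margin
  expect_equal(min(p), 1e-3, tolerance = 1e-12)
})

test_that("standardization round-trips and preserves score order", {
  set.seed(7)
  rec <- data.frame(age = runif(100, 10, 25), score = runif(100, 50, 900))
  spec <- fit_standardization(rec)
  expect_equal(destandardize_age(spec, standardize_age(spec, rec$age)),
               rec$age, tolerance = 1e-9)
  expect_equal(destandardize_score(spec, standardize_score(spec, rec$score)),
               rec$score, tolerance = 1e-9)
  expect_identical(order(standardize_score(spec, rec$score)),
                   order(rec$score))
})

test_that("degenerate data is rejected", {
  expect_error(fit_standardization(data.frame(age = c(12, 12), score = c(1, 2))),
               "degenerate")
  expect_error(fit_standardization(data.frame(age = c(12, 13), score = c(5, 5))),
               "degenerate")
})

test_that("training table and transform sidecar round-trip through disk", {
  rec <- data.frame(individual_id = c("A", "B"), age = c(12, 17),
                    score = c(300, 120))
  spec <- fit_standardization(rec)
  std <- standardize_records(spec, rec)
  path <- tempfile(fileext = ".csv")
  write_training_table(std, spec, path)
  back <- utils::read.csv(path)
  expect_equal(back$score_std, std$score_std, tolerance = 1e-12)
  spec2 <- read_standardization(paste0(path, ".json"))
  expect_equal(unclass(spec2), unclass(spec), tolerance = 1e-12)
})
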