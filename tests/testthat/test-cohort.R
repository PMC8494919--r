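test_that("cohort generation is deterministic and respects the spec", {
  cs <- cohortSpec(nSubjects = 20, seed = 33)
  c1 <- generateCohort(cs)
  c2 <- generateCohort(cs)
  expect_identical(cohortRecords(c1), cohortRecords(c2))
  rec <- cohortRecords(c1)
  expect_true(all(rec$pdff >= 1 & rec$pdff <= 28))
  expect_true(all(rec$eit_mean > 0))
  expect_true(all(rec$bmi > 25))
  # BMI consistent with weight/height^2 within rounding
  expect_equal(rec$weight, round(rec$bmi * (rec$height / 100)^2, 1),
               tolerance = 0.02)
})

test_that("a noise-free linear map gives perfect negative correlation", {
  cs <- cohortSpec(nSubjects = 20, noiseSD = 0, seed = 5)
  rec <- cohortRecords(generateCohort(cs))
  expect_equal(cor(rec$eit_mean, rec$pdff), -1, tolerance = 1e-12)
})

test_that("cohort correlation follows the attenuation closed form", {
  # R = -1 / sqrt(1 + SD^2 / (b^2 Var(PDFF))), Var(PDFF) = 27^2/12 for the
  # uniform draw over 1-28
  a <- 0.355; b <- 0.003; sdN <- 0.012
  pred <- -1 / sqrt(1 + sdN^2 / (b^2 * 27^2 / 12))
  rs <- vapply(1:200, function(s) {
    rec <- cohortRecords(generateCohort(cohortSpec(
      nSubjects = 16, mapIntercept = a, mapSlope = b, noiseSD = sdN,
      seed = s)))
    cor(rec$eit_mean, rec$pdff)
  }, numeric(1))
  expect_lt(abs(median(rs) - pred), 0.15)
})

test_that("large conductivity noise attenuates the correlation below 0.3", {
  b <- 0.0021
  sdBig <- 5 * b * sqrt(27^2 / 12)   # >= 5x the signal SD
  rs <- vapply(1:100, function(s) {
    rec <- cohortRecords(generateCohort(cohortSpec(
      nSubjects = 16, mapSlope = b, mapIntercept = 0.45, noiseSD = sdBig,
      seed = 500 + s)))
    cor(rec$eit_mean, rec$pdff)
  }, numeric(1))
  expect_lt(abs(median(rs)), 0.3)
})

test_that("specs that could produce non-positive conductivity are rejected", {
  expect_error(cohortSpec(mapIntercept = 0.05, mapSlope = 0.003), "positive")
  expect_error(cohortSpec(mapSlope = -0.01), "decreasing")
  expect_error(cohortSpec(noiseSD = -1), "noiseSD")
})

test_that("subjectToPhantom substitutes the mapped conductivity and scales the waist", {
  cs <- cohortSpec()
  base <- referencePhantom()
  rec <- list(pdff = (cs@mapIntercept - 0.33) / cs@mapSlope, waist = 100)
  ph <- subjectToPhantom(rec, base, cs)
  liver <- ph@regions[[which(vapply(ph@regions, `[[`, character(1), "label") ==
                               "liver")]]
  expect_equal(liver$conductivity, 0.33, tolerance = 1e-12)
  expect_equal(polygonPerimeter(ph@outline), 100, tolerance = 1)
  # functional determinism: equal pdff, equal conductivity
  ph2 <- subjectToPhantom(list(pdff = rec$pdff, waist = 90), base, cs)
  expect_equal(ph2@regions[[1]]$conductivity, liver$conductivity)
  noLiver <- phantomSpec(base@outline, list())
  expect_error(subjectToPhantom(rec, noLiver, cs), "liver")
})

test_that("exclusion policies filter the flagged subjects", {
  cs <- cohortSpec(nSubjects = 50, exclusionRate = 0.3, seed = 12)
  cohort <- generateCohort(cs)
  all <- cohortRecords(cohort, applyPolicy = FALSE)
  n16 <- cohortRecords(setExclusionPolicy(cohort, "study_n16"))
  expect_equal(nrow(n16), sum(!all$excluded))
  n18 <- cohortRecords(setExclusionPolicy(cohort, "study_n18"))
  expect_equal(nrow(n18),
               nrow(all) - sum(all$excluded &
                                 all$exclusion_reason == "electrode_malfunction"))
})

test_that("cohort CSV round-trips losslessly", {
  cohort <- generateCohort(cohortSpec(nSubjects = 8, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  writeCohort(cohort, path)
  back <- readCohort(path)
  expect_identical(back@records$pdff, cohort@records$pdff)
  expect_identical(back@records$eit_mean, cohort@records$eit_mean)
  expect_identical(back@records$excluded, cohort@records$excluded)
  writeLines("subject,pdff", path)
  expect_error(readCohort(path), "empty")
})
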