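test_that("shipped scoring tables load and their bands partition the range", {
  for (nm in c("caide", "framingham_cvd", "framingham_stroke")) {
    tb <- load_scoring_table(nm)
    expect_s3_class(tb, "scoring_table")
    expect_true(all(tb$points == round(tb$points)))
    # within each component stratum, band points are monotone in band order
    # (risk factors increase points; protective factors like education
    # decrease them — either way, never oscillating)
    key <- paste(tb$component, tb$sex, tb$condition_field,
                 tb$condition_value)
    for (k in unique(key[tb$type == "band"])) {
      rows <- tb[key == k & tb$type == "band", ]
      rows <- rows[order(rows$low), ]
      dp <- diff(rows$points)
      expect_true(all(dp >= 0) || all(dp <= 0), info = paste(nm, k))
    }
  }
})

test_that("a gap or overlap in a band partition is rejected at load", {
  tb <- utils::read.csv(system.file("extdata", "scoring_tables", "caide.csv",
                                    package = "atnpredict"))
  tb$high[tb$component == "age" & tb$low == 0] <- 46   # creates a gap
  tf <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tb, tf, row.names = FALSE, na = "")
  expect_error(load_scoring_table(tf), "gap or overlap")
  tb2 <- utils::read.csv(system.file("extdata", "scoring_tables",
                                     "caide.csv", package = "atnpredict"))
  tb2 <- tb2[!(tb2$component == "sex" & tb2$flag_value == 0), ]
  tf2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tb2, tf2, row.names = FALSE, na = "")
  expect_error(load_scoring_table(tf2), "flag")
})

test_that("CAIDE sums its seven components; self-reported cholesterol adds 2", {
  # hand-summed worked profile: age 66 (4) + female (0) + 8 y education (2)
  # + SBP 150 (2) + BMI 31 (2) + cholesterol (2) + inactive (1) = 13
  worked <- base_record(age = 66, sex_female = 1L, education_years = 8,
                        systolic_bp = 150, bmi = 31, high_cholesterol = 1L,
                        physical_inactivity = 1L)
  expect_equal(caide_score(worked)$raw_points, 13)
  with_chol <- caide_score(base_record(high_cholesterol = 1L))$raw_points
  without <- caide_score(base_record(high_cholesterol = 0L))$raw_points
  expect_equal(with_chol - without, 2)
  minimum <- base_record(age = 45, sex_female = 1L, education_years = 16,
                         systolic_bp = 120, bmi = 24, high_cholesterol = 0L,
                         physical_inactivity = 0L)
  expect_equal(caide_score(minimum)$raw_points, 0)
})

test_that("Framingham CVD is sex-specific and maps cholesterol to diabetes points", {
  prof <- base_record(age = 62, systolic_bp = 150, bp_medication = 0L,
                      ever_smoked = 1L, diabetes = 0L, high_cholesterol = 0L)
  f <- framingham_cvd_score(prof)$raw_points
  m <- framingham_cvd_score(base_record(age = 62, systolic_bp = 150,
                                        bp_medication = 0L, ever_smoked = 1L,
                                        sex_female = 0L))$raw_points
  # female: age 9 + SBP 4 + smoker 3 = 16; male: 11 + 2 + 4 = 17
  expect_equal(f, 16)
  expect_equal(m, 17)
  # cholesterol awards the sex-specific diabetes points
  dfem <- framingham_cvd_score(base_record(high_cholesterol = 1L))$raw_points -
    framingham_cvd_score(base_record(high_cholesterol = 0L))$raw_points
  dmal <- framingham_cvd_score(base_record(sex_female = 0L,
                                           high_cholesterol = 1L))$raw_points -
    framingham_cvd_score(base_record(sex_female = 0L,
                                     high_cholesterol = 0L))$raw_points
  expect_equal(dfem, 4)
  expect_equal(dmal, 3)
  # treated and untreated SBP use different bands
  treated <- framingham_cvd_score(base_record(bp_medication = 1L))$raw_points
  untreated <- framingham_cvd_score(base_record(bp_medication = 0L))$raw_points
  expect_gt(treated, untreated)
  # all-lowest-band female profile reaches the table minimum of -3
  lowest <- base_record(age = 32, systolic_bp = 110, bp_medication = 0L,
                        ever_smoked = 0L, diabetes = 0L, high_cholesterol = 0L)
  expect_equal(framingham_cvd_score(lowest)$raw_points, -3)
})

test_that("Framingham stroke sums eight components with LVH defaulting to absent", {
  dmal <- framingham_stroke_score(
    base_record(sex_female = 0L, prior_cvd = 1L))$raw_points -
    framingham_stroke_score(base_record(sex_female = 0L,
                                        prior_cvd = 0L))$raw_points
  dfem <- framingham_stroke_score(base_record(prior_cvd = 1L))$raw_points -
    framingham_stroke_score(base_record(prior_cvd = 0L))$raw_points
  expect_equal(dmal, 4)
  expect_equal(dfem, 2)
  # missing LVH is scored as absent (complete result)
  rec <- base_record()
  rec$left_ventricular_hypertrophy <- NA_integer_
  res <- framingham_stroke_score(rec)
  expect_false(res$incomplete)
  expect_equal(res$raw_points,
               framingham_stroke_score(base_record())$raw_points)
  # but a missing atrial fibrillation flag makes the score incomplete
  res2 <- framingham_stroke_score(base_record(atrial_fibrillation = NA))
  expect_true(res2$incomplete)
  expect_true(is.na(res2$raw_points))
})

test_that("a missing required field yields an incomplete result, not an error", {
  res <- caide_score(base_record(bmi = NA))
  expect_true(res$incomplete)
  expect_true(is.na(res$raw_points))
  res2 <- framingham_cvd_score(base_record(sex_female = NA))
  expect_true(res2$incomplete)
  # conditioned SBP bands need the treatment flag
  res3 <- framingham_cvd_score(base_record(bp_medication = NA))
  expect_true(res3$incomplete)
})

test_that("scores are bounded by the table totals and monotone in each component", {
  cohort <- small_analytic_cohort(seed = 13)
  for (scorer in list(caide_score, framingham_cvd_score,
                      framingham_stroke_score)) {
    res <- scorer(cohort)
    tb <- load_scoring_table(res$score_name[1])
    mx <- scoring_table_max(tb)
    expect_true(all(res$raw_points <= mx, na.rm = TRUE))
    expect_true(all(res$raw_points == round(res$raw_points), na.rm = TRUE))
  }
  # worsening any single flag never decreases the total
  flags <- c("high_cholesterol", "physical_inactivity", "ever_smoked",
             "diabetes", "prior_cvd", "atrial_fibrillation")
  for (fl in flags) {
    lo <- base_record(); lo[[fl]] <- 0L
    hi <- base_record(); hi[[fl]] <- 1L
    for (scorer in list(caide_score, framingham_cvd_score,
                        framingham_stroke_score))
      expect_gte(scorer(hi)$raw_points, scorer(lo)$raw_points)
  }
})

test_that("z-standardisation centres and scales complete results only", {
  z <- standardize_scores(c(4, 6))
  expect_equal(z, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  x <- c(3, 7, 5, NA, 9)
  z2 <- standardize_scores(x)
  expect_true(is.na(z2[4]))
  expect_equal(mean(z2, na.rm = TRUE), 0, tolerance = 1e-10)
  expect_equal(sd(z2, na.rm = TRUE), 1, tolerance = 1e-10)
  expect_error(standardize_scores(c(5, 5, 5)), "zero variance")
  expect_error(standardize_scores(c(1, NA)), "at least 2")
})
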