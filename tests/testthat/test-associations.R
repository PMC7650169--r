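make_flag_cohort <- function(d, flag) {
  d$a_flag <- as.logical(d[[flag]])
  d
}

test_that("an unadjusted two-by-two fit equals the cross-product odds ratio", {
  # counts: exposed cases 20, exposed controls 30, unexposed cases 10,
  # unexposed controls 40 -> OR = (20*40)/(30*10)
  d <- data.frame(
    x = rep(c(1, 1, 0, 0), times = c(20, 30, 10, 40)),
    y = rep(c(1, 0, 1, 0), times = c(20, 30, 10, 40)))
  d$a_flag <- as.logical(d$y)
  res <- fit_pathology_logistic(d, "A+", "x", covariates = NULL)
  expect_equal(res$estimate, (20 * 40) / (30 * 10), tolerance = 1e-6)
  expect_equal(res$n_used, 100L)
  expect_false(res$non_estimable)
})

test_that("a null exposure at large n gives an odds ratio near one", {
  d <- generate_from_model(
    50000, list(x = list(dist = "bernoulli", p = 0.5),
                age = list(dist = "normal", mean = 65, sd = 7),
                sex_female = list(dist = "bernoulli", p = 0.6)),
    c("(Intercept)" = -0.8, x = 0, age = 0, sex_female = 0), seed = 71)
  d$a_flag <- as.logical(d$y)
  res <- fit_pathology_logistic(d, "A+", "x")
  expect_gt(res$estimate, 0.95)
  expect_lt(res$estimate, 1.05)
})

test_that("complete separation is reported as non-estimable, not an error", {
  d <- data.frame(x = rep(c(0, 1), each = 30),
                  a_flag = rep(c(FALSE, TRUE), each = 30))
  res <- suppressWarnings(
    fit_pathology_logistic(d, "A+", "x", covariates = NULL))
  expect_true(res$non_estimable)
})

test_that("too few complete rows raise an insufficient-data error", {
  d <- data.frame(x = c(0, 1, NA), age = c(60, 70, 65),
                  sex_female = c(1, 0, 1),
                  a_flag = c(TRUE, FALSE, TRUE))
  expect_error(fit_pathology_logistic(d, "A+", "x"), "insufficient")
})

test_that("the multinomial fit reduces to binary logistic on two groups", {
  set.seed(72)
  n <- 800
  d <- data.frame(age = rnorm(n, 65, 7), sex_female = rbinom(n, 1, .6),
                  x = rbinom(n, 1, .4))
  p <- plogis(-1 + 0.6 * d$x + 0.02 * (d$age - 65))
  d$atn_group <- factor(ifelse(runif(n) < p, "alzheimers_disease",
                               "normal_ad_biomarkers"))
  multi <- fit_multinomial(d, "x", include_site = FALSE, reltol = 1e-16)
  glmfit <- stats::glm(atn_group == "alzheimers_disease" ~ x + age +
                         sex_female, data = d, family = binomial())
  or <- exp(coef(glmfit)[["x"]])
  expect_equal(multi$estimate, or, tolerance = 1e-6)
  expect_equal(multi$estimate_type, "RRR")
  expect_equal(multi$reference, "normal_ad_biomarkers")
})

test_that("effect estimates are invariant to recoding the sex covariate", {
  d <- small_analytic_cohort(seed = 23)
  a <- fit_multinomial(d, "apoe4_carrier", include_site = FALSE,
                       reltol = 1e-12)
  d$sex_male <- 1 - d$sex_female
  b <- fit_multinomial(d, "apoe4_carrier", include_site = FALSE,
                       covariates = c("age", "sex_male"), reltol = 1e-12)
  expect_equal(a$estimate, b$estimate, tolerance = 1e-4)
})

test_that("age- and sex-adjusted amyloid model recovers its generating APOE4 odds ratio", {
  covs <- list(age = list(dist = "normal", mean = 64.6, sd = 6.8),
               sex_female = list(dist = "bernoulli", p = 0.59),
               apoe4_carrier = list(dist = "bernoulli", p = 0.375))
  gen <- c("(Intercept)" = 0, age = log(1.03), sex_female = 0,
           apoe4_carrier = log(2.24))
  probe <- generate_from_model(100000, covs, gen, seed = 73, outcome = "y")
  eta <- log(1.03) * probe$age + log(2.24) * probe$apoe4_carrier
  gen[["(Intercept)"]] <- calibrate_logit_intercept(eta, 0.306)
  d <- generate_from_model(100000, covs, gen, seed = 73, outcome = "y")
  expect_lt(abs(mean(d$y) - 0.306), 0.01)
  d$a_flag <- as.logical(d$y)
  res <- fit_pathology_logistic(d, "A+", "apoe4_carrier")
  expect_lt(abs(res$estimate / 2.24 - 1), 0.05)
  expect_true(res$ci_low <= res$estimate && res$estimate <= res$ci_high)
})

test_that("the interaction scan recovers a nonzero product coefficient", {
  covs <- list(x = list(dist = "normal", mean = 0, sd = 1),
               apoe4_carrier = list(dist = "bernoulli", p = 0.4),
               age = list(dist = "normal", mean = 65, sd = 7),
               sex_female = list(dist = "bernoulli", p = 0.6))
  cf <- rbind(g2 = c("(Intercept)" = -1.2, x = 0.2, apoe4_carrier = 0.3,
                     "x:apoe4_carrier" = 0.5))
  d <- generate_from_model(100000, covs, cf, seed = 74,
                           outcome = "atn_group")
  res <- interaction_scan(d, "x", "apoe4_carrier", include_site = FALSE)
  expect_lt(abs(log(res$estimate) - 0.5), 0.05)
  expect_lt(res$p_value, 1e-10)
})

test_that("a constant moderator is non-estimable", {
  d <- small_analytic_cohort(seed = 31)
  d$apoe4_carrier <- 1L
  expect_error(interaction_scan(d, "bmi", "apoe4_carrier"),
               "non-estimable")
})

test_that("product-term p-values are uniform under the null", {
  ps <- vapply(1:200, function(s) {
    covs <- list(x = list(dist = "normal", mean = 0, sd = 1),
                 m = list(dist = "bernoulli", p = 0.5))
    cf <- rbind(g2 = c("(Intercept)" = -0.3, x = 0.3, m = 0.2),
                g3 = c("(Intercept)" = -0.8, x = -0.2, m = 0.1))
    d <- generate_from_model(600, covs, cf, seed = 9000 + s,
                             outcome = "atn_group", reference = "ref")
    interaction_scan(d, "x", "m", include_site = FALSE,
                     covariates = NULL, reference = "ref",
                     reltol = 1e-10)$p_value[1]
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("group comparison of a continuous variable matches ANOVA with capped Bonferroni", {
  d <- small_analytic_cohort(seed = 17)
  res <- compare_groups(d, "bmi")
  expect_equal(res$test, "anova")
  oracle <- stats::oneway.test(bmi ~ atn_group, data = d, var.equal = TRUE)
  expect_equal(res$omnibus_statistic, unname(oracle$statistic),
               tolerance = 1e-10)
  expect_equal(res$omnibus_p, oracle$p.value, tolerance = 1e-10)
  expect_equal(nrow(res$pairwise), 10L)
  expect_true(all(res$pairwise$p_bonferroni <= 1))
  expect_true(all(res$pairwise$p_bonferroni >=
                    pmin(1, res$pairwise$p_raw * 10) - 1e-12))
})

test_that("adjusted residuals vanish on an exact-independence table", {
  g <- rep(atn_groups()[1:5], each = 10)
  x <- rep(rep(c(0, 1), times = c(6, 4)), times = 5)
  d <- data.frame(atn_group = g, v = x)
  res <- compare_groups(d, "v")
  expect_equal(res$test, "chi_square")
  expect_true(all(abs(res$adjusted_residuals) < 1e-12))
  expect_false(any(res$significant_cells))
})

test_that("adjusted residuals match the independent textbook implementation", {
  set.seed(77)
  tab <- matrix(rpois(10, 30) + 1, nrow = 2)
  R <- adjusted_residuals(tab)
  oracle <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$stdres
  expect_equal(unname(R), unname(as.matrix(oracle)), tolerance = 1e-12)
  # deviations balance over both margins
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(rowSums(tab - E), c(0, 0), tolerance = 1e-9)
  expect_equal(colSums(tab - E), rep(0, 5), tolerance = 1e-9)
})

test_that("small expected cells attach a warning flag", {
  d <- data.frame(atn_group = rep(c("a", "b"), times = c(100, 3)),
                  v = c(rep(0, 100), 0, 0, 1))
  res <- compare_groups(d, "v")
  expect_true(res$small_cell_warning)
})

test_that("Bonferroni thresholds follow the family arithmetic", {
  expect_equal(bonferroni_threshold(0.5, 21), 0.5 / 21)
  expect_equal(round(bonferroni_threshold(0.5, 21), 3), 0.024)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 84), 0.05 / 84)
  expect_error(bonferroni_threshold(1.2, 3))
  expect_error(bonferroni_threshold(0.05, 0))
})
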