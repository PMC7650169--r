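#' Nested prediction-model specifications for one pathology contrast
#'
#' Emits the nine logistic model specifications used to discriminate one
#' pathology group from the normal-AD-biomarkers group: model 1 (age, sex,
#' APOE4), models 2–5 adding family history, BMI, WML volume and MMSE in
#' turn, model 6 with all of them, and models 7a–c adding each z-scored
#' composite risk score. For the Alzheimer's-pathologic-change contrast
#' only, every model additionally carries age-by-APOE4 and sex-by-MMSE
#' product terms.
#'
#' @param contrast One of the four non-reference groups of [atn_groups()].
#' @return Named list (`m1`, `m2_family`, `m3_bmi`, `m4_wml`, `m5_mmse`,
#'   `m6_all`, `m7a_caide`, `m7b_fcvd`, `m7c_stroke`) of character vectors
#'   of model terms.
#' @export
build_model_set <- function(contrast = c("alzheimers_disease",
                                         "alzheimers_pathologic_change",
                                         "ad_and_non_ad_pathologic_change",
                                         "non_ad_pathologic_change")) {
  contrast <- match.arg(contrast)
  base <- c("age", "sex_female", "apoe4_carrier")
  if (contrast == "alzheimers_pathologic_change")
    base <- c(base, "age:apoe4_carrier", "sex_female:mmse_total")
  list(
    m1 = base,
    m2_family = c(base, "family_history"),
    m3_bmi = c(base, "bmi"),
    m4_wml = c(base, "wml_fraction"),
    m5_mmse = c(base, "mmse_total"),
    m6_all = c(base, "family_history", "bmi", "wml_fraction", "mmse_total"),
    m7a_caide = c(base, "caide_z"),
    m7b_fcvd = c(base, "framingham_cvd_z"),
    m7c_stroke = c(base, "framingham_stroke_z")
  )
}

model_vars <- function(terms) unique(unlist(strsplit(terms, ":", fixed = TRUE)))

#' Area under the ROC curve by the rank (Mann–Whitney) formulation
#'
#' The probability that a randomly chosen case outranks a randomly chosen
#' control, computed from mid-ranks so ties contribute one half.
#'
#' @param scores Numeric predictor (higher = more case-like).
#' @param labels Logical or 0/1 case indicator.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  y <- as.logical(labels)
  stopifnot(length(scores) == length(y), any(y), any(!y))
  r <- rank(scores, ties.method = "average")
  n1 <- sum(y); n0 <- sum(!y)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' DeLong 95% confidence interval for an AUC
#'
#' Placement-value (DeLong) variance estimate for a single apparent AUC,
#' with a normal-approximation CI clipped to \[0, 1\].
#'
#' @inheritParams auc_rank
#' @return List with `auc`, `se`, `ci_low`, `ci_high`.
#' @export
auc_delong_ci <- function(scores, labels) {
  y <- as.logical(labels)
  cases <- scores[y]; controls <- scores[!y]
  m <- length(cases); n <- length(controls)
  psi <- function(x, ys) (sum(ys < x) + 0.5 * sum(ys == x)) / length(ys)
  v10 <- vapply(cases, psi, numeric(1), ys = controls)
  v01 <- vapply(controls, function(yv)
    (sum(cases > yv) + 0.5 * sum(cases == yv)) / m, numeric(1))
  auc <- mean(v10)
  se <- sqrt(stats::var(v10) / m + stats::var(v01) / n)
  z <- stats::qnorm(0.975)
  list(auc = auc, se = se,
       ci_low = max(0, auc - z * se),
       ci_high = min(1, auc + z * se))
}

#' Fit one nested-model specification and compute its apparent AUC
#'
#' Restricts the cohort to the contrast group versus the normal group,
#' takes complete cases on the model variables, fits the logistic model,
#' and computes the in-sample AUC of the fitted probabilities with a
#' DeLong 95% CI. Coefficients are reported as odds ratios with Wald CIs.
#'
#' @param cohort Analytic data.frame with `atn_group` and the model
#'   variables (composite z-scores via [add_composite_scores()]).
#' @param terms Character vector of model terms (see [build_model_set()]).
#' @param contrast The pathology group to discriminate from
#'   `"normal_ad_biomarkers"`.
#' @param model_id Optional tag stored in the result.
#' @return List of class `"roc_model"`: `contrast`, `model_id`, `terms`,
#'   `fit` (the glm), `coefficients` (term/OR/ci_low/ci_high),
#'   `auc`, `auc_ci_low`, `auc_ci_high`, `n_cases`, `n_controls`.
#' @export
fit_and_auc <- function(cohort, terms, contrast, model_id = NA_character_) {
  vars <- model_vars(terms)
  stopifnot(all(c("atn_group", vars) %in% names(cohort)))
  d <- cohort[as.character(cohort$atn_group) %in%
                c("normal_ad_biomarkers", contrast), , drop = FALSE]
  d <- d[stats::complete.cases(d[, vars, drop = FALSE]), , drop = FALSE]
  d$.y <- as.integer(as.character(d$atn_group) == contrast)
  if (length(unique(d$.y)) < 2L)
    stop("non-estimable: a single class remains after listwise deletion")
  fml <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  fit <- stats::glm(fml, data = d, family = stats::binomial())
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm)[-1],
                      or = exp(sm[-1, "Estimate"]),
                      ci_low = exp(sm[-1, "Estimate"] -
                                     1.96 * sm[-1, "Std. Error"]),
                      ci_high = exp(sm[-1, "Estimate"] +
                                      1.96 * sm[-1, "Std. Error"]),
                      stringsAsFactors = FALSE)
  dl <- auc_delong_ci(stats::fitted(fit), d$.y)
  structure(list(contrast = contrast, model_id = model_id, terms = terms,
                 fit = fit, data = d, coefficients = coefs,
                 auc = dl$auc, auc_ci_low = dl$ci_low,
                 auc_ci_high = dl$ci_high,
                 n_cases = sum(d$.y), n_controls = sum(1 - d$.y)),
            class = "roc_model")
}

#' Likelihood-ratio comparison of an extended model against the basic model
#'
#' Nested-model chi-square test: both models are refit on the common
#' complete-case subsample (the extended model's fitting rows), and the
#' deviance difference is referred to a chi-square with the number of
#' added parameters as degrees of freedom.
#'
#' @param basic,extended `"roc_model"` objects from [fit_and_auc()];
#'   `extended`'s term set must strictly contain `basic`'s.
#' @return List: `p_value`, `chi_square`, `df`, `n`.
#' @export
compare_to_basic <- function(basic, extended) {
  if (!all(basic$terms %in% extended$terms) ||
      length(extended$terms) <= length(basic$terms))
    stop("models are not strictly nested")
  d <- extended$data
  fml_b <- stats::as.formula(paste(".y ~",
                                   paste(basic$terms, collapse = " + ")))
  fml_e <- stats::as.formula(paste(".y ~",
                                   paste(extended$terms, collapse = " + ")))
  fb <- stats::glm(fml_b, data = d, family = stats::binomial())
  fe <- stats::glm(fml_e, data = d, family = stats::binomial())
  stat <- fb$deviance - fe$deviance
  df <- length(stats::coef(fe)) - length(stats::coef(fb))
  list(p_value = stats::pchisq(max(stat, 0), df, lower.tail = FALSE),
       chi_square = stat, df = df, n = nrow(d))
}

#' Run the full nested ROC battery for one contrast
#'
#' Fits all nine specifications from [build_model_set()] and the
#' likelihood-ratio comparison of each extension against model 1.
#'
#' @inheritParams fit_and_auc
#' @return Data.frame with one row per model: `contrast`, `model_id`,
#'   `auc`, `auc_ci_low`, `auc_ci_high`, `p_vs_basic` (NA for m1),
#'   `n_cases`, `n_controls`.
#' @export
roc_battery <- function(cohort, contrast) {
  specs <- build_model_set(contrast)
  fits <- lapply(names(specs), function(id)
    fit_and_auc(cohort, specs[[id]], contrast, model_id = id))
  names(fits) <- names(specs)
  rows <- lapply(names(specs), function(id) {
    f <- fits[[id]]
    p <- if (id == "m1") NA_real_ else
      compare_to_basic(fits$m1, f)$p_value
    data.frame(contrast = contrast, model_id = id, auc = f$auc,
               auc_ci_low = f$auc_ci_low, auc_ci_high = f$auc_ci_high,
               p_vs_basic = p, n_cases = f$n_cases,
               n_controls = f$n_controls, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
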