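#' Age- and sex-adjusted logistic model for a single pathology flag
#'
#' Fits a binary logistic regression of one pathology flag (A+, T+ or N+)
#' on a risk-factor exposure plus adjustment covariates (age and sex by
#' default), by maximum likelihood on complete cases. Returns the
#' exposure's odds ratio with a Wald 95% CI and p-value.
#'
#' @param cohort Analytic data.frame with logical `a_flag`/`t_flag`/`n_flag`
#'   columns (e.g. from [classify_atn()]) and the exposure/covariates.
#' @param outcome `"A+"`, `"T+"` or `"N+"`.
#' @param exposure Name of the exposure column.
#' @param covariates Character vector of adjustment columns (default
#'   `c("age", "sex_female")`; may be `NULL` for an unadjusted fit).
#' @return Data.frame of class `"association_result"`: `outcome`,
#'   `exposure`, `estimate_type` (`"OR"`), `estimate`, `ci_low`, `ci_high`,
#'   `p_value`, `n_used`, `non_estimable`.
#' @details Complete separation (or otherwise unbounded estimates) is
#'   reported with `non_estimable = TRUE` rather than an error; the model
#'   requires more complete rows than parameters.
#' @export
fit_pathology_logistic <- function(cohort, outcome = c("A+", "T+", "N+"),
                                   exposure,
                                   covariates = c("age", "sex_female")) {
  outcome <- match.arg(outcome)
  flag_col <- c("A+" = "a_flag", "T+" = "t_flag", "N+" = "n_flag")[[outcome]]
  vars <- c(flag_col, exposure, covariates)
  stopifnot(all(vars %in% names(cohort)))
  d <- cohort[stats::complete.cases(cohort[, vars, drop = FALSE]),
              vars, drop = FALSE]
  d$.y <- as.integer(d[[flag_col]])
  rhs <- paste(c(exposure, covariates), collapse = " + ")
  if (nrow(d) < length(c(exposure, covariates)) + 2L)
    stop("insufficient data: ", nrow(d), " complete rows")
  fit <- stats::glm(stats::as.formula(paste(".y ~", rhs)), data = d,
                    family = stats::binomial())
  summarise_logistic_term(fit, exposure, outcome, "OR", nrow(d))
}

# Wald summary for one term of a fitted binomial glm
summarise_logistic_term <- function(fit, term, outcome, type, n_used) {
  sm <- summary(fit)$coefficients
  row <- grep(paste0("^", term), rownames(sm), value = TRUE)[1]
  b <- sm[row, "Estimate"]; se <- sm[row, "Std. Error"]
  non_est <- !fit$converged || !is.finite(se) || se > 1e3 || abs(b) > 15
  z <- b / se
  structure(data.frame(
    outcome = outcome, exposure = term, estimate_type = type,
    estimate = exp(b), ci_low = exp(b - 1.96 * se),
    ci_high = exp(b + 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(z)),
    n_used = n_used, non_estimable = non_est,
    stringsAsFactors = FALSE),
    class = c("association_result", "data.frame"))
}

#' Multinomial logistic model over the five ATN groups
#'
#' Fits a multinomial logit of ATN group membership on an exposure with
#' age, sex and (optionally) study-site adjustment, taking the normal-AD-
#' biomarkers group as the reference. Effect sizes are relative risk ratios
#' (RRR): the exponentiated exposure coefficient for each non-reference
#' group, with Wald 95% CIs.
#'
#' @param cohort Analytic data.frame with an `atn_group` factor (or a
#'   custom `group_col`), the exposure, covariates and `site_id`.
#' @param exposure Name of the exposure column.
#' @param include_site Add fixed study-site effects (default `TRUE`).
#' @param covariates Adjustment columns (default `c("age", "sex_female")`).
#' @param group_col Name of the outcome factor column.
#' @param reference Reference level (default `"normal_ad_biomarkers"`).
#' @param reltol Convergence tolerance passed to [nnet::multinom()].
#' @return Data.frame of class `"association_result"`, one row per
#'   non-reference group: `outcome` (the group), `exposure`,
#'   `estimate_type` (`"RRR"`), `estimate`, `ci_low`, `ci_high`, `p_value`,
#'   `n_used`, `reference`, `non_estimable`.
#' @export
fit_multinomial <- function(cohort, exposure, include_site = TRUE,
                            covariates = c("age", "sex_female"),
                            group_col = "atn_group",
                            reference = "normal_ad_biomarkers",
                            reltol = 1e-10) {
  vars <- c(group_col, exposure, covariates,
            if (include_site) "site_id")
  stopifnot(all(vars %in% names(cohort)))
  d <- cohort[stats::complete.cases(cohort[, vars, drop = FALSE]),
              vars, drop = FALSE]
  g <- factor(as.character(d[[group_col]]))
  if (!reference %in% levels(g))
    stop("reference group absent from complete cases: ", reference)
  if (nlevels(g) < 2L) stop("need at least 2 groups present")
  d$.g <- stats::relevel(g, ref = reference)
  rhs <- paste(c(exposure, covariates,
                 if (include_site) "factor(site_id)"), collapse = " + ")
  fit <- nnet::multinom(stats::as.formula(paste(".g ~", rhs)), data = d,
                        Hess = TRUE, trace = FALSE, maxit = 500,
                        reltol = reltol, MaxNWts = 10000)
  summarise_multinom_term(fit, exposure, reference, nrow(d))
}

# Wald summaries for terms matching `pattern` in a fitted multinom
summarise_multinom_term <- function(fit, pattern, reference, n_used) {
  cf <- stats::coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1,
                                     dimnames = list(fit$lev[2],
                                                     names(cf)))
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  term <- grep(paste0("^", pattern), colnames(cf), value = TRUE)
  if (length(term) == 0L) stop("term not found in model: ", pattern)
  out <- lapply(term, function(tm) {
    rows <- lapply(rownames(cf), function(gname) {
      b <- cf[gname, tm]
      vname <- paste(gname, tm, sep = ":")
      if (!is.null(vc) && !vname %in% rownames(vc) && tm %in% rownames(vc))
        vname <- tm   # two-class fits drop the group prefix
      se <- if (!is.null(vc) && vname %in% rownames(vc))
        sqrt(vc[vname, vname]) else NA_real_
      non_est <- !is.finite(se) || se > 1e3 || abs(b) > 15
      z <- b / se
      data.frame(outcome = gname, exposure = tm, estimate_type = "RRR",
                 estimate = exp(b), ci_low = exp(b - 1.96 * se),
                 ci_high = exp(b + 1.96 * se),
                 p_value = 2 * stats::pnorm(-abs(z)), n_used = n_used,
                 reference = reference, non_estimable = non_est,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  structure(do.call(rbind, out),
            class = c("association_result", "data.frame"))
}

#' Exposure-by-moderator interaction scan in the multinomial model
#'
#' Refits the site-adjusted multinomial model with an added
#' exposure-by-moderator product term and reports the product-term RRR and
#' Wald test per group contrast. Moderators follow the study design:
#' APOE4 carriership, age or sex.
#'
#' @inheritParams fit_multinomial
#' @param moderator Name of the moderator column (e.g. `"apoe4_carrier"`,
#'   `"age"`, `"sex_female"`); must vary in the sample.
#' @return Data.frame of class `"association_result"` for the product term
#'   (one row per non-reference group).
#' @export
interaction_scan <- function(cohort, exposure, moderator,
                             include_site = TRUE,
                             covariates = c("age", "sex_female"),
                             group_col = "atn_group",
                             reference = "normal_ad_biomarkers",
                             reltol = 1e-10) {
  vars <- c(group_col, exposure, moderator,
            setdiff(covariates, c(exposure, moderator)),
            if (include_site) "site_id")
  stopifnot(all(vars %in% names(cohort)))
  d <- cohort[stats::complete.cases(cohort[, vars, drop = FALSE]),
              vars, drop = FALSE]
  if (length(unique(d[[moderator]])) < 2L)
    stop("non-estimable: moderator is constant in the sample")
  g <- factor(as.character(d[[group_col]]))
  if (!reference %in% levels(g))
    stop("reference group absent from complete cases: ", reference)
  d$.g <- stats::relevel(g, ref = reference)
  d$.prod <- d[[exposure]] * d[[moderator]]
  main_terms <- unique(c(exposure, moderator,
                         setdiff(covariates, c(exposure, moderator))))
  rhs <- paste(c(main_terms, ".prod",
                 if (include_site) "factor(site_id)"), collapse = " + ")
  fit <- nnet::multinom(stats::as.formula(paste(".g ~", rhs)), data = d,
                        Hess = TRUE, trace = FALSE, maxit = 500,
                        reltol = reltol, MaxNWts = 10000)
  res <- summarise_multinom_term(fit, "\\.prod", reference, nrow(d))
  res$exposure <- paste(exposure, moderator, sep = ":")
  res
}

#' Bonferroni-corrected significance threshold
#'
#' @param family_alpha Family-wise alpha in (0, 1).
#' @param m Number of tests in the family (>= 1).
#' @return `family_alpha / m`.
#' @export
bonferroni_threshold <- function(family_alpha, m) {
  stopifnot(m >= 1, family_alpha > 0, family_alpha < 1)
  family_alpha / m
}

#' Adjusted standardised residuals of a contingency table
#'
#' Cell residuals \eqn{R_{gc} = (O_{gc} - E_{gc}) /
#' \sqrt{E_{gc} (1 - n_{g.}/N)(1 - n_{.c}/N)}}; `|R| > 2` flags the cells
#' driving an omnibus chi-square result.
#'
#' @param tab A two-way contingency table (matrix of counts).
#' @return Matrix of adjusted standardised residuals.
#' @export
adjusted_residuals <- function(tab) {
  tab <- as.matrix(tab)
  N <- sum(tab)
  rs <- rowSums(tab); cs <- colSums(tab)
  E <- outer(rs, cs) / N
  (tab - E) / sqrt(E * outer(1 - rs / N, 1 - cs / N))
}

#' Omnibus and post hoc comparison of one variable across the five groups
#'
#' Continuous variables: one-way ANOVA omnibus plus all pairwise two-sample
#' t-tests with Bonferroni-multiplied p-values (capped at 1). Binary
#' variables: 2-by-5 chi-square omnibus plus adjusted standardised
#' residuals per group, with `|R| > 2` flagged as significant subgroup
#' effects. A warning is attached when any expected cell count falls
#' below 1.
#'
#' @param cohort Analytic data.frame with the grouping factor.
#' @param variable Column to compare.
#' @param type `"auto"` (binary columns detected as 0/1), `"continuous"`
#'   or `"binary"`.
#' @param group_col Grouping column (default `"atn_group"`).
#' @param family_alpha Family-wise alpha used to report the Bonferroni
#'   per-test threshold alongside the results (default 0.05).
#' @param m_tests Size of the test family for that threshold (default:
#'   number of pairwise comparisons, or 1 for binary).
#' @return A list of class `"group_comparison"`: `variable`, `test`
#'   (`"anova"`/`"chi_square"`), `omnibus_statistic`, `omnibus_p`,
#'   `pairwise` (continuous; data.frame group_i/group_j/p_raw/p_bonferroni),
#'   `adjusted_residuals` and `significant_cells` (binary),
#'   `bonferroni_threshold`, `small_cell_warning`.
#' @export
compare_groups <- function(cohort, variable, type = c("auto", "continuous",
                                                      "binary"),
                           group_col = "atn_group", family_alpha = 0.05,
                           m_tests = NULL) {
  type <- match.arg(type)
  g <- factor(as.character(cohort[[group_col]]))
  x <- cohort[[variable]]
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- droplevels(g[ok])
  if (type == "auto")
    type <- if (all(x %in% c(0, 1))) "binary" else "continuous"
  if (type == "continuous") {
    fit <- stats::aov(x ~ g)
    an <- summary(fit)[[1]]
    omnibus <- an[["F value"]][1]
    omnibus_p <- an[["Pr(>F)"]][1]
    lv <- levels(g)
    pairs <- utils::combn(lv, 2)
    m <- if (is.null(m_tests)) ncol(pairs) else m_tests
    pw <- apply(pairs, 2, function(pr) {
      pv <- stats::t.test(x[g == pr[1]], x[g == pr[2]])$p.value
      c(p_raw = pv, p_bonferroni = min(1, pv * m))
    })
    pairwise <- data.frame(group_i = pairs[1, ], group_j = pairs[2, ],
                           p_raw = pw["p_raw", ],
                           p_bonferroni = pw["p_bonferroni", ],
                           stringsAsFactors = FALSE)
    structure(list(variable = variable, test = "anova",
                   omnibus_statistic = omnibus, omnibus_p = omnibus_p,
                   pairwise = pairwise, adjusted_residuals = NULL,
                   significant_cells = NULL,
                   bonferroni_threshold = family_alpha / m,
                   small_cell_warning = FALSE),
              class = "group_comparison")
  } else {
    tab <- table(factor(x, levels = c(0, 1)), g)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    small <- any(E < 1)
    chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    R <- adjusted_residuals(tab)
    m <- if (is.null(m_tests)) 1 else m_tests
    structure(list(variable = variable, test = "chi_square",
                   omnibus_statistic = unname(chi$statistic),
                   omnibus_p = chi$p.value, pairwise = NULL,
                   adjusted_residuals = R,
                   significant_cells = abs(R) > 2,
                   bonferroni_threshold = family_alpha / m,
                   small_cell_warning = small),
              class = "group_comparison")
  }
}
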