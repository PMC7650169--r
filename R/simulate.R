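#' Default per-group covariate marginals for the synthetic cohort
#'
#' Group-specific means/SDs for continuous covariates and prevalences for
#' flags, one set per ATN biomarker group, encoding a realistic cognitively
#' healthy research cohort of older European adults. White matter lesion
#' (WML) burden is strongly right-skewed and is matched by a log-normal.
#'
#' @return Named list: one element per group (see [atn_groups()]), each a
#'   list of covariate specs (`list(dist, mean, sd)` or `list(dist, p)`).
#' @export
default_group_marginals <- function() {
  grp <- function(age, sexf, edu, apoe, fam, sbp, bmi, chol, inact, smoke,
                  bpmed, diab, cvd, af, wml, mmse, rbl, rbc) {
    list(
      age = list(dist = "normal", mean = age[1], sd = age[2]),
      sex_female = list(dist = "bernoulli", p = sexf),
      education_years = list(dist = "normal", mean = edu[1], sd = edu[2]),
      apoe4_carrier = list(dist = "bernoulli", p = apoe),
      family_history = list(dist = "bernoulli", p = fam),
      systolic_bp = list(dist = "normal", mean = sbp[1], sd = sbp[2]),
      bmi = list(dist = "normal", mean = bmi[1], sd = bmi[2]),
      high_cholesterol = list(dist = "bernoulli", p = chol),
      physical_inactivity = list(dist = "bernoulli", p = inact),
      ever_smoked = list(dist = "bernoulli", p = smoke),
      bp_medication = list(dist = "bernoulli", p = bpmed),
      diabetes = list(dist = "bernoulli", p = diab),
      prior_cvd = list(dist = "bernoulli", p = cvd),
      atrial_fibrillation = list(dist = "bernoulli", p = af),
      wml_fraction = list(dist = "lognormal", mean = wml[1], sd = wml[2]),
      mmse_total = list(dist = "normal", mean = mmse[1], sd = mmse[2]),
      rbans_list_learning = list(dist = "normal", mean = rbl[1], sd = rbl[2]),
      rbans_coding = list(dist = "normal", mean = rbc[1], sd = rbc[2])
    )
  }
  list(
    normal_ad_biomarkers = grp(
      c(63.6, 6.6), 0.601, c(14.8, 3.7), 0.322, 0.721, c(133.5, 17.6),
      c(26.4, 4.3), 0.173, 0.433, 0.521, 0.176, 0.049, 0.037, 0.016,
      c(9.3, 26.2), c(28.9, 1.3), c(29.4, 4.2), c(47.5, 9.9)),
    alzheimers_pathologic_change = grp(
      c(64.7, 7.1), 0.540, c(14.9, 3.7), 0.475, 0.692, c(136.4, 17.9),
      c(26.5, 4.3), 0.147, 0.383, 0.531, 0.133, 0.019, 0.028, 0.014,
      c(17.3, 35.2), c(28.9, 1.2), c(29.0, 4.2), c(45.5, 10.4)),
    alzheimers_disease = grp(
      c(69.1, 5.9), 0.567, c(13.9, 3.8), 0.692, 0.866, c(137.8, 17.0),
      c(24.8, 3.7), 0.119, 0.433, 0.582, 0.134, 0.060, 0.045, 0.015,
      c(27.8, 48.5), c(28.2, 1.9), c(27.4, 4.5), c(41.6, 9.5)),
    ad_and_non_ad_pathologic_change = grp(
      c(62.4, 7.1), 0.516, c(15.8, 3.5), 0.367, 0.613, c(136.9, 18.1),
      c(27.2, 4.5), 0.097, 0.367, 0.600, 0.161, 0.000, 0.065, 0.000,
      c(24.1, 42.8), c(29.0, 1.3), c(29.7, 3.6), c(47.5, 11.8)),
    non_ad_pathologic_change = grp(
      c(66.7, 6.2), 0.605, c(14.5, 3.6), 0.349, 0.612, c(136.0, 18.8),
      c(26.2, 4.6), 0.172, 0.459, 0.594, 0.157, 0.082, 0.052, 0.037,
      c(11.2, 27.8), c(28.6, 1.2), c(28.5, 4.3), c(44.3, 11.2))
  )
}

#' Synthetic-cohort configuration
#'
#' Builds the configuration consumed by [generate_cohort()]. The defaults
#' encode the study conditions the package is designed around: a 1500-person
#' cohort of over-50s across 21 sites whose analytic subset of 1010 splits
#' into the five ATN groups as 567 / 211 / 67 / 31 / 134, with per-flag
#' combination counts consistent with 309 A+, 158 T+ and 90 N+ records, and
#' an exclusion cascade of 82 (dementia/MCI diagnosis), 171 (CDR >= 0.5)
#' and 237 (incomplete ATN profile).
#'
#' The A+T+ (Alzheimer's disease) split across N-/N+ and the non-AD group's
#' split across its three flag combinations are free choices constrained
#' only by those margins; the defaults use 58/9 and 84/7/43.
#'
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param combo_counts Named integer vector over the eight A/T/N flag
#'   combinations, names like `"A+T-N-"`.
#' @param exclusion_counts Named integer vector with elements
#'   `dementia_mci`, `cdr`, `missing_atn`.
#' @param group_marginals As [default_group_marginals()].
#' @param site_count Number of study sites (uniform assignment).
#' @param abeta_rule,ptau_rule Active cut-off rules; generated CSF values
#'   are placed on the requested side of these thresholds.
#' @param abeta_margin_scale,ptau_margin_scale Scales (pg/ml) of the
#'   half-normal margins between generated CSF values and the thresholds.
#' @param abeta_margin_offset,ptau_margin_offset Fixed minimum margins
#'   (pg/ml, default 0). With the default pure half-normal margins the CSF
#'   densities peak at the cut-off itself; a positive offset pushes the two
#'   sides apart into a genuinely bimodal distribution, which the
#'   mixture-refit threshold route requires.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(seed = 1L,
                          combo_counts = c("A-T-N-" = 567L, "A+T-N-" = 211L,
                                           "A+T+N-" = 58L, "A+T+N+" = 9L,
                                           "A+T-N+" = 31L, "A-T+N-" = 84L,
                                           "A-T+N+" = 7L, "A-T-N+" = 43L),
                          exclusion_counts = c(dementia_mci = 82L, cdr = 171L,
                                               missing_atn = 237L),
                          group_marginals = default_group_marginals(),
                          site_count = 21L,
                          abeta_rule = default_cutoff("abeta42"),
                          ptau_rule = default_cutoff("ptau"),
                          abeta_margin_scale = 150,
                          ptau_margin_scale = 5,
                          abeta_margin_offset = 0,
                          ptau_margin_offset = 0) {
  all_combos <- combo_names()
  if (is.null(names(combo_counts)) ||
      !all(names(combo_counts) %in% all_combos))
    stop("combo_counts must be named with A/T/N combinations like 'A+T-N-'")
  full <- stats::setNames(integer(length(all_combos)), all_combos)
  full[names(combo_counts)] <- as.integer(combo_counts)
  if (any(full < 0)) stop("combo counts must be non-negative")
  if (any(exclusion_counts < 0)) stop("exclusion counts must be non-negative")
  if (!all(c("dementia_mci", "cdr", "missing_atn") %in%
           names(exclusion_counts)))
    stop("exclusion_counts needs dementia_mci, cdr, missing_atn")
  structure(list(seed = as.integer(seed), combo_counts = full,
                 exclusion_counts = exclusion_counts,
                 group_marginals = group_marginals,
                 site_count = as.integer(site_count),
                 abeta_rule = abeta_rule, ptau_rule = ptau_rule,
                 abeta_margin_scale = abeta_margin_scale,
                 ptau_margin_scale = ptau_margin_scale,
                 abeta_margin_offset = abeta_margin_offset,
                 ptau_margin_offset = ptau_margin_offset),
            class = "cohort_config")
}

combo_names <- function() {
  as.vector(outer(c("A-", "A+"), outer(c("T-", "T+"), c("N-", "N+"),
                                       paste0), paste0))
}

combo_to_group <- function(combo) {
  a <- substr(combo, 2, 2) == "+"
  t <- substr(combo, 4, 4) == "+"
  n <- substr(combo, 6, 6) == "+"
  as.character(assign_group(a, t, n))
}

# draw from a truncated normal by resampling (bounds far in the tail here)
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower | x >= upper)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower | x[bad] >= upper]
    guard <- guard + 1L
  }
  if (length(bad)) x[bad] <- pmin(pmax(x[bad], lower + 1e-6), upper - 1e-6)
  x
}

# log-normal parameterised by its arithmetic mean and SD
rlnorm_match <- function(n, mean, sd) {
  cv2 <- (sd / mean)^2
  sigma2 <- log(1 + cv2)
  mu <- log(mean) - sigma2 / 2
  stats::rlnorm(n, mu, sqrt(sigma2))
}

draw_covariate <- function(n, spec) {
  switch(spec$dist,
         normal = stats::rnorm(n, spec$mean, spec$sd),
         bernoulli = stats::rbinom(n, 1L, spec$p),
         lognormal = rlnorm_match(n, spec$mean, spec$sd),
         stop("unknown distribution: ", spec$dist))
}

# Scheltens scores on the requested side of the age-specific threshold,
# weighted toward the threshold so groups overlap realistically
draw_scheltens <- function(age, positive) {
  thr <- scheltens_threshold(age)
  vapply(seq_along(age), function(i) {
    levels <- seq(0, 4, by = 0.5)
    allowed <- if (positive[i]) levels[levels > thr[i]]
               else levels[levels <= thr[i]]
    w <- 0.5^seq_along(allowed)
    if (!positive[i]) w <- rev(w)
    sample(allowed, 1L, prob = w / sum(w))
  }, numeric(1))
}

# CSF concentration strictly on one side of the threshold:
# offset + half-normal margin
draw_csf <- function(n, rule, positive, scale, offset = 0) {
  margin <- offset + abs(stats::rnorm(n, 0, scale))
  sgn_pos <- if (rule$positive_direction == "below") -1 else 1
  x <- rule$threshold + ifelse(positive, sgn_pos, -sgn_pos) * margin
  bad <- which(x <= 0)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    m2 <- offset + abs(stats::rnorm(length(bad), 0, scale))
    x[bad] <- rule$threshold +
      ifelse(positive[bad], sgn_pos, -sgn_pos) * m2
    bad <- bad[x[bad] <= 0]
    guard <- guard + 1L
  }
  if (length(bad)) x[bad] <- rule$threshold / 2
  x
}

#' Generate a synthetic ATN cohort
#'
#' Deterministically (given the config seed) generates a participant table
#' whose analytic subset classifies back to exactly the requested A/T/N
#' combination counts under the active cut-off rules, with group-specific
#' covariate marginals, followed by the configured excluded participants:
#' records with a dementia/MCI diagnosis, records with CDR >= 0.5, and
#' records with one randomly chosen missing ATN input.
#'
#' @param config A [cohort_config()].
#' @return Data.frame in the [cohort_schema()] layout (rows shuffled).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  marg <- config$group_marginals
  combos <- combo_names()
  blocks <- list()
  for (cb in combos) {
    n <- config$combo_counts[[cb]]
    if (n == 0L) next
    grp <- combo_to_group(cb)
    m <- marg[[grp]]
    a_pos <- substr(cb, 2, 2) == "+"
    t_pos <- substr(cb, 4, 4) == "+"
    n_pos <- substr(cb, 6, 6) == "+"
    d <- draw_block(n, m, config)
    d$csf_abeta42 <- draw_csf(n, config$abeta_rule, rep(a_pos, n),
                              config$abeta_margin_scale,
                              config$abeta_margin_offset)
    d$csf_ptau <- draw_csf(n, config$ptau_rule, rep(t_pos, n),
                           config$ptau_margin_scale,
                           config$ptau_margin_offset)
    d$scheltens_mta <- draw_scheltens(d$age, rep(n_pos, n))
    d$dementia_or_mci_dx <- 0L
    d$cdr_global <- 0
    blocks[[length(blocks) + 1L]] <- d
  }
  # excluded participants, drawn from the combination mix of the analytic set
  exc <- config$exclusion_counts
  n_exc <- sum(exc)
  if (n_exc > 0L) {
    share <- config$combo_counts / max(sum(config$combo_counts), 1L)
    if (sum(config$combo_counts) == 0L)
      share <- rep(1 / 8, 8)
    cb_draw <- sample(combos, n_exc, replace = TRUE, prob = share)
    stage <- rep(c("dementia_mci", "cdr", "missing_atn"),
                 times = c(exc[["dementia_mci"]], exc[["cdr"]],
                           exc[["missing_atn"]]))
    for (i in seq_len(n_exc)) {
      cb <- cb_draw[i]
      grp <- combo_to_group(cb)
      m <- marg[[grp]]
      d <- draw_block(1L, m, config)
      d$csf_abeta42 <- draw_csf(1L, config$abeta_rule,
                                substr(cb, 2, 2) == "+",
                                config$abeta_margin_scale,
                                config$abeta_margin_offset)
      d$csf_ptau <- draw_csf(1L, config$ptau_rule, substr(cb, 4, 4) == "+",
                             config$ptau_margin_scale,
                             config$ptau_margin_offset)
      d$scheltens_mta <- draw_scheltens(d$age, substr(cb, 6, 6) == "+")
      if (stage[i] == "dementia_mci") {
        d$dementia_or_mci_dx <- 1L
        d$cdr_global <- sample(c(0.5, 1, 2), 1L, prob = c(0.6, 0.3, 0.1))
      } else if (stage[i] == "cdr") {
        d$dementia_or_mci_dx <- 0L
        d$cdr_global <- sample(c(0.5, 1), 1L, prob = c(0.9, 0.1))
      } else {
        d$dementia_or_mci_dx <- 0L
        d$cdr_global <- 0
        miss <- sample(c("csf_abeta42", "csf_ptau", "scheltens_mta"), 1L)
        d[[miss]] <- NA_real_
      }
      blocks[[length(blocks) + 1L]] <- d
    }
  }
  out <- do.call(rbind, blocks)
  n_tot <- nrow(out)
  out <- out[sample.int(n_tot), , drop = FALSE]
  out$participant_id <- sprintf("P%05d", seq_len(n_tot))
  out$site_id <- sprintf("S%02d", sample.int(config$site_count, n_tot,
                                             replace = TRUE))
  out$left_ventricular_hypertrophy <- 0L
  rownames(out) <- NULL
  out[, schema_columns()]
}

# covariate block for one combination (no biomarkers yet)
draw_block <- function(n, m, config) {
  d <- data.frame(row.names = seq_len(n))
  for (v in names(m)) d[[v]] <- draw_covariate(n, m[[v]])
  # respect schema ranges: over-50 recruitment, MMSE integer in [0, 30]
  d$age <- rnorm_trunc(n, m$age$mean, m$age$sd, lower = 50.01)
  d$mmse_total <- pmin(30, pmax(0, round(d$mmse_total)))
  d$education_years <- pmax(0, d$education_years)
  d$systolic_bp <- pmax(70, d$systolic_bp)
  d$bmi <- pmax(13, d$bmi)
  d$rbans_list_learning <- pmax(0, d$rbans_list_learning)
  d$rbans_coding <- pmax(0, d$rbans_coding)
  d
}

#' Calibrate a logistic intercept to a target prevalence
#'
#' Given the non-intercept part of the linear predictor, finds the intercept
#' for which the mean of `plogis(b0 + eta)` equals the target prevalence.
#'
#' @param eta Numeric vector: linear predictor without intercept.
#' @param target_prev Target mean outcome probability in (0, 1).
#' @return The intercept (scalar).
#' @export
calibrate_logit_intercept <- function(eta, target_prev) {
  stopifnot(target_prev > 0, target_prev < 1)
  f <- function(b0) mean(stats::plogis(b0 + eta)) - target_prev
  stats::uniroot(f, c(-50, 50), tol = 1e-10)$root
}

#' Simulate covariates and outcomes from a (multinomial) logistic model
#'
#' Draws covariates from stated base distributions and samples a binary or
#' multi-category outcome from the specified logistic model — the
#' effect-recovery companion to [generate_cohort()]. A binary outcome is
#' generated through the two-category multinomial path, so the two forms
#' coincide exactly on matched seeds.
#'
#' @param n Number of records.
#' @param covariates Named list of specs as in [default_group_marginals()]
#'   (`normal`, `bernoulli` or `lognormal`).
#' @param coefficients For a binary outcome, a named numeric vector of
#'   log-odds including `"(Intercept)"`; for a multi-category outcome, a
#'   matrix with one row per non-reference category (rownames = category
#'   labels) and columns named by terms including `"(Intercept)"`. The
#'   reference category is `reference`.
#' @param seed Integer seed.
#' @param outcome Name of the generated outcome column.
#' @param reference Reference-category label (multinomial; default
#'   `"normal_ad_biomarkers"`).
#' @param site_count If > 0, adds a uniformly assigned `site_id` factor
#'   with this many levels (no outcome effect).
#' @return Data.frame with the covariates, `site_id` (optional) and the
#'   outcome (integer 0/1, or factor with the reference level first).
#' @export
generate_from_model <- function(n, covariates, coefficients, seed = 1L,
                                outcome = "y",
                                reference = "normal_ad_biomarkers",
                                site_count = 0L) {
  set.seed(seed)
  d <- data.frame(row.names = seq_len(n))
  for (v in names(covariates)) d[[v]] <- draw_covariate(n, covariates[[v]])
  if (site_count > 0L)
    d$site_id <- sprintf("S%02d", sample.int(site_count, n, replace = TRUE))
  binary <- !is.matrix(coefficients)
  coef_mat <- if (binary) matrix(coefficients, nrow = 1,
                                 dimnames = list("1", names(coefficients)))
              else coefficients
  if (!all(is.finite(coef_mat))) stop("coefficients must be finite")
  terms <- colnames(coef_mat)
  if (!"(Intercept)" %in% terms) stop("coefficients need an (Intercept)")
  X <- cbind(`(Intercept)` = rep(1, n))
  for (tm in setdiff(terms, "(Intercept)")) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]   # "a:b" = product term
    if (!all(parts %in% names(d)))
      stop("no covariate for coefficient: ", tm)
    X <- cbind(X, Reduce(`*`, d[parts]))
    colnames(X)[ncol(X)] <- tm
  }
  eta <- X[, terms, drop = FALSE] %*% t(coef_mat)
  expeta <- cbind(1, exp(eta))   # reference category first
  p <- expeta / rowSums(expeta)
  u <- stats::runif(n)
  k <- rep(1L, n)
  acc <- p[, 1]
  for (j in seq_len(ncol(p) - 1L)) {
    k[u >= acc] <- j + 1L
    acc <- acc + p[, j + 1L]
  }
  if (binary) {
    d[[outcome]] <- as.integer(k == 2L)
  } else {
    labels <- c(reference, rownames(coef_mat))
    d[[outcome]] <- factor(labels[k], levels = labels)
  }
  d
}
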