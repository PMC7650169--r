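#' The five ATN biomarker groups
#'
#' Factor levels used throughout the package, in display order. The sixth
#' level marks participants with at least one missing A/T/N flag.
#' @return Character vector of group labels.
#' @export
atn_groups <- function() {
  c("normal_ad_biomarkers", "alzheimers_pathologic_change",
    "alzheimers_disease", "ad_and_non_ad_pathologic_change",
    "non_ad_pathologic_change", "unclassifiable")
}

#' Derive A/T/N positivity flags from cut-off rules
#'
#' Applies the cut-off rules to the CSF analytes and the decade-specific
#' medial-temporal-atrophy threshold to each record. All comparisons are
#' strict: amyloid positivity is CSF A\eqn{\beta}42 strictly below its
#' threshold, tau positivity is p-Tau strictly above its threshold, and
#' neurodegeneration positivity is a Scheltens score strictly above
#' [scheltens_threshold()] for the participant's age. Ties at a threshold
#' are negative. A missing input yields a missing flag, never an error.
#'
#' @param cohort Data.frame with (at least) `csf_abeta42`, `csf_ptau`,
#'   `scheltens_mta` and `age` columns.
#' @param abeta_rule,ptau_rule `"cutoff_rule"` objects; defaults are the
#'   shipped 1025 / 24 pg/ml rules ([default_cutoff()]).
#' @return `cohort` with logical columns `a_flag`, `t_flag`, `n_flag`
#'   (`TRUE` = positive, `NA` = missing), a factor column `atn_group`
#'   (levels [atn_groups()]) and logical `atn_complete`.
#' @export
classify_atn <- function(cohort,
                         abeta_rule = default_cutoff("abeta42"),
                         ptau_rule = default_cutoff("ptau")) {
  stopifnot(inherits(abeta_rule, "cutoff_rule"),
            inherits(ptau_rule, "cutoff_rule"))
  apply_rule <- function(x, rule) {
    if (rule$positive_direction == "below") x < rule$threshold
    else x > rule$threshold
  }
  a <- apply_rule(cohort$csf_abeta42, abeta_rule)
  t <- apply_rule(cohort$csf_ptau, ptau_rule)
  n <- cohort$scheltens_mta > scheltens_threshold(cohort$age)
  cohort$a_flag <- a
  cohort$t_flag <- t
  cohort$n_flag <- n
  cohort$atn_group <- assign_group(a, t, n)
  cohort$atn_complete <- !is.na(a) & !is.na(t) & !is.na(n)
  cohort
}

#' Map A/T/N flags to the five biomarker groups
#'
#' Total mapping over the eight non-missing flag combinations:
#' \itemize{
#'   \item A−T−N− — normal AD biomarkers
#'   \item A+T−N− — Alzheimer's pathologic change
#'   \item A+T+N− and A+T+N+ — Alzheimer's disease
#'   \item A+T−N+ — AD and concomitant non-AD pathologic change
#'   \item A−T+N−, A−T+N+ and A−T−N+ — non-AD pathologic change
#' }
#' Any missing flag maps to `"unclassifiable"`.
#'
#' @param a,t,n Logical vectors (`TRUE` = positive, `NA` = missing).
#' @return Factor with levels [atn_groups()].
#' @export
assign_group <- function(a, t, n) {
  g <- rep(NA_character_, length(a))
  g[which(!a & !t & !n)] <- "normal_ad_biomarkers"
  g[which(a & !t & !n)] <- "alzheimers_pathologic_change"
  g[which(a & t)] <- "alzheimers_disease"
  g[which(a & !t & n)] <- "ad_and_non_ad_pathologic_change"
  g[which(!a & (t | n))] <- "non_ad_pathologic_change"
  g[which(is.na(a) | is.na(t) | is.na(n))] <- "unclassifiable"
  factor(g, levels = atn_groups())
}

#' Apply the analytic-sample exclusion cascade
#'
#' Excludes participants in three ordered stages, attributing each excluded
#' participant to the first stage that catches them: (1) a clinical
#' dementia/MCI diagnosis; (2) CDR global score >= 0.5 among the remainder;
#' (3) an incomplete A/T/N profile among the remainder. The stage counts
#' plus the analytic n always sum to the input n.
#'
#' @param cohort A classified cohort (output of [classify_atn()]) with
#'   `participant_id`, `dementia_or_mci_dx`, `cdr_global` and `atn_complete`.
#' @return A list with `analytic` (the surviving records), `report` (a list
#'   with `n_input`, `n_dementia_mci`, `n_cdr`, `n_missing_atn`,
#'   `n_analytic`) and `reasons` (per-participant exclusion reason,
#'   `NA` for survivors).
#' @details A missing diagnosis flag or CDR score is treated as not meeting
#'   the exclusion; only a positive flag or a measured CDR >= 0.5 excludes.
#' @export
apply_exclusions <- function(cohort) {
  if (anyDuplicated(cohort$participant_id))
    stop("data-integrity error: duplicate participant_id")
  n <- nrow(cohort)
  reason <- rep(NA_character_, n)
  s1 <- !is.na(cohort$dementia_or_mci_dx) & cohort$dementia_or_mci_dx == 1
  reason[s1] <- "dementia_or_mci_dx"
  s2 <- is.na(reason) & !is.na(cohort$cdr_global) & cohort$cdr_global >= 0.5
  reason[s2] <- "cdr_ge_0.5"
  s3 <- is.na(reason) & !cohort$atn_complete
  reason[s3] <- "missing_atn"
  analytic <- cohort[is.na(reason), , drop = FALSE]
  rownames(analytic) <- NULL
  report <- list(n_input = n,
                 n_dementia_mci = sum(s1),
                 n_cdr = sum(s2),
                 n_missing_atn = sum(s3),
                 n_analytic = nrow(analytic))
  stopifnot(report$n_analytic ==
              n - report$n_dementia_mci - report$n_cdr - report$n_missing_atn)
  list(analytic = analytic, report = report, reasons = reason)
}
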