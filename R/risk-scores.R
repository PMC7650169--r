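#' Load and validate a declarative scoring table
#'
#' A scoring table maps risk-factor fields to integer points through bands
#' (half-open numeric intervals `[low, high)`) or flag values, optionally
#' sex-specific (`sex` in `both/female/male`) and optionally conditioned on
#' another flag (e.g. systolic-BP bands that differ by antihypertensive
#' treatment). The shipped defaults encode the CAIDE and the sex-specific
#' Framingham general-cardiovascular and stroke point systems with this
#' package's self-report adaptations (see the methods vignette).
#'
#' Validation: within each component / sex / condition stratum, band rows
#' must partition `[0, Inf)` with no gaps or overlaps, and flag rows must
#' cover both flag values exactly once. Points must be integers (negative
#' points are permitted; the Framingham general-CVD source assigns them to
#' low systolic-BP bands).
#'
#' @param path Path to a scoring-table CSV, or one of the shipped names
#'   `"caide"`, `"framingham_cvd"`, `"framingham_stroke"`.
#' @return An object of class `"scoring_table"` (a validated data.frame
#'   with attribute `score_name`).
#' @export
load_scoring_table <- function(path) {
  if (path %in% c("caide", "framingham_cvd", "framingham_stroke")) {
    name <- path
    path <- system.file("extdata", "scoring_tables", paste0(name, ".csv"),
                        package = "atnpredict", mustWork = TRUE)
  } else {
    name <- sub("\\.csv$", "", basename(path))
  }
  tb <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(low = "numeric", high = "numeric",
                                       points = "numeric"))
  needed <- c("component", "field", "sex", "type", "low", "high",
              "flag_value", "condition_field", "condition_value", "points")
  missing_cols <- setdiff(needed, names(tb))
  if (length(missing_cols))
    stop("scoring table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!all(tb$sex %in% c("both", "female", "male")))
    stop("scoring table: sex must be both/female/male")
  if (!all(tb$type %in% c("band", "flag")))
    stop("scoring table: type must be band or flag")
  if (any(tb$points != round(tb$points)))
    stop("scoring table: points must be integers")
  tb$condition_field[is.na(tb$condition_field)] <- ""
  key <- paste(tb$component, tb$sex, tb$condition_field, tb$condition_value)
  for (k in unique(key)) {
    rows <- tb[key == k, , drop = FALSE]
    if (rows$type[1] == "band") {
      rows <- rows[order(rows$low), , drop = FALSE]
      if (rows$low[1] != 0)
        stop("band partition must start at 0: ", k)
      if (!is.infinite(rows$high[nrow(rows)]))
        stop("band partition must end at Inf: ", k)
      if (nrow(rows) > 1 &&
          any(abs(rows$high[-nrow(rows)] - rows$low[-1]) > 1e-9))
        stop("band partition has a gap or overlap: ", k)
    } else {
      if (!setequal(rows$flag_value, c(0, 1)) || nrow(rows) != 2L)
        stop("flag component must cover values 0 and 1 exactly once: ", k)
    }
  }
  structure(tb, score_name = name, class = c("scoring_table", "data.frame"))
}

#' Maximum attainable total of a scoring table
#' @param table A `"scoring_table"`.
#' @param sex `"female"`, `"male"` or `"both"` (the larger of the two).
#' @return Integer maximum point total.
#' @export
scoring_table_max <- function(table, sex = "both") {
  per_sex <- function(s) {
    tb <- table[table$sex %in% c("both", s), , drop = FALSE]
    sum(tapply(tb$points, tb$component, max))
  }
  if (sex == "both") max(per_sex("female"), per_sex("male")) else per_sex(sex)
}

#' Score a cohort against a scoring table
#'
#' Sums the applicable component points for every record. A record is
#' `incomplete` — and carries no point total — when any required input is
#' missing: the field itself, the condition field of an applicable
#' conditioned component, or sex for a sex-specific table.
#'
#' @param cohort Data.frame with the fields named by the table.
#' @param table A `"scoring_table"` from [load_scoring_table()].
#' @return Data.frame with `score_name`, `raw_points` (NA when incomplete)
#'   and `incomplete`.
#' @export
score_composite <- function(cohort, table) {
  n <- nrow(cohort)
  sex_specific <- any(table$sex != "both")
  sexv <- cohort$sex_female
  total <- rep(0, n)
  incomplete <- rep(FALSE, n)
  if (sex_specific) incomplete <- incomplete | is.na(sexv)
  for (comp in unique(table$component)) {
    rows <- table[table$component == comp, , drop = FALSE]
    vals <- cohort[[rows$field[1]]]
    if (is.null(vals)) stop("cohort lacks field: ", rows$field[1])
    pts <- rep(NA_real_, n)
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      ok <- rep(TRUE, n)
      if (r$sex != "both")
        ok <- ok & !is.na(sexv) & (sexv == as.integer(r$sex == "female"))
      if (nzchar(r$condition_field)) {
        cond <- cohort[[r$condition_field]]
        if (is.null(cond)) stop("cohort lacks field: ", r$condition_field)
        ok <- ok & !is.na(cond) & cond == r$condition_value
      }
      if (r$type == "band") {
        ok <- ok & !is.na(vals) & vals >= r$low & vals < r$high
      } else {
        ok <- ok & !is.na(vals) & vals == r$flag_value
      }
      pts[which(ok)] <- r$points
    }
    # a missing field, condition, or sex leaves pts NA for that record
    incomplete <- incomplete | is.na(pts)
    total <- total + ifelse(is.na(pts), 0, pts)
  }
  data.frame(score_name = attr(table, "score_name"),
             raw_points = ifelse(incomplete, NA_real_, total),
             incomplete = incomplete)
}

#' CAIDE dementia risk score
#'
#' Sums the seven CAIDE components (age, sex, education, systolic BP, BMI,
#' cholesterol, physical inactivity). Following the self-report adaptation,
#' the cholesterol component contributes exactly 2 points when
#' `high_cholesterol` is set, replacing the original > 6.5 mmol/L
#' total-cholesterol criterion.
#'
#' @param cohort Participant data.frame.
#' @param table Scoring table (default: shipped CAIDE table).
#' @return As [score_composite()].
#' @export
caide_score <- function(cohort, table = load_scoring_table("caide")) {
  score_composite(cohort, table)
}

#' Framingham general cardiovascular disease risk score
#'
#' Sex-specific point system over age, systolic BP (separate treated and
#' untreated bands), smoking, diabetes and cholesterol. In the self-report
#' adaptation the cholesterol component awards the sex-specific diabetes
#' points when `high_cholesterol` is set.
#'
#' @inheritParams caide_score
#' @export
framingham_cvd_score <- function(cohort,
                                 table = load_scoring_table("framingham_cvd")) {
  score_composite(cohort, table)
}

#' Framingham stroke risk score
#'
#' Sex-specific point system over age, systolic BP, antihypertensive
#' treatment, diabetes, smoking, prior cardiovascular disease, atrial
#' fibrillation and left ventricular hypertrophy. LVH defaults to absent
#' when not recorded.
#'
#' @inheritParams caide_score
#' @export
framingham_stroke_score <- function(cohort,
                                    table = load_scoring_table("framingham_stroke")) {
  lvh <- cohort$left_ventricular_hypertrophy
  if (is.null(lvh)) lvh <- rep(NA_real_, nrow(cohort))
  cohort$left_ventricular_hypertrophy <- ifelse(is.na(lvh), 0, lvh)
  score_composite(cohort, table)
}

#' Cohort-wide z-standardisation of composite scores
#'
#' Composite scores enter regression models as z-scores. The mean and the
#' sample (n - 1) SD are computed over complete results only; incomplete
#' results keep a missing z-score.
#'
#' @param raw_points Numeric vector of point totals (NA = incomplete).
#' @return Numeric vector of z-scores (NA preserved).
#' @export
standardize_scores <- function(raw_points) {
  ok <- !is.na(raw_points)
  if (sum(ok) < 2L) stop("need at least 2 complete scores to standardise")
  s <- stats::sd(raw_points[ok])
  if (s <= 0) stop("degenerate scores: zero variance")
  (raw_points - mean(raw_points[ok])) / s
}

#' Attach all three composite scores (raw and z) to a cohort
#'
#' Convenience wrapper used by the pipeline: computes CAIDE, Framingham
#' general-CVD and Framingham stroke scores and their cohort-wide z-scores.
#'
#' @param cohort Participant data.frame.
#' @return `cohort` with columns `caide`, `framingham_cvd`,
#'   `framingham_stroke` and `caide_z`, `framingham_cvd_z`,
#'   `framingham_stroke_z`.
#' @export
add_composite_scores <- function(cohort) {
  cohort$caide <- caide_score(cohort)$raw_points
  cohort$framingham_cvd <- framingham_cvd_score(cohort)$raw_points
  cohort$framingham_stroke <- framingham_stroke_score(cohort)$raw_points
  cohort$caide_z <- standardize_scores(cohort$caide)
  cohort$framingham_cvd_z <- standardize_scores(cohort$framingham_cvd)
  cohort$framingham_stroke_z <- standardize_scores(cohort$framingham_stroke)
  cohort
}
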