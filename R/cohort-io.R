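#' Canonical participant-table schema
#'
#' Returns the column schema shared by every pipeline stage: one row per
#' column with its name, storage type and legal range. All other readers,
#' writers, simulators and models in the package use exactly these column
#' names.
#'
#' Types are `character` (opaque identifiers), `categorical` (site codes),
#' `numeric`, `integer`, `flag` (0/1 with tolerant parsing) and `enum`
#' (a finite numeric set, e.g. the CDR global score). Any column may be
#' missing (`NA`) unless listed in `$required_value`.
#'
#' @return A data.frame describing the schema.
#' @export
cohort_schema <- function() {
  s <- function(column, type, min = -Inf, max = Inf, levels = NA) {
    data.frame(column = column, type = type, min = min, max = max,
               levels = levels, stringsAsFactors = FALSE)
  }
  rbind(
    s("participant_id", "character"),
    s("site_id", "categorical"),
    s("age", "numeric", min = 1e-9),
    s("sex_female", "flag"),
    s("education_years", "numeric", min = 0),
    s("apoe4_carrier", "flag"),
    s("family_history", "flag"),
    s("dementia_or_mci_dx", "flag"),
    s("cdr_global", "enum", levels = "0,0.5,1,2,3"),
    s("mmse_total", "integer", min = 0, max = 30),
    s("rbans_list_learning", "numeric", min = 0),
    s("rbans_coding", "numeric", min = 0),
    s("systolic_bp", "numeric", min = 0),
    s("bmi", "numeric", min = 0),
    s("high_cholesterol", "flag"),
    s("physical_inactivity", "flag"),
    s("ever_smoked", "flag"),
    s("bp_medication", "flag"),
    s("diabetes", "flag"),
    s("prior_cvd", "flag"),
    s("atrial_fibrillation", "flag"),
    s("left_ventricular_hypertrophy", "flag"),
    s("csf_abeta42", "numeric", min = 0),
    s("csf_ptau", "numeric", min = 0),
    s("scheltens_mta", "enum",
      levels = paste(seq(0, 4, by = 0.5), collapse = ",")),
    s("wml_fraction", "numeric", min = 0)
  )
}

schema_columns <- function() cohort_schema()$column

# tolerant flag parser: 0/1/true/false/yes/no, case-insensitive; "" / "NA" -> NA
parse_flag <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_integer_, length(x))
  out[x %in% c("1", "true", "yes")] <- 1L
  out[x %in% c("0", "false", "no")] <- 0L
  bad <- !(x %in% c("1", "true", "yes", "0", "false", "no", "", "na"))
  attr(out, "bad") <- bad
  out
}

parse_num <- function(x) {
  x <- trimws(as.character(x))
  miss <- x == "" | toupper(x) == "NA"
  out <- suppressWarnings(as.numeric(x))
  out[miss] <- NA_real_
  attr(out, "bad") <- !miss & is.na(out)
  out
}

#' Read and validate a participant table
#'
#' Reads a CSV with the [cohort_schema()] columns, applying full validation:
#' each input row is either accepted as a record or rejected with a located
#' error (row index, column, message). Empty cells and the token `"NA"`
#' (case-insensitive) denote missing values; flags accept
#' `{0, 1, true, false, yes, no}` case-insensitively. Extra columns are
#' ignored with a warning; a missing schema column is an error.
#'
#' @param path Path to a CSV file with a header row.
#' @param delim Field delimiter (default `","`).
#' @return A data.frame of accepted records (typed per the schema) with
#'   attribute `"rejected"`: a data.frame of row-level errors with columns
#'   `row`, `column`, `message`. `nrow(records) + length(unique(rejected$row))`
#'   always equals the number of input rows.
#' @export
read_cohort <- function(path, delim = ",") {
  if (!file.exists(path)) stop("file does not exist: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = NULL,
                           quote = "\"", comment.char = "")
  sch <- cohort_schema()
  missing_cols <- setdiff(sch$column, names(raw))
  if (length(missing_cols) > 0L)
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(raw), sch$column)
  if (length(extra) > 0L)
    warning("ignoring extra column(s): ", paste(extra, collapse = ", "))
  raw <- raw[, sch$column, drop = FALSE]
  validate_cohort(raw)
}

#' Validate a raw (character) participant table against the schema
#'
#' Workhorse behind [read_cohort()]; exported so in-memory tables can be
#' validated the same way. Validation is total: every row is accepted or
#' produces at least one located error, and no out-of-range value is
#' silently coerced.
#'
#' @param raw A data.frame whose columns are the schema columns (values may
#'   be character or already-typed).
#' @return As [read_cohort()].
#' @export
validate_cohort <- function(raw) {
  sch <- cohort_schema()
  n <- nrow(raw)
  errs <- list()
  out <- vector("list", nrow(sch))
  names(out) <- sch$column
  add_err <- function(rows, column, message) {
    if (any(rows))
      errs[[length(errs) + 1L]] <<- data.frame(
        row = which(rows), column = column, message = message,
        stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(sch))) {
    col <- sch$column[i]
    x <- raw[[col]]
    type <- sch$type[i]
    if (type %in% c("character", "categorical")) {
      v <- trimws(as.character(x))
      v[v == "" | toupper(v) == "NA"] <- NA_character_
      out[[col]] <- v
    } else if (type == "flag") {
      v <- parse_flag(x)
      add_err(attr(v, "bad"), col, "unparseable flag value")
      attr(v, "bad") <- NULL
      out[[col]] <- v
    } else {
      v <- parse_num(x)
      add_err(attr(v, "bad"), col, "unparseable numeric value")
      attr(v, "bad") <- NULL
      oob <- !is.na(v) & (v < sch$min[i] | v > sch$max[i])
      if (type == "integer") oob <- oob | (!is.na(v) & v != round(v))
      if (type == "enum") {
        lv <- as.numeric(strsplit(sch$levels[i], ",")[[1]])
        oob <- oob | (!is.na(v) & !vapply(v, function(z)
          isTRUE(any(abs(z - lv) < 1e-9)), logical(1)))
      }
      add_err(oob, col, sprintf("value out of range for %s", col))
      out[[col]] <- v
    }
  }
  rejected <- if (length(errs)) do.call(rbind, errs) else
    data.frame(row = integer(), column = character(), message = character(),
               stringsAsFactors = FALSE)
  keep <- !(seq_len(n) %in% rejected$row)
  rec <- as.data.frame(out, stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "rejected") <- rejected[order(rejected$row), , drop = FALSE]
  rec
}

#' Write a participant (or result) table as CSV
#'
#' Missing values are written as empty cells, so
#' `read_cohort(write_cohort(x))` round-trips schema-valid tables losslessly,
#' including missingness.
#'
#' @param rows A data.frame sharing a common column set.
#' @param path Output path.
#' @param delim Field delimiter (default `","`).
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(rows, path, delim = ",") {
  utils::write.table(rows, path, sep = delim, na = "", row.names = FALSE,
                     qmethod = "double")
  invisible(path)
}
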