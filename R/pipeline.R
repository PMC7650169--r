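#' Run the simulate → cut-offs → classify → score → analyze → roc pipeline
#'
#' Executes the full analysis from a single plain-text (YAML) configuration:
#' simulate or read a cohort, derive or fix the CSF cut-offs, classify
#' A/T/N and apply the exclusion cascade, attach composite risk scores, run
#' the group-comparison and multinomial association battery, and fit the
#' nested ROC models. Stage outputs are CSVs under `output_dir`; a run
#' manifest (YAML) records the seed, a config digest, per-stage row counts
#' and output-file digests, so identical configs reproduce identical
#' digests. Any stage failure halts the run with the failing stage named;
#' prior outputs are preserved.
#'
#' @param config Path to a YAML config, or an equivalent named list. See
#'   `system.file("extdata", "epad_like.yml", package = "atnpredict")` for
#'   the shipped example; required sections: `seed`, `output_dir`,
#'   `cohort` (either `simulate: true` or `input:` a CSV path) and
#'   `thresholds`.
#' @return The manifest, invisibly (also written to
#'   `output_dir/manifest.yml`).
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  for (key in c("seed", "output_dir", "cohort", "thresholds"))
    if (is.null(cfg[[key]]))
      stop("config error: missing section '", key, "'")
  out_dir <- cfg$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    seed = cfg$seed,
    config_digest = unname(digest_text(yaml::as.yaml(
      cfg[sort(names(cfg))]))),
    stages = list(), files = list())
  stage <- function(name, f) {
    res <- tryCatch(f(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    res
  }
  seeds <- derive_stage_seeds(cfg$seed)

  cohort <- stage("simulate", function() {
    if (isTRUE(cfg$cohort$simulate)) {
      cc_args <- cfg$cohort$config %||% list()
      cc_args$seed <- seeds[["simulate"]]
      cc <- do.call(cohort_config, cc_args)
      generate_cohort(cc)
    } else {
      read_cohort(cfg$cohort$input)
    }
  })
  manifest$stages$simulate <- list(rows = nrow(cohort))
  write_stage(cohort, file.path(out_dir, "cohort.csv"), manifest) -> manifest

  rules <- stage("cutoffs", function() {
    mk <- function(analyte) {
      th <- cfg$thresholds[[analyte]]
      if (is.null(th)) stop("thresholds.", analyte, " missing")
      if (identical(th$method, "fixed")) {
        cutoff_rule(analyte, th$value,
                    if (analyte == "abeta42") "below" else "above", "fixed")
      } else if (identical(th$method, "gmm_intersection")) {
        vals <- cohort[[paste0("csf_", if (analyte == "abeta42") "abeta42"
                               else "ptau")]]
        fit <- fit_two_component_mixture(vals, seed = seeds[["cutoffs"]],
                                         n_starts = th$n_starts %||% 10L,
                                         tol = th$tol %||% 1e-8)
        intersection_cutoff(fit, analyte)
      } else stop("unknown threshold method for ", analyte)
    }
    list(abeta = mk("abeta42"), ptau = mk("ptau"))
  })
  manifest$stages$cutoffs <- list(
    abeta42 = rules$abeta$threshold, ptau = rules$ptau$threshold)

  classified <- stage("classify", function()
    classify_atn(cohort, rules$abeta, rules$ptau))
  excl <- stage("classify", function() apply_exclusions(classified))
  manifest$stages$classify <- excl$report
  write_stage(classified, file.path(out_dir, "atn.csv"), manifest) -> manifest
  exrep <- data.frame(participant_id = classified$participant_id,
                      exclusion_reason = excl$reasons)
  write_stage(exrep, file.path(out_dir, "exclusions.csv"),
              manifest) -> manifest

  analytic <- stage("score", function() add_composite_scores(excl$analytic))
  manifest$stages$score <- list(rows = nrow(analytic))
  write_stage(analytic, file.path(out_dir, "scored.csv"), manifest) -> manifest

  if (!is.null(cfg$analyze)) {
    assoc <- stage("analyze", function() {
      exps <- cfg$analyze$exposures %||% c("apoe4_carrier")
      do.call(rbind, lapply(exps, function(e)
        fit_multinomial(analytic, e,
                        include_site = isTRUE(cfg$analyze$include_site))))
    })
    manifest$stages$analyze <- list(rows = nrow(assoc))
    write_stage(assoc, file.path(out_dir, "associations.csv"),
                manifest) -> manifest
  }

  if (!is.null(cfg$roc)) {
    roc <- stage("roc", function() {
      contrasts <- cfg$roc$contrasts %||% "alzheimers_disease"
      do.call(rbind, lapply(contrasts, function(ct)
        roc_battery(analytic, ct)))
    })
    manifest$stages$roc <- list(rows = nrow(roc))
    write_stage(roc, file.path(out_dir, "roc.csv"), manifest) -> manifest
  }

  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yml"))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

digest_text <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  as.character(tools::md5sum(tf))
}

# one derived seed per stage from the master seed (kept below 2^31)
derive_stage_seeds <- function(master) {
  stages <- c("simulate", "cutoffs", "classify", "score", "analyze", "roc")
  offs <- vapply(stages, function(s)
    sum(utf8ToInt(s) * seq_along(utf8ToInt(s))), numeric(1))
  stats::setNames(as.integer((as.numeric(master) * 7919 + offs) %%
                               2147483647), stages)
}

write_stage <- function(df, path, manifest) {
  write_cohort(df, path)
  manifest$files[[basename(path)]] <-
    list(md5 = unname(as.character(tools::md5sum(path))), rows = nrow(df))
  manifest
}
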