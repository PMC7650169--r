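# shared fixtures, built in code

# one fully specified participant row in the schema layout
base_record <- function(...) {
  rec <- data.frame(
    participant_id = "P00001", site_id = "S01", age = 66,
    sex_female = 1L, education_years = 14, apoe4_carrier = 0L,
    family_history = 1L, dementia_or_mci_dx = 0L, cdr_global = 0,
    mmse_total = 29L, rbans_list_learning = 29, rbans_coding = 47,
    systolic_bp = 134, bmi = 26, high_cholesterol = 0L,
    physical_inactivity = 0L, ever_smoked = 0L, bp_medication = 0L,
    diabetes = 0L, prior_cvd = 0L, atrial_fibrillation = 0L,
    left_ventricular_hypertrophy = 0L, csf_abeta42 = 1200,
    csf_ptau = 18, scheltens_mta = 0.5, wml_fraction = 8,
    stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) rec[[nm]] <- mods[[nm]]
  rec
}

# small deterministic analytic cohort with ATN columns and scores
small_analytic_cohort <- function(seed = 7L, scale = 5L) {
  counts <- c("A-T-N-" = 567L, "A+T-N-" = 211L, "A+T+N-" = 58L,
              "A+T+N+" = 9L, "A+T-N+" = 31L, "A-T+N-" = 84L,
              "A-T+N+" = 7L, "A-T-N+" = 43L)
  cc <- cohort_config(seed = seed,
                      combo_counts = setNames(pmax(1L, counts %/% scale),
                                              names(counts)),
                      exclusion_counts = c(dementia_mci = 0L, cdr = 0L,
                                           missing_atn = 0L))
  add_composite_scores(apply_exclusions(classify_atn(
    generate_cohort(cc)))$analytic)
}

# two-group cohort drawn from the group-specific marginals (normal vs AD)
two_group_cohort <- function(seed, n_normal = 525L, n_ad = 64L) {
  cc <- cohort_config(
    seed = seed,
    combo_counts = c("A-T-N-" = n_normal,
                     "A+T+N-" = round(n_ad * 58 / 64),
                     "A+T+N+" = n_ad - round(n_ad * 58 / 64)),
    exclusion_counts = c(dementia_mci = 0L, cdr = 0L, missing_atn = 0L))
  classify_atn(generate_cohort(cc))
}

expect_no_error <- function(expr) expect_error(expr, NA)
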