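# End-to-end orchestration: simulate (or read) claims, select the cohort,
# classify CVD under every definition and window, and emit the report tables
# plus a reproducibility manifest.

#' Configure a pipeline run
#'
#' Either `claims_dir` (an existing interchange-schema extract, see
#' [read_claims()]) or `simulation` (a [sim_config()]) must be given.
#'
#' @param claims_dir Directory with the five claims files, or `NULL`.
#' @param simulation A [sim_config()], or `NULL`.
#' @param definitions CVD definition names to sweep.
#' @param start_years Window start years (windows all end in `index_year`).
#' @param index_year Index calendar year.
#' @param use_ops Whether OPS procedures contribute to CVD classification.
#' @param z Critical value for confidence intervals.
#' @param reference_population Insured population the totals are
#'   extrapolated to (default: persons with German statutory health
#'   insurance in 2015).
#' @return An object of class `run_config`.
#' @export
pipeline_config <- function(claims_dir = NULL, simulation = NULL,
                            definitions = c("narrow", "narrow_chf", "wide"),
                            start_years = 2010:2015, index_year = 2015L,
                            use_ops = TRUE, z = 1.96,
                            reference_population = 70728398) {
  if (is.null(claims_dir) && is.null(simulation)) {
    abort("pipeline_config(): provide either claims_dir or a simulation config",
      class = "t2dcvd_config_error"
    )
  }
  if (!is.null(simulation)) validate_sim_config(simulation)
  structure(
    list(
      claims_dir = claims_dir, simulation = simulation,
      definitions = definitions, start_years = as.integer(start_years),
      index_year = as.integer(index_year), use_ops = isTRUE(use_ops),
      z = z, reference_population = reference_population
    ),
    class = "run_config"
  )
}

#' Run the full phenotyping and reporting pipeline
#'
#' Stages: load or simulate the claims bundle; select the study population
#' (adult, continuously enrolled); identify T2D cases; characterize them
#' (comorbidity, events, therapy, duration); classify CVD under the primary
#' definition and sweep definitions x windows; estimate prevalences with
#' confidence intervals and extrapolate to the reference population. When
#' `out_dir` is given, writes `table1.csv` (database-wide one-year
#' prevalence of cardiovascular conditions), `table2.csv` (selection flow
#' and cohort characteristics), `table3.csv` (primary CVD prevalence by
#' sex), `table4.csv` (definition x window grid), `cohort.csv` (per-person
#' decisions) and `manifest.json` (config echo, code sets, row counts,
#' package version) for audit and byte-identical re-runs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list: `bundle`, `cohort`, `tables` (named list of
#'   tibbles), `summary`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(fmt, ...) if (!quiet) rlang::inform(sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        class = "t2dcvd_pipeline_error", parent = e
      )
    })
  }
  iy <- config$index_year

  truth <- NULL
  bundle <- stage("load", {
    if (!is.null(config$simulation)) {
      sim <- simulate_claims(config$simulation)
      truth <- sim$ground_truth
      sim$bundle
    } else {
      suppressMessages(read_claims(config$claims_dir))
    }
  })
  say("stage load: %d persons, %d diagnoses", nrow(bundle$persons), nrow(bundle$diagnoses))

  cohort <- stage("cohort", build_cohort(bundle, index_year = iy))
  n_total <- nrow(cohort)
  n_adult <- sum(cohort$adult, na.rm = TRUE)
  n_enrolled_adult <- sum(cohort$adult & cohort$continuously_enrolled, na.rm = TRUE)
  n_cases <- sum(cohort$is_case)
  n_e14_excluded <- sum(cohort$excluded_e14_only, na.rm = TRUE)
  say(
    "stage cohort: %d persons -> %d adults -> %d continuously enrolled -> %d T2D cases (%d excluded E14-only)",
    n_total, n_adult, n_enrolled_adult, n_cases, n_e14_excluded
  )
  case_ids <- cohort$person_id[cohort$is_case]
  if (n_cases == 0L) {
    abort("pipeline stage 'cohort' failed: no T2D cases identified",
      class = "t2dcvd_pipeline_error"
    )
  }

  classified <- stage("classify", {
    primary <- build_definition(config$definitions[1], use_ops = config$use_ops)
    cvd <- classify_cvd(bundle, case_ids, primary,
      window = c(min(config$start_years), iy)
    )
    char <- characterize(bundle, case_ids, index_year = iy)
    ther <- classify_therapy(bundle, case_ids, index_year = iy)
    cvd %>%
      left_join(char, by = "person_id") %>%
      left_join(ther, by = "person_id")
  })
  cohort <- left_join(cohort, classified, by = "person_id")
  cases <- filter(cohort, .data$is_case)
  say("stage classify: %d of %d cases CVD-positive (primary definition)",
    sum(cases$cvd), n_cases)

  tables <- stage("report", {
    t1 <- database_one_year_table(bundle, iy, z = config$z)
    t2 <- selection_flow_table(cohort, n_total, n_adult, n_enrolled_adult,
      n_cases, n_e14_excluded)
    t3 <- stratify(cases, by = "sex", outcome = "cvd", z = config$z)
    t4 <- window_sweep(bundle, case_ids,
      definitions = config$definitions,
      start_years = config$start_years, end_year = iy,
      use_ops = config$use_ops, z = config$z
    )
    list(table1 = t1, table2 = t2, table3 = t3, table4 = t4)
  })

  extr <- extrapolate(sum(cases$cvd), n_total, config$reference_population)
  summary <- tibble(
    n_persons = n_total, n_adult = n_adult,
    n_continuously_enrolled_adult = n_enrolled_adult,
    n_t2d_cases = n_cases, n_e14_excluded = n_e14_excluded,
    t2d_prevalence_pct = prevalence(n_cases, n_enrolled_adult, z = config$z)$percent,
    cvd_numerator = sum(cases$cvd),
    cvd_prevalence_pct = prevalence(sum(cases$cvd), n_cases, z = config$z)$percent,
    extrapolated_cvd_count = extr$extrapolated_count
  )

  manifest <- list(
    package = "t2dcvd",
    version = as.character(utils::packageVersion("t2dcvd")),
    config = unclass(config)[c(
      "claims_dir", "definitions", "start_years", "index_year",
      "use_ops", "z", "reference_population"
    )],
    simulation = if (!is.null(config$simulation)) unclass(config$simulation),
    code_sets = load_cvd_codes(),
    counts = list(
      persons = n_total, adults = n_adult,
      continuously_enrolled_adults = n_enrolled_adult,
      t2d_cases = n_cases, e14_excluded = n_e14_excluded,
      claims_rows = lapply(bundle[claim_tables], nrow)
    )
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables)) {
      readr::write_csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    }
    readr::write_csv(cohort, file.path(out_dir, "cohort.csv"))
    readr::write_csv(summary, file.path(out_dir, "summary.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA
    )
    say("report written to %s", out_dir)
  }

  invisible(list(
    bundle = bundle, cohort = cohort, ground_truth = truth,
    tables = tables, summary = summary, manifest = manifest
  ))
}

# database-wide one-year prevalence of common cardiovascular conditions,
# computed over all persons in the bundle (stroke/PVD/AMI reuse the
# macrovascular component sets; PVD here is peripheral vascular disease I73.9)
database_one_year_table <- function(bundle, index_year, z = 1.96) {
  year_of <- function(d) as.integer(format(d, "%Y"))
  dxq <- assured_diagnoses(bundle$diagnoses) %>%
    filter(year_of(.data$service_date) == index_year)
  n_all <- nrow(bundle$persons)
  conditions <- list(
    hypertension = code_set("hypertension", "ICD", "I10"),
    chronic_heart_failure = code_set("chf", "ICD", "I50"),
    stroke = code_set("stroke", "ICD", c("I60", "I61", "I62", "I63", "I64")),
    peripheral_vascular_disease = code_set("pvd", "ICD", "I739"),
    acute_myocardial_infarction = code_set("ami", "ICD", "I21"),
    chronic_kidney_disease_5 = code_set("ckd5", "ICD", "N185")
  )
  purrr::imap_dfr(conditions, function(cs, label) {
    n <- dplyr::n_distinct(dxq$person_id[code_matches(dxq$icd_code, cs)])
    est <- prevalence(n, n_all, z = z, digits = 1)
    dplyr::bind_cols(tibble(condition = label), est)
  })
}

selection_flow_table <- function(cohort, n_total, n_adult, n_enrolled_adult,
                                 n_cases, n_e14_excluded) {
  cases <- filter(cohort, .data$is_case)
  pct_of_adult <- function(n) round_half_up(100 * n / n_adult, 1)
  flow <- tibble(
    parameter = c(
      "persons_in_database", "adult_at_index", "continuously_enrolled",
      "t2d_cases", "excluded_e14_only"
    ),
    n = c(n_total, n_adult, n_enrolled_adult, n_cases, n_e14_excluded),
    pct_of_adults = c(NA, 100, pct_of_adult(n_enrolled_adult),
      pct_of_adult(n_cases), pct_of_adult(n_e14_excluded))
  )
  pct_cases <- function(x) round_half_up(100 * mean(x), 1)
  chars <- tibble(
    parameter = c(
      "female_pct", "male_pct", "mean_age", "mean_age_female", "mean_age_male",
      "age_u40_pct", "age_40_59_pct", "age_60_79_pct", "age_80plus_pct",
      "duration_5plus_pct", "duration_4y_pct", "duration_3y_pct",
      "duration_2y_pct", "duration_1y_pct", "incident_pct",
      "hypertension_pct", "lipometabolic_pct", "macrovascular_event_pct",
      "microvascular_event_pct", "t2d_hospitalization_pct",
      "pharmacotherapy_pct", "insulin_pct"
    ),
    n = NA_real_,
    pct_of_adults = NA_real_
  )
  chars$value <- c(
    pct_cases(cases$sex == "female"), pct_cases(cases$sex == "male"),
    round_half_up(mean(cases$age), 1),
    round_half_up(mean(cases$age[cases$sex == "female"]), 1),
    round_half_up(mean(cases$age[cases$sex == "male"]), 1),
    pct_cases(cases$age < 40), pct_cases(cases$age >= 40 & cases$age < 60),
    pct_cases(cases$age >= 60 & cases$age < 80), pct_cases(cases$age >= 80),
    pct_cases(cases$duration_category == "5plus"),
    pct_cases(cases$duration_category == "4y"),
    pct_cases(cases$duration_category == "3y"),
    pct_cases(cases$duration_category == "2y"),
    pct_cases(cases$duration_category == "1y"),
    pct_cases(startsWith(cases$duration_category, "incident")),
    pct_cases(cases$hypertension), pct_cases(cases$lipometabolic),
    pct_cases(cases$macrovascular_event), pct_cases(cases$microvascular_event),
    pct_cases(cases$t2d_hospitalization),
    pct_cases(cases$therapy_class != "none"), pct_cases(cases$insulin)
  )
  flow$value <- NA_real_
  bind_rows(flow, chars)
}
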