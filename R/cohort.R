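# Study-population selection: continuous-enrollment / adult-age eligibility,
# the four-criterion claims-based T2D case-identification algorithm with the
# unspecific-diabetes (E14) exclusion, and diabetes-duration categories.

#' Eligibility for the study population
#'
#' A person enters the study population when they are an adult (age >= 18 on
#' 1 January of the index year, computed from birth year alone) and
#' continuously enrolled from 1 January of `index_year - 5` through
#' 31 December of the index year. Decedents stay eligible when their
#' enrollment runs to death: the span only needs to cover
#' `min(31 Dec index_year, death_date)`. Whether T2D evidence precedes death
#' is enforced in [identify_t2d()], not here.
#'
#' @param persons The `persons` table of a [claims_bundle()] (or the bundle
#'   itself).
#' @param index_year Index calendar year (default 2015).
#' @return A tibble with one row per person: `person_id`, `adult`,
#'   `continuously_enrolled`, `eligible` and a `reason` string (non-empty
#'   whenever a flag is false).
#' @export
check_eligibility <- function(persons, index_year = 2015L) {
  if (inherits(persons, "claims_bundle")) persons <- persons$persons
  persons <- as_tibble(persons)
  span_start <- as.Date(sprintf("%d-01-01", index_year - 5L))
  span_end <- as.Date(sprintf("%d-12-31", index_year))
  required_end <- pmin(span_end, dplyr::coalesce(persons$death_date, span_end))
  adult <- (index_year - persons$birth_year) >= 18L
  enrolled <- persons$enrollment_start <= span_start &
    persons$enrollment_end >= required_end
  reason <- dplyr::case_when(
    !adult & !enrolled ~ "under 18; enrollment does not cover the study period",
    !adult ~ "under 18 at index",
    !enrolled ~ "enrollment does not cover the study period",
    TRUE ~ ""
  )
  tibble(
    person_id = persons$person_id, adult = adult,
    continuously_enrolled = enrolled, eligible = adult & enrolled,
    reason = reason
  )
}

# qualifying diagnoses: assured ("gesichert") ambulatory, or any hospital
# setting. Suspected (V), excluded (A) and status-post (Z) ambulatory
# qualifiers never count as evidence.
assured_diagnoses <- function(diagnoses) {
  filter(
    diagnoses,
    .data$setting %in% c("hospital_main", "hospital_secondary") |
      (.data$setting == "ambulatory" & .data$qualifier == "G")
  )
}

# restrict any event table to rows at or before a person's death
drop_post_death <- function(tab, persons, date_col) {
  dd <- persons$death_date[match(tab$person_id, persons$person_id)]
  tab[is.na(dd) | tab[[date_col]] <= dd, , drop = FALSE]
}

#' Identify T2D cases from one index year of claims
#'
#' Implements a pharmacoepidemiologic case-identification algorithm for type
#' 2 diabetes. A person is a case when at least one of four criteria holds in
#' the index year and the unspecific-diabetes exclusion does not apply:
#'
#' * **C1** -- at least one prescription of a non-insulin glucose-lowering
#'   agent (ATC `A10B`) in at least two distinct calendar quarters;
#' * **C2** -- at least one glucose-lowering prescription (any `A10`) plus at
#'   least one E11 diagnosis (assured ambulatory, or hospital main/secondary);
#' * **C3** -- at least one `A10B` prescription with a blood-glucose/HbA1c
#'   lab billing (EBM 32025, 32057, 32881, 32094) by the prescribing
#'   physician in the prescription quarter;
#' * **C4** -- E11 diagnoses (assured ambulatory or hospital) in at least
#'   three of the four quarters.
#'
#' The exclusion removes persons qualifying *only* through the drug-based
#' criteria (C1/C3) who carry an unspecific-diabetes (E14) diagnosis but no
#' E11 in the index year. For decedents only evidence up to the death date
#' counts. Persons qualifying via C1 alone with no diabetes diagnosis of any
#' kind are retained and flagged (`no_diabetes_dx`).
#'
#' @param bundle A [claims_bundle()].
#' @param person_ids Persons to evaluate (default: all persons in the
#'   bundle); pass the eligible set from [check_eligibility()].
#' @param index_year Index calendar year (default 2015).
#' @return A tibble with one row per requested person: criterion flags
#'   `c1_two_quarter_a10b`, `c2_a10_plus_e11`, `c3_a10b_plus_lab`,
#'   `c4_e11_three_quarters`, `excluded_e14_only`, `is_case`,
#'   `no_diabetes_dx`.
#' @export
identify_t2d <- function(bundle, person_ids = NULL, index_year = 2015L) {
  stopifnot(inherits(bundle, "claims_bundle"))
  persons <- bundle$persons
  if (is.null(person_ids)) person_ids <- persons$person_id
  unknown <- setdiff(person_ids, persons$person_id)
  if (length(unknown)) {
    abort(sprintf(
      "identify_t2d(): person id(s) not in bundle: %s",
      paste(head(unknown, 3L), collapse = ", ")
    ), class = "t2dcvd_input_error")
  }

  year_of <- function(d) as.integer(format(d, "%Y"))
  rx <- bundle$prescriptions %>%
    filter(.data$person_id %in% .env$person_ids, year_of(.data$dispense_date) == index_year) %>%
    drop_post_death(persons, "dispense_date")
  dxq <- assured_diagnoses(bundle$diagnoses) %>%
    filter(.data$person_id %in% .env$person_ids, year_of(.data$service_date) == index_year) %>%
    drop_post_death(persons, "service_date")
  lab <- bundle$lab_services %>%
    filter(
      .data$person_id %in% .env$person_ids,
      year_of(.data$service_date) == index_year,
      .data$ebm_code %in% glucose_ebm_codes()
    ) %>%
    drop_post_death(persons, "service_date")

  a10 <- filter(rx, startsWith(.data$atc_code, "A10"))
  a10b <- filter(a10, startsWith(.data$atc_code, "A10B"))
  e11 <- filter(dxq, startsWith(.data$icd_code, "E11"))
  e14 <- filter(dxq, startsWith(.data$icd_code, "E14"))

  c1_ids <- a10b %>%
    distinct(.data$person_id, qk = quarter_key(.data$dispense_date)) %>%
    count(.data$person_id) %>%
    filter(.data$n >= 2L) %>%
    pull(.data$person_id)
  c2_ids <- intersect(unique(a10$person_id), unique(e11$person_id))
  c3_ids <- a10b %>%
    mutate(qk = quarter_key(.data$dispense_date)) %>%
    inner_join(
      lab %>% mutate(qk = quarter_key(.data$service_date)) %>%
        distinct(.data$person_id, .data$qk, .data$physician_id),
      by = c("person_id", "qk", prescriber_id = "physician_id")
    ) %>%
    pull(.data$person_id) %>%
    unique()
  c4_ids <- e11 %>%
    distinct(.data$person_id, qk = quarter_key(.data$service_date)) %>%
    count(.data$person_id) %>%
    filter(.data$n >= 3L) %>%
    pull(.data$person_id)

  out <- tibble(person_id = person_ids) %>%
    mutate(
      c1_two_quarter_a10b = .data$person_id %in% c1_ids,
      c2_a10_plus_e11 = .data$person_id %in% c2_ids,
      c3_a10b_plus_lab = .data$person_id %in% c3_ids,
      c4_e11_three_quarters = .data$person_id %in% c4_ids,
      has_e11 = .data$person_id %in% unique(e11$person_id),
      has_e14 = .data$person_id %in% unique(e14$person_id),
      excluded_e14_only = (.data$c1_two_quarter_a10b | .data$c3_a10b_plus_lab) &
        .data$has_e14 & !.data$has_e11,
      is_case = (.data$c1_two_quarter_a10b | .data$c2_a10_plus_e11 |
        .data$c3_a10b_plus_lab | .data$c4_e11_three_quarters) &
        !.data$excluded_e14_only,
      no_diabetes_dx = .data$is_case & !.data$has_e11 & !.data$has_e14
    ) %>%
    select(-"has_e11", -"has_e14")
  out
}

#' Time since first claims evidence of diabetes
#'
#' The earliest year in `(index_year - 5):index_year` with an E11 diagnosis
#' (assured ambulatory or hospital) or any glucose-lowering (`A10`)
#' prescription defines the first evidence year; cases with no evidence
#' before the index year are incident. First evidence in the earliest
#' observable year is censored into the open-ended `5plus` category.
#'
#' @inheritParams identify_t2d
#' @return A tibble: `person_id`, `first_evidence_year` (`NA` when the index
#'   year itself is the first), `duration_category` with levels
#'   `incident_2015`, `1y` .. `4y`, `5plus` (labels follow `index_year`).
#' @export
duration_category <- function(bundle, person_ids = NULL, index_year = 2015L) {
  stopifnot(inherits(bundle, "claims_bundle"))
  persons <- bundle$persons
  if (is.null(person_ids)) person_ids <- persons$person_id
  year_of <- function(d) as.integer(format(d, "%Y"))
  first_year <- bind_rows(
    assured_diagnoses(bundle$diagnoses) %>%
      filter(startsWith(.data$icd_code, "E11")) %>%
      drop_post_death(persons, "service_date") %>%
      mutate(year = year_of(.data$service_date)) %>%
      select("person_id", "year"),
    bundle$prescriptions %>%
      filter(startsWith(.data$atc_code, "A10")) %>%
      drop_post_death(persons, "dispense_date") %>%
      mutate(year = year_of(.data$dispense_date)) %>%
      select("person_id", "year")
  ) %>%
    filter(
      .data$person_id %in% .env$person_ids,
      .data$year >= index_year - 5L, .data$year <= index_year
    ) %>%
    group_by(.data$person_id) %>%
    summarise(first_evidence_year = min(.data$year), .groups = "drop")

  incident_label <- sprintf("incident_%d", index_year)
  tibble(person_id = person_ids) %>%
    left_join(first_year, by = "person_id") %>%
    mutate(duration_category = case_when(
      is.na(.data$first_evidence_year) ~ incident_label,
      .data$first_evidence_year >= index_year ~ incident_label,
      .data$first_evidence_year == index_year - 5L ~ "5plus",
      TRUE ~ sprintf("%dy", index_year - .data$first_evidence_year)
    ))
}

#' Build the analysis cohort table
#'
#' Runs [check_eligibility()], [identify_t2d()] and [duration_category()] and
#' returns one row per person in the bundle with demographics (age at 1
#' January of the index year, age band), eligibility, criterion flags, case
#' status and diabetes duration. Downstream stages ([classify_cvd()],
#' [characterize()], [classify_therapy()]) join onto this table.
#'
#' @inheritParams identify_t2d
#' @return A tibble, one row per person.
#' @export
build_cohort <- function(bundle, index_year = 2015L) {
  stopifnot(inherits(bundle, "claims_bundle"))
  elig <- check_eligibility(bundle$persons, index_year)
  eligible_ids <- elig$person_id[elig$eligible]
  dec <- identify_t2d(bundle, eligible_ids, index_year)
  case_ids <- dec$person_id[dec$is_case]
  dur <- duration_category(bundle, case_ids, index_year)

  bundle$persons %>%
    mutate(
      age = index_year - .data$birth_year,
      age_band = cut(.data$age,
        breaks = c(-Inf, 17, 39, 59, 79, Inf),
        labels = c("u18", "18-39", "40-59", "60-79", "80+")
      ) %>% as.character()
    ) %>%
    select("person_id", "sex", "birth_year", "age", "age_band", "death_date") %>%
    left_join(elig, by = "person_id") %>%
    left_join(dec, by = "person_id") %>%
    left_join(dur, by = "person_id") %>%
    mutate(is_case = dplyr::coalesce(.data$is_case, FALSE))
}

#' Sensitivity and specificity of case identification against ground truth
#'
#' Compares the algorithmic case flag with the simulator's latent T2D state.
#' Only persons present in both tables are scored (typically the eligible
#' set).
#'
#' @param decisions Output of [identify_t2d()] or [build_cohort()].
#' @param ground_truth The `ground_truth` tibble from [simulate_claims()].
#' @return A one-row tibble: `n`, `sensitivity`, `specificity`, `ppv`.
#' @export
phenotype_performance <- function(decisions, ground_truth) {
  m <- inner_join(
    select(decisions, "person_id", "is_case"),
    select(ground_truth, "person_id", "true_t2d"),
    by = "person_id"
  )
  tibble(
    n = nrow(m),
    sensitivity = mean(m$is_case[m$true_t2d]),
    specificity = mean(!m$is_case[!m$true_t2d]),
    ppv = mean(m$true_t2d[m$is_case])
  )
}
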