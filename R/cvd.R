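# Executable CVD definitions: named prefix-inclusion/exclusion code sets over
# ICD-10-GM and OPS, window-parameterized classification, comorbidity and
# therapy characterization.

#' Construct a prefix code set
#'
#' A code set is the executable form of a disease definition: a named set of
#' normalized code prefixes to include, minus a set of prefixes to exclude.
#' A code matches when it extends (or equals) an include prefix and extends
#' no exclude prefix; exclusion overrides inclusion regardless of prefix
#' length. Dotted or dashed spellings are accepted and normalized.
#'
#' @param name Label for the set.
#' @param system `"ICD"` or `"OPS"`.
#' @param include,exclude Character vectors of code prefixes.
#' @return An object of class `code_set`.
#' @examples
#' cs <- code_set("ihd", "ICD", include = c("I24", "I25"),
#'                exclude = c("I25.3", "I25.4", "I25.10", "I25.19"))
#' code_matches(c("I2511", "I2510"), cs) # TRUE FALSE
#' @export
code_set <- function(name, system = c("ICD", "OPS"), include, exclude = character()) {
  system <- match.arg(system)
  include <- unique(normalize_code(include, system))
  exclude <- if (length(exclude)) unique(normalize_code(exclude, system)) else character()
  extends_some <- function(x, prefixes) {
    vapply(x, function(cc) any(startsWith(cc, prefixes)), logical(1))
  }
  if (length(exclude)) {
    orphan <- !extends_some(exclude, include)
    if (any(orphan)) {
      abort(sprintf(
        "code_set '%s': exclude prefix '%s' extends no include prefix",
        name, exclude[orphan][1L]
      ), class = "t2dcvd_config_error")
    }
    if (any(include %in% exclude)) {
      abort(sprintf("code_set '%s': include and exclude prefixes overlap", name),
        class = "t2dcvd_config_error"
      )
    }
  }
  structure(
    list(name = name, system = system, include = include, exclude = exclude),
    class = "code_set"
  )
}

#' @rdname code_set
#' @param codes Character vector of codes (normalized or raw).
#' @param cs A `code_set`.
#' @param system Coding system of `codes`; must equal the set's system.
#' @return `code_matches()`: logical vector, one element per code.
#' @export
code_matches <- function(codes, cs, system = cs$system) {
  stopifnot(inherits(cs, "code_set"))
  if (!identical(system, cs$system)) {
    abort(sprintf(
      "code system mismatch: codes are %s, code set '%s' is %s",
      system, cs$name, cs$system
    ), class = "t2dcvd_config_error")
  }
  if (length(codes) == 0L) {
    return(logical())
  }
  codes <- normalize_code(codes, cs$system)
  if (length(cs$include) == 0L) {
    return(rep(FALSE, length(codes)))
  }
  inc <- vapply(codes, function(cc) any(startsWith(cc, cs$include)), logical(1))
  if (length(cs$exclude)) {
    exc <- vapply(codes, function(cc) any(startsWith(cc, cs$exclude)), logical(1))
    inc <- inc & !exc
  }
  unname(inc)
}

#' @export
print.code_set <- function(x, ...) {
  cat(sprintf(
    "<code_set '%s' (%s): %d include, %d exclude prefixes>\n",
    x$name, x$system, length(x$include), length(x$exclude)
  ))
  invisible(x)
}

#' Path to the bundled CVD code-set configuration
#'
#' The include/exclude prefix lists behind [build_definition()] are shipped
#' as a JSON file so a run can echo the exact definition it used and users
#' can supply edited variants.
#'
#' @return File path of the bundled JSON.
#' @export
cvd_codes_config_path <- function() {
  system.file("extdata", "cvd_code_sets.json", package = "t2dcvd", mustWork = TRUE)
}

load_cvd_codes <- function(path = cvd_codes_config_path()) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Build a CVD definition
#'
#' Three definitions of prevalent cardiovascular disease, of increasing
#' breadth, each a pair of ICD-10-GM and OPS code sets:
#'
#' * `narrow` -- aligned to the inclusion criteria of a cardiovascular
#'   outcome trial: cerebrovascular disease and stroke (I63/I64), unstable
#'   angina and ischemic heart disease (I20.0, I21--I22, I24--I25 excluding
#'   I25.3/.4/.10/.19), peripheral arterial occlusive disease (I73.9,
#'   I70.2x), plus coronary revascularization (OPS 5-361/5-362/5-363) and
#'   bypass/stent procedures (OPS 8-836/8-837/8-84x);
#' * `narrow_chf` -- the narrow set plus chronic heart failure (I50);
#' * `wide` -- additionally intracranial hemorrhage (I60--I64) and all
#'   ischemic heart disease codes (I20--I25, no exclusions).
#'
#' The `x` suffix in printed code lists denotes child codes and is read as a
#' bare prefix (8-84, I702).
#'
#' @param name One of `"narrow"`, `"narrow_chf"`, `"wide"`.
#' @param use_ops Whether OPS procedure codes contribute to classification
#'   (the OPS-exclusion sensitivity analysis sets this to `FALSE`).
#' @param config_path JSON file with the prefix lists; defaults to the
#'   bundled configuration.
#' @return An object of class `cvd_definition` with elements `name`,
#'   `icd_set`, `ops_set`, `use_ops`.
#' @export
build_definition <- function(name = c("narrow", "narrow_chf", "wide"),
                             use_ops = TRUE,
                             config_path = cvd_codes_config_path()) {
  name <- match.arg(name)
  cfg <- load_cvd_codes(config_path)
  if (!name %in% names(cfg)) {
    abort(sprintf("unknown CVD definition '%s' in %s", name, config_path),
      class = "t2dcvd_config_error"
    )
  }
  entry <- cfg[[name]]
  structure(
    list(
      name = name,
      icd_set = code_set(paste0(name, "_icd"), "ICD",
        include = entry$icd_include,
        exclude = entry$icd_exclude %||% character()
      ),
      ops_set = code_set(paste0(name, "_ops"), "OPS", include = entry$ops_include),
      use_ops = isTRUE(use_ops)
    ),
    class = "cvd_definition"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cvd_definition <- function(x, ...) {
  cat(sprintf(
    "<cvd_definition '%s'%s: ICD prefixes %s%s; OPS %s>\n",
    x$name, if (x$use_ops) "" else " (OPS disabled)",
    paste(x$icd_set$include, collapse = ","),
    if (length(x$icd_set$exclude)) {
      paste0(" excl ", paste(x$icd_set$exclude, collapse = ","))
    } else {
      ""
    },
    paste(x$ops_set$include, collapse = ",")
  ))
  invisible(x)
}

#' Classify prevalent CVD within an observation window
#'
#' A person counts as having a history of CVD when at least one diagnosis
#' (assured ambulatory -- the M1Q convention -- or any hospital setting)
#' matches the definition's ICD set within the window, or, when the
#' definition uses procedures, at least one OPS procedure matches within the
#' window. The first matching event is returned for audit.
#'
#' @param bundle A [claims_bundle()].
#' @param person_ids Persons to classify (typically the T2D cases).
#' @param definition A [build_definition()] object.
#' @param window Two-element integer vector `c(start_year, end_year)`,
#'   inclusive calendar years.
#' @return A tibble: `person_id`, `cvd` (logical), `first_hit_date`,
#'   `first_hit_code`, `first_hit_source` (`"diagnosis"`/`"procedure"`).
#' @export
classify_cvd <- function(bundle, person_ids = NULL, definition = build_definition("narrow"),
                         window = c(2010L, 2015L)) {
  stopifnot(inherits(bundle, "claims_bundle"), inherits(definition, "cvd_definition"))
  stopifnot(length(window) == 2L, window[1] <= window[2])
  if (is.null(person_ids)) person_ids <- bundle$persons$person_id
  year_of <- function(d) as.integer(format(d, "%Y"))

  dx <- assured_diagnoses(bundle$diagnoses) %>%
    filter(
      .data$person_id %in% .env$person_ids,
      year_of(.data$service_date) >= window[1],
      year_of(.data$service_date) <= window[2]
    )
  hits <- dx[code_matches(dx$icd_code, definition$icd_set), ] %>%
    mutate(code = .data$icd_code, source = "diagnosis") %>%
    select("person_id", date = "service_date", "code", "source")
  if (definition$use_ops) {
    pr <- bundle$procedures %>%
      filter(
        .data$person_id %in% .env$person_ids,
        year_of(.data$service_date) >= window[1],
        year_of(.data$service_date) <= window[2]
      )
    hits <- bind_rows(
      hits,
      pr[code_matches(pr$ops_code, definition$ops_set), ] %>%
        mutate(code = .data$ops_code, source = "procedure") %>%
        select("person_id", date = "service_date", "code", "source")
    )
  }
  first_hits <- hits %>%
    arrange(.data$person_id, .data$date, .data$source, .data$code) %>%
    group_by(.data$person_id) %>%
    slice(1L) %>%
    ungroup()
  tibble(person_id = person_ids) %>%
    left_join(first_hits, by = "person_id") %>%
    mutate(cvd = !is.na(.data$date)) %>%
    select("person_id", "cvd",
      first_hit_date = "date", first_hit_code = "code",
      first_hit_source = "source"
    )
}

# component code sets behind the characterization flags (hospitalization-based
# macro-/microvascular events)
macro_icd_set <- function() {
  code_set("macrovascular_icd", "ICD",
    include = c("I60", "I61", "I62", "I63", "I64", "I21", "I50", "I739", "I20")
  )
}
macro_ops_set <- function() {
  code_set("macrovascular_ops", "OPS",
    include = c("5-361", "5-362", "5-363", "8-836", "8-837", "8-84")
  )
}
micro_icd_set <- function() code_set("microvascular_icd", "ICD", include = "N185")
micro_ops_set <- function() {
  code_set("microvascular_ops", "OPS", include = c("5-864", "5-865", "5-158", "5-159"))
}

#' Index-year characterization of T2D cases
#'
#' Comorbidity and event flags for the index year:
#' * `hypertension` -- any essential-hypertension (I10) diagnosis (assured
#'   ambulatory or hospital);
#' * `lipometabolic` -- any lipid-disorder (E78) diagnosis;
#' * `macrovascular_event` -- hospitalization due to stroke (I60--I64),
#'   acute myocardial infarction (I21), congestive heart failure (I50),
#'   coronary revascularization (OPS 5-361/5-362/5-363), percutaneous
#'   intervention or stent (OPS 8-836/8-837/8-84), peripheral vascular
#'   disease (I73.9) or angina pectoris (I20): hospital-setting diagnoses
#'   and procedures only;
#' * `microvascular_event` -- hospitalization due to lower-extremity
#'   amputation (OPS 5-864/5-865), vitrectomy (OPS 5-158/5-159) or
#'   chronic kidney disease stage 5 (N18.5);
#' * `t2d_hospitalization` -- E11 as hospital main diagnosis.
#'
#' @inheritParams classify_cvd
#' @param index_year Calendar year the flags refer to.
#' @return A tibble with one row per requested person and the five flags.
#' @export
characterize <- function(bundle, person_ids = NULL, index_year = 2015L) {
  stopifnot(inherits(bundle, "claims_bundle"))
  if (is.null(person_ids)) person_ids <- bundle$persons$person_id
  year_of <- function(d) as.integer(format(d, "%Y"))
  dx <- bundle$diagnoses %>%
    filter(.data$person_id %in% .env$person_ids, year_of(.data$service_date) == index_year)
  dxq <- assured_diagnoses(dx)
  hosp <- filter(dx, .data$setting %in% c("hospital_main", "hospital_secondary"))
  pr <- bundle$procedures %>%
    filter(.data$person_id %in% .env$person_ids, year_of(.data$service_date) == index_year)

  ids_with <- function(tab, col, cs) unique(tab$person_id[code_matches(tab[[col]], cs)])
  hyp_ids <- unique(dxq$person_id[startsWith(dxq$icd_code, "I10")])
  lip_ids <- unique(dxq$person_id[startsWith(dxq$icd_code, "E78")])
  macro_ids <- union(
    ids_with(hosp, "icd_code", macro_icd_set()),
    ids_with(pr, "ops_code", macro_ops_set())
  )
  micro_ids <- union(
    ids_with(hosp, "icd_code", micro_icd_set()),
    ids_with(pr, "ops_code", micro_ops_set())
  )
  t2dh_ids <- unique(dx$person_id[dx$setting == "hospital_main" &
    startsWith(dx$icd_code, "E11")])

  tibble(person_id = person_ids) %>%
    mutate(
      hypertension = .data$person_id %in% hyp_ids,
      lipometabolic = .data$person_id %in% lip_ids,
      macrovascular_event = .data$person_id %in% macro_ids,
      microvascular_event = .data$person_id %in% micro_ids,
      t2d_hospitalization = .data$person_id %in% t2dh_ids
    )
}

#' ATC subclass map for glucose-lowering drugs
#'
#' Maps ATC prefixes to pharmacologic classes used by [classify_therapy()]:
#' metformin (A10BA), sulfonylureas (A10BB), DPP-4 inhibitors (A10BH), GLP-1
#' receptor agonists (A10BJ), SGLT-2 inhibitors (A10BK), glinides
#' (A10BX02/A10BX03), alpha-glucosidase inhibitors (A10BF), and fixed
#' metformin combinations (A10BD02/07/08/10/11/15/16/20) expanded to their
#' components. The map is an editable table: supply a modified copy through
#' the `atc_map` argument of [classify_therapy()] to override it.
#'
#' @return A tibble with columns `atc_prefix` and `classes` (list column of
#'   component class labels).
#' @export
default_atc_classes <- function() {
  tibble(
    atc_prefix = c(
      "A10BA", "A10BB", "A10BH", "A10BJ", "A10BK", "A10BX02", "A10BX03",
      "A10BF", "A10BD02", "A10BD05", "A10BD07", "A10BD08", "A10BD10",
      "A10BD11", "A10BD15", "A10BD16", "A10BD20"
    ),
    classes = list(
      "metformin", "sulfonylurea", "dpp4", "glp1", "sglt2", "glinide",
      "glinide", "glucosidase",
      c("metformin", "sulfonylurea"), c("metformin", "glitazone"),
      c("metformin", "dpp4"), c("metformin", "dpp4"), c("metformin", "dpp4"),
      c("metformin", "dpp4"), c("metformin", "sglt2"), c("metformin", "sglt2"),
      c("metformin", "sglt2")
    )
  )
}

#' Classify the index-year glucose-lowering therapy regimen
#'
#' Assigns each person exactly one therapy class from the set of distinct
#' non-insulin drug classes dispensed in the index year (longest-prefix
#' lookup in the ATC map, fixed combinations expanded to components) and the
#' presence of insulin (A10A): `none`, `<class>_mono` for single-class
#' non-insulin therapy, `dual_noninsulin`, `triple_plus_noninsulin`,
#' `insulin_only`, or `insulin_plus_noninsulin`. Dual therapy additionally
#' carries `metformin_su` / `metformin_dpp4` combination flags. `A10B` codes
#' not covered by the map count as one `other` non-insulin class, with a
#' warning.
#'
#' @inheritParams classify_cvd
#' @param index_year Calendar year of the prescriptions considered.
#' @param atc_map Subclass map, see [default_atc_classes()].
#' @return A tibble: `person_id`, `therapy_class`, `n_noninsulin_classes`,
#'   `insulin`, `metformin_su`, `metformin_dpp4`.
#' @export
classify_therapy <- function(bundle, person_ids = NULL, index_year = 2015L,
                             atc_map = default_atc_classes()) {
  stopifnot(inherits(bundle, "claims_bundle"))
  if (is.null(person_ids)) person_ids <- bundle$persons$person_id
  year_of <- function(d) as.integer(format(d, "%Y"))
  rx <- bundle$prescriptions %>%
    filter(
      .data$person_id %in% .env$person_ids,
      year_of(.data$dispense_date) == index_year,
      startsWith(.data$atc_code, "A10")
    ) %>%
    distinct(.data$person_id, .data$atc_code)

  map <- arrange(atc_map, -nchar(.data$atc_prefix)) # longest prefix wins
  classes_of <- function(code) {
    if (!startsWith(code, "A10B")) {
      return(character()) # insulin handled separately
    }
    hit <- which(startsWith(code, map$atc_prefix))
    if (length(hit) == 0L) {
      warn(sprintf("unmapped non-insulin ATC code '%s'; counted as 'other'", code),
        class = "t2dcvd_atc_warning"
      )
      return("other")
    }
    map$classes[[hit[1L]]]
  }
  per_person <- rx %>%
    group_by(.data$person_id) %>%
    summarise(
      insulin = any(startsWith(.data$atc_code, "A10A")),
      classes = list(sort(unique(unlist(lapply(.data$atc_code, classes_of))))),
      .groups = "drop"
    ) %>%
    mutate(
      n_noninsulin_classes = lengths(.data$classes),
      metformin_su = purrr::map_lgl(
        .data$classes, ~ all(c("metformin", "sulfonylurea") %in% .x)
      ) & .data$n_noninsulin_classes == 2L,
      metformin_dpp4 = purrr::map_lgl(
        .data$classes, ~ all(c("metformin", "dpp4") %in% .x)
      ) & .data$n_noninsulin_classes == 2L,
      therapy_class = case_when(
        .data$insulin & .data$n_noninsulin_classes == 0L ~ "insulin_only",
        .data$insulin ~ "insulin_plus_noninsulin",
        .data$n_noninsulin_classes == 1L ~ paste0(
          purrr::map_chr(.data$classes, ~ if (length(.x)) .x[[1]] else NA_character_),
          "_mono"
        ),
        .data$n_noninsulin_classes == 2L ~ "dual_noninsulin",
        .data$n_noninsulin_classes >= 3L ~ "triple_plus_noninsulin"
      )
    )

  tibble(person_id = person_ids) %>%
    left_join(
      select(
        per_person, "person_id", "therapy_class", "n_noninsulin_classes",
        "insulin", "metformin_su", "metformin_dpp4"
      ),
      by = "person_id"
    ) %>%
    mutate(
      therapy_class = dplyr::coalesce(.data$therapy_class, "none"),
      n_noninsulin_classes = dplyr::coalesce(.data$n_noninsulin_classes, 0L),
      insulin = dplyr::coalesce(.data$insulin, FALSE),
      metformin_su = dplyr::coalesce(.data$metformin_su, FALSE),
      metformin_dpp4 = dplyr::coalesce(.data$metformin_dpp4, FALSE)
    )
}
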