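# Domain model for SHI claims extracts: record schemas, code normalization,
# calendar-quarter arithmetic, and the in-memory claims bundle.

#' Normalize a clinical code for storage and matching
#'
#' Claims extracts and published code lists mix dotted, hyphenated and
#' dash-variant spellings of the same code (`"I25.10"`, `"5–361"`).
#' Codes are stored dot-free and uppercase internally so that prefix matching
#' is purely lexical; dotted forms are accepted on input anywhere a code or
#' code prefix is expected.
#'
#' * `ICD` (ICD-10-GM): uppercased, dots removed — `"I25.10"` becomes
#'   `"I2510"`.
#' * `OPS` (Operationen- und Prozedurenschluessel): the hyphen after the
#'   leading digit is kept, dots are removed, en/em dashes become hyphens —
#'   `"5–361.0"` becomes `"5-3610"`.
#' * `ATC`: uppercased; at most 7 characters, alphanumeric.
#'
#' Normalization is idempotent: applying it to an already-normalized code is
#' a no-op.
#'
#' @param raw Character vector of raw codes.
#' @param system One of `"ICD"`, `"OPS"`, `"ATC"`.
#' @return Character vector of normalized codes.
#' @examples
#' normalize_code("I73.9", "ICD")   # "I739"
#' normalize_code("5-361", "OPS")   # "5-361"
#' normalize_code("a10ba02", "ATC") # "A10BA02"
#' @export
normalize_code <- function(raw, system = c("ICD", "OPS", "ATC")) {
  system <- match.arg(system)
  if (length(raw) == 0L) {
    return(character())
  }
  x <- toupper(trimws(as.character(raw)))
  x <- gsub("–|—", "-", x)
  bad_empty <- is.na(x) | x == ""
  if (any(bad_empty)) {
    abort(sprintf(
      "empty or missing %s code at position %d", system,
      which(bad_empty)[1L]
    ), class = "t2dcvd_code_error")
  }
  x <- gsub(".", "", x, fixed = TRUE)
  pattern <- switch(system,
    ICD = "^[A-Z][0-9]+[A-Z]?$",
    OPS = "^[0-9]-[0-9A-Z]+$",
    ATC = "^[A-Z][0-9A-Z]{0,6}$"
  )
  ok <- grepl(pattern, x)
  # bare prefixes like "I20" or "8-84" are legal; full-length codes too
  if (!all(ok)) {
    abort(sprintf(
      "invalid %s code '%s' (normalized from '%s')",
      system, x[!ok][1L], as.character(raw)[!ok][1L]
    ), class = "t2dcvd_code_error")
  }
  x
}

#' Map dates to calendar quarters
#'
#' German claims criteria are phrased per calendar quarter ("in at least two
#' quarters in 2015"). `quarter_of()` maps dates to `(year, quarter)`;
#' `quarter_range()` is its inverse, returning the first and last day of a
#' quarter.
#'
#' @param d A `Date` vector (or character coercible to `Date`).
#' @return A tibble with columns `year` and `quarter` (1--4), one row per
#'   input date.
#' @examples
#' quarter_of(as.Date(c("2015-01-01", "2015-06-30", "2015-12-31")))
#' @export
quarter_of <- function(d) {
  d <- as.Date(d)
  if (anyNA(d)) {
    abort("quarter_of(): unparseable or missing date", class = "t2dcvd_date_error")
  }
  m <- as.integer(format(d, "%m"))
  tibble(
    year = as.integer(format(d, "%Y")),
    quarter = (m - 1L) %/% 3L + 1L
  )
}

#' @rdname quarter_of
#' @param year,quarter Integer vectors identifying quarters.
#' @return `quarter_range()`: a tibble with columns `start` and `end`
#'   (`Date`), covering Jan--Mar, Apr--Jun, Jul--Sep, Oct--Dec.
#' @export
quarter_range <- function(year, quarter) {
  stopifnot(all(quarter %in% 1:4))
  start <- as.Date(sprintf("%d-%02d-01", year, (quarter - 1L) * 3L + 1L))
  end_month <- quarter * 3L
  end <- as.Date(sprintf(
    "%d-%02d-%02d", year, end_month,
    ifelse(end_month %in% c(3L, 12L), 31L, 30L)
  ))
  tibble(start = start, end = end)
}

# integer key "year*4 + quarter-1": distinct-quarter counting and same-quarter
# joins reduce to integer equality
quarter_key <- function(d) {
  q <- quarter_of(d)
  q$year * 4L + q$quarter - 1L
}

claim_tables <- c("persons", "diagnoses", "prescriptions", "procedures", "lab_services")

#' Default EBM codes billing blood glucose / HbA1c determinations
#'
#' Fee-schedule (Einheitlicher Bewertungsmassstab) codes used by the
#' lab-pathway case criterion: 32025 (glucose), 32057 (glucose, POCT),
#' 32881 and 32094 (HbA1c).
#'
#' @return Character vector of EBM codes.
#' @export
glucose_ebm_codes <- function() c("32025", "32057", "32881", "32094")

empty_claims_tables <- function() {
  list(
    persons = tibble(
      person_id = character(), sex = character(), birth_year = integer(),
      enrollment_start = as.Date(character()), enrollment_end = as.Date(character()),
      death_date = as.Date(character())
    ),
    diagnoses = tibble(
      person_id = character(), icd_code = character(), setting = character(),
      qualifier = character(), service_date = as.Date(character())
    ),
    prescriptions = tibble(
      person_id = character(), atc_code = character(),
      dispense_date = as.Date(character()), prescriber_id = character()
    ),
    procedures = tibble(
      person_id = character(), ops_code = character(),
      service_date = as.Date(character())
    ),
    lab_services = tibble(
      person_id = character(), ebm_code = character(),
      service_date = as.Date(character()), physician_id = character()
    )
  )
}

#' Assemble and validate an in-memory claims bundle
#'
#' A claims bundle holds the five record streams of an SHI claims extract as
#' tibbles: `persons`, `diagnoses`, `prescriptions`, `procedures` and
#' `lab_services`. All clinical codes are normalized on construction (see
#' [normalize_code()]) and the schema invariants are enforced:
#'
#' * `enrollment_start <= enrollment_end`; a death date, when present, equals
#'   the enrollment end; `birth_year` precedes the enrollment-start year;
#' * diagnosis `setting` is one of `ambulatory`, `hospital_main`,
#'   `hospital_secondary`; the ambulatory qualifier (`G`assured, `V`suspected,
#'   `A`excluded, `Z`status-post) is present if and only if the setting is
#'   ambulatory;
#' * lab services carry a `ebm_known` flag marking codes outside
#'   `known_ebm_codes` (they are retained, never dropped).
#'
#' @param persons,diagnoses,prescriptions,procedures,lab_services Data frames
#'   in the interchange schema (see [read_claims()] for the column
#'   dictionary). Missing tables default to empty.
#' @param known_ebm_codes Character vector of recognized EBM billing codes.
#' @return An object of class `claims_bundle` (a named list of tibbles).
#' @export
claims_bundle <- function(persons = NULL, diagnoses = NULL, prescriptions = NULL,
                          procedures = NULL, lab_services = NULL,
                          known_ebm_codes = glucose_ebm_codes()) {
  empty <- empty_claims_tables()
  tabs <- list(
    persons = persons, diagnoses = diagnoses, prescriptions = prescriptions,
    procedures = procedures, lab_services = lab_services
  )
  for (nm in claim_tables) {
    if (is.null(tabs[[nm]])) {
      tabs[[nm]] <- empty[[nm]]
    } else {
      tabs[[nm]] <- as_tibble(tabs[[nm]])
      missing_cols <- setdiff(names(empty[[nm]]), names(tabs[[nm]]))
      if (length(missing_cols)) {
        if (nm == "persons" && identical(missing_cols, "death_date")) {
          tabs[[nm]]$death_date <- as.Date(NA)
        } else if (nm == "diagnoses" && identical(missing_cols, "qualifier")) {
          tabs[[nm]]$qualifier <- NA_character_
        } else {
          abort(sprintf(
            "table '%s' is missing column(s): %s", nm,
            paste(missing_cols, collapse = ", ")
          ), class = "t2dcvd_schema_error")
        }
      }
      tabs[[nm]] <- tabs[[nm]][names(empty[[nm]])]
    }
  }

  tabs$persons <- mutate(tabs$persons,
    person_id = as.character(.data$person_id),
    sex = as.character(.data$sex),
    birth_year = as.integer(.data$birth_year),
    enrollment_start = as.Date(.data$enrollment_start),
    enrollment_end = as.Date(.data$enrollment_end),
    death_date = as.Date(.data$death_date)
  )
  if (nrow(tabs$diagnoses)) {
    tabs$diagnoses <- mutate(tabs$diagnoses,
      person_id = as.character(.data$person_id),
      icd_code = normalize_code(.data$icd_code, "ICD"),
      setting = as.character(.data$setting),
      qualifier = as.character(.data$qualifier),
      service_date = as.Date(.data$service_date)
    )
  }
  if (nrow(tabs$prescriptions)) {
    tabs$prescriptions <- mutate(tabs$prescriptions,
      person_id = as.character(.data$person_id),
      atc_code = normalize_code(.data$atc_code, "ATC"),
      dispense_date = as.Date(.data$dispense_date),
      prescriber_id = as.character(.data$prescriber_id)
    )
  }
  if (nrow(tabs$procedures)) {
    tabs$procedures <- mutate(tabs$procedures,
      person_id = as.character(.data$person_id),
      ops_code = normalize_code(.data$ops_code, "OPS"),
      service_date = as.Date(.data$service_date)
    )
  }
  if (nrow(tabs$lab_services)) {
    tabs$lab_services <- mutate(tabs$lab_services,
      person_id = as.character(.data$person_id),
      ebm_code = as.character(.data$ebm_code),
      service_date = as.Date(.data$service_date),
      physician_id = as.character(.data$physician_id)
    )
  }
  tabs$lab_services$ebm_known <- tabs$lab_services$ebm_code %in% known_ebm_codes

  bundle <- structure(tabs, class = c("claims_bundle", "list"))
  validate_claims_bundle(bundle)
  if (nrow(bundle$persons) == 0L) {
    warn("claims bundle contains no persons")
  }
  bundle
}

#' @rdname claims_bundle
#' @param bundle A `claims_bundle`.
#' @return `validate_claims_bundle()` returns the bundle invisibly, erroring
#'   on the first violated invariant with the table and row index.
#' @export
validate_claims_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "claims_bundle"))
  p <- bundle$persons
  fail <- function(tab, rows, msg) {
    abort(sprintf("%s (table '%s', row %s)", msg, tab, head(rows, 1L)),
      class = "t2dcvd_schema_error"
    )
  }
  if (anyDuplicated(p$person_id)) {
    fail("persons", which(duplicated(p$person_id)), "duplicate person_id")
  }
  bad <- which(p$enrollment_start > p$enrollment_end)
  if (length(bad)) fail("persons", bad, "enrollment_start after enrollment_end")
  bad <- which(!is.na(p$death_date) & p$death_date != p$enrollment_end)
  if (length(bad)) fail("persons", bad, "death_date must equal enrollment_end")
  bad <- which(p$birth_year >= as.integer(format(p$enrollment_start, "%Y")))
  if (length(bad)) fail("persons", bad, "birth_year not before enrollment start")
  bad <- which(!p$sex %in% c("female", "male"))
  if (length(bad)) fail("persons", bad, "sex must be 'female' or 'male'")

  d <- bundle$diagnoses
  bad <- which(!d$setting %in% c("ambulatory", "hospital_main", "hospital_secondary"))
  if (length(bad)) fail("diagnoses", bad, sprintf("unknown setting '%s'", d$setting[bad[1L]]))
  amb <- d$setting == "ambulatory"
  bad <- which(amb & (is.na(d$qualifier) | !d$qualifier %in% c("G", "V", "A", "Z")))
  if (length(bad)) fail("diagnoses", bad, "ambulatory diagnosis needs qualifier G/V/A/Z")
  bad <- which(!amb & !is.na(d$qualifier))
  if (length(bad)) fail("diagnoses", bad, "qualifier only allowed on ambulatory diagnoses")

  for (nm in setdiff(claim_tables, "persons")) {
    ids <- bundle[[nm]]$person_id
    bad <- which(!ids %in% p$person_id)
    if (length(bad)) fail(nm, bad, sprintf("person_id '%s' not in persons table", ids[bad[1L]]))
  }
  invisible(bundle)
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle>\n")
  for (nm in claim_tables) {
    cat(sprintf("  %-14s %7d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

date_columns <- list(
  persons = c("enrollment_start", "enrollment_end", "death_date"),
  diagnoses = "service_date", prescriptions = "dispense_date",
  procedures = "service_date", lab_services = "service_date"
)

#' Read and write claims bundles in the delimited interchange schema
#'
#' One delimited file per record stream, with a header row and ISO-8601
#' dates. Both comma- and tab-separated files are accepted (the delimiter is
#' sniffed from the header line); quoted fields are handled by the reader.
#' Expected files and columns:
#'
#' * `persons.csv`: `person_id, sex, birth_year, enrollment_start,
#'   enrollment_end, death_date` (death empty when alive)
#' * `diagnoses.csv`: `person_id, icd_code, setting, qualifier, service_date`
#' * `prescriptions.csv`: `person_id, atc_code, dispense_date, prescriber_id`
#' * `procedures.csv`: `person_id, ops_code, service_date`
#' * `lab_services.csv`: `person_id, ebm_code, service_date, physician_id`
#'
#' Ambulatory diagnoses are dated by service date; hospital diagnoses by
#' admission date. Codes are normalized on read, so `write_claims()` followed
#' by `read_claims()` is the identity on a valid bundle.
#'
#' @param dir Directory holding the five files.
#' @param known_ebm_codes Passed to [claims_bundle()].
#' @return `read_claims()`: a validated `claims_bundle`.
#' @export
read_claims <- function(dir, known_ebm_codes = glucose_ebm_codes()) {
  if (!dir.exists(dir)) {
    abort(sprintf("claims directory '%s' does not exist", dir), class = "t2dcvd_io_error")
  }
  tabs <- list()
  for (nm in claim_tables) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) {
      abort(sprintf("missing claims file '%s'", path), class = "t2dcvd_io_error")
    }
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
    tab <- readr::read_delim(path,
      delim = delim, col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE, show_col_types = FALSE
    )
    expected <- names(empty_claims_tables()[[nm]])
    missing_cols <- setdiff(expected, names(tab))
    if (length(missing_cols)) {
      abort(sprintf(
        "file '%s' is missing column(s): %s", path,
        paste(missing_cols, collapse = ", ")
      ), class = "t2dcvd_io_error")
    }
    for (dc in intersect(date_columns[[nm]], names(tab))) {
      raw <- tab[[dc]]
      parsed <- as.Date(raw, format = "%Y-%m-%d")
      bad <- which(!is.na(raw) & raw != "" & is.na(parsed))
      if (length(bad)) {
        abort(sprintf(
          "file '%s', line %d, column '%s': unparseable date '%s'",
          path, bad[1L] + 1L, dc, raw[bad[1L]]
        ), class = "t2dcvd_io_error")
      }
      tab[[dc]] <- parsed
    }
    if (nm == "diagnoses" && nrow(tab)) {
      tab$qualifier[!is.na(tab$qualifier) & tab$qualifier == ""] <- NA_character_
    }
    tabs[[nm]] <- tab
  }
  bundle <- claims_bundle(
    persons = tabs$persons, diagnoses = tabs$diagnoses,
    prescriptions = tabs$prescriptions, procedures = tabs$procedures,
    lab_services = tabs$lab_services, known_ebm_codes = known_ebm_codes
  )
  counts <- vapply(bundle[claim_tables], nrow, integer(1))
  rlang::inform(sprintf(
    "read claims bundle from '%s': %s", dir,
    paste(sprintf("%s=%d", names(counts), counts), collapse = ", ")
  ), class = "t2dcvd_io_log")
  bundle
}

#' @rdname read_claims
#' @param bundle A `claims_bundle`.
#' @param delim Output field delimiter, `","` or `"\t"`.
#' @return `write_claims()`: the directory path, invisibly.
#' @export
write_claims <- function(bundle, dir, delim = ",") {
  validate_claims_bundle(bundle)
  stopifnot(delim %in% c(",", "\t"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in claim_tables) {
    tab <- bundle[[nm]]
    tab <- tab[names(empty_claims_tables()[[nm]])] # drop derived flags
    readr::write_delim(tab, file.path(dir, paste0(nm, ".csv")),
      delim = delim, na = ""
    )
  }
  invisible(dir)
}
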