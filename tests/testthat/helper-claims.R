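library(dplyr)

# Builders for hand-crafted fixtures and independently coded brute-force
# oracles. The oracles deliberately use naive per-person loops and substring
# comparisons so they share no code path with the package implementation.

person_row <- function(id = "p1", sex = "male", birth_year = 1950L,
                       start = "2010-01-01", end = "2015-12-31", death = NA) {
  tibble::tibble(
    person_id = id, sex = sex, birth_year = as.integer(birth_year),
    enrollment_start = as.Date(start), enrollment_end = as.Date(end),
    death_date = as.Date(death)
  )
}

dx_row <- function(id, code, date, setting = "ambulatory",
                   qualifier = ifelse(setting == "ambulatory", "G", NA)) {
  tibble::tibble(
    person_id = id, icd_code = code, setting = setting,
    qualifier = as.character(qualifier), service_date = as.Date(date)
  )
}

rx_row <- function(id, atc, date, prescriber = "dr1") {
  tibble::tibble(
    person_id = id, atc_code = atc, dispense_date = as.Date(date),
    prescriber_id = prescriber
  )
}

lab_row <- function(id, ebm, date, physician = "dr1") {
  tibble::tibble(
    person_id = id, ebm_code = as.character(ebm), service_date = as.Date(date),
    physician_id = physician
  )
}

proc_row <- function(id, ops, date) {
  tibble::tibble(person_id = id, ops_code = ops, service_date = as.Date(date))
}

bundle_of <- function(persons, diagnoses = NULL, prescriptions = NULL,
                      procedures = NULL, lab_services = NULL) {
  claims_bundle(
    persons = persons, diagnoses = diagnoses, prescriptions = prescriptions,
    procedures = procedures, lab_services = lab_services
  )
}

month_quarter <- function(d) (as.integer(format(as.Date(d), "%m")) - 1L) %/% 3L + 1L

# ---- brute-force T2D oracle -------------------------------------------------
# Direct transcription of the four criteria as per-person set comprehensions.
oracle_identify_t2d <- function(bundle, pid, index_year = 2015L) {
  prow <- bundle$persons[bundle$persons$person_id == pid, ]
  dd <- prow$death_date[1]
  in_year <- function(d) format(d, "%Y") == as.character(index_year)
  alive <- function(d) is.na(dd) | d <= dd

  dx <- bundle$diagnoses
  dx <- dx[dx$person_id == pid & in_year(dx$service_date) & alive(dx$service_date), ]
  ok_setting <- dx$setting %in% c("hospital_main", "hospital_secondary") |
    (dx$setting == "ambulatory" & !is.na(dx$qualifier) & dx$qualifier == "G")
  dx <- dx[ok_setting, ]
  rx <- bundle$prescriptions
  rx <- rx[rx$person_id == pid & in_year(rx$dispense_date) & alive(rx$dispense_date), ]
  lb <- bundle$lab_services
  lb <- lb[lb$person_id == pid & in_year(lb$service_date) & alive(lb$service_date) &
    lb$ebm_code %in% c("32025", "32057", "32881", "32094"), ]

  is_a10 <- substr(rx$atc_code, 1, 3) == "A10"
  is_a10b <- substr(rx$atc_code, 1, 4) == "A10B"
  is_e11 <- substr(dx$icd_code, 1, 3) == "E11"
  is_e14 <- substr(dx$icd_code, 1, 3) == "E14"

  c1 <- length(unique(month_quarter(rx$dispense_date[is_a10b]))) >= 2
  c2 <- any(is_a10) && any(is_e11)
  c3 <- FALSE
  if (any(is_a10b) && nrow(lb)) {
    for (i in which(is_a10b)) {
      qi <- month_quarter(rx$dispense_date[i])
      for (j in seq_len(nrow(lb))) {
        if (month_quarter(lb$service_date[j]) == qi &&
          lb$physician_id[j] == rx$prescriber_id[i]) {
          c3 <- TRUE
        }
      }
    }
  }
  c4 <- length(unique(month_quarter(dx$service_date[is_e11]))) >= 3
  excluded <- (c1 || c3) && any(is_e14) && !any(is_e11)
  list(
    c1 = c1, c2 = c2, c3 = c3, c4 = c4, excluded = excluded,
    is_case = (c1 || c2 || c3 || c4) && !excluded
  )
}

# ---- brute-force prefix-match oracle ---------------------------------------
oracle_match <- function(code, include, exclude = character()) {
  pref <- function(p) substr(code, 1, nchar(p)) == p
  inc <- FALSE
  for (p in include) if (pref(p)) inc <- TRUE
  if (inc) for (p in exclude) if (pref(p)) inc <- FALSE
  inc
}

# ---- randomized persons exercising every criterion edge --------------------
# returns a bundle of n persons with chaotic but schema-valid 2015 claims
random_criteria_bundle <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("r%04d", seq_len(n))
  persons <- purrr::map_dfr(ids, function(id) {
    death <- if (runif(1) < 0.05) {
      as.character(as.Date("2015-01-01") + sample.int(360, 1))
    } else {
      NA
    }
    person_row(id,
      sex = sample(c("female", "male"), 1), birth_year = sample(1920:1990, 1),
      end = if (is.na(death)) "2015-12-31" else death, death = death
    )
  })
  atc_pool <- c("A10BA02", "A10BB12", "A10BH01", "A10AB05", "A10AE04", "C07AB02")
  icd_pool <- c("E1190", "E1140", "E1490", "E1090", "I109", "E780")
  q_starts <- as.Date(c("2015-01-10", "2015-04-10", "2015-07-10", "2015-10-10"))
  rand_date <- function(k) q_starts[sample.int(4, k, replace = TRUE)] + sample.int(60, k, replace = TRUE)

  dx <- purrr::map_dfr(ids, function(id) {
    k <- sample(0:5, 1)
    if (k == 0) {
      return(NULL)
    }
    setting <- sample(c("ambulatory", "hospital_main", "hospital_secondary"),
      k,
      replace = TRUE, prob = c(0.7, 0.15, 0.15)
    )
    dx_row(id, sample(icd_pool, k, replace = TRUE), rand_date(k),
      setting = setting,
      qualifier = ifelse(setting == "ambulatory",
        sample(c("G", "V", "Z"), k, replace = TRUE, prob = c(0.7, 0.2, 0.1)), NA
      )
    )
  })
  rx <- purrr::map_dfr(ids, function(id) {
    k <- sample(0:4, 1)
    if (k == 0) {
      return(NULL)
    }
    rx_row(id, sample(atc_pool, k, replace = TRUE), rand_date(k),
      prescriber = sample(c("dr1", "dr2"), k, replace = TRUE)
    )
  })
  lb <- purrr::map_dfr(ids, function(id) {
    k <- sample(0:2, 1)
    if (k == 0) {
      return(NULL)
    }
    lab_row(id, sample(c("32025", "32057", "32881", "32094", "32999"), k, replace = TRUE),
      rand_date(k),
      physician = sample(c("dr1", "dr2"), k, replace = TRUE)
    )
  })
  # drop post-death claims so the bundle is physically plausible
  dd <- setNames(persons$death_date, persons$person_id)
  trim <- function(tab, col) {
    if (is.null(tab) || nrow(tab) == 0) {
      return(tab)
    }
    d <- dd[tab$person_id]
    tab[is.na(d) | tab[[col]] <= d, ]
  }
  bundle_of(persons,
    diagnoses = trim(dx, "service_date"),
    prescriptions = trim(rx, "dispense_date"),
    lab_services = trim(lb, "service_date")
  )
}

code_universe <- function() {
  readr::read_csv(
    system.file("extdata", "code_universe_synthetic.csv", package = "t2dcvd"),
    show_col_types = FALSE, progress = FALSE
  )
}
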