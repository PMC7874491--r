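# Synthetic SHI claims generator. Produces a claims bundle plus per-person
# ground truth (latent disease states, therapy, onset) so that the cohort,
# CVD and prevalence stages can be tested without access-restricted real data.

sim_age_bands <- c("u18", "18-39", "40-59", "60-79", "80+")
# birth-year ranges yielding the band's age at 2015-01-01
# u18 capped at 2009 so every person can be enrolled from 2010-01-01 on
sim_band_birth <- list(
  "u18" = c(1998L, 2009L), "18-39" = c(1976L, 1997L),
  "40-59" = c(1956L, 1975L), "60-79" = c(1936L, 1955L),
  "80+" = c(1916L, 1935L)
)

#' Therapy regimens and their ATC codes used by the simulator
#'
#' Maps each simulated glucose-lowering therapy class to the ATC codes it
#' dispenses (metformin A10BA02, glimepiride A10BB12, sitagliptin A10BH01,
#' liraglutide A10BJ02, empagliflozin A10BK03, repaglinide A10BX02, acarbose
#' A10BF01, insulins A10AB05/A10AE04).
#'
#' @return Named list of character vectors.
#' @export
sim_regimens <- function() {
  list(
    none = character(),
    metformin_mono = "A10BA02",
    sulfonylurea_mono = "A10BB12",
    dpp4_mono = "A10BH01",
    glp1_mono = "A10BJ02",
    sglt2_mono = "A10BK03",
    glinide_mono = "A10BX02",
    glucosidase_mono = "A10BF01",
    dual_met_su = c("A10BA02", "A10BB12"),
    dual_met_dpp4 = c("A10BA02", "A10BH01"),
    dual_other = c("A10BB12", "A10BH01"),
    triple_plus = c("A10BA02", "A10BB12", "A10BH01"),
    insulin_only = "A10AB05",
    insulin_plus = c("A10AE04", "A10BA02")
  )
}

#' Configure the synthetic claims simulation
#'
#' The defaults describe an age/sex-stratified insured population observed
#' 2010--2015 with roughly 2% enrollment churn, band-specific mortality,
#' ~10% adult T2D prevalence rising with age, a 50% chance of prevalent CVD
#' given T2D, and a per-year documentation probability (`doc_prob`) with
#' which each prevalent chronic condition (T2D, CVD, hypertension I10, lipid
#' disorder E78) is coded at least once, independently across years. The
#' default `doc_prob = 0.78` makes the one-year/six-year ascertainment ratio
#' of a chronic condition match what German claims analyses of CVD typically
#' observe (about 0.79 under the geometric model `1 - (1 - p)^y`).
#'
#' @param n_persons Number of insured persons to simulate.
#' @param seed Integer seed; a fixed seed yields byte-identical output.
#' @param age_band_weights Named distribution over bands
#'   `u18, 18-39, 40-59, 60-79, 80+` (must sum to 1).
#' @param sex_ratio Fraction female.
#' @param t2d_prevalence_by_band Named per-band probabilities of latent T2D.
#' @param cvd_given_t2d,cvd_given_no_t2d Probability of prevalent CVD.
#' @param doc_prob Per-year probability a prevalent chronic condition is
#'   coded at least once.
#' @param churn_prob Per-person probability of an incomplete enrollment span
#'   (late entry or early exit) inside 2010--2015.
#' @param death_rate_by_band Named per-band probability of death during
#'   2010--2015; deaths truncate enrollment.
#' @param therapy_mix Named distribution over therapy classes (see
#'   [sim_regimens()]).
#' @param e14_miscoding_prob Probability that a drug-treated diabetic is
#'   coded only with unspecific diabetes (E14), never E11.
#' @param onset_year_weights Named distribution over true T2D onset years;
#'   the `"2008"` bucket stands for onset at least five years before 2015.
#' @param hypertension_given_t2d,hypertension_given_no_t2d,
#'   lipid_given_t2d,lipid_given_no_t2d Comorbidity probabilities.
#' @param lab_prob Probability that a quarter with a non-insulin prescription
#'   also has a glucose/HbA1c lab billing by the prescribing physician.
#' @param cvd_icd_pool,cvd_ops_pool Codes a documented CVD event draws from
#'   (uniformly).
#' @param cvd_ops_prob Probability a documented CVD year also has an OPS
#'   procedure row.
#' @param micro_event_prob Probability of a microvascular hospitalization
#'   (amputation/vitrectomy OPS, CKD-5 N18.5) for a T2D person in 2015.
#' @param t2d_hosp_prob Probability of a 2015 hospitalization with E11 as
#'   main diagnosis for a T2D person.
#' @param noise_v_prob Per person-year probability of a suspected-only (V)
#'   E11 diagnosis in a person without T2D.
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(n_persons = 5000,
                       seed = 1L,
                       age_band_weights = c(
                         "u18" = 0.16, "18-39" = 0.27, "40-59" = 0.29,
                         "60-79" = 0.21, "80+" = 0.07
                       ),
                       sex_ratio = 0.51,
                       t2d_prevalence_by_band = c(
                         "u18" = 0, "18-39" = 0.01, "40-59" = 0.07,
                         "60-79" = 0.20, "80+" = 0.24
                       ),
                       cvd_given_t2d = 0.50,
                       cvd_given_no_t2d = 0.10,
                       doc_prob = 0.78,
                       churn_prob = 0.02,
                       death_rate_by_band = c(
                         "u18" = 0.001, "18-39" = 0.005, "40-59" = 0.03,
                         "60-79" = 0.12, "80+" = 0.40
                       ),
                       therapy_mix = c(
                         none = 0.302, metformin_mono = 0.230,
                         sulfonylurea_mono = 0.022, dpp4_mono = 0.021,
                         glp1_mono = 0.001, sglt2_mono = 0.001,
                         glinide_mono = 0.004, glucosidase_mono = 0.001,
                         dual_met_su = 0.033, dual_met_dpp4 = 0.066,
                         dual_other = 0.018, triple_plus = 0.035,
                         insulin_only = 0.123, insulin_plus = 0.143
                       ),
                       e14_miscoding_prob = 0.025,
                       onset_year_weights = c(
                         "2008" = 0.722, "2011" = 0.075, "2012" = 0.059,
                         "2013" = 0.057, "2014" = 0.051, "2015" = 0.036
                       ),
                       hypertension_given_t2d = 0.85,
                       hypertension_given_no_t2d = 0.25,
                       lipid_given_t2d = 0.60,
                       lipid_given_no_t2d = 0.18,
                       lab_prob = 0.35,
                       cvd_icd_pool = c(
                         "I639", "I64", "I200", "I210", "I214", "I221",
                         "I241", "I2511", "I739", "I7020", "I7021"
                       ),
                       cvd_ops_pool = c("5-361", "5-362", "8-836", "8-837", "8-840"),
                       cvd_ops_prob = 0.10,
                       micro_event_prob = 0.017,
                       t2d_hosp_prob = 0.034,
                       noise_v_prob = 0.01) {
  cfg <- list(
    n_persons = as.integer(n_persons), seed = as.integer(seed),
    age_band_weights = age_band_weights, sex_ratio = sex_ratio,
    t2d_prevalence_by_band = t2d_prevalence_by_band,
    cvd_given_t2d = cvd_given_t2d, cvd_given_no_t2d = cvd_given_no_t2d,
    doc_prob = doc_prob, churn_prob = churn_prob,
    death_rate_by_band = death_rate_by_band, therapy_mix = therapy_mix,
    e14_miscoding_prob = e14_miscoding_prob,
    onset_year_weights = onset_year_weights,
    hypertension_given_t2d = hypertension_given_t2d,
    hypertension_given_no_t2d = hypertension_given_no_t2d,
    lipid_given_t2d = lipid_given_t2d, lipid_given_no_t2d = lipid_given_no_t2d,
    lab_prob = lab_prob,
    cvd_icd_pool = normalize_code(cvd_icd_pool, "ICD"),
    cvd_ops_pool = normalize_code(cvd_ops_pool, "OPS"),
    cvd_ops_prob = cvd_ops_prob, micro_event_prob = micro_event_prob,
    t2d_hosp_prob = t2d_hosp_prob, noise_v_prob = noise_v_prob
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  probs <- c(
    cfg$sex_ratio, cfg$t2d_prevalence_by_band, cfg$cvd_given_t2d,
    cfg$cvd_given_no_t2d, cfg$doc_prob, cfg$churn_prob,
    cfg$death_rate_by_band, cfg$e14_miscoding_prob,
    cfg$hypertension_given_t2d, cfg$hypertension_given_no_t2d,
    cfg$lipid_given_t2d, cfg$lipid_given_no_t2d, cfg$lab_prob,
    cfg$cvd_ops_prob, cfg$micro_event_prob, cfg$t2d_hosp_prob,
    cfg$noise_v_prob
  )
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    abort("sim_config: all probabilities must lie in [0, 1]",
      class = "t2dcvd_config_error"
    )
  }
  if (cfg$n_persons < 0) {
    abort("sim_config: n_persons must be non-negative", class = "t2dcvd_config_error")
  }
  for (w in list(cfg$age_band_weights, cfg$therapy_mix, cfg$onset_year_weights)) {
    if (any(w < 0) || abs(sum(w) - 1) > 1e-6) {
      abort("sim_config: weight vectors must be non-negative and sum to 1",
        class = "t2dcvd_config_error"
      )
    }
  }
  if (!setequal(names(cfg$age_band_weights), sim_age_bands) ||
    !setequal(names(cfg$t2d_prevalence_by_band), sim_age_bands) ||
    !setequal(names(cfg$death_rate_by_band), sim_age_bands)) {
    abort(sprintf(
      "sim_config: band-indexed parameters need names %s",
      paste(sim_age_bands, collapse = ", ")
    ), class = "t2dcvd_config_error")
  }
  if (!all(names(cfg$therapy_mix) %in% names(sim_regimens()))) {
    abort("sim_config: unknown therapy class in therapy_mix",
      class = "t2dcvd_config_error"
    )
  }
  invisible(cfg)
}

#' Expected fraction of prevalent cases observed within a window
#'
#' Under per-year documentation with probability `doc_prob`, independent
#' across years, a prevalent chronic condition is coded at least once within
#' a `window_years`-year observation window with probability
#' `1 - (1 - doc_prob)^window_years`. This geometric form is the mechanism by
#' which observed period prevalence of chronic conditions rises with window
#' length while one-year claims analyses underestimate it.
#'
#' @param doc_prob Per-year documentation probability in `[0, 1]`.
#' @param window_years Window length in years (>= 1).
#' @return Expected observed fraction, same length as the longer argument.
#' @examples
#' expected_observed_fraction(0.5, 2) # 0.75
#' expected_observed_fraction(0.78, 1:6)
#' @export
expected_observed_fraction <- function(doc_prob, window_years) {
  if (any(doc_prob < 0 | doc_prob > 1)) {
    abort("doc_prob must lie in [0, 1]", class = "t2dcvd_config_error")
  }
  if (any(window_years < 1)) {
    abort("window_years must be >= 1", class = "t2dcvd_config_error")
  }
  1 - (1 - doc_prob)^window_years
}

# uniform date in [lo, hi], elementwise; lo <= hi assumed
rand_date_between <- function(lo, hi) {
  span <- as.integer(hi - lo) + 1L
  lo + floor(runif(length(lo)) * span)
}

# expand df (with columns year, lo, hi) to nq[i] distinct random quarters per
# row, dated uniformly within quarter ∩ [lo, hi]; rows whose quarter misses
# the enrollment span are dropped
expand_to_quarters <- function(df, nq) {
  if (nrow(df) == 0L) {
    return(mutate(df, quarter = integer(), date = as.Date(character())))
  }
  df$.row <- seq_len(nrow(df))
  df$.nq <- nq
  ex <- df[rep(df$.row, each = 4L), ]
  ex$quarter <- rep(1:4, times = nrow(df))
  ex$.u <- runif(nrow(ex))
  ex <- ex %>%
    group_by(.data$.row) %>%
    filter(rank(.data$.u) <= .data$.nq) %>%
    ungroup()
  qr <- quarter_range(ex$year, ex$quarter)
  ex$.qlo <- pmax(ex$lo, qr$start)
  ex$.qhi <- pmin(ex$hi, qr$end)
  ex <- filter(ex, .data$.qlo <= .data$.qhi)
  ex$date <- rand_date_between(ex$.qlo, ex$.qhi)
  select(ex, -".row", -".nq", -".u", -".qlo", -".qhi")
}

#' Generate a synthetic claims bundle with ground truth
#'
#' Simulates the insured population described by `config` and emits the five
#' claims streams together with the latent truth that produced them. Key
#' behaviors:
#'
#' * every treated T2D person dispenses their regimen's ATC codes in 2--4
#'   distinct quarters of each enrolled year from onset on;
#' * each prevalent chronic condition (T2D/E11 or E14, CVD components,
#'   hypertension I10, lipid disorder E78) is documented in a given year with
#'   probability `doc_prob`, independently across years;
#' * documented CVD draws ICD codes uniformly from `cvd_icd_pool` and
#'   occasionally adds an OPS procedure;
#' * glucose/HbA1c lab billings share the physician id with the matching
#'   prescription, exercising the lab-pathway case criterion;
#' * churned persons have a shortened enrollment span; deaths truncate
#'   enrollment, and no claim row exists outside a person's span.
#'
#' @param config A [sim_config()].
#' @return A list with elements `bundle` (a [claims_bundle()]) and
#'   `ground_truth` (tibble: `person_id`, `true_t2d`, `true_cvd`,
#'   `true_onset_year`, `therapy_class`, `true_hypertension`, `true_lipid`,
#'   `e14_only`).
#' @export
simulate_claims <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_persons
  if (n == 0L) {
    return(list(
      bundle = suppressWarnings(claims_bundle()),
      ground_truth = tibble(
        person_id = character(), true_t2d = logical(), true_cvd = logical(),
        true_onset_year = integer(), therapy_class = character(),
        true_hypertension = logical(), true_lipid = logical(),
        e14_only = logical()
      )
    ))
  }

  band <- sample(sim_age_bands, n, replace = TRUE, prob = config$age_band_weights)
  sex <- ifelse(runif(n) < config$sex_ratio, "female", "male")
  birth_lo <- vapply(sim_band_birth[band], `[`, integer(1), 1L)
  birth_hi <- vapply(sim_band_birth[band], `[`, integer(1), 2L)
  birth_year <- birth_lo + as.integer(floor(runif(n) * (birth_hi - birth_lo + 1L)))

  start <- rep(as.Date("2010-01-01"), n)
  end <- rep(as.Date("2015-12-31"), n)
  churn <- runif(n) < config$churn_prob
  late <- churn & runif(n) < 0.5
  early <- churn & !late
  if (any(late)) {
    start[late] <- rand_date_between(
      rep(as.Date("2010-02-01"), sum(late)), rep(as.Date("2014-12-31"), sum(late))
    )
  }
  if (any(early)) {
    end[early] <- rand_date_between(
      rep(as.Date("2010-06-01"), sum(early)), rep(as.Date("2015-11-30"), sum(early))
    )
  }
  death_p <- config$death_rate_by_band[band]
  died <- !churn & runif(n) < death_p
  death_date <- rep(as.Date(NA), n)
  if (any(died)) {
    death_date[died] <- rand_date_between(
      pmax(start[died], as.Date("2010-07-01")), end[died]
    )
    end[died] <- death_date[died]
  }

  true_t2d <- runif(n) < config$t2d_prevalence_by_band[band]
  onset_pool <- as.integer(names(config$onset_year_weights))
  true_onset_year <- rep(NA_integer_, n)
  true_onset_year[true_t2d] <- sample(onset_pool, sum(true_t2d),
    replace = TRUE, prob = config$onset_year_weights
  )
  true_cvd <- runif(n) < ifelse(true_t2d, config$cvd_given_t2d, config$cvd_given_no_t2d)
  true_hyp <- runif(n) < ifelse(true_t2d, config$hypertension_given_t2d,
    config$hypertension_given_no_t2d
  )
  true_lip <- runif(n) < ifelse(true_t2d, config$lipid_given_t2d, config$lipid_given_no_t2d)
  therapy <- rep("none", n)
  if (any(true_t2d)) {
    therapy[true_t2d] <- sample(names(config$therapy_mix), sum(true_t2d),
      replace = TRUE, prob = config$therapy_mix
    )
  }
  e14_only <- true_t2d & therapy != "none" & runif(n) < config$e14_miscoding_prob

  person_id <- sprintf("p%06d", seq_len(n))
  physician <- sprintf("dr%04d", sample.int(max(20L, n %/% 50L), n, replace = TRUE))

  persons <- tibble(
    person_id = person_id, sex = sex, birth_year = birth_year,
    enrollment_start = start, enrollment_end = end, death_date = death_date
  )

  # person-year frame restricted to enrolled-alive overlap
  py <- tidyr::crossing(tibble(
    person_id = person_id, band = band, start = start, end = end,
    true_t2d = true_t2d, true_cvd = true_cvd, true_hyp = true_hyp,
    true_lip = true_lip, therapy = therapy, e14_only = e14_only,
    onset = true_onset_year, physician = physician
  ), year = 2010:2015) %>%
    mutate(
      lo = pmax(.data$start, as.Date(sprintf("%d-01-01", .data$year))),
      hi = pmin(.data$end, as.Date(sprintf("%d-12-31", .data$year)))
    ) %>%
    filter(.data$lo <= .data$hi)

  dx <- list()
  rx <- list()
  proc <- list()
  lab <- list()

  ## --- diabetes diagnoses -------------------------------------------------
  dm_years <- filter(py, .data$true_t2d, .data$year >= .data$onset)
  dm_doc <- dm_years[runif(nrow(dm_years)) < config$doc_prob, ]
  if (nrow(dm_doc)) {
    nq <- sample(1:4, nrow(dm_doc), replace = TRUE, prob = c(0.2, 0.2, 0.3, 0.3))
    dmq <- expand_to_quarters(dm_doc, nq)
    code_pool_e11 <- c("E1190", "E1140", "E1120", "E1172", "E1165")
    setting <- sample(c("ambulatory", "hospital_secondary", "hospital_main"),
      nrow(dmq),
      replace = TRUE, prob = c(0.85, 0.10, 0.05)
    )
    dx$dm <- tibble(
      person_id = dmq$person_id,
      icd_code = ifelse(dmq$e14_only, "E1490",
        sample(code_pool_e11, nrow(dmq), replace = TRUE)
      ),
      setting = setting,
      qualifier = ifelse(setting == "ambulatory", "G", NA_character_),
      service_date = dmq$date
    )
  }

  ## --- suspected-diabetes noise (V qualifier, never counts) ---------------
  noise_years <- filter(py, !.data$true_t2d)
  noise_years <- noise_years[runif(nrow(noise_years)) < config$noise_v_prob, ]
  if (nrow(noise_years)) {
    dx$noise <- tibble(
      person_id = noise_years$person_id, icd_code = "E1190",
      setting = "ambulatory", qualifier = "V",
      service_date = rand_date_between(noise_years$lo, noise_years$hi)
    )
  }

  ## --- prescriptions + lab billing ----------------------------------------
  regimens <- sim_regimens()
  rx_years <- filter(py, .data$true_t2d, .data$therapy != "none", .data$year >= .data$onset)
  if (nrow(rx_years)) {
    nq <- sample(2:4, nrow(rx_years), replace = TRUE, prob = c(0.3, 0.3, 0.4))
    rxq <- expand_to_quarters(rx_years, nq)
    n_codes <- lengths(regimens)[rxq$therapy]
    rxx <- rxq[rep(seq_len(nrow(rxq)), times = n_codes), ]
    rxx$atc_code <- unlist(regimens[rxq$therapy], use.names = FALSE)
    rx$main <- tibble(
      person_id = rxx$person_id, atc_code = rxx$atc_code,
      dispense_date = rxx$date, prescriber_id = rxx$physician
    )
    # glucose/HbA1c billing by the prescribing physician in A10B quarters
    labq <- distinct(
      filter(rxx, startsWith(.data$atc_code, "A10B")),
      .data$person_id, .data$year, .data$quarter, .data$physician,
      .data$lo, .data$hi
    )
    labq <- labq[runif(nrow(labq)) < config$lab_prob, ]
    if (nrow(labq)) {
      qr <- quarter_range(labq$year, labq$quarter)
      lab$rx <- tibble(
        person_id = labq$person_id,
        ebm_code = sample(glucose_ebm_codes(), nrow(labq), replace = TRUE),
        service_date = rand_date_between(pmax(labq$lo, qr$start), pmin(labq$hi, qr$end)),
        physician_id = labq$physician
      )
    }
  }

  ## --- CVD documentation ---------------------------------------------------
  cvd_years <- filter(py, .data$true_cvd)
  cvd_doc <- cvd_years[runif(nrow(cvd_years)) < config$doc_prob, ]
  if (nrow(cvd_doc)) {
    setting <- sample(c("ambulatory", "hospital_main", "hospital_secondary"),
      nrow(cvd_doc),
      replace = TRUE, prob = c(0.5, 0.3, 0.2)
    )
    date <- rand_date_between(cvd_doc$lo, cvd_doc$hi)
    dx$cvd <- tibble(
      person_id = cvd_doc$person_id,
      icd_code = sample(config$cvd_icd_pool, nrow(cvd_doc), replace = TRUE),
      setting = setting,
      qualifier = ifelse(setting == "ambulatory", "G", NA_character_),
      service_date = date
    )
    with_ops <- runif(nrow(cvd_doc)) < config$cvd_ops_prob
    if (any(with_ops)) {
      proc$cvd <- tibble(
        person_id = cvd_doc$person_id[with_ops],
        ops_code = sample(config$cvd_ops_pool, sum(with_ops), replace = TRUE),
        service_date = date[with_ops]
      )
    }
  }

  ## --- hypertension & lipid disorder --------------------------------------
  for (cond in c("hyp", "lip")) {
    flag_col <- paste0("true_", cond)
    cy <- filter(py, .data[[flag_col]])
    cy <- cy[runif(nrow(cy)) < config$doc_prob, ]
    if (nrow(cy)) {
      setting <- sample(c("ambulatory", "hospital_secondary"), nrow(cy),
        replace = TRUE, prob = c(0.9, 0.1)
      )
      dx[[cond]] <- tibble(
        person_id = cy$person_id,
        icd_code = if (cond == "hyp") {
          rep("I10", nrow(cy))
        } else {
          sample(c("E780", "E785"), nrow(cy), replace = TRUE)
        },
        setting = setting,
        qualifier = ifelse(setting == "ambulatory", "G", NA_character_),
        service_date = rand_date_between(cy$lo, cy$hi)
      )
    }
  }

  ## --- 2015 severe events: microvascular + T2D hospitalization ------------
  y2015 <- filter(py, .data$year == 2015L, .data$true_t2d)
  micro <- y2015[runif(nrow(y2015)) < config$micro_event_prob, ]
  if (nrow(micro)) {
    kind <- sample(c("ops", "ckd"), nrow(micro), replace = TRUE, prob = c(0.7, 0.3))
    date <- rand_date_between(micro$lo, micro$hi)
    if (any(kind == "ops")) {
      proc$micro <- tibble(
        person_id = micro$person_id[kind == "ops"],
        ops_code = sample(c("5-864", "5-865", "5-158", "5-159"),
          sum(kind == "ops"),
          replace = TRUE
        ),
        service_date = date[kind == "ops"]
      )
    }
    if (any(kind == "ckd")) {
      dx$ckd <- tibble(
        person_id = micro$person_id[kind == "ckd"], icd_code = "N185",
        setting = "hospital_main", qualifier = NA_character_,
        service_date = date[kind == "ckd"]
      )
    }
  }
  t2dhosp <- y2015[runif(nrow(y2015)) < config$t2d_hosp_prob, ]
  if (nrow(t2dhosp)) {
    dx$t2dhosp <- tibble(
      person_id = t2dhosp$person_id,
      icd_code = ifelse(t2dhosp$e14_only, "E1490", "E1190"),
      setting = "hospital_main", qualifier = NA_character_,
      service_date = rand_date_between(t2dhosp$lo, t2dhosp$hi)
    )
  }

  sort_by <- function(df, col) arrange(df, .data$person_id, .data[[col]])
  diagnoses <- if (length(dx)) sort_by(bind_rows(dx), "service_date") else NULL
  prescriptions <- if (length(rx)) sort_by(bind_rows(rx), "dispense_date") else NULL
  procedures <- if (length(proc)) sort_by(bind_rows(proc), "service_date") else NULL
  lab_services <- if (length(lab)) sort_by(bind_rows(lab), "service_date") else NULL

  bundle <- claims_bundle(
    persons = persons, diagnoses = diagnoses, prescriptions = prescriptions,
    procedures = procedures, lab_services = lab_services
  )
  ground_truth <- tibble(
    person_id = person_id, true_t2d = true_t2d, true_cvd = true_cvd,
    true_onset_year = true_onset_year, therapy_class = therapy,
    true_hypertension = true_hyp, true_lipid = true_lip, e14_only = e14_only
  )
  list(bundle = bundle, ground_truth = ground_truth)
}
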