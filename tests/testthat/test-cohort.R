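# Eligibility and the four-criterion T2D case-identification algorithm.

test_that("adult and continuous-enrollment flags follow the boundary rules", {
  p <- bind_rows(
    person_row("age18", birth_year = 1997L),
    person_row("age17", birth_year = 1998L),
    person_row("gap", birth_year = 1950L, start = "2011-03-01"),
    person_row("short", birth_year = 1950L, end = "2014-12-31"),
    person_row("died2015", birth_year = 1940L, end = "2015-08-01", death = "2015-08-01"),
    person_row("died2012", birth_year = 1940L, end = "2012-05-01", death = "2012-05-01")
  )
  e <- check_eligibility(p, 2015L)
  g <- function(id) e[e$person_id == id, ]
  expect_true(g("age18")$adult)
  expect_false(g("age17")$adult)
  expect_true(g("age17")$continuously_enrolled)
  expect_match(g("age17")$reason, "under 18")
  expect_false(g("gap")$continuously_enrolled)
  expect_false(g("short")$continuously_enrolled)
  # decedents stay eligible when enrolled to death
  expect_true(g("died2015")$continuously_enrolled)
  expect_true(g("died2012")$continuously_enrolled)
  expect_true(g("died2015")$eligible)
})

test_that("each criterion identifies exactly the persons it should", {
  persons <- bind_rows(
    person_row("c1"), person_row("c3"), person_row("c4"),
    person_row("single_e11"), person_row("insulin_e14"), person_row("c2")
  )
  b <- bundle_of(
    persons,
    diagnoses = bind_rows(
      # c4: assured ambulatory E11 in Q1, Q2, Q4; no drugs
      dx_row("c4", "E11.9", "2015-02-01"),
      dx_row("c4", "E11.9", "2015-05-01"),
      dx_row("c4", "E11.9", "2015-11-01"),
      # one E11 in a single quarter only: not a case
      dx_row("single_e11", "E11.9", "2015-02-01"),
      # insulin-only + E14, no E11: not a case (C1 needs A10B, C2 needs E11)
      dx_row("insulin_e14", "E14.9", "2015-03-01"),
      # c2: one A10 prescription + one hospital E11
      dx_row("c2", "E11.72", "2015-09-20", setting = "hospital_secondary")
    ),
    prescriptions = bind_rows(
      # c1: A10B in two distinct quarters
      rx_row("c1", "A10BA02", "2015-01-15"),
      rx_row("c1", "A10BA02", "2015-07-15"),
      # c3: single A10B prescription in Q2
      rx_row("c3", "A10BA02", "2015-05-10", prescriber = "dr7"),
      # insulin in two quarters: A10A does not satisfy C1
      rx_row("insulin_e14", "A10AB05", "2015-02-01"),
      rx_row("insulin_e14", "A10AB05", "2015-08-01"),
      rx_row("c2", "A10AB05", "2015-09-01")
    ),
    lab_services = bind_rows(
      # same quarter, same physician -> C3 fires
      lab_row("c3", "32025", "2015-06-20", physician = "dr7"),
      # wrong quarter for c1 -> no C3 there
      lab_row("c1", "32025", "2015-04-01", physician = "dr1")
    )
  )
  d <- identify_t2d(b)
  d <- setNames(split(d, seq_len(nrow(d))), d$person_id)
  expect_true(d$c1$is_case)
  expect_true(d$c1$c1_two_quarter_a10b)
  expect_false(d$c1$c3_a10b_plus_lab)
  expect_true(d$c3$is_case)
  expect_true(d$c3$c3_a10b_plus_lab)
  expect_false(d$c3$c1_two_quarter_a10b)
  expect_true(d$c4$is_case)
  expect_true(d$c4$c4_e11_three_quarters)
  expect_false(d$single_e11$is_case)
  expect_false(d$insulin_e14$is_case)
  expect_false(d$insulin_e14$excluded_e14_only)
  expect_true(d$c2$is_case)
  expect_true(d$c2$c2_a10_plus_e11)
  # c1 qualified via drugs alone and has no diabetes diagnosis at all
  expect_true(d$c1$no_diabetes_dx)
})

test_that("only assured ambulatory diagnoses count as E11 evidence", {
  b <- bundle_of(
    person_row("v"),
    diagnoses = bind_rows(
      dx_row("v", "E11.9", "2015-02-01", qualifier = "V"),
      dx_row("v", "E11.9", "2015-05-01", qualifier = "Z"),
      dx_row("v", "E11.9", "2015-08-01", qualifier = "A")
    ),
    prescriptions = rx_row("v", "A10BA02", "2015-02-10")
  )
  d <- identify_t2d(b)
  expect_false(d$is_case) # suspected/excluded/status-post rows never count
})

test_that("E14 exclusion removes drug-only cases and is the one monotonicity exception", {
  base_rx <- bind_rows(
    rx_row("x", "A10BA02", "2015-01-15"),
    rx_row("x", "A10BA02", "2015-07-15")
  )
  case0 <- identify_t2d(bundle_of(person_row("x"), prescriptions = base_rx))
  expect_true(case0$is_case)
  # adding an E14 row flips the drug-only case to excluded
  case1 <- identify_t2d(bundle_of(person_row("x"),
    prescriptions = base_rx,
    diagnoses = dx_row("x", "E14.9", "2015-03-01")
  ))
  expect_false(case1$is_case)
  expect_true(case1$excluded_e14_only)
  # adding an E11 row on top restores the case (exclusion needs E14 *only*)
  case2 <- identify_t2d(bundle_of(person_row("x"),
    prescriptions = base_rx,
    diagnoses = bind_rows(
      dx_row("x", "E14.9", "2015-03-01"),
      dx_row("x", "E11.9", "2015-04-01")
    )
  ))
  expect_true(case2$is_case)
  expect_false(case2$excluded_e14_only)
})

test_that("evidence after death does not count", {
  b <- bundle_of(
    person_row("d", end = "2015-06-30", death = "2015-06-30"),
    prescriptions = bind_rows(
      rx_row("d", "A10BA02", "2015-02-01"),
      rx_row("d", "A10BA02", "2015-05-01")
    )
  )
  expect_true(identify_t2d(b)$is_case)
  # same evidence pattern but death precedes the second quarter
  b2 <- bundle_of(
    person_row("d", end = "2015-03-31", death = "2015-03-31"),
    prescriptions = rx_row("d", "A10BA02", "2015-02-01")
  )
  expect_false(identify_t2d(b2)$is_case)
})

test_that("vectorized identification agrees with the brute-force oracle", {
  b <- random_criteria_bundle(400, seed = 101)
  dec <- identify_t2d(b)
  for (i in seq_len(nrow(dec))) {
    o <- oracle_identify_t2d(b, dec$person_id[i])
    expect_identical(dec$is_case[i], o$is_case,
      label = sprintf("is_case for %s", dec$person_id[i])
    )
    expect_identical(
      unlist(dec[i, c(
        "c1_two_quarter_a10b", "c2_a10_plus_e11",
        "c3_a10b_plus_lab", "c4_e11_three_quarters", "excluded_e14_only"
      )], use.names = FALSE),
      c(o$c1, o$c2, o$c3, o$c4, o$excluded),
      label = sprintf("criteria for %s", dec$person_id[i])
    )
  }
})

test_that("duration categories follow first claims evidence", {
  persons <- bind_rows(
    person_row("old"), person_row("y1"), person_row("inc"), person_row("y3")
  )
  b <- bundle_of(
    persons,
    diagnoses = bind_rows(
      dx_row("old", "E11.9", "2010-06-01"), # first evidence 2010 -> 5plus
      dx_row("old", "E11.9", "2015-02-01"),
      dx_row("y3", "E11.9", "2012-03-01"), # 2012 -> 3y
      dx_row("y3", "E11.9", "2015-03-01"),
      dx_row("inc", "E11.9", "2015-07-01") # nothing before 2015 -> incident
    ),
    prescriptions = bind_rows(
      rx_row("y1", "A10BA02", "2014-05-01"), # first A10 in 2014 -> 1y
      rx_row("y1", "A10BA02", "2015-01-05"),
      rx_row("y1", "A10BA02", "2015-04-05")
    )
  )
  dur <- duration_category(b)
  got <- setNames(dur$duration_category, dur$person_id)
  expect_equal(got[["old"]], "5plus")
  expect_equal(got[["y1"]], "1y")
  expect_equal(got[["y3"]], "3y")
  expect_equal(got[["inc"]], "incident_2015")
})

test_that("case identification recovers simulated truth reproducibly", {
  cfg <- sim_config(n_persons = 3000, seed = 31)
  out <- simulate_claims(cfg)
  cohort <- build_cohort(out$bundle)
  perf <- phenotype_performance(
    dplyr::filter(cohort, .data$eligible),
    out$ground_truth
  )
  # deterministic under the fixed seed
  out2 <- simulate_claims(cfg)
  perf2 <- phenotype_performance(
    dplyr::filter(build_cohort(out2$bundle), .data$eligible),
    out2$ground_truth
  )
  expect_identical(perf, perf2)
  # the algorithm finds most treated prevalent diabetics and invents none
  expect_gt(perf$sensitivity, 0.6)
  expect_gt(perf$specificity, 0.99)
  expect_gt(perf$ppv, 0.95)
})
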