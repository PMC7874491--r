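# Code-set matching with exclusions, the three CVD definitions, windowed
# classification, characterization flags, therapy classes.

test_that("prefix matching honors exclusions regardless of prefix length", {
  narrow <- build_definition("narrow")$icd_set
  expect_true(code_matches("I2511", narrow))
  expect_false(code_matches("I2510", narrow)) # excluded child of included I25
  expect_false(code_matches("I2519", narrow))
  expect_false(code_matches("I253", narrow))
  expect_false(code_matches("I2530", narrow)) # child of an excluded prefix
  expect_true(code_matches("I639", narrow))
  expect_true(code_matches("I64", narrow))
  expect_true(code_matches("I200", narrow))
  expect_false(code_matches("I201", narrow)) # only unstable angina I20.0
  expect_true(code_matches("I739", narrow))
  expect_false(code_matches("I738", narrow))
  expect_true(code_matches("I7021", narrow))
  # dotted input is accepted
  expect_true(code_matches("I25.11", narrow))
  # empty set matches nothing
  empty <- code_set("empty", "ICD", include = character())
  expect_false(any(code_matches(c("I10", "E11"), empty)))
})

test_that("code-set construction rejects inconsistent prefix sets", {
  expect_error(
    code_set("bad", "ICD", include = "I25", exclude = "I63"),
    "extends no include", class = "t2dcvd_config_error"
  )
  expect_error(
    code_set("bad", "ICD", include = c("I25", "I63"), exclude = "I63"),
    "overlap", class = "t2dcvd_config_error"
  )
  cs <- code_set("ops", "OPS", include = "5-361")
  expect_error(code_matches("I25", cs, system = "ICD"),
    "mismatch", class = "t2dcvd_config_error"
  )
})

test_that("the three definitions nest and differ where they should", {
  narrow <- build_definition("narrow")
  chf <- build_definition("narrow_chf")
  wide <- build_definition("wide")
  expect_true(code_matches("8-8401", narrow$ops_set)) # 8-84x children
  expect_true(code_matches("I501", chf$icd_set))
  expect_false(code_matches("I501", narrow$icd_set))
  expect_true(code_matches("I609", wide$icd_set))
  expect_false(code_matches("I609", chf$icd_set))
  expect_true(code_matches("I2510", wide$icd_set)) # wide drops the exclusions
  expect_error(build_definition("bogus"))
})

test_that("definition coverage nests over the synthetic code universe", {
  u <- code_universe()
  icd <- u$code[u$system == "ICD"]
  ops <- u$code[u$system == "OPS"]
  defs <- lapply(c("narrow", "narrow_chf", "wide"), build_definition)
  cover <- lapply(defs, function(d) {
    c(icd[code_matches(icd, d$icd_set)], ops[code_matches(ops, d$ops_set)])
  })
  expect_true(all(cover[[1]] %in% cover[[2]]))
  expect_true(all(cover[[2]] %in% cover[[3]]))
  expect_gt(length(setdiff(cover[[2]], cover[[1]])), 0) # I50 children
  expect_gt(length(setdiff(cover[[3]], cover[[2]])), 0) # I60-I62 etc.
})

test_that("matching equals exhaustive enumeration on the code universe", {
  u <- code_universe()
  for (def_name in c("narrow", "wide")) {
    d <- build_definition(def_name)
    for (sys in c("ICD", "OPS")) {
      codes <- u$code[u$system == sys]
      cs <- if (sys == "ICD") d$icd_set else d$ops_set
      got <- code_matches(codes, cs)
      want <- vapply(
        codes, oracle_match, logical(1),
        include = cs$include, exclude = cs$exclude
      )
      expect_identical(got, unname(want), label = paste(def_name, sys))
    }
  }
})

test_that("windowed classification sees only in-window qualifying events", {
  b <- bundle_of(
    bind_rows(person_row("a"), person_row("b"), person_row("c")),
    diagnoses = bind_rows(
      dx_row("a", "I21.0", "2012-05-01", setting = "hospital_main"),
      dx_row("b", "I21.0", "2015-05-01", qualifier = "V") # suspected: never counts
    ),
    procedures = proc_row("c", "5-361", "2011-03-03")
  )
  narrow <- build_definition("narrow")
  full <- classify_cvd(b, definition = narrow, window = c(2010, 2015))
  got <- setNames(full$cvd, full$person_id)
  expect_true(got[["a"]])
  expect_false(got[["b"]])
  expect_true(got[["c"]])
  late <- classify_cvd(b, definition = narrow, window = c(2013, 2015))
  expect_false(setNames(late$cvd, late$person_id)[["a"]])
  # OPS toggle removes procedure-only cases
  no_ops <- classify_cvd(b,
    definition = build_definition("narrow", use_ops = FALSE),
    window = c(2010, 2015)
  )
  expect_false(setNames(no_ops$cvd, no_ops$person_id)[["c"]])
  # first hit is reported for audit
  a_row <- full[full$person_id == "a", ]
  expect_equal(a_row$first_hit_code, "I210")
  expect_equal(a_row$first_hit_date, as.Date("2012-05-01"))
})

test_that("definition and window monotonicity hold on random event streams", {
  set.seed(77)
  pool_icd <- c(
    "I2511", "I2510", "I200", "I201", "I501", "I609", "I639", "I739",
    "I10", "E780", "I21", "I229"
  )
  ids <- sprintf("m%03d", 1:120)
  persons <- purrr::map_dfr(ids, person_row)
  dx <- purrr::map_dfr(ids, function(id) {
    k <- sample(0:4, 1)
    if (k == 0) {
      return(NULL)
    }
    dx_row(id, sample(pool_icd, k, replace = TRUE),
      as.Date("2010-01-01") + sample.int(2190, k),
      setting = sample(c("ambulatory", "hospital_main"), k, replace = TRUE)
    )
  })
  b <- bundle_of(persons, diagnoses = dx)
  defs <- lapply(
    setNames(nm = c("narrow", "narrow_chf", "wide")), build_definition
  )
  flags <- lapply(defs, function(d) {
    classify_cvd(b, definition = d, window = c(2012, 2015))$cvd
  })
  expect_true(all(flags$narrow <= flags$narrow_chf))
  expect_true(all(flags$narrow_chf <= flags$wide))
  w1 <- classify_cvd(b, definition = defs$narrow, window = c(2014, 2015))$cvd
  w2 <- classify_cvd(b, definition = defs$narrow, window = c(2010, 2015))$cvd
  expect_true(all(w1 <= w2))
})

test_that("characterization flags follow the hospitalization-based rules", {
  b <- bundle_of(
    bind_rows(
      person_row("hyp"), person_row("amb_mi"), person_row("hosp_mi"),
      person_row("micro"), person_row("t2dh")
    ),
    diagnoses = bind_rows(
      dx_row("hyp", "I10", "2015-02-01"),
      dx_row("amb_mi", "I21.0", "2015-03-01"), # ambulatory: not an event
      dx_row("hosp_mi", "I21.0", "2015-03-01", setting = "hospital_main"),
      dx_row("t2dh", "E11.9", "2015-06-01", setting = "hospital_main")
    ),
    procedures = proc_row("micro", "5-864", "2015-07-01")
  )
  ch <- characterize(b)
  g <- function(id) ch[ch$person_id == id, ]
  expect_true(g("hyp")$hypertension)
  expect_false(g("amb_mi")$macrovascular_event)
  expect_true(g("hosp_mi")$macrovascular_event)
  expect_true(g("micro")$microvascular_event)
  expect_true(g("t2dh")$t2d_hospitalization)
  expect_false(g("hyp")$macrovascular_event)
})

test_that("therapy classes partition the cohort and honor combinations", {
  b <- bundle_of(
    bind_rows(
      person_row("met"), person_row("met_su"), person_row("ins_plus"),
      person_row("none"), person_row("ins"), person_row("combo_fix"),
      person_row("triple")
    ),
    prescriptions = bind_rows(
      rx_row("met", "A10BA02", "2015-01-01"),
      rx_row("met_su", "A10BA02", "2015-01-01"),
      rx_row("met_su", "A10BB01", "2015-04-01"),
      rx_row("ins_plus", "A10AB01", "2015-01-01"),
      rx_row("ins_plus", "A10BA02", "2015-02-01"),
      rx_row("ins", "A10AE04", "2015-02-01"),
      rx_row("combo_fix", "A10BD07", "2015-05-01"), # fixed metformin+DPP4
      rx_row("triple", "A10BA02", "2015-01-01"),
      rx_row("triple", "A10BB12", "2015-02-01"),
      rx_row("triple", "A10BH01", "2015-03-01")
    )
  )
  th <- classify_therapy(b)
  g <- function(id) th[th$person_id == id, ]
  expect_equal(g("met")$therapy_class, "metformin_mono")
  expect_equal(g("met_su")$therapy_class, "dual_noninsulin")
  expect_true(g("met_su")$metformin_su)
  expect_false(g("met_su")$metformin_dpp4)
  expect_equal(g("ins_plus")$therapy_class, "insulin_plus_noninsulin")
  expect_equal(g("none")$therapy_class, "none")
  expect_equal(g("ins")$therapy_class, "insulin_only")
  # a fixed combination expands to its two component classes
  expect_equal(g("combo_fix")$therapy_class, "dual_noninsulin")
  expect_true(g("combo_fix")$metformin_dpp4)
  expect_equal(g("triple")$therapy_class, "triple_plus_noninsulin")
  # exactly one label per person
  expect_false(anyNA(th$therapy_class))
  expect_equal(nrow(th), 7L)
  # unmapped A10B subclasses warn and count as 'other'
  b2 <- bundle_of(person_row("odd"), prescriptions = rx_row("odd", "A10BG03", "2015-01-01"))
  expect_warning(th2 <- classify_therapy(b2), "unmapped")
  expect_equal(th2$therapy_class, "other_mono")
})
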