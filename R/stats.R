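# Prevalence estimation with Wald confidence intervals, observation-window
# sweeps, stratified tables, and extrapolation to a reference population.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding as used in the printed tables, as opposed
#' to the IEEE round-half-to-even of base [round()].
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Binomial period prevalence with a Wald confidence interval
#'
#' Percentage `100 * n/N` with the normal-approximation (Wald) interval
#' `100 * (p +/- z * sqrt(p (1 - p) / N))`, computed on the unrounded
#' proportion, each bound then rounded half-up to `digits` decimals and
#' clamped to `[0, 100]`. Wilson and Clopper-Pearson intervals are available
#' behind `method` but the Wald interval is the default because it is what
#' descriptive claims-data tables conventionally print.
#'
#' @param numerator,denominator Non-negative counts, `numerator <=
#'   denominator`, `denominator > 0`. Vectorized.
#' @param z Critical value (default 1.96 for 95%).
#' @param digits Decimals for the printed percentage and bounds.
#' @param method `"wald"` (default), `"wilson"` or `"clopper-pearson"`.
#' @return A tibble: `numerator`, `denominator`, `percent`, `ci_low`,
#'   `ci_high`, `z`.
#' @examples
#' prevalence(151598, 324708) # 46.69 (46.52; 46.86)
#' @export
prevalence <- function(numerator, denominator, z = 1.96, digits = 2,
                       method = c("wald", "wilson", "clopper-pearson")) {
  method <- match.arg(method)
  if (any(denominator <= 0)) {
    abort("prevalence(): denominator must be positive", class = "t2dcvd_input_error")
  }
  if (any(numerator < 0) || any(numerator > denominator)) {
    abort("prevalence(): numerator must lie in [0, denominator]",
      class = "t2dcvd_input_error"
    )
  }
  p <- numerator / denominator
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / denominator)
    lo <- p - half
    hi <- p + half
  } else if (method == "wilson") {
    z2 <- z^2
    centre <- (p + z2 / (2 * denominator)) / (1 + z2 / denominator)
    half <- z * sqrt(p * (1 - p) / denominator + z2 / (4 * denominator^2)) /
      (1 + z2 / denominator)
    lo <- centre - half
    hi <- centre + half
  } else {
    alpha <- 2 * stats::pnorm(-abs(z)) # z back to the matching alpha
    lo <- ifelse(numerator == 0, 0,
      stats::qbeta(alpha / 2, numerator, denominator - numerator + 1)
    )
    hi <- ifelse(numerator == denominator, 1,
      stats::qbeta(1 - alpha / 2, numerator + 1, denominator - numerator)
    )
  }
  tibble(
    numerator = numerator, denominator = denominator,
    percent = round_half_up(100 * p, digits),
    ci_low = pmax(0, round_half_up(100 * lo, digits)),
    ci_high = pmin(100, round_half_up(100 * hi, digits)),
    z = z
  )
}

#' Extrapolate a sample proportion to a reference population
#'
#' Computes `round(reference_population * numerator / denominator)` under
#' exact rational arithmetic: the product `numerator * reference_population`
#' can exceed the 2^53 integer range of doubles, so the multiplication and
#' division are carried out by split long division whose intermediates all
#' stay exactly representable. Halves round up.
#'
#' @param numerator,denominator Sample counts, `denominator > 0`.
#' @param reference_population Size of the population extrapolated to.
#' @return A one-row tibble: `sample_numerator`, `sample_denominator`,
#'   `reference_population`, `extrapolated_count`.
#' @examples
#' extrapolate(151598, 3876632, 70728398) # 2,765,876
#' @export
extrapolate <- function(numerator, denominator, reference_population) {
  if (length(numerator) != 1L || length(denominator) != 1L ||
    length(reference_population) != 1L) {
    abort("extrapolate(): scalar inputs expected", class = "t2dcvd_input_error")
  }
  if (denominator <= 0) {
    abort("extrapolate(): denominator must be positive", class = "t2dcvd_input_error")
  }
  if (numerator < 0 || reference_population < 0) {
    abort("extrapolate(): counts must be non-negative", class = "t2dcvd_input_error")
  }
  if (any(c(numerator, denominator, reference_population) %% 1 != 0) ||
    any(c(numerator, denominator, reference_population) >= 2^31)) {
    abort("extrapolate(): inputs must be integers below 2^31",
      class = "t2dcvd_input_error"
    )
  }
  tibble(
    sample_numerator = numerator, sample_denominator = denominator,
    reference_population = reference_population,
    extrapolated_count = exact_scaled_count(numerator, reference_population, denominator)
  )
}

# round(a * b / n) with all intermediates exact in double arithmetic:
# split a into base-1e6 limbs and long-divide limb by limb
exact_scaled_count <- function(a, b, n) {
  a1 <- a %/% 1e6
  a0 <- a %% 1e6
  d1 <- a1 * b # < 2^31/1e6 * 2^31 ~ 4.6e12
  q1 <- d1 %/% n
  r1 <- d1 %% n
  d0 <- r1 * 1e6 + a0 * b # < 2^31*1e6 + 1e6*2^31 ~ 4.3e15 < 2^53
  q0 <- d0 %/% n
  r0 <- d0 %% n
  q <- q1 * 1e6 + q0
  if (2 * r0 >= n) q + 1 else q
}

#' Sweep observation windows and CVD definitions
#'
#' Recomputes CVD period prevalence among the cohort's cases for every
#' combination of observation window (all ending in `end_year`, starting in
#' `start_years`) and CVD definition. The resulting grid is, on any dataset,
#' non-decreasing from narrow to wide definitions and from shorter to longer
#' windows, because the definitions nest and the windows nest.
#'
#' @param bundle A [claims_bundle()].
#' @param case_ids Person ids of the T2D cases (the denominator).
#' @param definitions Character vector of definition names, see
#'   [build_definition()].
#' @param start_years Integer vector of window start years.
#' @param end_year Common window end year.
#' @param use_ops Whether OPS procedures contribute.
#' @param z,digits Passed to [prevalence()].
#' @return A tibble with one row per window x definition:
#'   `start_year`, `end_year`, `definition`, plus the [prevalence()] columns.
#' @export
window_sweep <- function(bundle, case_ids,
                         definitions = c("narrow", "narrow_chf", "wide"),
                         start_years = 2010:2015, end_year = 2015L,
                         use_ops = TRUE, z = 1.96, digits = 2) {
  if (length(case_ids) == 0L) {
    abort("window_sweep(): empty cohort (denominator 0)", class = "t2dcvd_input_error")
  }
  defs <- lapply(setNames(definitions, definitions), build_definition, use_ops = use_ops)
  grid <- tidyr::crossing(start_year = start_years, definition = definitions)
  purrr::pmap_dfr(grid, function(start_year, definition) {
    cl <- classify_cvd(bundle, case_ids, defs[[definition]],
      window = c(start_year, end_year)
    )
    est <- prevalence(sum(cl$cvd), length(case_ids), z = z, digits = digits)
    dplyr::bind_cols(
      tibble(
        start_year = start_year, end_year = end_year,
        definition = definition
      ),
      est
    )
  })
}

#' Stratified prevalence of a cohort flag
#'
#' Splits a cohort table by a stratification column and estimates the
#' prevalence of a logical outcome column per stratum (plus mean age, when an
#' `age` column is present). Strata partition the cohort, so per-stratum
#' numerators and denominators sum to the totals.
#'
#' @param cohort A data frame with one row per person.
#' @param by Name of the stratification column (e.g. `"sex"`, `"age_band"`,
#'   `"duration_category"`, `"therapy_class"`).
#' @param outcome Name of the logical outcome column (default `"cvd"`).
#' @param z,digits Passed to [prevalence()].
#' @param total Append a `"total"` row.
#' @return A tibble: `stratum`, the [prevalence()] columns, `mean_age`.
#' @export
stratify <- function(cohort, by, outcome = "cvd", z = 1.96, digits = 2, total = TRUE) {
  if (!by %in% names(cohort)) {
    abort(sprintf("stratify(): unknown stratum column '%s'", by),
      class = "t2dcvd_input_error"
    )
  }
  if (!outcome %in% names(cohort)) {
    abort(sprintf("stratify(): unknown outcome column '%s'", outcome),
      class = "t2dcvd_input_error"
    )
  }
  if (anyNA(cohort[[by]])) {
    abort(sprintf("stratify(): missing stratum label in '%s'", by),
      class = "t2dcvd_input_error"
    )
  }
  one <- function(df, label) {
    est <- prevalence(sum(df[[outcome]]), nrow(df), z = z, digits = digits)
    est$stratum <- label
    est$mean_age <- if ("age" %in% names(df)) {
      round_half_up(mean(df$age), 2)
    } else {
      NA_real_
    }
    select(est, "stratum", dplyr::everything())
  }
  strata <- sort(unique(as.character(cohort[[by]])))
  out <- bind_rows(lapply(strata, function(s) {
    one(cohort[as.character(cohort[[by]]) == s, , drop = FALSE], s)
  }))
  if (total) out <- bind_rows(out, one(cohort, "total"))
  out
}
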