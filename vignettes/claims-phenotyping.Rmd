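---
title: "Claims-based phenotyping of cardiovascular disease in type 2 diabetes"
author: "t2dcvd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Claims-based phenotyping of cardiovascular disease in type 2 diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2dcvd)
library(dplyr)
```

## The problem

German statutory health insurance (SHI) claims are a routine by-product of
reimbursement: quarter-stamped ambulatory diagnoses with qualifier codes,
hospital main/secondary discharge diagnoses, ATC-coded pharmacy dispensings,
OPS-coded procedures, and fee-schedule (EBM) lab billings. They cover about
90% of the German population and are therefore attractive for estimating
how common cardiovascular disease (CVD) is among people with type 2
diabetes (T2D) — but neither "has T2D" nor "has a history of CVD" is a
field in the data. Both must be *phenotyped*: reconstructed from coded
traces under explicit, auditable rules.

`t2dcvd` packages that reconstruction as a pipeline with four analytic
stages (cohort selection, T2D case identification, code-set-based CVD
classification, prevalence estimation) plus a synthetic claims generator
with known ground truth, so every stage can be validated without access to
real, access-restricted SHI data.

## The case-identification algorithm

A person enters the study population when they are an adult (≥ 18 at 1
January of the index year, from birth year alone — claims extracts carry no
exact birth date) and continuously enrolled over the six calendar years
ending with the index year. Persons who die during the index year remain
eligible when enrolled to death; their evidence window simply truncates at
the death date.

A person is a T2D case when at least one of four criteria holds in the
index year:

* **C1** — a non-insulin glucose-lowering agent (ATC `A10B`) dispensed in
  at least two *distinct calendar quarters*;
* **C2** — any glucose-lowering agent (ATC `A10`, insulins included) plus
  at least one E11 diagnosis that is either an assured ("gesichert",
  qualifier G) ambulatory diagnosis or a hospital main/secondary diagnosis;
* **C3** — an `A10B` dispensing with a blood-glucose/HbA1c lab billing
  (EBM 32025, 32057, 32881, 32094) by the *prescribing physician* in the
  *prescription quarter*;
* **C4** — assured-or-hospital E11 diagnoses in at least three of the four
  quarters.

Persons qualifying *only* through the drug pathways (C1/C3) who carry an
unspecific-diabetes code (E14) but no E11 in the index year are excluded:
their diabetes type cannot be asserted. This is the algorithm's single
non-monotonicity — adding an E14 row can turn a drug-only case into a
non-case, and adding an E11 row turns it back — and it is tested as such.
Persons qualifying via C1 alone with no diabetes diagnosis of any kind are
retained (the rule as written does not require one) but flagged
(`no_diabetes_dx`) so users can tabulate or drop them.

Design choices worth making explicit:

* Only qualifier-G ambulatory diagnoses count as diabetes evidence,
  for E11 and E14 alike; V (suspected), A (excluded) and Z (status-post)
  rows never count. The same rule applies to CVD diagnoses.
* C2 deliberately accepts any `A10` prefix while C1/C3 require `A10B`: an
  insulin-treated person with a confirmed E11 diagnosis is a case, but
  insulin alone (compatible with type 1 diabetes) is not.
* Quarter counting is distinct-quarter, not distinct-prescription.
* Diabetes duration is the time since first claims evidence (E11 or `A10`)
  within the observable six years; first evidence in the earliest
  observable year is censored into the open-ended `5plus` category, and
  cases with no evidence before the index year are incident.

## CVD definitions as executable code sets

A disease definition is a `code_set`: include prefixes minus exclude
prefixes over normalized (dot-free, uppercase) ICD-10-GM or OPS codes. A
code matches when it extends an include prefix and no exclude prefix;
exclusion overrides inclusion regardless of prefix length, which is what
"I24–I25 excluding I25.3/.4/.10/.19" requires. Three definitions ship as a
JSON config (echoed into every run's manifest for audit):

* **narrow** — aligned with the inclusion criteria of a cardiovascular
  outcome trial in T2D: stroke/cerebrovascular disease (I63, I64),
  unstable angina and ischemic heart disease (I20.0, I21–I22, I24–I25 with
  the four exclusions), peripheral arterial occlusive disease (I73.9,
  I70.2x), coronary revascularization (OPS 5-361/5-362/5-363) and
  bypass/stent procedures (OPS 8-836/8-837/8-84x);
* **narrow_chf** — adds chronic heart failure (I50);
* **wide** — adds intracranial hemorrhage and all stroke codes (I60–I64)
  and the full ischemic-heart-disease block (I20–I25, exclusions dropped).

The printed `x` suffix ("8-84x", "I70.2x") denotes child codes and is read
as a bare prefix. The three definitions nest by construction; the package
verifies the nesting by enumeration over a bundled synthetic code universe
(a dense stand-in for the ICD-10-GM/OPS catalogues) rather than trusting
the configuration.

Classification is M1Q: one qualifying diagnosis (assured ambulatory or any
hospital setting) or procedure inside the observation window suffices, and
the first matching event is returned for audit. Whether OPS procedures
contribute at all is a flag (`use_ops`), mirroring the sensitivity analysis
that drops them.

## Statistics

Period prevalence is a binomial proportion reported as a percentage with a
Wald interval, `100·(p ± z·√(p(1−p)/N))`, computed on the unrounded
proportion and only then rounded half-up (commercial rounding, matching how
such tables are printed) to 2 decimals and clamped to [0, 100]. Wald is the
default because it is what descriptive claims-data tables conventionally
print; Wilson and Clopper–Pearson are available behind the `method`
argument. Extrapolation to a reference insured population multiplies the
full stratified-sample proportion by the population size under exact
rational arithmetic (split long division with all intermediates below
2^53), because `numerator × population` overflows double-exact integers.

```{r worked}
prevalence(151598, 324708)
extrapolate(151598, 3876632, 70728398)
```

## What the generator emulates — and what it does not

`sim_config()` describes an age/sex-stratified insured population observed
over six years. Latent states (T2D by age band, CVD given T2D, hypertension,
lipid disorder, therapy regimen, onset year) are drawn per person; claims
are then emitted from the latent states. The central behavioral parameter
is `doc_prob`, the per-year probability that a prevalent chronic condition
is coded at least once, independent across years. Reimbursement does not
require re-documenting every pre-existing diagnosis at every contact, so a
one-year window misses prevalent disease; under independence the observed
fraction after `y` years is `1 − (1 − doc_prob)^y`
(`expected_observed_fraction()`), which is exactly the mechanism behind
period prevalence rising with window length.

Defaults, chosen once as plausible for the emulated system and not tuned:

| parameter | default | rationale |
|---|---|---|
| `age_band_weights` | 0.16/0.27/0.29/0.21/0.07 | rough German age structure (u18, 18–39, 40–59, 60–79, 80+) |
| `t2d_prevalence_by_band` | 0/0.01/0.07/0.20/0.24 | ≈ 10% latent adult T2D, strongly age-dependent |
| `cvd_given_t2d` | 0.50 | about half of prevalent T2D carries CVD history over six years |
| `doc_prob` | 0.78 | `p/(1−(1−p)^6) ≈ 0.79` at p = 0.78, the 1-year/6-year ascertainment ratio typical of CVD in German claims |
| `churn_prob` | 0.02 | ≈ 2% lost to follow-up over the period |
| `death_rate_by_band` | up to 0.40 (80+) | six-year cumulative mortality, truncating enrollment |
| `therapy_mix` | see `sim_config()` | echoes the regimen distribution of treated T2D (≈ 30% untreated, 23% metformin mono, 12% insulin only, …) |
| `e14_miscoding_prob` | 0.025 | share of treated diabetics coded only as unspecific diabetes |

The generator intentionally omits features of real claims: no contact
clustering (documentation is independent across years by design — the
simplest model producing the geometric window effect), no incident CVD
during follow-up (the analysis measures *history* of CVD, so prevalent
cases predate the index year), no regional or household structure, no
costs, and no calibration against official German morbidity statistics.
One schema-level simplification: a person record carries a single
enrollment span, so churn appears as late entry or early exit rather than
an interior gap; the eligibility check treats both identically. Children
are generated with birth years ≤ 2009 so that every person can plausibly be
enrolled from the first study year. Passing tests on this generator
therefore demonstrate that the *rules* are implemented correctly and that
the window mechanism behaves as modeled — not that the defaults reproduce
German epidemiology.

Detected prevalence in the simulation sits below latent prevalence
(roughly 6.5–7% detected vs ~9.7% latent adult T2D under defaults): the
untreated-and-rarely-coded, and persons dying before the index year, are
invisible to an index-year algorithm. That gap is a real property of
claims phenotyping, and `phenotype_performance()` quantifies it
(sensitivity ≈ 0.7 against all latent T2D including pre-index deaths,
specificity ≈ 1).

## Numerical and degenerate-input choices

* Rounding is half-up at the reporting boundary only; all intermediate
  arithmetic is unrounded.
* `prevalence()` refuses denominator 0 and numerator > denominator; an
  empty cohort surfaces as an explicit error from `window_sweep()` rather
  than an NaN cell.
* Ties among same-day first CVD hits break deterministically
  (diagnosis before procedure, then code order) so audit output is stable.
* `quarter_of()` rejects unparseable dates outright; readers report file,
  line and column.
* Seeded runs are byte-identical: the generator draws everything from one
  `set.seed(seed)` stream, and the pipeline writes a manifest (config echo,
  code sets, row counts) sufficient to reproduce a run.

## Problem sizes

The shipped tests run the oracle-equivalence suite on 1,000 randomized
persons, the mechanism-recovery check on a 20,000-person simulation at
`doc_prob = 0.5` (≈ 550–600 true-CVD identified cases; the observed
1-to-6-year ascertainment fractions sit within 3 Monte-Carlo standard
errors of the geometric closed form), and a 2,000-replicate coverage check
of the Wald interval at p = 0.45, N = 5,000, which lands in the 94–96%
band. These sizes were chosen so the full validation runs comfortably on a
laptop while keeping Monte-Carlo error small relative to the tolerances
tested.

## Known limitations

* The algorithm cannot see undiagnosed diabetes, and persons treated by
  lifestyle alone are only found via C4.
* M1Q CVD classification accepts single assured ambulatory diagnoses;
  false-positive ambulatory coding inflates CVD history somewhat, which is
  the price of aligning with trial inclusion criteria rather than the
  stricter M2Q convention.
* Code lists are configuration, not clinical truth: the bundled sets
  implement one published translation of trial criteria and are meant to be
  edited (`cvd_codes_config_path()`, the `atc_map` argument of
  `classify_therapy()`).
* The Wald interval degenerates at p near 0 or 1 (e.g. a 0/N cohort yields
  a zero-width interval); use `method = "wilson"` or `"clopper-pearson"`
  when tail behavior matters.
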