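---
title: "Methods: case/non-case signal detection, adjusted RORs and time-to-onset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case/non-case signal detection, adjusted RORs and time-to-onset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and data model

pvsignal analyzes spontaneous adverse-event report databases distributed
as four delimited tables keyed by a case identifier — demographics (sex,
age, reporting year), drug history (name, involvement code, start date),
adverse events (preferred term, onset date, outcome) and medical
history/primary illness (condition terms). This is the layout of the
Japanese JADER database, and the package ships a `jader_dialect()`
preset (Shift-JIS encoding, Japanese headers); any other delimited
source can be described with `table_dialect()`. The motivating analysis
is drug-induced hyponatremia under anticancer therapy, but every case
definition, drug panel and cancer panel is user-supplied configuration:
the package bundles no terminology, because MedDRA term lists are
licensed content.

Spontaneous reports are not a cohort. All statistics below are
*disproportionality* measures: they compare the mix of reports, not
incidence, and carry the usual caveats (reporting bias, no denominator,
no causality).

## Ingestion choices

* **De-duplication.** Databases of this kind ship multiple revisions of
  a case over time. We keep, per case identifier, the demographics row
  with the highest revision marker when the dialect provides one, else
  the last row in file order — i.e. the latest report version. Child
  rows without a demographics row are dropped and counted as orphans.
* **Exclusions.** Reports with unknown sex or unknown age band are
  removed before any analysis; the count is retained and reported.
* **Ages** are stored as decade bands (the granularity of the source);
  numeric ages are binned. The age covariate dichotomizes at the 60s
  band: `age_ge60 = 1` for 60s and above, the 0–59 group being the
  reference.
* **Dates** accept `YYYYMMDD`, `YYYY-MM-DD` and `YYYY/MM/DD`. Partial
  dates (year or year–month) are valid for the reporting year but count
  as missing for time-to-onset, which needs day resolution.
* **Exposure** means a drug entry with the *suspected* involvement code;
  concomitant and interaction entries never count.
* **Cancer-site indicators** are matched in the medical-history table.
  The source field for underlying disease is ambiguous in this class of
  databases (history vs. reason-for-use); we use the history table only,
  and a report may carry several cancer sites.
* **Term matching** is whole-term and case-insensitive by default, never
  substring-based: a set listing "Hyponatraemia" does not match
  "Hyponatraemic coma" unless the latter is listed. This errs toward
  specificity of the case definition.

# Crude screening

For an exposure indicator the reports form the 2×2 table (a, b, c, d)
and the reporting odds ratio is ROR = ad/bc with the Wald interval
exp(ln ROR ± 1.96·sqrt(1/a + 1/b + 1/c + 1/d)). The multiplier is the
literal 1.96 of the conventional formula rather than qnorm(0.975); the
difference is below a tenth of a percent and the literal form matches
how published intervals in this field are computed. A signal is a CI
lower bound above 1 — a one-sided rule with nominal 2.5% type-I error
under no association, which the test suite verifies empirically on
generator nulls. Zero cells receive the Haldane–Anscombe +0.5 on all
four cells (flagged in the output; an error mode is available);
exposures with an empty table row are reported as undefined without
aborting a multi-drug screen. Two-sided Fisher's exact p-values
accompany every row via `stats::fisher.test`, whose
sum-of-less-probable-tables definition (with a 1e-7 relative tie
tolerance) is exactly the convention intended here; the test suite
checks it against a full hypergeometric enumeration for every table with
N ≤ 40. Panel membership uses the conventional "more than 10 case
reports" rule, read strictly (a drug with exactly 10 cases is out).

# Adjusted model

The adjusted analysis is a logistic regression of case status on
reporting year (integer offset from the earliest year — centering
affects only the intercept), female sex, age ≥ 60, cancer-site
indicators, drug indicators, and configured drug×{sex, age, cancer}
interactions. Reference categories are male, age 0–59, no exposure, no
cancer at the site. Estimation is Newton–Raphson/IRLS written in the
package (the model *is* the method here, so it is authored rather than
delegated; `stats::glm` serves as an independent cross-check in the
tests):

* step-halving guarantees the log-likelihood never decreases across
  accepted iterations;
* convergence at gradient max-norm < 1e-8 or relative log-likelihood
  change < 1e-10, capped at 100 iterations;
* standard errors from the inverse observed information at the optimum;
  Wald CIs and p-values (consistent with symmetric published intervals);
* a coefficient passing |β| > 15 (odds ratio beyond 3×10⁶) aborts with a
  separation error naming the term — beyond that magnitude a binary
  covariate is separated for all practical purposes;
* constant non-intercept columns (including interactions forced to zero
  by their factors) are rejected by `design_matrix()` with the term
  named.

Main effects are flagged at p ≤ 0.05 and interactions at p ≤ 0.10, both
inclusive — the more permissive interaction threshold reflects the lower
power of product terms in rare-event data.

With a single binary covariate the logistic MLE reproduces the crude
odds ratio exactly (saturated model); the suite checks this equivalence
to six significant digits, plus CI coverage of a known coefficient
vector on generated data.

## Pipeline-level relaxation

`run_pipeline()` builds a default model (covariates + cancer sites +
crudely-signalled drugs, with drug×{sex, age, cancer} interactions) when
none is configured. Because small datasets routinely make some
interaction product identically zero, the pipeline drops *interaction*
columns that are constant, with a logged message, instead of aborting;
`design_matrix()` itself remains strict. An explicitly configured model
is used as-is.

# Time-to-onset

For a (drug, event) pair the onset day is (event onset date − earliest
suspected start date) + 1, so a same-day onset is day 1 and the
histogram starts at day 1. The analysis window defaults to 365 days;
complete pairs outside [1, window] are counted but not analyzed. The
in-window days are fitted by Weibull maximum likelihood in (scale α,
shape β), optimized on the log-parameter scale (BFGS on the exact
log-likelihood, initialized at α = mean, β = 1) with Wald intervals on
log α, log β transformed back, so the intervals respect positivity. By
default the unconditional density is fitted to the truncated sample —
the common practice in this literature; a right-truncated likelihood
(density divided by F(window)) is available as `truncated = TRUE`, and
on heavily truncated data it recovers larger scales, as the tests
demonstrate. Day counts are integers but are fitted as continuous values
without a discreteness correction. The generator rounds its Weibull
draws up to whole days (minimum 1) to respect the day-1 convention.

The shape parameter carries the clinical reading: hazard increasing over
time only when the 95% CI of β lies above 1, decreasing only when it
lies below, otherwise "constant-compatible". The model median is
α·(ln 2)^(1/β); quartiles reported next to it are empirical
(linear-interpolation quantiles), since published IQRs in this field are
typically empirical. Fits require at least 10 in-window observations and
refuse degenerate (all-equal) samples, for which the shape MLE diverges.

# The synthetic generator

`synthetic_config()` defines the study conditions under which the
package is exercised. Defaults emulate the marginal structure of a large
anticancer-drug hyponatremia screen: 14 drugs at their observed exposure
prevalences (0.6–2%), seven cancer sites at theirs, female fraction
0.486, 63.5% of reports aged ≥ 60, reporting years 2004–2020, and a
logistic event model whose coefficients equal the published adjusted
estimates (cisplatin log 4.05, female log 1.33, age log 2.73, the
cisplatin interactions, and an intercept of −6.1 giving an overall event
rate near 0.5%). Cisplatin onset days are drawn from Weibull(scale
10.38 days, shape 0.98). Missing sex (1%), age (2%) and dates (15%
each) default to rates that leave roughly three-quarters of case pairs
date-complete, matching the completeness typical of onset analyses in
this field.

The generator emits exactly one suspected-drug row per exposure and one
event row per report; optional concomitant "noise" rows never alter
exposure flags. With missingness switched off, `build_dataset()` on the
rendered tables reproduces the ground-truth indicator matrix cell for
cell — the property the test suite uses to validate the whole ingestion
chain. A single seeded RNG stream with a fixed draw order makes equal
configurations byte-identical on disk.

What the generator does *not* emulate: polypharmacy correlation between
drugs, duplicate or revised reports (covered by dedicated unit
fixtures instead), secular trends in reporting, coding noise in terms,
and the real databases' marginal distributions beyond the configured
panels. Passing tests therefore demonstrate correctness of the
*estimators* under the stated model, not robustness to real-world coding
artifacts.

## Simulation sizes

The stochastic checks run at sizes chosen to make their asymptotic
claims meaningful while staying lightweight: null operating
characteristics at 2,000 replicates of 10,000 reports with expected
exposed-case counts near 200 (the regime the Wald interval is designed
for); coefficient-recovery and CI-coverage at 50 replicates of 200,000
reports (rare events need large n for stable interaction cells); Weibull
recovery at 200 replicates of n = 162, the published sample size for
the cisplatin onset analysis.

# Known limitations

* Wald intervals everywhere (crude, adjusted, Weibull), matching field
  practice; no profile-likelihood or exact intervals.
* No alternative disproportionality statistics (PRR, IC, EBGM) and no
  penalized or exact logistic regression for separated data — separation
  is an error, not a fallback.
* Published screens are only partially recomputable from printed
  marginals; where a published row is internally inconsistent the
  package reproduces the arithmetic, not the printed number.
* One onset distribution per drug; no competing risks, no censoring
  model beyond the single truncation window.
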