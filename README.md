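# pvsignal

Case/non-case pharmacovigilance analysis for spontaneous adverse-event
report databases in the four-table JADER layout (demographics, drug
history, adverse events, medical history). The package is aimed at
pharmacoepidemiologists who screen such databases for drug–event
associations — the motivating application is anticancer-drug-induced
hyponatremia — and provides the full chain from raw delimited tables to
adjusted effect estimates and onset-timing analysis:

1. **Ingestion** — read, validate, join and de-duplicate the four tables;
   exclude reports with unknown sex or age
   (`read_jader_table()`, `merge_tables()`, `filter_valid()`).
2. **Cohort construction** — binary case, suspected-exposure and
   cancer-site indicators per report, with sex/age/year covariates
   (`build_dataset()`, `select_drugs()`).
3. **Crude signal screening** — reporting odds ratios with Wald intervals,
   Fisher's exact tests and the lower-bound signal rule
   (`screen_signals()`).
4. **Adjusted analysis** — multivariate logistic regression with
   interaction terms, fitted by IRLS with step-halving (`fit_adjusted()`).
5. **Time-to-onset** — Weibull maximum likelihood on days from first
   suspected prescription to event onset, with hazard-shape
   classification (`extract_onsets()`, `fit_weibull()`).
6. **Synthetic data** — a generator emitting the four tables with known
   ground truth, so the whole pipeline is testable without a licensed
   database extract (`synthetic_config()`, `generate_reports()`).

## The statistics

For one exposure, reports are cross-classified into a 2×2 table —
`a` exposed cases, `b` exposed non-cases, `c` unexposed cases,
`d` unexposed non-cases. The crude reporting odds ratio and its Wald 95%
confidence interval are

    ROR = (a/b) / (c/d),
    95% CI = exp( ln ROR ± 1.96 · sqrt(1/a + 1/b + 1/c + 1/d) ),

with the Haldane–Anscombe +0.5 correction when a cell is zero. A *signal*
is declared when the CI lower bound exceeds 1. Adjusted RORs are
exponentiated coefficients of the logistic model

    log odds(case) = β0 + β1·Y + β2·S + β3·A + β4·D + β5·C
                     + β6·S·D + β7·A·D + β8·C·D,

with Y the reporting year (centered), S female sex, A age ≥ 60, D drug
exposure and C cancer site; main effects are tested at p ≤ 0.05 and
interactions at p ≤ 0.10. Onset timing uses days from the earliest
suspected prescription (same-day onset = day 1) within a 365-day window,
fitted by a Weibull distribution with scale α and shape β; the hazard is
classified increasing/decreasing only when the 95% CI of β excludes 1,
and the model median is α·(ln 2)^(1/β).

## Worked example

The bundled configuration runs the whole study on a synthetic database
of 6,000 reports whose generating model has a cisplatin effect (true
adjusted OR 4.05), a cisplatin×lung-cancer interaction (true OR 1.5) and
cisplatin onset times drawn from Weibull(scale 10.38, shape 0.98):

```r
library(pvsignal)
cfg <- read_run_config(system.file("extdata", "example_config.yaml",
                                   package = "pvsignal"))
res <- run_pipeline(cfg, "results/example")
#> ingest: 6000 reports, 202 excluded (unknown sex/age), 5798 analyzed
#> cohort: 628 cases / 5798 reports
#> screen: 1 drug signal(s): cisplatin
#> adjust: 4 significant term(s)
#> tto: cisplatin, n = 111, shape 1.01 (constant-compatible)

res$drug_screen
#>        label total case noncase ratio_pct  ror ci_low ci_high p_fisher signal
#>    cisplatin   435  131     304     30.11 4.22   3.37    5.28   <0.001   TRUE
#>  carboplatin   324   39     285     12.04 1.13   0.80    1.60     0.46  FALSE
#>  gemcitabine   186   18     168      9.68 0.88   0.54    1.44     0.72  FALSE

res$onset$fit
#> Weibull fit (n = 111): scale 10.86 (95% CI 8.94-13.19), shape 1.01 (95% CI 0.88-1.16)
#>   model median 7.56 days; empirical IQR 3.0-13.0; hazard constant-compatible
```

Only cisplatin crosses the signal threshold (CI lower bound 3.37 > 1)
and its crude ROR of 4.22 brackets the generating value; the adjusted
table (`res$adjusted$table`) gives cisplatin 4.33 (3.12–6.01) and flags
the cisplatin×lung interaction at p = 0.025. The fitted onset shape of
1.01 (0.88–1.16) correctly includes the generating 0.98 and is classified
constant-compatible: no evidence that the hazard of onset rises or falls
over the first year.

Published screens can be re-checked directly from their printed
marginals, e.g. a database of 595,121 reports with 2,943 hyponatremia
cases, of which 11,468 reports and 221 cases mention cisplatin:

```r
crude_ror(contingency_from_margins(11468, 221, 595121, 2943))
#> ROR 4.19 (95% CI 3.65-4.82)
```

The same pipeline is scriptable from a shell via
`inst/scripts/pvsignal.R` with subcommands `run-all`, `screen`,
`adjust`, `tto` and `simulate`.

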