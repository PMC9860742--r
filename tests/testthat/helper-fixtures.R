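# Shared fixtures and independent oracles, all built in code at test time.

# write delimited lines to a temp file and read them back as a table
read_tiny <- function(kind, lines, dialect = table_dialect()) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  read_jader_table(f, kind, dialect)
}

# a small fully-specified report set: 4 reports covering the main branches
tiny_report_set <- function() {
  demo <- read_tiny("demo", c(
    "case_id,sex,age,reporting_year",
    "A,male,60s,2015",
    "B,female,50s,2016",
    "C,female,70s,2017",
    "D,male,40s,2018"))
  drug <- read_tiny("drug", c(
    "case_id,drug_name,involvement,start_date",
    "A,Cisplatin,suspected,2015-03-01",
    "A,Ondansetron,concomitant,2015-03-01",
    "B,cisplatin,concomitant,2016-05-10",
    "C,Gemcitabine,suspected,20170601"))
  reac <- read_tiny("reac", c(
    "case_id,term,onset_date,outcome",
    "A,Hyponatraemia,2015-03-05,Recovered",
    "B,Nausea,2016-05-12,Recovered",
    "C,hyponatraemia,2017-06-03,Unknown",
    "D,Rash,,Recovered"))
  hist <- read_tiny("hist", c(
    "case_id,condition",
    "A,Lung cancer",
    "C,Renal cancer"))
  merge_tables(demo, drug, reac, hist, quiet = TRUE)
}

# independent two-sided Fisher oracle: full hypergeometric enumeration
fisher_oracle <- function(a, b, c, d) {
  m <- a + c; n2 <- b + d; k <- a + b
  supp <- max(0, k - n2):min(k, m)
  p <- stats::dhyper(supp, m, n2, k)
  sum(p[p <= stats::dhyper(a, m, n2, k) * (1 + 1e-7)])
}

# independent Weibull maximizer: dense grid search over the same likelihood
grid_weibull <- function(t, n_grid = 400L) {
  ag <- seq(max(t) * 0.02, 3 * max(t), length.out = n_grid)
  bg <- seq(0.05, 10, length.out = n_grid)
  ll <- outer(ag, bg, Vectorize(function(a, b)
    sum(stats::dweibull(t, shape = b, scale = a, log = TRUE))))
  ix <- arrayInd(which.max(ll), dim(ll))
  list(alpha = ag[ix[1L]], beta = bg[ix[2L]],
       res_alpha = diff(ag[1:2]), res_beta = diff(bg[1:2]))
}

# null generator: one drug, no covariate effects, counts large enough for
# the Wald interval to operate in its asymptotic regime
null_config <- function(seed, n = 10000L) {
  synthetic_config(
    n_reports = n, seed = seed,
    drug_panel = c(drugA = 0.2),
    cancer_panel = stats::setNames(numeric(0), character(0)),
    event_model = list(intercept = stats::qlogis(0.1), coefficients = c()),
    onset_model = list(),
    missingness = list(sex = 0, age = 0, start_date = 0, onset_date = 0))
}

# generator with a known coefficient vector including a drug x cancer
# interaction, for parameter-recovery and CI-coverage checks
recovery_config <- function(seed, n = 200000L) {
  synthetic_config(
    n_reports = n, seed = seed,
    drug_panel = c(drugA = 0.05),
    cancer_panel = c(lung = 0.1),
    event_model = list(intercept = -5.3, coefficients = c(
      reporting_year = -0.01, sex_female = log(1.33), age_ge60 = log(2.7),
      lung = log(1.5), drugA = log(4), "drugA:lung" = log(1.5))),
    onset_model = list(),
    missingness = list(sex = 0, age = 0, start_date = 0, onset_date = 0))
}

recovery_spec <- function() {
  model_spec(c("reporting_year", "sex_female", "age_ge60", "lung", "drugA"),
             list(c("drugA", "lung")))
}

# complete small synthetic setup without missingness, panels matching the
# generator labels, for exact ground-truth recovery through the file layer
observed_config <- function(seed = 11L, n = 1500L, ...) {
  base <- list(
    n_reports = n, seed = seed,
    drug_panel = c(cisplatin = 0.08, carboplatin = 0.05, gemcitabine = 0.03),
    cancer_panel = c(lung = 0.06, renal = 0.04),
    event_model = list(intercept = -3.2, coefficients = c(
      sex_female = log(1.33), age_ge60 = log(2.73), lung = log(1.49),
      cisplatin = log(4.05), "cisplatin:lung" = log(1.5))),
    onset_model = list(cisplatin = c(scale = 10.38, shape = 0.98)),
    missingness = list(sex = 0, age = 0, start_date = 0, onset_date = 0))
  over <- list(...)
  base[names(over)] <- over
  do.call(synthetic_config, base)
}

panels_for <- function(config) {
  list(drug_panel = as.list(stats::setNames(names(config$drug_panel),
                                            names(config$drug_panel))),
       cancer_panels = as.list(config$cancer_terms))
}

dataset_from_tables <- function(gen, config) {
  rs <- merge_tables(gen$tables$demo, gen$tables$drug, gen$tables$reac,
                     gen$tables$hist, quiet = TRUE)
  rs <- filter_valid(rs)
  p <- panels_for(config)
  build_dataset(rs, term_set("event", config$event_term),
                p$drug_panel, p$cancer_panels)
}
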