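# Synthetic four-table report generator with known ground truth.  Default
# parameters mirror the marginal structure of the published anticancer-drug
# hyponatremia analysis: a 14-drug suspected-exposure panel, seven cancer
# sites, a rare event (~0.5% of reports) driven by a logistic model with
# drug, sex, age, cancer and interaction effects, and Weibull-distributed
# onset days for exposed cases.

.default_drug_panel <- c(
  cisplatin = 11468, carboplatin = 9266, oxaliplatin = 11973,
  cyclophosphamide = 10889, pemetrexed = 3471, vincristine = 6179,
  etoposide = 5307, nivolumab = 9307, pembrolizumab = 5505,
  irinotecan = 8695, doxorubicin = 6555, paclitaxel = 11161,
  docetaxel = 7848, gemcitabine = 5338) / 595121

.default_cancer_panel <- c(
  esophageal = 1607, lung = 15256, renal = 7706, stomach = 8202,
  prostate = 7944, colorectal = 15913, breast = 12604) / 595121

.default_age_weights <- c(
  "0s" = 0.02, "10s" = 0.02, "20s" = 0.04, "30s" = 0.06, "40s" = 0.09,
  "50s" = 0.135, "60s" = 0.22, "70s" = 0.25, "80s" = 0.13, "90s" = 0.03,
  "100s" = 0.005)

.default_event_model <- list(
  intercept = -6.1,
  coefficients = c(
    reporting_year = -0.01,
    sex_female = log(1.33),
    age_ge60 = log(2.73),
    renal = log(1.57), lung = log(1.49), esophageal = log(1.06),
    cisplatin = log(4.05), etoposide = log(1.23), pemetrexed = log(1.16),
    "cisplatin:lung" = log(1.50),
    "cisplatin:sex_female" = log(0.98),
    "cisplatin:age_ge60" = log(0.71)))

#' Configuration for the synthetic report generator
#'
#' All probabilities and model coefficients are explicit so that every
#' downstream statistic has a known ground truth. Defaults emulate a large
#' spontaneous-report database screened for a rare electrolyte adverse
#' event: exposure prevalences and cancer-site prevalences at the published
#' marginal rates, a logistic event model whose coefficients equal the
#' published adjusted estimates (including the cisplatin interactions), and
#' a cisplatin onset-time distribution with Weibull scale 10.38 days and
#' shape 0.98.
#'
#' @param n_reports Number of reports to generate.
#' @param seed Integer seed; identical configuration and seed give
#'   byte-identical tables.
#' @param sex_female_prob Probability of female sex.
#' @param age_band_weights Named weights over decade age bands.
#' @param year_range Length-2 integer vector, inclusive reporting-year span.
#' @param drug_panel Named vector of suspected-exposure probabilities.
#' @param cancer_panel Named vector of cancer-site prevalences.
#' @param event_model List with `intercept` and named `coefficients` on the
#'   log-odds scale; names refer to covariates, panel labels, or `a:b`
#'   interaction products. The reporting year enters centered at
#'   `year_range[1]`.
#' @param onset_model Named list: drug label -> `c(scale, shape)` of the
#'   Weibull onset-day distribution for exposed cases of that drug.
#' @param missingness List of probabilities `sex`, `age`, `start_date`,
#'   `onset_date` applied after generation (set all to 0 for fully
#'   observed data).
#' @param event_term Preferred term written for case reports.
#' @param filler_terms Event terms written for non-case reports.
#' @param cancer_terms Optional named map label -> condition string written
#'   in the history table (default: "<Label> cancer").
#' @param concomitant_noise Per-report probability of an extra concomitant
#'   drug row (never counted as exposure).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_reports = 5000L, seed = 1L,
                             sex_female_prob = 0.486,
                             age_band_weights = .default_age_weights,
                             year_range = c(2004L, 2020L),
                             drug_panel = .default_drug_panel,
                             cancer_panel = .default_cancer_panel,
                             event_model = .default_event_model,
                             onset_model = list(cisplatin = c(scale = 10.38,
                                                              shape = 0.98)),
                             missingness = list(sex = 0.01, age = 0.02,
                                                start_date = 0.15,
                                                onset_date = 0.15),
                             event_term = "Hyponatraemia",
                             filler_terms = c("Nausea", "Pyrexia", "Rash"),
                             cancer_terms = NULL,
                             concomitant_noise = 0) {
  probs <- c(sex_female_prob, drug_panel, cancer_panel,
             unlist(missingness), concomitant_noise)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1))
    pv_error("probabilities must lie in [0, 1]", "pvsignal_config_error")
  if (n_reports < 1) pv_error("n_reports must be >= 1", "pvsignal_config_error")
  if (any(age_band_weights < 0) || sum(age_band_weights) <= 0)
    pv_error("invalid age band weights", "pvsignal_config_error")
  for (om in onset_model)
    if (any(om <= 0)) pv_error("Weibull scale and shape must be positive",
                               "pvsignal_config_error")
  if (is.null(cancer_terms))
    cancer_terms <- stats::setNames(
      paste0(toupper(substring(names(cancer_panel), 1, 1)),
             substring(names(cancer_panel), 2), " cancer"),
      names(cancer_panel))
  structure(list(n_reports = as.integer(n_reports), seed = as.integer(seed),
                 sex_female_prob = sex_female_prob,
                 age_band_weights = age_band_weights,
                 year_range = as.integer(year_range),
                 drug_panel = drug_panel, cancer_panel = cancer_panel,
                 event_model = event_model, onset_model = onset_model,
                 missingness = missingness, event_term = event_term,
                 filler_terms = filler_terms, cancer_terms = cancer_terms,
                 concomitant_noise = concomitant_noise),
            class = "synthetic_config")
}

.resolve_term <- function(term, env) {
  if (grepl(":", term, fixed = TRUE)) {
    p <- strsplit(term, ":", fixed = TRUE)[[1L]]
    return(.resolve_term(p[1L], env) * .resolve_term(p[2L], env))
  }
  v <- env[[term]]
  if (is.null(v)) pv_error(paste0("event model refers to unknown term: '",
                                  term, "'"), "pvsignal_config_error")
  v
}

#' Generate the ground-truth analysis dataset directly
#'
#' Draws covariates, exposures and the event without rendering the
#' four-table files — the in-memory path used for simulation studies of the
#' estimators. The result is the exact indicator matrix that
#' [build_dataset()] would recover from the rendered tables of the same
#' configuration when no missingness is applied.
#'
#' @param config A [synthetic_config()].
#' @return A list with `dataset` (an `analysis_dataset`), `prob` (true event
#'   probabilities), `onset_day` (true onset day or `NA`), `onset_drug`,
#'   `missing` (data frame of missingness flags), and `coefficients` (the
#'   generating vector, intercept first).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_reports
  y0 <- config$year_range[1L]; y1 <- config$year_range[2L]

  env <- new.env()
  env$sex_female <- stats::rbinom(n, 1L, config$sex_female_prob)
  bands <- sample(names(config$age_band_weights), n, replace = TRUE,
                  prob = config$age_band_weights)
  env$age_ge60 <- as.integer(.band_decade(bands) >= 60L)
  year <- sample(y0:y1, n, replace = TRUE)
  env$reporting_year <- year - y0

  drugs <- vapply(config$drug_panel, function(p) stats::rbinom(n, 1L, p),
                  integer(n))
  cancers <- if (length(config$cancer_panel))
    vapply(config$cancer_panel, function(p) stats::rbinom(n, 1L, p),
           integer(n))
  else matrix(integer(0), nrow = n, ncol = 0)
  if (n == 1L) { drugs <- t(drugs); if (length(config$cancer_panel)) cancers <- t(cancers) }
  colnames(drugs) <- names(config$drug_panel)
  if (ncol(cancers)) colnames(cancers) <- names(config$cancer_panel)
  for (lab in colnames(drugs)) env[[lab]] <- drugs[, lab]
  for (lab in colnames(cancers)) env[[lab]] <- cancers[, lab]

  eta <- rep(config$event_model$intercept, n)
  for (tm in names(config$event_model$coefficients))
    eta <- eta + config$event_model$coefficients[[tm]] * .resolve_term(tm, env)
  prob <- stats::plogis(eta)
  event <- stats::rbinom(n, 1L, prob)

  onset_day <- rep(NA_integer_, n)
  onset_drug <- rep(NA_character_, n)
  for (lab in names(config$onset_model)) {
    om <- config$onset_model[[lab]]
    idx <- which(event == 1L & drugs[, lab] == 1L & is.na(onset_day))
    if (length(idx)) {
      d <- pmax(1, ceiling(stats::rweibull(length(idx), shape = om[["shape"]],
                                           scale = om[["scale"]])))
      onset_day[idx] <- as.integer(d)
      onset_drug[idx] <- lab
    }
  }

  m <- config$missingness
  missing <- data.frame(
    sex = stats::rbinom(n, 1L, m$sex) == 1L,
    age = stats::rbinom(n, 1L, m$age) == 1L,
    start_date = stats::rbinom(n, 1L, m$start_date) == 1L,
    onset_date = stats::rbinom(n, 1L, m$onset_date) == 1L)

  ds <- data.frame(case_id = sprintf("SYN%07d", seq_len(n)),
                   event = event,
                   sex_female = env$sex_female,
                   age_ge60 = env$age_ge60,
                   reporting_year = year,
                   stringsAsFactors = FALSE)
  ds <- cbind(ds, as.data.frame(drugs))
  if (ncol(cancers)) ds <- cbind(ds, as.data.frame(cancers))
  ds <- structure(ds, drug_labels = names(config$drug_panel),
                  cancer_labels = names(config$cancer_panel),
                  class = c("analysis_dataset", "data.frame"))

  list(dataset = ds, prob = prob, onset_day = onset_day,
       onset_drug = onset_drug, age_band = bands, missing = missing,
       coefficients = c("(Intercept)" = config$event_model$intercept,
                        config$event_model$coefficients))
}

#' Generate the four JADER-style tables with ground truth
#'
#' Renders the draw of [generate_dataset()] as demographics, drug, adverse
#' event and history tables: one suspected-drug row per exposure, one event
#' row per report (the case term for cases, a filler term otherwise), one
#' condition row per cancer indicator. For cases exposed to a drug of the
#' onset model, the event onset date equals that drug's start date plus the
#' Weibull-drawn day minus one. Missingness (blank sex, age or dates) is
#' applied last and never alters the ground truth.
#'
#' @param config A [synthetic_config()].
#' @return A list with `tables` (named list of `jader_table` data frames)
#'   and `truth` (the [generate_dataset()] result, row-aligned with the
#'   demographics table).
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  truth <- generate_dataset(config)
  ds <- truth$dataset
  n <- nrow(ds)
  y0 <- config$year_range[1L]
  year_start <- as.Date(paste0(ds$reporting_year, "-01-01"))

  demo <- data.frame(
    case_id = ds$case_id,
    revision = "1",
    sex = ifelse(truth$missing$sex, "",
                 ifelse(ds$sex_female == 1L, "female", "male")),
    age = ifelse(truth$missing$age, "", truth$age_band),
    reporting_year = as.character(ds$reporting_year),
    stringsAsFactors = FALSE)[, c("case_id", "sex", "age", "reporting_year",
                                  "revision")]

  # one suspected row per exposed drug; start dates uniform within the year,
  # except the onset drug of a case, whose start anchors the onset date
  drug_rows <- list()
  start_by_case <- rep(as.Date(NA), n)   # start date of the onset drug
  for (lab in names(config$drug_panel)) {
    idx <- which(ds[[lab]] == 1L)
    if (!length(idx)) next
    st <- year_start[idx] + sample(0:364, length(idx), replace = TRUE)
    anchor <- !is.na(truth$onset_drug[idx]) & truth$onset_drug[idx] == lab
    start_by_case[idx[anchor]] <- st[anchor]
    miss <- truth$missing$start_date[idx]
    drug_rows[[lab]] <- data.frame(
      case_id = ds$case_id[idx], drug_name = lab, involvement = "suspected",
      start_date = ifelse(miss, "", format(st, "%Y-%m-%d")),
      stringsAsFactors = FALSE)
  }
  if (config$concomitant_noise > 0) {
    idx <- which(stats::rbinom(n, 1L, config$concomitant_noise) == 1L)
    if (length(idx))
      drug_rows[["..noise"]] <- data.frame(
        case_id = ds$case_id[idx], drug_name = "acetaminophen",
        involvement = "concomitant",
        start_date = format(year_start[idx] +
                              sample(0:364, length(idx), replace = TRUE),
                            "%Y-%m-%d"),
        stringsAsFactors = FALSE)
  }
  drug <- if (length(drug_rows)) do.call(rbind, drug_rows)
  else data.frame(case_id = character(), drug_name = character(),
                  involvement = character(), start_date = character(),
                  stringsAsFactors = FALSE)
  drug <- drug[order(match(drug$case_id, ds$case_id)), , drop = FALSE]
  rownames(drug) <- NULL

  onset_date <- rep(as.Date(NA), n)
  anchored <- !is.na(truth$onset_day) & !is.na(start_by_case)
  onset_date[anchored] <- start_by_case[anchored] + truth$onset_day[anchored] - 1L
  free <- is.na(onset_date)
  onset_date[free] <- year_start[free] + sample(0:364, sum(free), replace = TRUE)

  term <- ifelse(ds$event == 1L, config$event_term,
                 sample(config$filler_terms, n, replace = TRUE))
  reac <- data.frame(
    case_id = ds$case_id, term = term,
    onset_date = ifelse(truth$missing$onset_date, "",
                        format(onset_date, "%Y-%m-%d")),
    outcome = "Recovered", stringsAsFactors = FALSE)

  hist_rows <- lapply(names(config$cancer_panel), function(lab) {
    idx <- which(ds[[lab]] == 1L)
    data.frame(case_id = ds$case_id[idx],
               condition = config$cancer_terms[[lab]],
               stringsAsFactors = FALSE)
  })
  hist <- if (length(hist_rows)) do.call(rbind, hist_rows)
  else data.frame(case_id = character(), condition = character(),
                  stringsAsFactors = FALSE)
  if (nrow(hist)) {
    hist <- hist[order(match(hist$case_id, ds$case_id)), , drop = FALSE]
    rownames(hist) <- NULL
  }

  tables <- list(demo = .as_jader_table(demo, "demo"),
                 drug = .as_jader_table(drug, "drug"),
                 reac = .as_jader_table(reac, "reac"),
                 hist = .as_jader_table(hist, "hist"))
  list(tables = tables, truth = truth)
}

#' Write generated tables to delimited files
#'
#' Emits the four tables in the given dialect (delimiter, encoding, header
#' names via the reverse column map), round-trip lossless through
#' [read_jader_table()].
#'
#' @param tables Named list of `jader_table`s from [generate_reports()].
#' @param directory Output directory (created if needed).
#' @param dialect A [table_dialect()].
#' @return Named character vector of the four file paths.
#' @export
write_tables <- function(tables, directory, dialect = table_dialect()) {
  stopifnot(all(.table_kinds %in% names(tables)))
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  paths <- character()
  for (kind in .table_kinds) {
    tab <- as.data.frame(tables[[kind]])
    map <- dialect$column_map[[kind]]
    header <- names(tab)
    if (!is.null(map)) {
      if (is.null(names(map))) names(map) <- map
      hit <- match(header, unname(map))
      header[!is.na(hit)] <- names(map)[hit[!is.na(hit)]]
    }
    path <- file.path(directory, paste0(kind, ".csv"))
    lines <- c(if (dialect$header)
                 paste(header, collapse = dialect$delimiter),
               do.call(paste, c(tab, sep = dialect$delimiter)))
    enc <- iconv(lines, from = "UTF-8", to = dialect$encoding)
    if (anyNA(enc))
      pv_error(paste0("cannot encode '", kind, "' table as ",
                      dialect$encoding), "pvsignal_encoding_error")
    con <- file(path, "wb")
    writeLines(enc, con, useBytes = TRUE)
    close(con)
    paths[[kind]] <- path
  }
  paths
}
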