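# Orchestration of the full study from one configuration: ingest -> cohort
# -> crude screens (drugs, cancer sites) -> adjusted model -> time-to-onset.

#' Read a run configuration from a YAML file
#'
#' The configuration names either the four input files (with a dialect) or a
#' synthetic-data block — exactly one of the two — plus the event term set,
#' the drug panel, the cancer panels, the model specification and the onset
#' settings. See `system.file("extdata", "example_config.yaml",
#' package = "pvsignal")` for a complete annotated example.
#'
#' @param path Path to a YAML file.
#' @return A validated run-configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A configuration list (as produced by parsing the YAML).
#' @export
as_run_config <- function(cfg) {
  has_files <- !is.null(cfg$tables)
  has_syn <- !is.null(cfg$synthetic)
  if (has_files == has_syn)
    pv_error("exactly one of 'tables' and 'synthetic' must be configured",
             "pvsignal_config_error")
  if (is.null(cfg$event_terms))
    pv_error("'event_terms' is required", "pvsignal_config_error")
  if (has_syn) {
    syn <- cfg$synthetic
    syn$n_reports <- syn$n_reports %||% 5000L
    syn$seed <- syn$seed %||% 1L
    known <- names(formals(synthetic_config))
    bad <- setdiff(names(syn), known)
    if (length(bad))
      pv_error(paste0("unknown synthetic option(s): ",
                      paste(bad, collapse = ", ")), "pvsignal_config_error")
    if (!is.null(syn$drug_panel)) syn$drug_panel <- unlist(syn$drug_panel)
    if (!is.null(syn$cancer_panel)) syn$cancer_panel <- unlist(syn$cancer_panel)
    if (!is.null(syn$onset_model))
      syn$onset_model <- lapply(syn$onset_model, unlist)
    if (!is.null(syn$event_model))
      syn$event_model$coefficients <- unlist(syn$event_model$coefficients)
    cfg$synthetic <- do.call(synthetic_config, syn)
  }
  if (is.null(cfg$drug_panel)) {
    if (!has_syn)
      pv_error("'drug_panel' is required with file input", "pvsignal_config_error")
    cfg$drug_panel <- stats::setNames(
      as.list(names(cfg$synthetic$drug_panel)),
      names(cfg$synthetic$drug_panel))
  }
  if (is.null(cfg$cancer_panels)) {
    cfg$cancer_panels <- if (has_syn)
      as.list(cfg$synthetic$cancer_terms) else list()
  }
  cfg$min_cases <- cfg$min_cases %||% 10L
  cfg$onset <- cfg$onset %||% list()
  cfg$onset$window_days <- cfg$onset$window_days %||% 365L
  structure(cfg, class = "run_config")
}

.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  list(value = value, seconds = proc.time()[["elapsed"]] - t0)
}

#' Run the full pharmacovigilance pipeline
#'
#' Executes the four analysis stages in order — ingestion and exclusions,
#' crude ROR screens of the drug panel and the cancer sites, the adjusted
#' logistic model, and the time-to-onset analysis — and writes the result
#' tables plus a machine-readable summary to `out_dir`. Stage counts are
#' logged to standard error; any stage error aborts with the stage name.
#'
#' Outputs written: `drug_screen.tsv`, `cancer_screen.tsv`,
#' `adjusted_ror.tsv`, `weibull_summary.tsv`, `onset_histogram.tsv`,
#' `summary.json` (all statistics), `run_report.json` (counts and per-stage
#' durations).
#'
#' @param config A `run_config` (from [read_run_config()] /
#'   [as_run_config()]) or a path to a YAML file.
#' @param out_dir Output directory, created if needed.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with all stage results and the run report.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  report <- list(stages = list())

  ingest <- .stage("ingest", {
    if (!is.null(config$synthetic)) {
      gen <- generate_reports(config$synthetic)
      tabs <- gen$tables
    } else {
      dialect <- switch(config$tables$dialect %||% "default",
                        default = table_dialect(), jader = jader_dialect())
      tabs <- list(
        demo = read_jader_table(config$tables$demo, "demo", dialect),
        drug = read_jader_table(config$tables$drug, "drug", dialect),
        reac = read_jader_table(config$tables$reac, "reac", dialect),
        hist = read_jader_table(config$tables$hist, "hist", dialect))
    }
    records <- merge_tables(tabs$demo, tabs$drug, tabs$reac, tabs$hist,
                            quiet = quiet)
    filter_valid(records)
  })
  records <- ingest$value
  report$n_reports <- n_reports(records) + attr(records, "n_excluded")
  report$n_excluded <- attr(records, "n_excluded")
  report$n_duplicates <- attr(records, "n_duplicates")
  report$n_orphans <- attr(records, "n_orphans")
  report$n_analyzed <- n_reports(records)
  say("ingest: ", report$n_reports, " reports, ", report$n_excluded,
      " excluded (unknown sex/age), ", report$n_analyzed, " analyzed")

  cohort <- .stage("cohort", {
    event_terms <- term_set("event", unlist(config$event_terms))
    drug_panel <- lapply(config$drug_panel, unlist)
    cancer_panels <- lapply(config$cancer_panels, unlist)
    build_dataset(records, event_terms, drug_panel, cancer_panels)
  })
  dataset <- cohort$value
  report$n_cases <- sum(dataset$event)
  say("cohort: ", report$n_cases, " cases / ", nrow(dataset), " reports")

  screens <- .stage("screen", {
    drug_screen <- screen_signals(dataset, drug_labels(dataset))
    cancer_screen <- if (length(cancer_labels(dataset)))
      screen_signals(dataset, cancer_labels(dataset)) else NULL
    list(drug = drug_screen, cancer = cancer_screen)
  })
  drug_screen <- screens$value$drug
  signal_drugs <- drug_screen$label[!is.na(drug_screen$signal) &
                                      drug_screen$signal]
  say("screen: ", length(signal_drugs), " drug signal(s): ",
      paste(signal_drugs, collapse = ", "))
  write_screen(drug_screen, file.path(out_dir, "drug_screen.tsv"))
  if (!is.null(screens$value$cancer))
    write_screen(screens$value$cancer, file.path(out_dir, "cancer_screen.tsv"))

  adjusted <- .stage("adjust", {
    spec <- .resolve_model_spec(config, dataset, signal_drugs)
    spec <- .drop_degenerate_interactions(spec, dataset, quiet)
    fit_adjusted(dataset, spec)
  })
  utils::write.table(as.data.frame(adjusted$value$table),
                     file.path(out_dir, "adjusted_ror.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  say("adjust: ", sum(adjusted$value$table$significant),
      " significant term(s)")

  onset <- .stage("tto", {
    lab <- config$onset$drug %||%
      (if (length(signal_drugs)) signal_drugs[[1L]] else
         drug_labels(dataset)[[1L]])
    sample <- extract_onsets(records, unlist(config$drug_panel[[lab]]),
                             term_set("event", unlist(config$event_terms)),
                             window_days = config$onset$window_days)
    fit <- fit_weibull(sample)
    list(label = lab, sample = sample, fit = fit,
         summary = empirical_summary(sample))
  })
  w <- onset$value
  say("tto: ", w$label, ", n = ", w$sample$n_in_window, ", shape ",
      round(w$fit$beta, 2), " (", w$fit$hazard_class, ")")
  utils::write.table(
    data.frame(drug = w$label, n_total = w$sample$n_total,
               n_complete = w$sample$n_complete,
               n_in_window = w$sample$n_in_window,
               alpha = w$fit$alpha, alpha_low = w$fit$alpha_ci[1L],
               alpha_high = w$fit$alpha_ci[2L], beta = w$fit$beta,
               beta_low = w$fit$beta_ci[1L], beta_high = w$fit$beta_ci[2L],
               median_model = w$fit$median_days,
               median_empirical = w$summary$median, q1 = w$summary$q1,
               q3 = w$summary$q3, hazard = w$fit$hazard_class),
    file.path(out_dir, "weibull_summary.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(onset_histogram(w$sample),
                     file.path(out_dir, "onset_histogram.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  report$stages <- list(ingest = ingest$seconds, cohort = cohort$seconds,
                        screen = screens$seconds, adjust = adjusted$seconds,
                        tto = onset$seconds)
  summary_obj <- list(
    counts = report[c("n_reports", "n_excluded", "n_duplicates", "n_orphans",
                      "n_analyzed", "n_cases")],
    drug_screen = as.data.frame(drug_screen),
    cancer_screen = if (!is.null(screens$value$cancer))
      as.data.frame(screens$value$cancer),
    adjusted = as.data.frame(adjusted$value$table),
    weibull = list(drug = w$label, n = w$sample$n_in_window,
                   alpha = w$fit$alpha, alpha_ci = w$fit$alpha_ci,
                   beta = w$fit$beta, beta_ci = w$fit$beta_ci,
                   median_model = w$fit$median_days,
                   median_empirical = w$summary$median,
                   iqr = c(w$summary$q1, w$summary$q3),
                   hazard_class = w$fit$hazard_class))
  jsonlite::write_json(summary_obj, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(records = records, dataset = dataset,
                 drug_screen = drug_screen,
                 cancer_screen = screens$value$cancer,
                 adjusted = adjusted$value, onset = w, report = report))
}

.resolve_model_spec <- function(config, dataset, signal_drugs) {
  if (!is.null(config$model)) {
    main <- unlist(config$model$main)
    inter <- config$model$interactions %||% list()
    return(model_spec(main, inter,
                      alpha_main = config$model$alpha_main %||% 0.05,
                      alpha_interaction = config$model$alpha_interaction %||% 0.10))
  }
  # default: covariates + all cancer sites + drugs with crude signals, and
  # signal-drug x {sex, age, cancer} interactions
  drugs <- if (length(signal_drugs)) signal_drugs else drug_labels(dataset)[1L]
  main <- c("reporting_year", "sex_female", "age_ge60",
            cancer_labels(dataset), drugs)
  inter <- list()
  for (d in drugs)
    for (o in c("sex_female", "age_ge60", cancer_labels(dataset)))
      inter[[length(inter) + 1L]] <- c(d, o)
  model_spec(main, inter)
}

.drop_degenerate_interactions <- function(spec, dataset, quiet = FALSE) {
  keep <- vapply(spec$interactions, function(p) {
    v <- dataset[[p[1L]]] * dataset[[p[2L]]]
    length(unique(v)) > 1L
  }, logical(1))
  if (any(!keep) && !quiet)
    message("dropping ", sum(!keep), " degenerate interaction term(s): ",
            paste(vapply(spec$interactions[!keep], .interaction_label,
                         character(1)), collapse = ", "))
  spec$interactions <- spec$interactions[keep]
  spec
}
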