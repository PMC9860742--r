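# Time-to-onset analysis: extraction of day counts for a (drug, event)
# pair, Weibull maximum likelihood with Wald intervals on the log-parameter
# scale, and hazard-shape classification from the shape parameter.

#' Extract time-to-onset days for a drug-event pair
#'
#' For every report with suspected exposure to one of `drug_names` and a
#' matching event, the onset day is the difference between the event onset
#' date and the earliest suspected-drug start date, plus one — day 1 means
#' onset on the day treatment started. Reports missing either date count
#' toward `n_total` only; complete pairs whose day falls outside
#' `[1, window_days]` count toward `n_complete` but are excluded from the
#' analyzed sample.
#'
#' @param records A `report_set`.
#' @param drug_names Character vector of drug names defining the exposure.
#' @param event_terms A [term_set()] (or character vector) defining the
#'   event.
#' @param window_days Analysis window after treatment start (default 365).
#' @param synonyms Optional drug-name synonym map.
#' @return An object of class `onset_sample`: `days` (integer vector),
#'   `window_days`, `n_total`, `n_complete`, `n_in_window`.
#' @export
extract_onsets <- function(records, drug_names, event_terms,
                           window_days = 365L, synonyms = NULL) {
  stopifnot(inherits(records, "report_set"), window_days >= 1)
  ts <- .as_term_set(event_terms, "event")
  wanted <- normalize_drug(drug_names, synonyms)

  d <- records$drugs
  d <- d[d$involvement == "suspected" &
           normalize_drug(d$drug_name, synonyms) %in% wanted, , drop = FALSE]
  e <- records$events
  e <- e[.match_terms(e$term, ts), , drop = FALSE]

  pair_ids <- intersect(unique(d$case_id), unique(e$case_id))
  n_total <- length(pair_ids)
  if (!n_total)
    return(structure(list(days = integer(), window_days = window_days,
                          n_total = 0L, n_complete = 0L, n_in_window = 0L),
                     class = "onset_sample"))

  # earliest suspected start date and earliest matching onset date per case
  min_by <- function(df, col) {
    v <- tapply(as.numeric(df[[col]]), df$case_id, min, na.rm = FALSE)
    # tapply with na.rm=FALSE propagates NA only via min(); min(c(NA,1)) is NA,
    # but a case is "complete" if ANY dated row exists -> use custom reducer
    v
  }
  safe_min <- function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
  start <- tapply(as.numeric(d$start_date), d$case_id, safe_min)[pair_ids]
  onset <- tapply(as.numeric(e$onset_date), e$case_id, safe_min)[pair_ids]

  complete <- !is.na(start) & !is.na(onset)
  day <- as.integer(onset[complete] - start[complete]) + 1L
  in_window <- day >= 1L & day <= window_days
  structure(list(days = day[in_window], window_days = as.integer(window_days),
                 n_total = n_total, n_complete = sum(complete),
                 n_in_window = sum(in_window)),
            class = "onset_sample")
}

#' @export
print.onset_sample <- function(x, ...) {
  cat("onset_sample:", x$n_total, "reports with the pair;", x$n_complete,
      "with both dates;", x$n_in_window, "within", x$window_days, "days\n")
  invisible(x)
}

#' Median of a Weibull distribution
#'
#' @param alpha Scale parameter (days), > 0.
#' @param beta Shape parameter, > 0.
#' @return `alpha * log(2)^(1/beta)`.
#' @examples
#' weibull_median(10.38, 0.98)  # about 7.1 days
#' @export
weibull_median <- function(alpha, beta) {
  stopifnot(alpha > 0, beta > 0)
  alpha * log(2)^(1 / beta)
}

#' Fit a Weibull distribution to onset days by maximum likelihood
#'
#' Maximizes the Weibull log-likelihood in the scale alpha and shape beta,
#' parameterized on the log scale for stable optimization and Wald
#' intervals (intervals are computed on log(alpha), log(beta) from the
#' observed information and transformed back, so they respect positivity).
#' With `truncated = TRUE` the density is renormalized by the distribution
#' function at the analysis window, i.e. a right-truncated likelihood.
#'
#' @param sample An `onset_sample`, or a numeric vector of positive times.
#' @param truncated Use the right-truncated likelihood (default `FALSE`,
#'   matching the common practice of fitting the unconditional density to
#'   the in-window sample).
#' @param window_days Window for the truncated likelihood when `sample` is a
#'   bare numeric vector.
#' @param min_n Minimum sample size (default 10).
#' @return An object of class `weibull_fit`: `alpha`, `beta`, `alpha_ci`,
#'   `beta_ci`, `median_days`, `iqr_days` (empirical quartiles), `hazard_class`,
#'   `n`, `log_likelihood`, `converged`.
#' @export
fit_weibull <- function(sample, truncated = FALSE, window_days = 365L,
                        min_n = 10L) {
  if (inherits(sample, "onset_sample")) {
    t <- as.numeric(sample$days)
    window_days <- sample$window_days
  } else t <- as.numeric(sample)
  if (length(t) < min_n)
    pv_error(paste0("insufficient sample: ", length(t), " onset times (< ",
                    min_n, ")"), "pvsignal_insufficient_sample")
  if (any(t <= 0)) pv_error("onset times must be positive",
                            "pvsignal_value_error")
  if (length(unique(t)) == 1L)
    pv_error("degenerate sample: all onset times equal",
             "pvsignal_degenerate_sample")

  nll <- function(par) {
    if (any(!is.finite(par)) || any(abs(par) > 30)) return(1e10)
    a <- exp(par[1L]); b <- exp(par[2L])
    ll <- suppressWarnings(sum(stats::dweibull(t, shape = b, scale = a,
                                               log = TRUE)))
    if (truncated)
      ll <- ll - length(t) *
        log(stats::pweibull(window_days, shape = b, scale = a))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  init <- c(log(mean(t)), 0)
  opt <- stats::optim(init, nll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  se <- tryCatch(sqrt(diag(solve(opt$hessian))),
                 error = function(e) rep(NA_real_, 2))
  a <- exp(opt$par[1L]); b <- exp(opt$par[2L])
  aci <- exp(opt$par[1L] + c(-1, 1) * 1.96 * se[1L])
  bci <- exp(opt$par[2L] + c(-1, 1) * 1.96 * se[2L])
  q <- stats::quantile(t, c(0.25, 0.5, 0.75), type = 7, names = FALSE)

  fit <- structure(list(alpha = a, beta = b,
                        alpha_ci = aci, beta_ci = bci,
                        median_days = weibull_median(a, b),
                        iqr_days = c(q1 = q[1L], q3 = q[3L]),
                        n = length(t),
                        log_likelihood = -opt$value,
                        converged = opt$convergence == 0L),
                   class = "weibull_fit")
  fit$hazard_class <- classify_hazard(fit)
  fit
}

#' Classify the hazard trend from the Weibull shape parameter
#'
#' The hazard of a Weibull distribution rises with time when beta > 1 and
#' falls when beta < 1; beta = 1 is the constant-hazard (exponential) case.
#' The classification demands that the 95% CI of beta excludes 1:
#' `"increasing"` if the lower bound exceeds 1, `"decreasing"` if the upper
#' bound is below 1, otherwise `"constant-compatible"`.
#'
#' @param fit A `weibull_fit` (or any list with a `beta_ci` element).
#' @return One of `"increasing"`, `"decreasing"`, `"constant-compatible"`.
#' @export
classify_hazard <- function(fit) {
  ci <- fit$beta_ci
  stopifnot(length(ci) == 2L)
  if (!anyNA(ci)) {
    if (ci[1L] > 1) return("increasing")
    if (ci[2L] < 1) return("decreasing")
  }
  "constant-compatible"
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("Weibull fit (n = %d): scale %.2f (95%% CI %.2f-%.2f), shape %.2f (95%% CI %.2f-%.2f)\n",
              x$n, x$alpha, x$alpha_ci[1L], x$alpha_ci[2L],
              x$beta, x$beta_ci[1L], x$beta_ci[2L]))
  cat(sprintf("  model median %.2f days; empirical IQR %.1f-%.1f; hazard %s\n",
              x$median_days, x$iqr_days[1L], x$iqr_days[2L], x$hazard_class))
  invisible(x)
}

#' Empirical summary of an onset sample
#'
#' @param sample An `onset_sample` with at least one in-window day.
#' @param cut_days Cut point for the cumulative fraction (e.g. 10 days).
#' @return A list with `median`, `q1`, `q3` (linear-interpolation quantiles)
#'   and `fraction_within_cut`.
#' @export
empirical_summary <- function(sample, cut_days = 10L) {
  stopifnot(inherits(sample, "onset_sample"))
  if (sample$n_in_window < 1L)
    pv_error("no onset days within the window", "pvsignal_insufficient_sample")
  t <- sample$days
  q <- stats::quantile(t, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2L], q1 = q[1L], q3 = q[3L],
       fraction_within_cut = mean(t <= cut_days))
}

#' Day-by-day onset histogram
#'
#' Counts onsets per day over the whole analysis window, for bar-chart
#' output.
#'
#' @param sample An `onset_sample`.
#' @return A data frame with columns `day` (1..window) and `count`.
#' @export
onset_histogram <- function(sample) {
  stopifnot(inherits(sample, "onset_sample"))
  data.frame(day = seq_len(sample$window_days),
             count = tabulate(sample$days, nbins = sample$window_days))
}
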