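# Crude disproportionality analysis: 2x2 contingency tables, reporting odds
# ratios with Wald confidence intervals, Fisher's exact test, signal flags.

#' Construct a 2x2 case/non-case contingency table
#'
#' The four cells follow the case/non-case convention of disproportionality
#' analysis: `a` exposed cases, `b` exposed non-cases, `c` unexposed cases,
#' `d` unexposed non-cases.
#'
#' @param a,b,c,d Non-negative counts; the total must be positive.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0))
    pv_error("contingency cells must be non-negative counts",
             "pvsignal_value_error")
  if (sum(cells) <= 0)
    pv_error("contingency table is empty", "pvsignal_value_error")
  structure(as.list(cells), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c("exposed", "unexposed"),
                              c("case", "non-case")))
  print(m)
  invisible(x)
}

#' Contingency table from published marginal counts
#'
#' Reconstructs the 2x2 table from the marginals usually printed in
#' disproportionality tables: the number of reports mentioning the exposure,
#' the cases among them, the database total, and the total cases.
#'
#' @param exposed_total Reports with the exposure (`a + b`).
#' @param exposed_cases Cases with the exposure (`a`).
#' @param overall_total All reports (`a + b + c + d`).
#' @param overall_cases All cases (`a + c`).
#' @return A `contingency_table`.
#' @examples
#' contingency_from_margins(11468, 221, 595121, 2943)  # cisplatin row
#' @export
contingency_from_margins <- function(exposed_total, exposed_cases,
                                     overall_total, overall_cases) {
  a <- exposed_cases
  b <- exposed_total - exposed_cases
  c <- overall_cases - exposed_cases
  d <- overall_total - exposed_total - c
  contingency_table(a, b, c, d)
}

#' Cross-tabulate an exposure indicator against the event
#'
#' @param dataset An `analysis_dataset`.
#' @param label Name of an indicator column (drug or cancer label).
#' @return A `contingency_table`.
#' @export
contingency <- function(dataset, label) {
  stopifnot(inherits(dataset, "analysis_dataset"))
  if (!label %in% names(dataset))
    pv_error(paste0("unknown exposure label: '", label, "'"),
             "pvsignal_value_error")
  e <- dataset[[label]]; y <- dataset$event
  contingency_table(sum(e == 1L & y == 1L), sum(e == 1L & y == 0L),
                    sum(e == 0L & y == 1L), sum(e == 0L & y == 0L))
}

#' Crude reporting odds ratio with Wald 95% confidence interval
#'
#' Computes ROR = (a/b)/(c/d) with the Wald interval
#' exp(ln ROR ± 1.96 sqrt(1/a + 1/b + 1/c + 1/d)). When any cell is zero the
#' Haldane–Anscombe correction (+0.5 on all four cells) is applied first and
#' the result is flagged `corrected`; set `zero_cells = "error"` to refuse
#' such tables instead.
#'
#' @param table A `contingency_table`.
#' @param zero_cells `"correct"` (default) or `"error"`.
#' @return A list of class `ror_estimate` with elements `ror`, `ci_low`,
#'   `ci_high`, `corrected`.
#' @examples
#' crude_ror(contingency_from_margins(11468, 221, 595121, 2943))
#' @export
crude_ror <- function(table, zero_cells = c("correct", "error")) {
  stopifnot(inherits(table, "contingency_table"))
  zero_cells <- match.arg(zero_cells)
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  if ((a + b) == 0 || (c + d) == 0)
    pv_error("undefined exposure: an exposure row of the table is empty",
             "pvsignal_undefined_exposure")
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) {
    if (zero_cells == "error")
      pv_error("zero cell in contingency table", "pvsignal_value_error")
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  structure(list(ror = ror,
                 ci_low = exp(log(ror) - 1.96 * se),
                 ci_high = exp(log(ror) + 1.96 * se),
                 corrected = corrected),
            class = "ror_estimate")
}

#' @export
print.ror_estimate <- function(x, digits = 2, ...) {
  cat(sprintf("ROR %.*f (95%% CI %.*f-%.*f)%s\n", digits, x$ror,
              digits, x$ci_low, digits, x$ci_high,
              if (x$corrected) " [continuity-corrected]" else ""))
  invisible(x)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The two-sided p-value sums the hypergeometric probabilities, at fixed
#' margins, of every table no more probable than the observed one (with a
#' small relative tolerance guarding ties in floating point).
#'
#' @param table A `contingency_table`.
#' @return The two-sided p-value in (0, 1].
#' @export
fisher_exact <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  m <- matrix(c(table$a, table$c, table$b, table$d), 2)
  stats::fisher.test(m)$p.value
}

#' Screen exposures for disproportionality signals
#'
#' Runs the crude ROR analysis for each label: the 2x2 table, the case ratio
#' a/(a+b) in percent, ROR with 95% CI, Fisher's exact p, and the signal
#' flag (CI lower bound above 1). Rows are sorted by descending case ratio.
#' Labels whose table has an empty exposure row yield a warning and an
#' all-`NA` row rather than aborting the screen.
#'
#' @param x An `analysis_dataset`, or a named list of `contingency_table`s
#'   (e.g. reconstructed from published marginals).
#' @param labels Indicator columns to screen; defaults to all drug labels of
#'   the dataset. Ignored for the list method.
#' @param ... Passed on to [crude_ror()].
#' @return A data frame of class `signal_screen` with columns `label`,
#'   `total`, `case`, `noncase`, `ratio_pct`, `ror`, `ci_low`, `ci_high`,
#'   `p_fisher`, `signal`, `corrected`.
#' @export
screen_signals <- function(x, labels = NULL, ...) UseMethod("screen_signals")

#' @rdname screen_signals
#' @export
screen_signals.analysis_dataset <- function(x, labels = NULL, ...) {
  if (is.null(labels)) labels <- drug_labels(x)
  tabs <- lapply(labels, function(l) contingency(x, l))
  names(tabs) <- labels
  screen_signals(tabs, ...)
}

#' @rdname screen_signals
#' @export
screen_signals.list <- function(x, labels = NULL, ...) {
  stopifnot(length(x) > 0, !is.null(names(x)))
  rows <- lapply(names(x), function(l) {
    tab <- x[[l]]
    base <- data.frame(label = l, total = tab$a + tab$b, case = tab$a,
                       noncase = tab$b,
                       ratio_pct = if (tab$a + tab$b > 0)
                         100 * tab$a / (tab$a + tab$b) else NA_real_,
                       stringsAsFactors = FALSE)
    est <- tryCatch(crude_ror(tab, ...), pvsignal_undefined_exposure = function(e) e)
    if (inherits(est, "error")) {
      warning("screen_signals: '", l, "': ", conditionMessage(est), call. = FALSE)
      cbind(base, ror = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
            p_fisher = NA_real_, signal = NA, corrected = NA)
    } else {
      cbind(base, ror = est$ror, ci_low = est$ci_low, ci_high = est$ci_high,
            p_fisher = fisher_exact(tab), signal = est$ci_low > 1,
            corrected = est$corrected)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$ratio_pct, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("signal_screen", "data.frame"))
}

#' @export
print.signal_screen <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  for (col in c("ratio_pct", "ror", "ci_low", "ci_high"))
    y[[col]] <- round(y[[col]], digits)
  y$p_fisher <- ifelse(is.na(y$p_fisher), NA,
                       ifelse(y$p_fisher < 0.001, "<0.001",
                              sprintf("%.2f", y$p_fisher)))
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write a signal screen as a tab-separated table
#'
#' @param screen A `signal_screen`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_screen <- function(screen, path) {
  stopifnot(inherits(screen, "signal_screen"))
  utils::write.table(as.data.frame(screen), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
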