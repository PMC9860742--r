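# Adjusted reporting odds ratios: multivariate logistic model with
# interaction terms, fitted by iteratively reweighted least squares with
# step-halving; Wald inference throughout.

#' Specify the adjusted logistic model
#'
#' Declares the main-effect terms (covariates and indicator labels of the
#' analysis dataset) and the interaction pairs entering the model
#' log odds(case) = b0 + sum(b_j x_j) + sum(b_jk x_j x_k). Reference
#' categories are the absence of each indicator: male sex, age 0-59, no
#' exposure, no cancer at that site. The reporting year enters as an integer
#' offset from the earliest year in the data, which affects only the
#' intercept.
#'
#' @param main_terms Ordered character vector of column names, drawn from
#'   `reporting_year`, `sex_female`, `age_ge60` and the drug/cancer labels.
#' @param interactions List of length-2 character vectors; both members must
#'   appear in `main_terms`.
#' @param alpha_main Significance level for main effects (default 0.05).
#' @param alpha_interaction Significance level for interactions (default
#'   0.10).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(main_terms, interactions = list(),
                       alpha_main = 0.05, alpha_interaction = 0.10) {
  stopifnot(is.character(main_terms), length(main_terms) > 0)
  interactions <- lapply(interactions, function(p) {
    if (is.character(p) && length(p) == 1L && grepl(":", p))
      p <- strsplit(p, ":", fixed = TRUE)[[1L]]
    if (!is.character(p) || length(p) != 2L)
      pv_error("each interaction must be a pair of term names",
               "pvsignal_config_error")
    bad <- setdiff(p, main_terms)
    if (length(bad))
      pv_error(paste0("interaction references undeclared main term: ",
                      paste(bad, collapse = ", ")), "pvsignal_config_error")
    p
  })
  structure(list(main_terms = main_terms, interactions = interactions,
                 alpha_main = alpha_main,
                 alpha_interaction = alpha_interaction),
            class = "model_spec")
}

.interaction_label <- function(pair) paste(pair, collapse = ":")

#' Build the design matrix for the adjusted model
#'
#' Produces the intercept column, one column per main term (the reporting
#' year centered at its minimum; all other terms as 0/1 indicators), and one
#' elementwise-product column per interaction, in specification order.
#' Any non-intercept column that is constant across rows is degenerate (its
#' coefficient would be unidentifiable) and raises an error naming the term.
#'
#' @param dataset An `analysis_dataset`.
#' @param spec A [model_spec()].
#' @return A list with the matrix `X`, the response `y`, and `labels`.
#' @export
design_matrix <- function(dataset, spec) {
  stopifnot(inherits(dataset, "analysis_dataset"), inherits(spec, "model_spec"))
  bad <- setdiff(spec$main_terms, names(dataset))
  if (length(bad))
    pv_error(paste0("model term not in dataset: ", paste(bad, collapse = ", ")),
             "pvsignal_value_error")
  n <- nrow(dataset)
  cols <- list(`(Intercept)` = rep(1, n))
  for (tm in spec$main_terms) {
    v <- dataset[[tm]]
    if (tm == "reporting_year") {
      if (anyNA(v)) pv_error("missing reporting_year in dataset",
                             "pvsignal_value_error")
      v <- as.numeric(v - min(v))
    } else v <- as.numeric(v)
    cols[[tm]] <- v
  }
  for (p in spec$interactions)
    cols[[.interaction_label(p)]] <- cols[[p[1L]]] * cols[[p[2L]]]
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  const <- vapply(seq_len(ncol(X))[-1L],
                  function(j) length(unique(X[, j])) == 1L, logical(1))
  if (any(const))
    pv_error(paste0("degenerate (constant) model column: ",
                    paste(colnames(X)[-1L][const], collapse = ", ")),
             "pvsignal_degenerate_column")
  list(X = X, y = as.numeric(dataset$event), labels = colnames(X))
}

.logistic_ll <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

#' Fit a logistic regression by maximum likelihood
#'
#' Newton-Raphson / iteratively reweighted least squares with step-halving
#' on the Bernoulli log-likelihood. Convergence is declared when the
#' gradient max-norm falls below `grad_tol` or the relative change in
#' log-likelihood falls below `ll_tol`. Standard errors come from the
#' inverse observed information at the optimum; confidence intervals and
#' p-values are Wald. The exponentiated coefficients are the adjusted
#' reporting odds ratios.
#'
#' @param X Design matrix including an intercept column (see
#'   [design_matrix()]).
#' @param y 0/1 response vector.
#' @param max_iter Iteration cap (default 100).
#' @param grad_tol Gradient max-norm tolerance (default 1e-8).
#' @param ll_tol Relative log-likelihood change tolerance (default 1e-10).
#' @return An object of class `logistic_fit`: named `coefficients`,
#'   `standard_errors`, `adjusted_ror`, `ci` (matrix with columns low/high),
#'   `p_values`, `converged`, `n_iterations`, `log_likelihood`, `n`.
#' @export
fit_logistic <- function(X, y, max_iter = 100L, grad_tol = 1e-8,
                         ll_tol = 1e-10) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (nrow(X) <= ncol(X))
    pv_error("more model columns than observations", "pvsignal_value_error")

  p <- ncol(X)
  beta <- rep(0, p)
  ll <- .logistic_ll(beta, X, y)
  converged <- FALSE
  iter <- 0L
  grad <- crossprod(X, y - stats::plogis(drop(X %*% beta)))

  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- stats::plogis(drop(X %*% beta))
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- drop(X %*% beta) + (y - mu) / w
    beta_new <- tryCatch(qr.coef(qr(X * sqrt(w)), z * sqrt(w)),
                         error = function(e)
                           pv_error("singular information matrix",
                                    "pvsignal_value_error"))
    if (anyNA(beta_new))
      pv_error(paste0("singular information matrix; aliased column: ",
                      paste(colnames(X)[is.na(beta_new)], collapse = ", ")),
               "pvsignal_value_error")
    # step-halving: never accept a step that decreases the likelihood
    step <- beta_new - beta
    ll_new <- .logistic_ll(beta + step, X, y)
    h <- 0L
    while (ll_new < ll && h < 30L) {
      step <- step / 2
      ll_new <- .logistic_ll(beta + step, X, y)
      h <- h + 1L
    }
    beta <- beta + step
    # a coefficient drifting past 15 on the log-odds scale (OR > 3e6) marks
    # a separated or quasi-separated term: the MLE is diverging
    if (any(abs(beta) > 15))
      pv_error(paste0("apparent complete separation on term: ",
                      colnames(X)[which.max(abs(beta))]),
               "pvsignal_separation_error")
    grad <- crossprod(X, y - stats::plogis(drop(X %*% beta)))
    rel <- abs(ll_new - ll) / (abs(ll) + 1e-12)
    ll <- ll_new
    if (max(abs(grad)) < grad_tol || rel < ll_tol) { converged <- TRUE; break }
  }

  if (!converged)
    pv_error(paste0("logistic fit did not converge in ", max_iter,
                    " iterations"), "pvsignal_nonconvergence_error")

  mu <- stats::plogis(drop(X %*% beta))
  info <- crossprod(X * sqrt(mu * (1 - mu)))
  se <- sqrt(diag(solve(info)))
  names(beta) <- names(se) <- colnames(X)
  z <- beta / se
  ci <- cbind(low = exp(beta - 1.96 * se), high = exp(beta + 1.96 * se))
  structure(list(coefficients = beta, standard_errors = se,
                 adjusted_ror = exp(beta), ci = ci,
                 p_values = 2 * stats::pnorm(-abs(z)),
                 converged = converged, n_iterations = iter,
                 log_likelihood = ll, n = nrow(X)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("logistic fit:", length(x$coefficients), "terms, n =", x$n,
      "| logLik", format(x$log_likelihood), "|", x$n_iterations,
      "iterations\n")
  print(round(cbind(beta = x$coefficients, se = x$standard_errors,
                    ROR = x$adjusted_ror, x$ci, p = x$p_values), 4))
  invisible(x)
}

#' Adjusted-ROR summary table for a fitted model
#'
#' One row per term with the adjusted ROR exp(beta), its Wald 95% CI and
#' p-value, and a significance flag: main effects are flagged at
#' `alpha_main`, interaction terms at the more permissive
#' `alpha_interaction` (both thresholds inclusive).
#'
#' @param fit A converged `logistic_fit`.
#' @param spec The [model_spec()] used to build the design matrix.
#' @return A data frame of class `adjusted_table` with columns `term`,
#'   `type`, `coef`, `se`, `ror`, `ci_low`, `ci_high`, `p`, `significant`.
#' @export
summarize_fit <- function(fit, spec) {
  stopifnot(inherits(fit, "logistic_fit"), inherits(spec, "model_spec"))
  if (!fit$converged) pv_error("fit did not converge", "pvsignal_value_error")
  terms <- names(fit$coefficients)
  inter_labels <- vapply(spec$interactions, .interaction_label, character(1))
  type <- ifelse(terms == "(Intercept)", "intercept",
                 ifelse(terms %in% inter_labels, "interaction", "main"))
  alpha <- ifelse(type == "interaction", spec$alpha_interaction,
                  spec$alpha_main)
  out <- data.frame(term = terms, type = type,
                    coef = unname(fit$coefficients),
                    se = unname(fit$standard_errors),
                    ror = unname(fit$adjusted_ror),
                    ci_low = unname(fit$ci[, "low"]),
                    ci_high = unname(fit$ci[, "high"]),
                    p = unname(fit$p_values),
                    stringsAsFactors = FALSE)
  out$significant <- type != "intercept" & out$p <= alpha
  structure(out, class = c("adjusted_table", "data.frame"))
}

#' Fit the adjusted model on an analysis dataset
#'
#' Convenience wrapper: [design_matrix()] then [fit_logistic()] then
#' [summarize_fit()].
#'
#' @inheritParams design_matrix
#' @param ... Passed to [fit_logistic()].
#' @return A list with elements `fit` (`logistic_fit`) and `table`
#'   (`adjusted_table`).
#' @export
fit_adjusted <- function(dataset, spec, ...) {
  dm <- design_matrix(dataset, spec)
  fit <- fit_logistic(dm$X, dm$y, ...)
  list(fit = fit, table = summarize_fit(fit, spec))
}
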