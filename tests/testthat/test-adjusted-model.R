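test_that("the design matrix follows the specification order and coding", {
  ds <- structure(
    data.frame(case_id = c("A", "B"), event = c(1L, 0L),
               sex_female = c(1L, 0L), age_ge60 = c(0L, 1L),
               reporting_year = c(2010L, 2015L), drugA = c(1L, 0L)),
    drug_labels = "drugA", cancer_labels = character(),
    class = c("analysis_dataset", "data.frame"))
  dm <- design_matrix(ds, model_spec("sex_female"))
  expect_equal(unname(dm$X), cbind(c(1, 1), c(1, 0)))
  expect_equal(dm$labels, c("(Intercept)", "sex_female"))

  dm2 <- design_matrix(ds, model_spec(c("reporting_year", "sex_female",
                                        "drugA"),
                                      list(c("sex_female", "drugA"))))
  expect_equal(dm2$X[, "reporting_year"], c(0, 5))   # centered at the minimum
  expect_equal(dm2$X[, "sex_female:drugA"],
               dm2$X[, "sex_female"] * dm2$X[, "drugA"])
  expect_equal(dm2$labels[5L], "sex_female:drugA")
})

test_that("a constant model column is rejected with the term named", {
  ds <- structure(
    data.frame(case_id = c("A", "B", "C"), event = c(1L, 0L, 1L),
               sex_female = c(1L, 0L, 1L), age_ge60 = 0L,
               reporting_year = 2010L, drugA = c(0L, 0L, 0L)),
    drug_labels = "drugA", cancer_labels = character(),
    class = c("analysis_dataset", "data.frame"))
  err <- expect_error(design_matrix(ds, model_spec(c("sex_female", "drugA"))),
                      "drugA")
  expect_s3_class(err, "pvsignal_degenerate_column")
  # an interaction with an all-zero factor is forced constant by the product
  ds$drugA <- c(1L, 1L, 1L)
  ds$age_ge60 <- c(1L, 0L, 1L)
  expect_error(design_matrix(ds, model_spec(c("age_ge60", "drugA"))),
               "drugA")
})

test_that("interaction pairs must reference declared main terms", {
  expect_error(model_spec("sex_female", list(c("sex_female", "drugA"))),
               "drugA")
})

test_that("the maximum-likelihood fit agrees with an independent IRLS implementation", {
  g <- generate_dataset(recovery_config(31L, n = 20000L))
  dm <- design_matrix(g$dataset, recovery_spec())
  fit <- fit_logistic(dm$X, dm$y)
  ref <- suppressWarnings(stats::glm.fit(dm$X, dm$y,
                                         family = stats::binomial()))
  expect_equal(unname(fit$coefficients), unname(ref$coefficients),
               tolerance = 1e-7)
  p <- ncol(dm$X)
  ref_se <- sqrt(diag(chol2inv(ref$qr$qr[1:p, 1:p, drop = FALSE])))
  expect_equal(unname(fit$standard_errors), ref_se, tolerance = 1e-3)
  expect_true(fit$converged)
  expect_true(all(fit$adjusted_ror > fit$ci[, "low"] &
                    fit$adjusted_ror < fit$ci[, "high"]))
})

test_that("with a single binary covariate the adjusted ROR equals the crude odds ratio", {
  g <- generate_dataset(recovery_config(8L, n = 30000L))
  ds <- g$dataset
  fit <- fit_logistic(design_matrix(ds, model_spec("drugA"))$X, ds$event)
  tab <- contingency(ds, "drugA")
  crude <- (tab$a * tab$d) / (tab$b * tab$c)
  expect_equal(fit$adjusted_ror[["drugA"]], crude, tolerance = 1e-9)
})

test_that("null data yield near-unit adjusted RORs for every covariate", {
  cfg <- synthetic_config(
    n_reports = 20000L, seed = 5L,
    drug_panel = c(drugA = 0.3), cancer_panel = c(lung = 0.3),
    event_model = list(intercept = stats::qlogis(0.3), coefficients = c()),
    onset_model = list(),
    missingness = list(sex = 0, age = 0, start_date = 0, onset_date = 0))
  g <- generate_dataset(cfg)
  spec <- model_spec(c("sex_female", "age_ge60", "lung", "drugA"))
  res <- fit_adjusted(g$dataset, spec)
  rors <- res$fit$adjusted_ror[-1L]
  expect_true(all(rors > 0.9 & rors < 1.1))
})

test_that("the fitted likelihood is a local maximum above the null start", {
  g <- generate_dataset(recovery_config(12L, n = 20000L))
  dm <- design_matrix(g$dataset, recovery_spec())
  fit <- fit_logistic(dm$X, dm$y)
  ll <- function(b) sum(dm$y * (dm$X %*% b) - log1p(exp(dm$X %*% b)))
  expect_gt(fit$log_likelihood, ll(rep(0, ncol(dm$X))))
  set.seed(2)
  for (i in 1:5) {
    perturbed <- fit$coefficients + stats::rnorm(ncol(dm$X), sd = 0.05)
    expect_gt(fit$log_likelihood, ll(perturbed))
  }
})

test_that("row order does not affect the estimates", {
  g <- generate_dataset(recovery_config(3L, n = 20000L))
  dm <- design_matrix(g$dataset, recovery_spec())
  fit1 <- fit_logistic(dm$X, dm$y)
  set.seed(99)
  perm <- sample(nrow(dm$X))
  fit2 <- fit_logistic(dm$X[perm, ], dm$y[perm])
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-10)
})

test_that("estimator bias shrinks as the sample grows", {
  bias_at <- function(n, seeds) {
    mean(vapply(seeds, function(s) {
      g <- generate_dataset(recovery_config(s, n = n))
      dm <- design_matrix(g$dataset, recovery_spec())
      abs(fit_logistic(dm$X, dm$y)$coefficients[["drugA"]] - log(4))
    }, numeric(1)))
  }
  expect_lt(bias_at(200000L, 301:305), bias_at(20000L, 301:305))
})

test_that("perfect separation is detected and named", {
  x <- c(rep(0, 30), rep(1, 30))
  X <- cbind("(Intercept)" = 1, sepvar = x)
  err <- expect_error(fit_logistic(X, x), "sepvar")
  expect_s3_class(err, "pvsignal_separation_error")
})

test_that("significance flags use the main and interaction thresholds", {
  spec <- model_spec(c("sex_female", "drugA"), list(c("sex_female", "drugA")))
  fake <- structure(list(
    coefficients = c("(Intercept)" = -2, sex_female = 0.1, drugA = 0.2,
                     "sex_female:drugA" = 0.3),
    standard_errors = c(0.1, 0.05, 0.1, 0.15),
    adjusted_ror = exp(c(-2, 0.1, 0.2, 0.3)),
    ci = cbind(low = rep(0.5, 4), high = rep(2, 4)),
    p_values = c("(Intercept)" = 0.001, sex_female = 0.051, drugA = 0.04,
                 "sex_female:drugA" = 0.051),
    converged = TRUE, n_iterations = 5L, log_likelihood = -10, n = 100L),
    class = "logistic_fit")
  tab <- summarize_fit(fake, spec)
  expect_false(tab$significant[tab$term == "sex_female"])        # 0.051 > 0.05
  expect_true(tab$significant[tab$term == "sex_female:drugA"])   # 0.051 <= 0.10
  expect_true(tab$significant[tab$term == "drugA"])
  expect_false(tab$significant[tab$term == "(Intercept)"])
})
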