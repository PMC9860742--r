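make_sample <- function(days, window = 365L) {
  structure(list(days = as.integer(days), window_days = as.integer(window),
                 n_total = length(days), n_complete = length(days),
                 n_in_window = length(days)),
            class = "onset_sample")
}

test_that("onset days follow the day-1 convention and the analysis window", {
  demo <- read_tiny("demo", c("case_id,sex,age,reporting_year",
                              paste0(LETTERS[1:5], ",male,60s,2020")))
  drug <- read_tiny("drug", c(
    "case_id,drug_name,involvement,start_date",
    "A,cisplatin,suspected,2020-01-01",
    "B,cisplatin,suspected,2020-01-01",
    "C,cisplatin,suspected,2020-01-01",
    "D,cisplatin,suspected,",            # missing start date
    "E,cisplatin,concomitant,2020-01-01" # not a suspected exposure
  ))
  reac <- read_tiny("reac", c(
    "case_id,term,onset_date,outcome",
    "A,Hyponatraemia,2020-01-01,Recovered",  # same day -> day 1
    "B,Hyponatraemia,2021-06-01,Recovered",  # beyond the window
    "C,Hyponatraemia,2020-01-10,Recovered",  # day 10
    "D,Hyponatraemia,2020-02-01,Recovered",
    "E,Hyponatraemia,2020-02-01,Recovered"))
  hist <- read_tiny("hist", "case_id,condition")
  rs <- merge_tables(demo, drug, reac, hist, quiet = TRUE)
  s <- extract_onsets(rs, "cisplatin", term_set("event", "Hyponatraemia"))
  expect_equal(s$n_total, 4L)       # E is concomitant only
  expect_equal(s$n_complete, 3L)    # D lacks a start date
  expect_equal(s$n_in_window, 2L)   # B exceeds 365 days
  expect_setequal(s$days, c(1L, 10L))
  expect_true(all(s$days >= 1 & s$days <= s$window_days))

  # earliest suspected start date anchors the count
  drug2 <- read_tiny("drug", c("case_id,drug_name,involvement,start_date",
                               "A,cisplatin,suspected,2020-01-05",
                               "A,cisplatin,suspected,2020-01-01"))
  rs2 <- merge_tables(demo, drug2, reac, hist, quiet = TRUE)
  s2 <- extract_onsets(rs2, "cisplatin", "Hyponatraemia")
  expect_equal(s2$days, 1L)
})

test_that("generated onset days are recovered exactly from the tables", {
  cfg <- observed_config(seed = 17L, n = 2500L)
  gen <- generate_reports(cfg)
  rs <- merge_tables(gen$tables$demo, gen$tables$drug, gen$tables$reac,
                     gen$tables$hist, quiet = TRUE)
  s <- extract_onsets(rs, "cisplatin", term_set("event", cfg$event_term))
  truth_days <- gen$truth$onset_day[!is.na(gen$truth$onset_day) &
                                      gen$truth$onset_drug == "cisplatin"]
  expect_equal(sort(s$days), sort(truth_days[truth_days <= 365]))
  expect_equal(s$n_total, length(truth_days))
})

test_that("the Weibull median closed form is exact and monotone in the scale", {
  expect_equal(weibull_median(1, 1), log(2))
  expect_equal(round(weibull_median(10.38, 0.98)), 7)
  expect_equal(weibull_median(10.38, 1e9), 10.38, tolerance = 1e-6)
  med <- vapply(seq(1, 30, by = 0.5), weibull_median, numeric(1), beta = 0.98)
  expect_true(all(diff(med) > 0))
})

test_that("exponential data recover scale near the mean and shape near one", {
  set.seed(10)
  t <- stats::rexp(800, rate = 1 / 10)
  fit <- fit_weibull(t)
  expect_equal(fit$alpha, mean(t), tolerance = 0.05)
  expect_equal(fit$beta, 1, tolerance = 0.08)
  expect_equal(fit$hazard_class, "constant-compatible")
  # at (mean, 1) the likelihood dominates nearby shape values
  ll <- function(a, b) sum(stats::dweibull(t, b, a, log = TRUE))
  expect_gte(ll(mean(t), 1), ll(mean(t), 1.2))
  expect_gte(ll(mean(t), 1), ll(mean(t), 0.8))
})

test_that("the MLE matches a dense grid search on small samples", {
  shapes <- c(0.7, 1, 1.8)
  for (i in seq_along(shapes)) {
    set.seed(100 + i)
    t <- stats::rweibull(sample(12:50, 1), shape = shapes[i], scale = 9)
    fit <- fit_weibull(t)
    g <- grid_weibull(t)
    expect_equal(fit$alpha, g$alpha, tolerance = g$res_alpha * 1.5)
    expect_equal(fit$beta, g$beta, tolerance = g$res_beta * 1.5)
    expect_gte(fit$log_likelihood,
               sum(stats::dweibull(t, g$beta, g$alpha, log = TRUE)) - 1e-6)
  }
})

test_that("rescaling time rescales the scale parameter and leaves the shape alone", {
  set.seed(3)
  t <- stats::rweibull(200, shape = 1.3, scale = 12)
  f1 <- fit_weibull(t)
  for (k in c(0.5, 3, 10)) {
    f2 <- fit_weibull(t * k)
    expect_equal(f2$alpha / f1$alpha, k, tolerance = 1e-5)
    expect_equal(f2$beta, f1$beta, tolerance = 1e-5)
  }
})

test_that("degenerate and undersized samples are refused", {
  expect_error(fit_weibull(rep(5, 20)), class = "pvsignal_degenerate_sample")
  expect_error(fit_weibull(1:5), class = "pvsignal_insufficient_sample")
  expect_error(fit_weibull(make_sample(1:5)),
               class = "pvsignal_insufficient_sample")
})

test_that("hazard classification requires the shape CI to exclude one", {
  expect_equal(classify_hazard(list(beta_ci = c(0.89, 1.08))),
               "constant-compatible")
  expect_equal(classify_hazard(list(beta_ci = c(1.5, 2.5))), "increasing")
  expect_equal(classify_hazard(list(beta_ci = c(0.3, 0.7))), "decreasing")
  expect_equal(classify_hazard(list(beta_ci = c(NA, NA))),
               "constant-compatible")
})

test_that("the truncated likelihood is available and shifts the fit", {
  set.seed(21)
  t <- stats::rweibull(4000, shape = 1, scale = 60)
  t <- t[t >= 1 & t <= 90]                  # heavy right truncation
  plain <- fit_weibull(t, window_days = 90L)
  trunc <- fit_weibull(t, truncated = TRUE, window_days = 90L)
  # accounting for truncation recovers a larger scale, closer to the truth
  expect_gt(trunc$alpha, plain$alpha)
  expect_lt(abs(trunc$alpha - 60), abs(plain$alpha - 60))
})

test_that("empirical summaries use interpolated quartiles and a day cut", {
  s <- make_sample(c(5, 6, 7, 8, 9))
  es <- empirical_summary(s, cut_days = 10)
  expect_equal(es$median, 7)
  expect_equal(es$q1, 6)
  expect_equal(es$fraction_within_cut, 1)
  s2 <- make_sample(c(1, 20))
  expect_equal(empirical_summary(s2, 10)$fraction_within_cut, 0.5)
})

test_that("the onset histogram covers the whole window", {
  s <- make_sample(c(1, 1, 3, 365))
  h <- onset_histogram(s)
  expect_equal(nrow(h), 365L)
  expect_equal(h$count[1L], 2L)
  expect_equal(h$count[3L], 1L)
  expect_equal(sum(h$count), 4L)
})
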