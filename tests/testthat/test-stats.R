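test_that("single-Poisson pdf and cdf take their analytic values", {
  m <- poisson_model(0.22)
  expect_equal(wait_pdf(m, 0), 0.22)
  expect_equal(wait_cdf(m, 0), 0)
  for (lam in c(0.08, 0.22, 2)) {
    expect_equal(wait_cdf(poisson_model(lam), 1 / lam), 1 - exp(-1))
  }
  expect_error(wait_pdf(m, -1), "nonnegative")
  q <- stats::integrate(function(t) wait_pdf(m, t), 0, 100 / 0.22)
  expect_equal(q$value, 1, tolerance = 1e-6)
})

test_that("count-rate estimation reproduces the printed rates", {
  expect_equal(rate_from_counts(44, 200)$rate, 0.22)
  expect_equal(rate_from_counts(16, 200)$rate, 0.08)
  expect_warning(m0 <- rate_from_counts(0, 200), "degenerate")
  expect_true(m0$degenerate)
})

test_that("the quantile regression inverts exponential order statistics exactly", {
  lam <- 0.5; n <- 200
  i <- seq_len(n - 1)
  w <- c(-(1 / lam) * log(1 - i / n), 30)   # order statistics + a finite max
  fit <- fit_poisson_quantile(w)
  expect_equal(fit$rate, lam, tolerance = 1e-12)
  expect_identical(fit$source, "quantile_fit")
  # simulation: recovered within 5%
  set.seed(1)
  w2 <- sample_waiting_times(poisson_model(0.22), 1e4)
  expect_lt(abs(fit_poisson_quantile(w2)$rate - 0.22) / 0.22, 0.05)
  # ties do not break the fit
  expect_true(is.finite(fit_poisson_quantile(c(1, 1, 2))$rate))
  expect_error(fit_poisson_quantile(c(1, 2)), "at least 3")
})

test_that("the hypoexponential density is symmetric, normalized and has the stated mean", {
  m <- double_poisson_model(1, 1 / 3.62)
  expect_equal(wait_pdf(m, 0), 0)
  expect_equal(wait_cdf(m, 0), 0)
  expect_equal(m$mean_wait, 4.62)
  swapped <- double_poisson_model(1 / 3.62, 1)
  tt <- seq(0, 30, by = 0.1)
  expect_equal(wait_pdf(m, tt), wait_pdf(swapped, tt))
  expect_equal(wait_cdf(m, tt), wait_cdf(swapped, tt))
  for (rates in list(c(1, 0.276), c(0.654, 0.123), c(2, 2))) {
    md <- double_poisson_model(rates[1], rates[2])
    q <- stats::integrate(function(t) wait_pdf(md, t), 0, Inf)
    expect_equal(q$value, 1, tolerance = 1e-6)
    expect_true(all(wait_pdf(md, tt) >= 0))
    mean_num <- stats::integrate(function(t) t * wait_pdf(md, t), 0, Inf)$value
    expect_equal(mean_num, md$mean_wait, tolerance = 1e-6)
  }
})

test_that("the equal-rate limit is the Erlang-2 form and is continuous", {
  lam <- 1
  m_eq <- double_poisson_model(lam, lam)
  expect_equal(wait_pdf(m_eq, 1), exp(-1))           # t e^-t at t = 1
  tt <- seq(0.01, 10, by = 0.05)
  erlang <- lam^2 * tt * exp(-lam * tt)
  expect_equal(wait_pdf(m_eq, tt), erlang)
  # continuity: rates differing by 1e-6 stay within 1e-4 of the limit
  m_near <- double_poisson_model(lam * (1 + 1e-6), lam)
  expect_lt(max(abs(wait_pdf(m_near, tt) - erlang)), 1e-4)
})

test_that("a very fast lag stage collapses to the single-Poisson model", {
  lc <- 0.3
  m <- double_poisson_model(1e3 * lc, lc)
  single <- poisson_model(lc)
  tt <- seq(0, 40, by = 0.05)
  expect_lt(max(abs(wait_cdf(m, tt) - wait_cdf(single, tt))), 1e-2)
})

test_that("maximum likelihood recovers both rates within 5% median error", {
  true <- c(lag = 1.0, cond = 0.276)
  errs <- purrr::map_dbl(1:20, function(s) {
    set.seed(s)
    w <- sample_waiting_times(double_poisson_model(true[1], true[2]), 1e4)
    f <- fit_double_poisson(w)
    max(abs(f$rate_lag - true[1]) / true[1],
        abs(f$rate_cond - true[2]) / true[2])
  })
  expect_lt(median(errs), 0.05)
})

test_that("fitted rates are labelled lag-fast and carry diagnostics", {
  set.seed(2)
  w <- sample_waiting_times(double_poisson_model(1, 0.25), 5e3)
  f <- fit_double_poisson(w)
  expect_gte(f$rate_lag, f$rate_cond)
  g <- glance(f)
  expect_true(g$converged)
  expect_false(g$near_degenerate)
  expect_equal(g$n, 5e3)
  # least-squares route agrees roughly with the MLE
  f2 <- fit_double_poisson(w, method = "lsq")
  expect_lt(abs(f2$rate_cond - f$rate_cond) / f$rate_cond, 0.25)
})

test_that("pure-exponential samples are flagged near-degenerate", {
  set.seed(3)
  w <- rexp(5e3, 0.3)
  expect_warning(f <- fit_double_poisson(w), "near-degenerate")
  expect_true(f$near_degenerate)
})

test_that("refitting reproduces the sample distribution (KS self-consistency)", {
  set.seed(6)
  w <- sample_waiting_times(double_poisson_model(1, 0.276), 1e4)
  f <- suppressWarnings(fit_double_poisson(w))
  w2 <- sample_waiting_times(f, 1e4, seed = 7)
  d <- suppressWarnings(stats::ks.test(w, w2))$statistic
  crit_1pc <- 1.628 * sqrt(2 / 1e4)   # two-sample 1% critical value
  expect_lt(unname(d), crit_1pc)
})

test_that("predicted event counts follow the fitted processes", {
  expect_equal(predicted_events(double_poisson_model(1, 1 / 3.62), 200),
               43.3, tolerance = 0.001)
  expect_equal(predicted_events(double_poisson_model(1 / 1.53, 1 / 8.14), 200),
               20.7, tolerance = 0.001)
  expect_equal(predicted_events(poisson_model(0.22), 200), 44)
  expect_error(predicted_events(poisson_model(0.22), -1), "positive")
})

test_that("log-normal duration fits recover the generating mean", {
  set.seed(9)
  mu <- log(1.24) - 0.45^2 / 2
  d <- rlnorm(1e4, mu, 0.45)
  f <- fit_durations(d)
  expect_lt(abs(f$mean_ns - 1.24) / 1.24, 0.03)
  expect_warning(fd <- fit_durations(rep(2, 10)), "degenerate")
  expect_equal(fd$mu, log(2))
  expect_true(fd$degenerate)
  expect_error(fit_durations(c(1, -1, 2, 3, 4)), "positive")
  expect_error(fit_durations(numeric(0)), "at least 5")
})

test_that("tidy methods return the model parameters as tibbles", {
  td <- tidy(double_poisson_model(1, 0.5))
  expect_equal(td$estimate[td$term == "mean_wait"], 3)
  expect_equal(tidy(poisson_model(0.22))$estimate, 0.22)
  set.seed(1)
  tf <- tidy(fit_durations(rlnorm(100, 0, 0.3)))
  expect_identical(tf$term, c("mu", "sigma", "mean"))
})
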