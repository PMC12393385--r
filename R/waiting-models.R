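#' Single-Poisson waiting-time model
#'
#' A homogeneous Poisson point process for permeation events: waiting times
#' between consecutive event starts are exponential with rate `rate`
#' (events/ns); the expected number of events in a window T is `rate * T`.
#'
#' @param rate event rate, events/ns; must be positive.
#' @param source how the rate was obtained (`"count_rate"`, `"quantile_fit"`
#'   or `"specified"`).
#' @return an object of class `poisson_model`.
#' @export
poisson_model <- function(rate, source = "specified") {
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    abort("`rate` must be a single positive number.")
  }
  structure(list(rate = rate, source = source, degenerate = FALSE),
            class = "poisson_model")
}

#' Double-Poisson (hypoexponential) waiting-time model
#'
#' Two chained Poisson stages: an entry lag with rate `rate_lag` followed by
#' a conduction stage with rate `rate_cond`. A waiting time is the sum of
#' two independent exponentials, so the mean inter-event time is
#' `1/rate_lag + 1/rate_cond` and the density is the (order-symmetric)
#' hypoexponential; at equal rates it reduces to the Erlang-2 form
#' `lambda^2 t exp(-lambda t)`.
#'
#' @param rate_lag lag-stage rate, events/ns.
#' @param rate_cond conduction-stage rate, events/ns.
#' @return an object of class `double_poisson_model`.
#' @export
double_poisson_model <- function(rate_lag, rate_cond) {
  if (any(c(rate_lag, rate_cond) <= 0) ||
      length(rate_lag) != 1 || length(rate_cond) != 1) {
    abort("Both rates must be single positive numbers.")
  }
  structure(
    list(rate_lag = rate_lag, rate_cond = rate_cond,
         mean_wait = 1 / rate_lag + 1 / rate_cond),
    class = "double_poisson_model"
  )
}

#' @export
print.poisson_model <- function(x, ...) {
  cat(sprintf("<poisson_model> rate = %.4g /ns (%s)%s\n", x$rate, x$source,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' @export
print.double_poisson_model <- function(x, ...) {
  cat(sprintf(
    "<double_poisson_model> rate_lag = %.4g /ns, rate_cond = %.4g /ns, mean wait = %.4g ns\n",
    x$rate_lag, x$rate_cond, x$mean_wait))
  invisible(x)
}

#' Waiting-time density and distribution functions
#'
#' `wait_pdf()` and `wait_cdf()` evaluate the probability density and the
#' cumulative distribution of inter-event waiting times under a fitted or
#' specified model. For the single-Poisson model these are
#' `f(t) = lambda exp(-lambda t)` and `F(t) = 1 - exp(-lambda t)`; for the
#' double-Poisson model the hypoexponential forms, continuous in the
#' equal-rate (Erlang-2) limit.
#'
#' @param model a [poisson_model()] or [double_poisson_model()].
#' @param t waiting times, ns; must be nonnegative.
#' @return numeric vector of densities (per ns) or probabilities.
#' @export
wait_pdf <- function(model, t) UseMethod("wait_pdf")

#' @rdname wait_pdf
#' @export
wait_cdf <- function(model, t) UseMethod("wait_cdf")

.check_t <- function(t) {
  if (any(t < 0)) abort("Waiting times `t` must be nonnegative.")
  t
}

#' @export
wait_pdf.poisson_model <- function(model, t) {
  .check_t(t)
  model$rate * exp(-model$rate * t)
}

#' @export
wait_cdf.poisson_model <- function(model, t) {
  .check_t(t)
  1 - exp(-model$rate * t)
}

# relative rate gap below which the Erlang-2 branch is used
.DP_EQ_TOL <- 1e-9

#' @export
wait_pdf.double_poisson_model <- function(model, t) {
  .check_t(t)
  l1 <- min(model$rate_lag, model$rate_cond)
  l2 <- max(model$rate_lag, model$rate_cond)
  if ((l2 - l1) <= .DP_EQ_TOL * l2) {
    l <- (l1 + l2) / 2
    return(l^2 * t * exp(-l * t))
  }
  # stable: l1 l2 / (l2 - l1) * exp(-l1 t) * (1 - exp(-(l2 - l1) t))
  l1 * l2 / (l2 - l1) * exp(-l1 * t) * (-expm1(-(l2 - l1) * t))
}

#' @export
wait_cdf.double_poisson_model <- function(model, t) {
  .check_t(t)
  l1 <- min(model$rate_lag, model$rate_cond)
  l2 <- max(model$rate_lag, model$rate_cond)
  if ((l2 - l1) <= .DP_EQ_TOL * l2) {
    l <- (l1 + l2) / 2
    return(1 - (1 + l * t) * exp(-l * t))
  }
  1 - (l2 * exp(-l1 * t) - l1 * exp(-l2 * t)) / (l2 - l1)
}

#' Event rate from a count over a window
#'
#' The count-rate estimator of the Poisson parameter: `lambda = count / dt`
#' (events/ns). A zero count yields a degenerate model flagged as such, with
#' rate `NA`.
#'
#' @param count number of events observed.
#' @param dt_ns observation window, ns; must be positive.
#' @return a [poisson_model()] with source `"count_rate"`.
#' @export
rate_from_counts <- function(count, dt_ns) {
  if (dt_ns <= 0) abort("`dt_ns` must be positive.")
  if (count <= 0) {
    warn("Zero events: degenerate rate model.")
    m <- structure(list(rate = NA_real_, source = "count_rate",
                        degenerate = TRUE), class = "poisson_model")
    return(m)
  }
  m <- poisson_model(count / dt_ns, source = "count_rate")
  m
}

#' Quantile-regression fit of the Poisson rate
#'
#' Sorts the waiting times and regresses the i-th order statistic on
#' `-log(1 - i/N)` (for i = 1..N-1; i = N is excluded as its regressor is
#' infinite) with the line forced through the origin, zero being the
#' shortest possible waiting time. The inverse slope is the rate. On data
#' generated exactly from the exponential quantile function the rate is
#' recovered to machine precision.
#'
#' @param waiting_times numeric vector of waiting times, ns; length >= 3.
#' @return a [poisson_model()] with source `"quantile_fit"`.
#' @export
fit_poisson_quantile <- function(waiting_times) {
  w <- sort(waiting_times)
  n <- length(w)
  if (n < 3) abort("Need at least 3 waiting times.")
  i <- seq_len(n - 1)
  x <- -log(1 - i / n)
  t_i <- w[i]
  slope <- sum(x * t_i) / sum(x^2)
  if (!is.finite(slope) || slope <= 0) abort("Degenerate quantile fit.")
  poisson_model(1 / slope, source = "quantile_fit")
}

#' Fit the double-Poisson model to waiting times
#'
#' Estimates the two stage rates of the hypoexponential waiting-time model.
#' The default is maximum likelihood on the hypoexponential density,
#' initialised from the method of moments
#' (`mean = 1/l1 + 1/l2`, `var = 1/l1^2 + 1/l2^2`); the alternative is least
#' squares against a binned empirical density (as one would fit a plotted
#' histogram). Rates are labelled with the convention
#' `rate_lag >= rate_cond` (the lag is the faster stage). Samples whose
#' variance is at least the squared mean are statistically indistinguishable
#' from a single exponential and are flagged `near_degenerate`.
#'
#' @param waiting_times numeric vector, ns; length >= 10.
#' @param method `"mle"` (default) or `"lsq"`.
#' @param bins number of histogram bins for `method = "lsq"`.
#' @return a `dp_fit` object (a [double_poisson_model()] with fit
#'   diagnostics: `loglik`, `n`, `converged`, `near_degenerate`, `method`).
#' @export
fit_double_poisson <- function(waiting_times, method = c("mle", "lsq"),
                               bins = 30) {
  method <- match.arg(method)
  w <- waiting_times[is.finite(waiting_times) & waiting_times > 0]
  if (length(w) < 10) abort("Need at least 10 positive waiting times.")
  m <- mean(w)
  v <- sum((w - m)^2) / length(w)
  near_degenerate <- v >= m^2
  # moment inversion: component means a,b solve a+b=m, a^2+b^2=v
  if (near_degenerate) {
    a0 <- 0.05 * m; b0 <- 0.95 * m
  } else {
    ab <- (m^2 - v) / 2
    disc <- max(m^2 - 4 * ab, 0)
    a0 <- (m - sqrt(disc)) / 2
    b0 <- (m + sqrt(disc)) / 2
    a0 <- max(a0, 1e-4 * m)
  }
  p0 <- log(1 / c(a0, b0))

  nll <- function(p) {
    mdl <- double_poisson_model(exp(p[1]), exp(p[2]))
    d <- wait_pdf(mdl, w)
    if (any(d <= 0 | !is.finite(d))) return(1e10)
    -sum(log(d))
  }
  if (method == "mle") {
    fit <- optim(p0, nll, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
    obj <- fit$value
    conv <- fit$convergence == 0
  } else {
    h <- graphics::hist(w, breaks = bins, plot = FALSE)
    mid <- h$mids
    dens <- h$density
    sse <- function(p) {
      mdl <- double_poisson_model(exp(p[1]), exp(p[2]))
      sum((wait_pdf(mdl, mid) - dens)^2)
    }
    fit <- optim(p0, sse, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
    obj <- fit$value
    conv <- fit$convergence == 0
  }
  rates <- sort(exp(fit$par), decreasing = TRUE)
  # a lag stage orders of magnitude faster than conduction is the single-
  # exponential boundary: the two-stage structure is not identifiable
  near_degenerate <- near_degenerate || rates[1] > 50 * rates[2]
  out <- double_poisson_model(rate_lag = rates[1], rate_cond = rates[2])
  out$loglik <- if (method == "mle") -obj else -nll(log(rates))
  out$n <- length(w)
  out$converged <- conv
  out$near_degenerate <- near_degenerate
  out$method <- method
  if (!conv) warn("Double-Poisson fit did not converge; see diagnostics.")
  if (near_degenerate) {
    warn("Sample variance >= squared mean: indistinguishable from a single exponential (near-degenerate).")
  }
  class(out) <- c("dp_fit", class(out))
  out
}

#' Expected number of events in a window
#'
#' For a single-Poisson model the expectation over a window `T` is
#' `rate * T`; for the double-Poisson model it is `T` divided by the mean
#' inter-event time `1/rate_lag + 1/rate_cond`.
#'
#' @param model a [poisson_model()] or [double_poisson_model()].
#' @param T_ns window length, ns; must be positive.
#' @return expected event count.
#' @export
predicted_events <- function(model, T_ns) {
  if (T_ns <= 0) abort("`T_ns` must be positive.")
  UseMethod("predicted_events")
}

#' @export
predicted_events.poisson_model <- function(model, T_ns) {
  if (isTRUE(model$degenerate)) return(0)
  model$rate * T_ns
}

#' @export
predicted_events.double_poisson_model <- function(model, T_ns) {
  T_ns / model$mean_wait
}

#' Log-normal fit of event durations
#'
#' Maximum-likelihood log-normal fit of crossing-event durations: `mu` and
#' `sigma` are the mean and (MLE, 1/n) standard deviation of log-durations;
#' the implied mean duration is `exp(mu + sigma^2/2)`. A zero spread
#' (all durations equal) is flagged degenerate.
#'
#' @param durations_ns positive durations, ns; length >= 5.
#' @return an object of class `duration_fit` with fields `mu`, `sigma`,
#'   `mean_ns`, `n`, `degenerate`.
#' @export
fit_durations <- function(durations_ns) {
  d <- durations_ns[is.finite(durations_ns)]
  if (length(d) < 5) abort("Need at least 5 durations.")
  if (any(d <= 0)) abort("Durations must be positive.")
  lg <- log(d)
  mu <- mean(lg)
  sigma <- sqrt(mean((lg - mu)^2))
  degenerate <- sigma < 1e-12
  if (degenerate) warn("All durations equal: degenerate log-normal fit (sigma = 0).")
  structure(
    list(mu = mu, sigma = sigma, mean_ns = exp(mu + sigma^2 / 2),
         n = length(d), degenerate = degenerate),
    class = "duration_fit"
  )
}

#' @export
print.duration_fit <- function(x, ...) {
  cat(sprintf("<duration_fit> log-normal mu = %.4g, sigma = %.4g, mean = %.4g ns (n = %d)\n",
              x$mu, x$sigma, x$mean_ns, x$n))
  invisible(x)
}

# ---- broom-style methods -------------------------------------------------

#' @exportS3Method generics::tidy
tidy.poisson_model <- function(x, ...) {
  tibble::tibble(term = "rate", estimate = x$rate, unit = "events/ns",
                 source = x$source)
}

#' @exportS3Method generics::tidy
tidy.double_poisson_model <- function(x, ...) {
  tibble::tibble(term = c("rate_lag", "rate_cond", "mean_wait"),
                 estimate = c(x$rate_lag, x$rate_cond, x$mean_wait),
                 unit = c("events/ns", "events/ns", "ns"))
}

#' @exportS3Method generics::glance
glance.dp_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n = x$n, converged = x$converged,
                 near_degenerate = x$near_degenerate, method = x$method)
}

#' @exportS3Method generics::tidy
tidy.duration_fit <- function(x, ...) {
  tibble::tibble(term = c("mu", "sigma", "mean"),
                 estimate = c(x$mu, x$sigma, x$mean_ns),
                 unit = c("log-ns", "log-ns", "ns"))
}

#' @exportS3Method generics::glance
glance.duration_fit <- function(x, ...) {
  tibble::tibble(mean_ns = x$mean_ns, n = x$n, degenerate = x$degenerate)
}
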