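# Posterior-coverage validity check of the pseudolikelihood: if tau is
# drawn from the prior and data from the model at tau, then H = posterior
# CDF evaluated at tau must be uniform(0,1) for a coverage-proper Bayesian
# likelihood; a Kolmogorov-Smirnov test quantifies departure.

#' Generic posterior-coverage check
#'
#' Engine for the coverage-validity simulation: repeatedly draw a scalar
#' parameter from its prior, generate data at that value, and evaluate the
#' posterior CDF at the drawn value.  Uniformity of the resulting sample is
#' tested with a one-sample Kolmogorov-Smirnov test.
#'
#' @param m Number of prior draws (at least 50 for a meaningful KS test).
#' @param rprior Function `function() -> tau` drawing one value from the
#'   prior.
#' @param rdata Function `function(tau) -> data` simulating one data set.
#' @param posterior_cdf Function `function(tau, data) -> H` returning the
#'   posterior CDF at `tau` (may return `NA` to flag a failed replicate,
#'   e.g. a nonconvergent chain).
#' @param seed Integer seed.
#' @return Object of class `gxe_validity` with fields `H`, `ks_stat`,
#'   `ks_p`, `n_failed`, `seed`.
#' @export
coverage_check_engine <- function(m, rprior, rdata, posterior_cdf, seed = 1L) {
  if (m < 50L) stop("'m' must be at least 50")
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, m)
  H <- numeric(m)
  for (k in seq_len(m)) {
    set.seed(rep_seeds[k])
    tau <- rprior()
    dat <- rdata(tau)
    H[k] <- posterior_cdf(tau, dat)
  }
  failed <- sum(is.na(H))
  Hok <- H[!is.na(H)]
  ks <- stats::ks.test(Hok, "punif")
  structure(list(H = Hok, ks_stat = unname(ks$statistic),
                 ks_p = ks$p.value, n_failed = failed, m = m, seed = seed),
            class = "gxe_validity")
}

#' @export
print.gxe_validity <- function(x, ...) {
  cat(sprintf(
    "Posterior-coverage check: m = %d (%d failed), KS statistic %.4f, p = %.4f\n",
    x$m, x$n_failed, x$ks_stat, x$ks_p))
  cat(if (x$ks_p < 0.05)
    "  uniformity REJECTED at the 0.05 level: coverage-propriety invalidated\n"
    else
      "  uniformity not rejected at the 0.05 level\n")
  invisible(x)
}

#' @export
plot.gxe_validity <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::hist(x$H, breaks = 20, freq = FALSE, main = "H statistics",
                 xlab = "H", ...)
  graphics::abline(h = 1, lty = 2)
  n <- length(x$H)
  plot(stats::ppoints(n), sort(x$H), xlab = "uniform quantile",
       ylab = "sorted H", main = "PP plot")
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

# mid-rank empirical CDF of a chain at tau, kept strictly inside (0, 1)
chain_cdf_at <- function(draws, tau) {
  (sum(draws < tau) + 0.5 * sum(draws == tau) + 0.5) / (length(draws) + 1)
}

#' Coverage-validity check of the pseudolikelihood posterior
#'
#' Monahan-Boos-style check applied to the pseudolikelihood: a monitored
#' risk coefficient is drawn from its normal prior, a case-control data set
#' is simulated from the scenario at that value (the logistic intercept is
#' recalibrated to the scenario prevalence each time), the posterior is
#' sampled by Metropolis-Hastings, and `H` is the posterior CDF at the
#' drawn value (mid-rank convention on the chain).  Uniform `H` across
#' draws is consistent with coverage propriety.
#'
#' @param scenario A [gxe_scenario()]; its risk coefficients other than the
#'   monitored one are held at their scenario values.
#' @param parameter Name of the monitored scalar coefficient (default
#'   `"beta_x"`).
#' @param prior A [prior_spec()] used both to draw the monitored value and
#'   in the Bayesian fit.
#' @param m Number of prior draws (default 100).
#' @param mcmc_options Options passed to [fit_bayes()] (chain length etc.).
#' @param seed Integer seed.
#' @return A `gxe_validity` report.
#' @export
coverage_check <- function(scenario, parameter = "beta_x",
                           prior = prior_spec(), m = 100L,
                           mcmc_options = list(n_iter = 3000L, burn_in = 1000L),
                           seed = 1L) {
  sd_tau <- if (is.null(prior$cov)) prior$sd else sqrt(prior$cov[1L, 1L])
  mu_tau <- prior$mu[1L]
  rprior <- function() stats::rnorm(1L, mu_tau, sd_tau)
  rdata <- function(tau) {
    sc <- set_scenario_coef(scenario, parameter, tau)
    simulate_case_control(sc)
  }
  posterior_cdf <- function(tau, dat) {
    ch <- tryCatch(suppressWarnings(do.call(
      fit_bayes, c(list(data = dat, spec = scenario$spec, prior = prior,
                        model_kind = scenario$params$model_kind,
                        pi = scenario$pi,
                        seed = sample.int(.Machine$integer.max, 1L)),
                   mcmc_options))),
      error = function(e) NULL)
    if (is.null(ch) || ch$acceptance_rate < 0.01 || ch$acceptance_rate > 0.99)
      return(NA_real_)
    chain_cdf_at(ch$draws[, parameter], tau)
  }
  coverage_check_engine(m, rprior, rdata, posterior_cdf, seed = seed)
}

# replace one named risk coefficient in a scenario and recalibrate beta0
set_scenario_coef <- function(scenario, parameter, value) {
  pr <- scenario$params
  set1 <- function(vec, i) { vec[1L, i] <- value; vec }
  if (parameter == "beta_x") pr$beta_t[1L] <- value
  else if (grepl("^beta_a[0-9]+$", parameter))
    pr$beta_a <- set1(pr$beta_a, as.integer(sub("beta_a", "", parameter)))
  else if (grepl("^beta_ax[0-9]+$", parameter))
    pr$beta_at <- set1(pr$beta_at, as.integer(sub("beta_ax", "", parameter)))
  else if (grepl("^beta_d[0-9]+$", parameter))
    pr$beta_d <- set1(pr$beta_d, as.integer(sub("beta_d", "", parameter)))
  else if (grepl("^beta_dx[0-9]+$", parameter))
    pr$beta_dt <- set1(pr$beta_dt, as.integer(sub("beta_dx", "", parameter)))
  else stop("unknown monitored parameter: ", parameter)
  gxe_scenario(scenario$panel, scenario$eta, scenario$spec, pr,
               scenario$n_controls, scenario$n_cases, pi = scenario$pi,
               missing_rate = scenario$missing_rate)
}

#' Conjugate beta-binomial coverage control
#'
#' Proper-Bayes positive control (and temperature-corrupted negative
#' control) for the coverage check: the success probability is drawn from a
#' Beta(`a`, `b`) prior, data are Binomial(`n`, tau), and the posterior is
#' the analytic Beta.  With `temperature != 1` the likelihood is raised to
#' that power (still analytic), which destroys coverage propriety and
#' should be flagged by the KS test.
#'
#' @param m Number of prior draws.
#' @param n Binomial sample size per draw (default 50).
#' @param a,b Beta prior shape parameters (default 2, 2).
#' @param temperature Likelihood temperature (default 1 = proper posterior).
#' @param seed Integer seed.
#' @return A `gxe_validity` report.
#' @export
conjugate_coverage_control <- function(m, n = 50L, a = 2, b = 2,
                                       temperature = 1, seed = 1L) {
  coverage_check_engine(
    m,
    rprior = function() stats::rbeta(1L, a, b),
    rdata = function(tau) stats::rbinom(1L, n, tau),
    posterior_cdf = function(tau, y)
      stats::pbeta(tau, a + temperature * y, b + temperature * (n - y)),
    seed = seed)
}
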