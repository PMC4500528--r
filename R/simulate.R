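# Synthetic case-control data: scenario definition, intercept calibration
# to a target prevalence, retrospective sampling, and the replicated
# bias/RMSE experiment runner.

#' Define a generative scenario for case-control simulation
#'
#' A scenario fixes the population (marker panel, exposure prevalence,
#' disease model, disease prevalence), the observation process
#' (misclassification, genotype missingness), and the study design (case
#' and control counts).
#'
#' @param panel A [marker_panel()].
#' @param eta True exposure prevalence `pr(T = 1)`.
#' @param spec A [misclass_spec()].
#' @param params A [risk_params()] holding the true risk coefficients
#'   (binary disease, `K = 1`).
#' @param n_controls,n_cases Design counts.
#' @param pi Target marginal disease prevalence `pr(D = 1)`; the logistic
#'   intercept \eqn{\beta_0} is calibrated to it by root finding.
#' @param missing_rate Probability that a genotype call is missing
#'   completely at random (default 0).
#' @return Object of class `gxe_scenario`.  The calibrated intercept and
#'   the implied offset \eqn{\kappa} are available via [scenario_truth()].
#' @export
gxe_scenario <- function(panel, eta, spec, params, n_controls, n_cases,
                         pi = 0.005, missing_rate = 0) {
  stopifnot(inherits(panel, "marker_panel"), inherits(spec, "misclass_spec"),
            inherits(params, "risk_params"))
  if (params$K != 1L) stop("scenarios support binary disease status")
  if (params$I != panel$n_markers)
    stop("risk parameters and panel disagree on the number of markers")
  if (eta <= 0 || eta >= 1 || pi <= 0 || pi >= 1)
    stop("'eta' and 'pi' must lie in (0, 1)")
  if (missing_rate < 0 || missing_rate >= 1) stop("invalid 'missing_rate'")
  sc <- structure(list(panel = panel, eta = eta, spec = spec,
                       params = params, n_controls = n_controls,
                       n_cases = n_cases, pi = pi,
                       missing_rate = missing_rate),
                  class = "gxe_scenario")
  sc$beta0 <- calibrate_beta0(sc)
  sc
}

#' @export
print.gxe_scenario <- function(x, ...) {
  cat(sprintf("Scenario: %s, %d markers, n0 = %d controls / n1 = %d cases\n",
              x$params$model_kind, x$panel$n_markers, x$n_controls, x$n_cases))
  cat(sprintf("  eta = %.3g, pi = %.3g, beta0 = %.4f, missing rate = %.2g\n",
              x$eta, x$pi, x$beta0, x$missing_rate))
  print(x$spec)
  invisible(x)
}

# population-average disease probability at intercept b0 (exact enumeration
# over the genotype x exposure grid)
population_prevalence <- function(scenario, b0) {
  gd <- genotype_distribution(scenario$panel)
  m <- riskgrid_m(scenario)
  sum(gd$prob * ((1 - scenario$eta) * stats::plogis(b0 + m[, 1L]) +
                   scenario$eta * stats::plogis(b0 + m[, 2L])))
}

# linear predictors m(g, t) over the genotype grid; columns t = 0, 1
riskgrid_m <- function(scenario) {
  gd <- genotype_distribution(scenario$panel)
  A <- gd$genotypes - 1L
  B <- encode_dominance(gd$genotypes, scenario$panel)
  pr <- scenario$params
  m0 <- as.vector(A %*% pr$beta_a[1L, ]) +
    as.vector(B %*% pr$beta_d[1L, ])
  m1 <- m0 + pr$beta_t[1L] + as.vector(A %*% pr$beta_at[1L, ]) +
    as.vector(B %*% pr$beta_dt[1L, ])
  cbind(m0, m1)
}

#' Calibrate the logistic intercept to a target disease prevalence
#'
#' Finds \eqn{\beta_0} such that the population-averaged disease
#' probability under the scenario's risk model equals the target prevalence
#' \eqn{\pi}, by 1-D root finding over the exact genotype-by-exposure grid.
#'
#' @param scenario A [gxe_scenario()] (its `pi` is the target), or a list
#'   with the same fields.
#' @return The calibrated intercept \eqn{\beta_0}.
#' @export
calibrate_beta0 <- function(scenario) {
  f <- function(b0) population_prevalence(scenario, b0) - scenario$pi
  if (f(-40) > 0 || f(20) < 0)
    stop("target prevalence unattainable under this risk model")
  stats::uniroot(f, c(-40, 20), tol = 1e-12)$root
}

#' True parameter values of a scenario, in estimator naming
#'
#' Returns the named vector of generative values in the same names used by
#' the fitted objects' `coef` methods, including the implied offset
#' \eqn{\kappa_1 = \beta_0 + \log(n_1/n_0) - \log(\pi_1/\pi_0)}.
#'
#' @param scenario A [gxe_scenario()].
#' @return Named numeric vector of true values.
#' @export
scenario_truth <- function(scenario) {
  pr <- scenario$params
  I <- pr$I
  kappa <- beta0_to_kappa(scenario$beta0,
                          c(scenario$n_controls, scenario$n_cases),
                          scenario$pi)
  out <- c(kappa = unname(kappa), beta_x = pr$beta_t[1L],
           stats::setNames(pr$beta_a[1L, ], paste0("beta_a", seq_len(I))),
           stats::setNames(pr$beta_at[1L, ], paste0("beta_ax", seq_len(I))))
  if (pr$model_kind == "GEM")
    out <- c(out,
             stats::setNames(pr$beta_d[1L, ], paste0("beta_d", seq_len(I))),
             stats::setNames(pr$beta_dt[1L, ], paste0("beta_dx", seq_len(I))))
  pairs <- if (I > 1L) t(utils::combn(I, 2L)) else NULL
  out <- c(out, eta = scenario$eta,
           stats::setNames(scenario$panel$p_m, paste0("p_m", seq_len(I))))
  if (!is.null(pairs))
    out <- c(out, stats::setNames(
      scenario$panel$delta[pairs],
      paste0("delta_", pairs[, 1L], pairs[, 2L])))
  c(out, pi = scenario$pi)
}

#' Simulate one retrospective case-control data set
#'
#' Implements the Bernoulli retrospective sampling scheme in its exact
#' conditional form: the joint cell probabilities of (genotype, true
#' exposure) given case or control status are computed from the calibrated
#' risk model, and `n_cases` / `n_controls` subjects are drawn from those
#' conditional distributions.  (This is distributionally identical to
#' drawing population subjects and rejecting until the quotas are met, and
#' avoids simulating ~`n/pi` individuals at rare-disease prevalences.)
#' Observed exposure `X` is then drawn from the misclassification kernel
#' and genotype calls are masked missing completely at random.
#'
#' @param scenario A [gxe_scenario()].
#' @param seed Optional integer seed for reproducibility.
#' @return A [case_control_data()] object; `attr(, "truth")` holds the
#'   generative parameter vector ([scenario_truth()]) and `attr(, "T")` the
#'   latent true exposures.
#' @export
simulate_case_control <- function(scenario, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gd <- genotype_distribution(scenario$panel)
  m <- riskgrid_m(scenario)
  p1 <- stats::plogis(scenario$beta0 + m)     # pr(D=1 | g, t), columns t=0,1
  pt <- c(1 - scenario$eta, scenario$eta)
  cell_prior <- gd$prob * rep(pt, each = nrow(m))        # (g, t) grid
  w1 <- cell_prior * as.vector(p1)
  w0 <- cell_prior * as.vector(1 - p1)
  draw <- function(w, n) {
    cnt <- as.vector(stats::rmultinom(1L, n, w / sum(w)))
    rep.int(seq_along(w), cnt)
  }
  cells <- c(draw(w0, scenario$n_controls), draw(w1, scenario$n_cases))
  D <- rep(c(0L, 1L), c(scenario$n_controls, scenario$n_cases))
  ng <- nrow(gd$genotypes)
  gidx <- (cells - 1L) %% ng + 1L
  Tt <- (cells - 1L) %/% ng
  ord <- sample.int(length(D))
  D <- D[ord]; gidx <- gidx[ord]; Tt <- Tt[ord]
  G <- gd$genotypes[gidx, , drop = FALSE]
  X <- ifelse(Tt == 1L,
              stats::rbinom(length(D), 1L, 1 - scenario$spec$xi0),
              stats::rbinom(length(D), 1L, scenario$spec$xi1))
  if (scenario$missing_rate > 0) {
    mask <- matrix(stats::runif(length(G)) < scenario$missing_rate,
                   nrow = nrow(G))
    G[mask] <- NA_integer_
  }
  dat <- case_control_data(D, X, G, pi = scenario$pi)
  attr(dat, "truth") <- scenario_truth(scenario)
  attr(dat, "T") <- Tt
  dat
}

#' Simulate a prospective population sample
#'
#' Draws `n` individuals from the scenario's source population (no
#' case-control selection): genotype from the panel, true exposure
#' Bernoulli(\eqn{\eta}), disease from the calibrated logistic model,
#' observed exposure from the misclassification kernel.  Mainly used to
#' audit the generative model (prevalence, allele frequencies, LD).
#'
#' @param scenario A [gxe_scenario()].
#' @param n Number of individuals.
#' @param seed Optional integer seed.
#' @return A data frame with columns `D`, `T`, `X` and the genotype dosages.
#' @export
simulate_population <- function(scenario, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gd <- genotype_distribution(scenario$panel)
  gidx <- sample.int(nrow(gd$genotypes), n, replace = TRUE, prob = gd$prob)
  G <- gd$genotypes[gidx, , drop = FALSE]
  Tt <- stats::rbinom(n, 1L, scenario$eta)
  m <- riskgrid_m(scenario)
  lp <- scenario$beta0 + ifelse(Tt == 1L, m[gidx, 2L], m[gidx, 1L])
  D <- stats::rbinom(n, 1L, stats::plogis(lp))
  X <- ifelse(Tt == 1L,
              stats::rbinom(n, 1L, 1 - scenario$spec$xi0),
              stats::rbinom(n, 1L, scenario$spec$xi1))
  out <- data.frame(D = D, T = Tt, X = X)
  colnames(G) <- paste0("g", seq_len(ncol(G)))
  cbind(out, as.data.frame(G))
}

## ---- shipped experiment designs -------------------------------------------

#' Shipped simulation designs
#'
#' `scenario_gem_large()` is the large-sample genotype-effect-model design:
#' 1,500 cases and 1,500 controls; three markers with coded-allele
#' frequency 0.25 and all pairwise LD coefficients 0.03; true exposure
#' Bernoulli(0.5) observed with misclassification `pr(X=0|T=1) = 0.20`,
#' `pr(X=1|T=0) = 0.25`; disease prevalence 0.005; true log-odds
#' coefficients `beta_x = 0.693`, `beta_a = (0.406, 0.789, 0.693)`,
#' `beta_ax = (0.916, 0.693, 1.099)`, `beta_d = (0.262, 0.095, 0.693)`,
#' `beta_dx = (1.099, 0.916, 1.099)`.  The same design evaluated with the
#' large-sample Gaussian posterior is the second shipped experiment.
#'
#' `scenario_aem_small()` is the small-sample additive-effect-model design:
#' 350 cases and 350 controls, the same three-marker panel and
#' misclassification, all dominance coefficients zero, and
#' `beta_x = 1.099`, `beta_a = (0.406, 0.789, 0.693)`,
#' `beta_ax = (0.916, 0.693, 1.099)`.
#'
#' @param missing_rate MCAR genotype missingness (default 0; the
#'   large-sample design is also studied at 0.5).
#' @return A [gxe_scenario()].
#' @export
scenario_gem_large <- function(missing_rate = 0) {
  gxe_scenario(
    panel = marker_panel(rep(0.25, 3L), delta = 0.03),
    eta = 0.5,
    spec = misclass_spec(xi0 = 0.20, xi1 = 0.25),
    params = risk_params(beta_t = log(2),
                         beta_a = c(0.406, 0.789, 0.693),
                         beta_at = c(0.916, 0.693, 1.099),
                         beta_d = c(0.262, 0.095, 0.693),
                         beta_dt = c(1.099, 0.916, 1.099),
                         model_kind = "GEM"),
    n_controls = 1500L, n_cases = 1500L, pi = 0.005,
    missing_rate = missing_rate)
}

#' @rdname scenario_gem_large
#' @export
scenario_aem_small <- function(missing_rate = 0) {
  gxe_scenario(
    panel = marker_panel(rep(0.25, 3L), delta = 0.03),
    eta = 0.5,
    spec = misclass_spec(xi0 = 0.20, xi1 = 0.25),
    params = risk_params(beta_t = 1.099,
                         beta_a = c(0.406, 0.789, 0.693),
                         beta_at = c(0.916, 0.693, 1.099),
                         model_kind = "AEM"),
    n_controls = 350L, n_cases = 350L, pi = 0.005,
    missing_rate = missing_rate)
}

## ---- replicated experiments -----------------------------------------------

#' Replicated bias/RMSE experiment
#'
#' Simulates `n_replicates` case-control data sets from a scenario and fits
#' the requested estimators to each, reporting per-parameter bias
#' (mean(estimate - truth)), RMSE, and Monte-Carlo standard errors.
#' Replicate seeds are derived deterministically from the master seed, so
#' identical calls give bit-identical tables.  Estimator failures in a
#' replicate are recorded (counted in `failures`) and excluded from the
#' summaries rather than aborting the sweep.
#'
#' @param scenario A [gxe_scenario()].
#' @param n_replicates Number of simulated data sets.
#' @param estimators Subset of `c("naive", "pml", "mcmc", "asymptotic")`.
#' @param seed Master seed.
#' @param pi_known Fit with the disease prevalence fixed at its true value
#'   (default `TRUE`); otherwise it is estimated.
#' @param mcmc_options List of options passed to [fit_bayes()] (`n_iter`,
#'   `burn_in`, `prior`, ...).
#' @param keep_estimates Keep the per-replicate estimate matrices (default
#'   `TRUE`).
#' @return Object of class `gxe_experiment`: a long-format data frame
#'   `table` with columns `estimator`, `parameter`, `truth`, `bias`,
#'   `rmse`, `mse`, `mc_se` (Monte-Carlo SE of the bias), plus replicate
#'   counts.
#' @export
run_experiment <- function(scenario, n_replicates, estimators = c("naive", "pml"),
                           seed = 1L, pi_known = TRUE, mcmc_options = list(),
                           keep_estimates = TRUE) {
  estimators <- match.arg(estimators,
                          c("naive", "pml", "mcmc", "asymptotic"),
                          several.ok = TRUE)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_replicates)
  truth <- scenario_truth(scenario)
  mk <- scenario$params$model_kind
  est <- list()
  failures <- stats::setNames(integer(length(estimators)), estimators)
  for (e in estimators) est[[e]] <- list()
  need_pml <- any(c("pml", "mcmc", "asymptotic") %in% estimators)
  need_vcov <- any(c("mcmc", "asymptotic") %in% estimators)
  for (r in seq_len(n_replicates)) {
    dat <- simulate_case_control(scenario, seed = rep_seeds[r])
    if (!pi_known) dat$pi <- NULL
    if ("naive" %in% estimators) {
      cf <- tryCatch(coef(fit_naive(dat, model_kind = mk)),
                     error = function(e) NULL)
      if (is.null(cf)) failures["naive"] <- failures["naive"] + 1L
      est$naive[[r]] <- cf
    }
    if (need_pml) {
      fit <- suppressWarnings(tryCatch(
        fit_pseudo_mle(dat, scenario$spec, model_kind = mk,
                       pi = if (pi_known) scenario$pi else NULL,
                       compute_vcov = need_vcov),
        error = function(e) NULL))
      if ("pml" %in% estimators) {
        if (is.null(fit)) failures["pml"] <- failures["pml"] + 1L
        est$pml[[r]] <- if (is.null(fit)) NULL else coef(fit)
      }
      if ("mcmc" %in% estimators) {
        ch <- if (is.null(fit)) NULL else tryCatch(
          do.call(fit_bayes,
                  c(list(data = dat, spec = scenario$spec, model_kind = mk,
                         pi = if (pi_known) scenario$pi else NULL,
                         init = fit, seed = rep_seeds[r] %% 1000003L),
                    mcmc_options)),
          error = function(e) NULL)
        if (is.null(ch)) failures["mcmc"] <- failures["mcmc"] + 1L
        est$mcmc[[r]] <- if (is.null(ch)) NULL else coef(ch)
      }
      if ("asymptotic" %in% estimators) {
        ap <- if (is.null(fit)) NULL else tryCatch(
          asymptotic_posterior(fit), error = function(e) NULL)
        if (is.null(ap)) failures["asymptotic"] <- failures["asymptotic"] + 1L
        est$asymptotic[[r]] <- if (is.null(ap)) NULL else ap$mean
      }
    }
  }
  rows <- list()
  mats <- list()
  for (e in estimators) {
    ok <- !vapply(est[[e]], is.null, TRUE)
    if (!any(ok)) next
    M <- do.call(rbind, est[[e]][ok])
    mats[[e]] <- M
    common <- intersect(colnames(M), names(truth))
    for (pn in common) {
      err <- M[, pn] - truth[pn]
      rows[[length(rows) + 1L]] <- data.frame(
        estimator = e, parameter = pn, truth = unname(truth[pn]),
        bias = mean(err), rmse = sqrt(mean(err^2)), mse = mean(err^2),
        mc_se = stats::sd(err) / sqrt(sum(ok)), n_ok = sum(ok))
    }
  }
  out <- list(table = do.call(rbind, rows), truth = truth,
              failures = failures, n_replicates = n_replicates,
              seed = seed, scenario = scenario,
              estimates = if (keep_estimates) mats else NULL)
  class(out) <- "gxe_experiment"
  out
}

#' @export
print.gxe_experiment <- function(x, digits = 3, ...) {
  cat(sprintf("Replicated experiment: %d replicates (seed %d)\n",
              x$n_replicates, x$seed))
  if (any(x$failures > 0)) {
    f <- x$failures[x$failures > 0]
    cat("  failures:", paste(names(f), f, sep = " = ", collapse = ", "), "\n")
  }
  tab <- x$table
  wide <- stats::reshape(
    tab[c("estimator", "parameter", "truth", "bias", "rmse")],
    idvar = c("parameter", "truth"), timevar = "estimator",
    direction = "wide")
  names(wide) <- sub("^(bias|rmse)\\.", "\\1_", names(wide))
  print(cbind(wide[1:2], round(wide[-(1:2)], digits)), row.names = FALSE)
  invisible(x)
}
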