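# Prior specification and Metropolis-Hastings sampling of the
# pseudolikelihood-based posterior.

#' Prior specification for the Bayesian fit
#'
#' Risk coefficients (exposure and genotype main effects and their
#' interactions; not the offset \eqn{\kappa}) receive a multivariate normal
#' prior.  The exposure prevalence \eqn{\eta}, allele frequencies and --
#' when estimated -- the disease prevalence receive noninformative
#' uniform(0, 1) priors; each pairwise LD coefficient is uniform on its
#' feasibility box given the allele frequencies.
#'
#' @param mu Prior mean for the risk coefficients: a scalar (recycled) or a
#'   vector matched by position when the model dimension is known.
#' @param cov Prior covariance matrix; if `NULL`, a diagonal matrix
#'   `sd^2 I` is used.
#' @param sd Prior standard deviation used when `cov` is `NULL` (default 3,
#'   a weakly informative choice on the log-odds scale).
#' @return Object of class `prior_spec`.
#' @export
prior_spec <- function(mu = 0, cov = NULL, sd = 3) {
  if (!is.null(cov)) {
    cov <- as.matrix(cov)
    if (max(abs(cov - t(cov))) > 1e-10) stop("'cov' must be symmetric")
    ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("'cov' must be positive definite")
  }
  structure(list(mu = mu, cov = cov, sd = sd), class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  if (is.null(x$cov))
    cat(sprintf("Normal prior on risk coefficients: mean %s, sd %.3g (diagonal)\n",
                paste(format(x$mu), collapse = ","), x$sd))
  else
    cat(sprintf("Normal prior on risk coefficients: mean %s, %dx%d covariance\n",
                paste(format(x$mu), collapse = ","), nrow(x$cov), ncol(x$cov)))
  cat("uniform(0,1) priors on frequency parameters; LD uniform on its feasibility box\n")
  invisible(x)
}

# expand a prior_spec to the risk-coefficient block of a skeleton
prior_matrices <- function(prior, skel) {
  p <- length(skel$risk_idx)
  mu <- rep(prior$mu, length.out = p)
  Sg <- if (is.null(prior$cov)) diag(prior$sd^2, p) else prior$cov
  if (!all(dim(Sg) == c(p, p)))
    stop("prior covariance has dimension ", nrow(Sg), ", model needs ", p)
  list(mu = mu, cov = Sg, prec = solve(Sg),
       logdet = determinant(Sg, logarithm = TRUE)$modulus)
}

#' LD-structured prior covariance for the genotype-effect blocks
#'
#' Builds a normal-prior covariance whose genotype-effect blocks follow the
#' known LD structure: each additive block (`beta_a`, `beta_ax`) gets
#' `scale^2` times the correlation matrix of the additive codes (from
#' `V_A`), each dominance block the correlation matrix of the dominance
#' codes (from `V_D`), and all other coefficients a diagonal `scale^2`.
#' With all LD coefficients zero this reduces to the conservative diagonal
#' prior.
#'
#' @param panel A [marker_panel()].
#' @param scale Prior standard deviation of each coefficient (default 3).
#' @param model_kind `"GEM"` or `"AEM"`.
#' @param mu Prior mean (default 0).
#' @return A [prior_spec()] with a full covariance matrix laid out as
#'   `(beta_x, beta_a*, beta_ax*, [beta_d*, beta_dx*])`.
#' @export
build_ld_prior <- function(panel, scale = 3, model_kind = c("GEM", "AEM"),
                           mu = 0) {
  model_kind <- match.arg(model_kind)
  mom <- coding_moments(panel)
  cor_of <- function(V) {
    s <- sqrt(diag(V))
    C <- V / tcrossprod(s)
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10) {
      warning("singular code-covariance block: falling back to diagonal prior")
      C <- diag(nrow(C))
    }
    C
  }
  CA <- cor_of(mom$V_A)
  blocks <- list(matrix(scale^2), scale^2 * CA, scale^2 * CA)
  if (model_kind == "GEM") {
    CD <- cor_of(mom$V_D)
    blocks <- c(blocks, list(scale^2 * CD, scale^2 * CD))
  }
  p <- sum(vapply(blocks, nrow, 0L))
  Sg <- matrix(0, p, p)
  at <- 0L
  for (b in blocks) {
    idx <- at + seq_len(nrow(b))
    Sg[idx, idx] <- b
    at <- at + nrow(b)
  }
  prior_spec(mu = mu, cov = Sg)
}

#' Log posterior density (up to a constant)
#'
#' Sum of the log pseudolikelihood over subjects, the normal log prior on
#' the risk coefficients, and the uniform priors on the frequency
#' parameters; `-Inf` outside the parameter support.
#'
#' @param theta Named parameter vector on the natural scale, in the order
#'   used by `coef(fit_pseudo_mle(...))`.
#' @param data A [case_control_data()].
#' @param prior A [prior_spec()].
#' @param spec A [misclass_spec()].
#' @param model_kind `"GEM"` or `"AEM"`.
#' @param pi Known disease prevalence, or `NULL` if `theta` carries a `pi`
#'   entry.
#' @return Log posterior density (scalar; `-Inf` out of support).
#' @export
log_posterior <- function(theta, data, prior, spec,
                          model_kind = c("GEM", "AEM"), pi = NULL) {
  model_kind <- match.arg(model_kind)
  if (is.null(pi) && !is.null(data$pi) && !("pi" %in% names(theta)))
    pi <- data$pi
  skel <- pl_skeleton(model_kind, data$I, has_z = !is.null(data$Z), pi = pi)
  if (!identical(names(theta), skel$names))
    theta <- theta[skel$names]
  if (any(is.na(theta))) stop("'theta' must carry entries: ",
                              paste(skel$names, collapse = ", "))
  ctx <- make_pl_context(data)
  pm <- prior_matrices(prior, skel)
  lp_prior <- pl_log_prior(theta, skel, pm)
  if (!is.finite(lp_prior)) return(-Inf)
  ll <- pl_loglik_core(theta, ctx, skel, spec)
  if (is.null(ll)) return(-Inf)
  ll + lp_prior
}

# log prior density on the natural scale (support checks included)
pl_log_prior <- function(theta, skel, pm) {
  b <- pl_bounds(theta, skel)
  v <- theta[b$idx]
  if (any(v <= b$lo) || any(v >= b$hi)) return(-Inf)
  d <- theta[skel$risk_idx] - pm$mu
  lp <- -0.5 * (length(d) * log(2 * pi) + pm$logdet +
                  sum(d * (pm$prec %*% d)))
  # LD coefficients: conditionally uniform on their feasibility box
  if (!is.null(skel$blk$delta)) {
    p <- theta[skel$blk$p_m]
    for (r in seq_along(skel$blk$delta)) {
      bb <- ld_bounds(p[skel$pairs[r, 1L]], p[skel$pairs[r, 2L]])
      lp <- lp - log(bb[2L] - bb[1L])
    }
  }
  lp
}

#' Metropolis-Hastings sampling of the pseudolikelihood posterior
#'
#' Random-walk Metropolis-Hastings on an unconstrained reparameterization
#' (logits for probabilities; a logit map onto the feasibility box for each
#' LD coefficient) with the appropriate Jacobian correction.  The proposal
#' is a multivariate normal whose shape is taken from the pseudo-MLE
#' sandwich covariance (falling back to a diagonal) and whose global scale
#' adapts toward an acceptance rate of 0.2-0.4 during burn-in, frozen
#' afterwards.  Point estimates are posterior means.
#'
#' @param data A [case_control_data()].
#' @param spec A [misclass_spec()].
#' @param prior A [prior_spec()] (default: mean-zero normal with sd 3).
#' @param model_kind `"GEM"` or `"AEM"`.
#' @param pi Known disease prevalence `pr(D = 1)`, or `NULL` to estimate it.
#' @param n_iter Total iterations (default 20000).
#' @param burn_in Burn-in iterations discarded from summaries (default 5000).
#' @param seed Integer seed; the chain is reproducible given the seed.
#' @param init Either a `gxe_pml` fit (default: fitted internally), a named
#'   parameter vector, or `"zero"` for a neutral start.
#' @param thin Keep every `thin`-th draw (default 1).
#' @return Object of class `gxe_mcmc`: `draws` (matrix of post-burn-in
#'   draws on the natural scale), `acceptance_rate`, `summaries`, `seed`.
#'   `coef()` returns posterior means.
#' @export
fit_bayes <- function(data, spec, prior = prior_spec(),
                      model_kind = c("GEM", "AEM"), pi = NULL,
                      n_iter = 20000L, burn_in = 5000L, seed = 1L,
                      init = NULL, thin = 1L) {
  model_kind <- match.arg(model_kind)
  if (n_iter <= burn_in) stop("'n_iter' must exceed 'burn_in'")
  if (is.null(pi) && !is.null(data$pi)) pi <- data$pi
  skel <- pl_skeleton(model_kind, data$I, has_z = !is.null(data$Z), pi = pi)
  ctx <- make_pl_context(data)
  pm <- prior_matrices(prior, skel)

  pml <- NULL
  if (is.null(init)) {
    pml <- suppressWarnings(fit_pseudo_mle(data, spec, model_kind = model_kind,
                                           pi = pi, compute_vcov = TRUE))
    theta0 <- coef(pml)
  } else if (inherits(init, "gxe_pml")) {
    pml <- init
    theta0 <- coef(pml)
  } else if (identical(init, "zero")) {
    theta0 <- pl_start_values(data, skel, spec)
    theta0[skel$risk_idx] <- 0
    theta0["kappa"] <- 0
  } else {
    theta0 <- init[skel$names]
    if (any(is.na(theta0))) stop("'init' must name every parameter")
  }

  # proposal shape on the unconstrained scale; when a pseudo-MLE fit is
  # available, both the starting point and the proposal are taken from the
  # Gaussian posterior approximation under this prior (with a weak prior
  # this is essentially the pseudo-MLE and its sandwich covariance)
  p <- skel$n_par
  Sg_u <- diag(0.05^2, p)
  Sg_nat <- NULL
  if (!is.null(pml) && !is.null(pml$vcov)) {
    ap <- tryCatch(asymptotic_posterior(pml, prior = prior),
                   error = function(e) NULL)
    if (!is.null(ap)) {
      Sg_nat <- ap$cov
      cand <- ap$mean
      b <- pl_bounds(cand, skel)
      eps <- 1e-6 * (b$hi - b$lo)
      cand[b$idx] <- pmin(pmax(cand[b$idx], b$lo + eps), b$hi - eps)
      theta0 <- cand
    } else Sg_nat <- pml$vcov
  }
  u0 <- pl_to_unconstrained(theta0, skel)
  if (!is.null(Sg_nat)) {
    Jm <- matrix(0, p, p)
    h <- 1e-5
    for (j in seq_len(p)) {
      up <- u0; up[j] <- u0[j] + h
      um <- u0; um[j] <- u0[j] - h
      Jm[, j] <- (pl_from_unconstrained(up, skel) -
                    pl_from_unconstrained(um, skel)) / (2 * h)
    }
    Ji <- tryCatch(solve(Jm), error = function(e) NULL)
    if (!is.null(Ji)) {
      S <- Ji %*% Sg_nat %*% t(Ji)
      S <- (S + t(S)) / 2
      ev <- eigen(S, symmetric = TRUE)
      if (min(ev$values) > 0) Sg_u <- S
      else Sg_u <- ev$vectors %*% diag(pmax(ev$values, 1e-8)) %*% t(ev$vectors)
    }
  }
  L <- t(chol(Sg_u + diag(1e-10, p)))

  target <- function(u) {
    th <- pl_from_unconstrained(u, skel, jacobian = TRUE)
    lp <- pl_log_prior(th, skel, pm)
    if (!is.finite(lp)) return(-Inf)
    ll <- pl_loglik_core(th, ctx, skel, spec)
    if (is.null(ll)) return(-Inf)
    ll + lp + attr(th, "log_jacobian")
  }

  set.seed(seed)
  scale <- 2.38 / sqrt(p)
  u <- u0
  lt <- target(u)
  if (!is.finite(lt)) stop("initial state has zero posterior density")
  keep <- floor((n_iter - burn_in) / thin)
  draws <- matrix(NA_real_, keep, p, dimnames = list(NULL, skel$names))
  acc_window <- 0L; acc_total <- 0L; kept <- 0L
  adapt_every <- 100L
  for (it in seq_len(n_iter)) {
    prop <- u + scale * as.vector(L %*% stats::rnorm(p))
    lt_prop <- target(prop)
    if (is.finite(lt_prop) && log(stats::runif(1)) < lt_prop - lt) {
      u <- prop; lt <- lt_prop
      acc_window <- acc_window + 1L
      if (it > burn_in) acc_total <- acc_total + 1L
    }
    if (it <= burn_in && it %% adapt_every == 0L) {
      rate <- acc_window / adapt_every
      if (rate < 0.2) scale <- scale * exp(-0.5 * (0.3 - rate))
      if (rate > 0.4) scale <- scale * exp(0.5 * (rate - 0.3))
      acc_window <- 0L
    }
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- pl_from_unconstrained(u, skel)
    }
  }
  acc_rate <- acc_total / (n_iter - burn_in)
  if (acc_rate < 0.01 || acc_rate > 0.99)
    warning(sprintf(
      "pathological post-adaptation acceptance rate %.3f; inspect the chain",
      acc_rate))
  qs <- t(apply(draws, 2L, stats::quantile, c(0.025, 0.5, 0.975)))
  summaries <- data.frame(mean = colMeans(draws),
                          sd = apply(draws, 2L, stats::sd),
                          q2.5 = qs[, 1L], median = qs[, 2L], q97.5 = qs[, 3L])
  structure(list(draws = draws, acceptance_rate = acc_rate,
                 summaries = summaries, seed = seed, n_iter = n_iter,
                 burn_in = burn_in, thin = thin, scale = scale,
                 skel = skel, prior = prior, spec = spec, init = theta0),
            class = "gxe_mcmc")
}

#' @export
coef.gxe_mcmc <- function(object, ...) {
  stats::setNames(object$summaries$mean, rownames(object$summaries))
}

#' @export
print.gxe_mcmc <- function(x, ...) {
  cat(sprintf(
    "Metropolis-Hastings posterior: %d iterations (%d burn-in), acceptance %.2f, seed %d\n",
    x$n_iter, x$burn_in, x$acceptance_rate, x$seed))
  print(round(x$summaries, 4))
  invisible(x)
}

#' @export
summary.gxe_mcmc <- function(object, ...) object$summaries

#' Split-chain potential-scale-reduction diagnostic
#'
#' Splits each parameter's chain in two halves and computes the
#' potential-scale-reduction factor; values near 1 indicate stationarity.
#'
#' @param object A `gxe_mcmc` fit.
#' @return Named vector of split-R-hat values.
#' @export
split_rhat <- function(object) {
  draws <- object$draws
  n <- nrow(draws)
  half <- floor(n / 2)
  apply(draws, 2L, function(x) {
    ch <- cbind(x[seq_len(half)], x[half + seq_len(half)])
    m <- colMeans(ch)
    W <- mean(apply(ch, 2L, stats::var))
    B <- half * stats::var(m)
    if (W <= 0) return(1)
    sqrt(((half - 1) / half * W + B / half) / W)
  })
}

#' Trace plot of posterior draws
#'
#' @param x A `gxe_mcmc` fit.
#' @param pars Parameters to plot (default: first four).
#' @param ... Passed to `plot`.
#' @export
plot.gxe_mcmc <- function(x, pars = NULL, ...) {
  if (is.null(pars)) pars <- utils::head(colnames(x$draws), 4L)
  op <- graphics::par(mfrow = c(length(pars), 1L),
                      mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  for (p in pars)
    plot(x$draws[, p], type = "l", ylab = p, xlab = "", ...)
  invisible(x)
}
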