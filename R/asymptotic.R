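# Large-sample Gaussian approximation of the pseudolikelihood posterior:
# per-subject scores, the case-control Lambda correction, and the
# precision-weighted posterior mean and covariance.

#' Per-subject score vectors of the log pseudolikelihood
#'
#' Numerical gradient (central differences on the natural scale, steps kept
#' inside the parameter support) of each subject's log pseudolikelihood
#' contribution, evaluated at `params`.  At the pseudo-MLE the column means
#' are approximately zero.
#'
#' @param fit A `gxe_pml` fit, or a [case_control_data()] (then `params`,
#'   `spec`, `model_kind`, `pi` must be given).
#' @param params Named parameter vector (natural scale); defaults to
#'   `coef(fit)`.
#' @param spec,model_kind,pi Model settings when `fit` is a data set.
#' @param h Relative finite-difference step (default 1e-5).
#' @return An `n x p` matrix of scores with parameter names as columns.
#' @export
score_matrix <- function(fit, params = NULL, spec = NULL,
                         model_kind = "GEM", pi = NULL, h = 1e-5) {
  if (inherits(fit, "gxe_pml")) {
    data <- fit$data; skel <- fit$skel
    if (is.null(spec)) spec <- fit$spec
    if (is.null(params)) params <- coef(fit)
  } else {
    data <- fit
    if (is.null(spec) || is.null(params))
      stop("supply 'params' and 'spec' when 'fit' is a data set")
    if (is.null(pi) && !is.null(data$pi) && !("pi" %in% names(params)))
      pi <- data$pi
    skel <- pl_skeleton(model_kind, data$I, has_z = !is.null(data$Z), pi = pi)
    params <- params[skel$names]
    if (any(is.na(params))) stop("'params' must name every model parameter")
  }
  b <- pl_bounds(params, skel)
  v <- params[b$idx]
  if (any(v <= b$lo + 1e-12) || any(v >= b$hi - 1e-12))
    stop("parameters on the boundary of the support: scores undefined")
  ctx <- make_pl_context(data)
  pl_scores(params, ctx, skel, spec, h = h)
}

#' Case-control score correction matrix
#'
#' \eqn{\hat\Lambda = \sum_d (n_d/n) \bar\Psi_d \bar\Psi_d^T}, where
#' \eqn{\bar\Psi_d} is the mean score vector within disease stratum `d`.
#' Under retrospective sampling the within-stratum score means are nonzero
#' even at the truth, and this matrix corrects the information identity.
#'
#' @param scores Matrix of per-subject scores ([score_matrix()]).
#' @param d Vector of disease categories, one per score row.
#' @return A `p x p` positive semidefinite matrix.
#' @export
lambda_correction <- function(scores, d) {
  if (nrow(scores) != length(d)) stop("'d' must have one entry per score row")
  n <- length(d)
  L <- matrix(0, ncol(scores), ncol(scores),
              dimnames = list(colnames(scores), colnames(scores)))
  for (k in unique(d)) {
    sel <- d == k
    if (!any(sel)) stop("empty disease stratum")
    mu <- colMeans(scores[sel, , drop = FALSE])
    L <- L + (sum(sel) / n) * tcrossprod(mu)
  }
  L
}

#' Gaussian approximation of the pseudolikelihood posterior
#'
#' Approximates the posterior by a normal distribution whose precision is
#' the sum of the data precision and the prior precision:
#' \deqn{\hat\Sigma_n = \{n\,\hat I + J(\Theta_0)\}^{-1}, \qquad
#'   \hat M_n = \hat\Sigma_n \{n\,\hat I\, \hat\Theta_n + J(\Theta_0)\Theta_0\},}
#' where \eqn{\hat\Theta_n} is the pseudo-MLE, \eqn{\Theta_0} the prior
#' mode, and \eqn{J} the negative Hessian of the log prior (the prior
#' precision on the risk-coefficient block, zero for the flat blocks).
#'
#' Three estimators of the per-subject information \eqn{\hat I} are
#' offered: `"sandwich"` (default) takes \eqn{n \hat I} to be the inverse
#' of the pseudo-MLE sandwich covariance, so the flat-prior approximation
#' reproduces the frequentist covariance exactly; `"score"` uses
#' \eqn{\hat\Sigma_\Psi + \hat\Lambda} (within-stratum score covariance
#' plus the case-control correction); `"hessian"` uses the observed
#' information \eqn{-n^{-1}\partial^2 \log L / \partial\Theta^2}.
#'
#' @param fit A `gxe_pml` fit (with `compute_vcov = TRUE`).
#' @param prior A [prior_spec()]; `NULL` gives the flat-prior (pure
#'   large-sample) approximation.
#' @param info Information estimator, see Details.
#' @return Object of class `gxe_asymp` with `mean`, `cov`, `se`, and
#'   `pieces` (the information matrix `I_hat`, prior precision `J`,
#'   `Lambda`, and score covariance) retained for audit.
#' @export
asymptotic_posterior <- function(fit, prior = prior_spec(),
                                 info = c("sandwich", "score", "hessian")) {
  if (!inherits(fit, "gxe_pml")) stop("'fit' must be a gxe_pml object")
  if (is.null(fit$scores)) stop("refit with compute_vcov = TRUE")
  info <- match.arg(info)
  skel <- fit$skel
  n <- fit$n
  theta_hat <- coef(fit)
  I_hat <- switch(info,
    sandwich = solve_psd(fit$vcov) / n,
    score = fit$score_cov + fit$lambda,
    hessian = {
      ctx <- make_pl_context(fit$data)
      fn <- function(th) {
        ll <- pl_loglik_core(th, ctx, skel, fit$spec)
        if (is.null(ll)) stop("Hessian evaluation left the parameter support")
        ll
      }
      H <- numeric_hessian(fn, theta_hat, skel)
      -(H + t(H)) / (2 * n)
    })
  p <- skel$n_par
  J <- matrix(0, p, p, dimnames = list(skel$names, skel$names))
  theta0 <- numeric(p)
  if (!is.null(prior)) {
    pm <- prior_matrices(prior, skel)
    J[skel$risk_idx, skel$risk_idx] <- pm$prec
    theta0[skel$risk_idx] <- pm$mu
  }
  prec <- n * I_hat + J
  Sg <- solve_psd(prec)
  Sg <- (Sg + t(Sg)) / 2
  Mn <- as.vector(Sg %*% (n * I_hat %*% theta_hat + J %*% theta0))
  names(Mn) <- skel$names
  dimnames(Sg) <- list(skel$names, skel$names)
  structure(list(mean = Mn, cov = Sg, se = sqrt(pmax(diag(Sg), 0)),
                 pieces = list(I_hat = I_hat, J = J, Lambda = fit$lambda,
                               score_cov = fit$score_cov, theta0 = theta0,
                               n = n, info = info),
                 theta_hat = theta_hat),
            class = "gxe_asymp")
}

# central-difference Hessian with steps kept inside the support
numeric_hessian <- function(fn, theta, skel, h = 1e-4) {
  p <- length(theta)
  b <- pl_bounds(theta, skel)
  step <- h * (1 + abs(theta))
  bi <- match(seq_len(p), b$idx)
  ok <- !is.na(bi)
  step[ok] <- pmin(step[ok], (theta[ok] - b$lo[bi[ok]]) / 3,
                   (b$hi[bi[ok]] - theta[ok]) / 3)
  H <- matrix(0, p, p)
  f0 <- fn(theta)
  for (i in seq_len(p)) for (j in i:p) {
    if (i == j) {
      tp <- theta; tp[i] <- theta[i] + step[i]
      tm <- theta; tm[i] <- theta[i] - step[i]
      H[i, i] <- (fn(tp) - 2 * f0 + fn(tm)) / step[i]^2
    } else {
      tpp <- theta; tpp[i] <- theta[i] + step[i]; tpp[j] <- theta[j] + step[j]
      tpm <- theta; tpm[i] <- theta[i] + step[i]; tpm[j] <- theta[j] - step[j]
      tmp <- theta; tmp[i] <- theta[i] - step[i]; tmp[j] <- theta[j] + step[j]
      tmm <- theta; tmm[i] <- theta[i] - step[i]; tmm[j] <- theta[j] - step[j]
      H[i, j] <- H[j, i] <-
        (fn(tpp) - fn(tpm) - fn(tmp) + fn(tmm)) / (4 * step[i] * step[j])
    }
  }
  H
}

#' @export
coef.gxe_asymp <- function(object, ...) object$mean

#' @export
vcov.gxe_asymp <- function(object, ...) object$cov

#' @export
print.gxe_asymp <- function(x, ...) {
  cat(sprintf("Asymptotic posterior approximation (info = %s)\n",
              x$pieces$info))
  print(round(cbind(mean = x$mean, se = x$se), 4))
  invisible(x)
}

#' @export
confint.gxe_asymp <- function(object, parm, level = 0.95, ...) {
  if (missing(parm)) parm <- names(object$mean)
  q <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(object$mean[parm] - q * object$se[parm],
               object$mean[parm] + q * object$se[parm])
  colnames(out) <- sprintf("%.1f %%",
                           c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  out
}
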