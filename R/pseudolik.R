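# Retrospective pseudolikelihood for case-control data with a
# misclassified binary exposure: parameter bookkeeping, the vectorized
# log-pseudolikelihood engine, the pseudo-MLE with sandwich variances, and
# the naive prospective-logistic comparator.
#
# All likelihood kernels are computed in log space (log-sum-exp for sums),
# so ratios of astronomically large exponentials never materialize.

## ---- parameter skeleton and transforms -----------------------------------

# Describes the free-parameter vector of the binary-disease (K = 1) fit:
# kappa, beta_x, beta_a*, beta_ax*, [beta_d*, beta_dx*], [beta_z, beta_az*,
# beta_dz*], eta, p_m*, delta_*, [pi].  Frequencies and prevalence are
# handled on logit scales, LD coefficients via a logit map onto their
# feasibility box given the current allele frequencies.
pl_skeleton <- function(model_kind, I, has_z = FALSE, pi = NULL) {
  nm <- c("kappa", "beta_x",
          paste0("beta_a", seq_len(I)), paste0("beta_ax", seq_len(I)))
  if (model_kind == "GEM")
    nm <- c(nm, paste0("beta_d", seq_len(I)), paste0("beta_dx", seq_len(I)))
  if (has_z) {
    nm <- c(nm, "beta_z", paste0("beta_az", seq_len(I)))
    if (model_kind == "GEM") nm <- c(nm, paste0("beta_dz", seq_len(I)))
  }
  nm <- c(nm, "eta", paste0("p_m", seq_len(I)))
  pairs <- NULL
  if (I > 1L) {
    pairs <- t(utils::combn(I, 2L))
    nm <- c(nm, paste0("delta_", pairs[, 1L], pairs[, 2L]))
  }
  pi_known <- !is.null(pi)
  if (!pi_known) nm <- c(nm, "pi")
  blk <- list()
  pos <- function(x) match(x, nm)
  blk$kappa <- pos("kappa"); blk$beta_x <- pos("beta_x")
  blk$beta_a <- pos(paste0("beta_a", seq_len(I)))
  blk$beta_ax <- pos(paste0("beta_ax", seq_len(I)))
  if (model_kind == "GEM") {
    blk$beta_d <- pos(paste0("beta_d", seq_len(I)))
    blk$beta_dx <- pos(paste0("beta_dx", seq_len(I)))
  }
  if (has_z) {
    blk$beta_z <- pos("beta_z")
    blk$beta_az <- pos(paste0("beta_az", seq_len(I)))
    if (model_kind == "GEM") blk$beta_dz <- pos(paste0("beta_dz", seq_len(I)))
  }
  blk$eta <- pos("eta"); blk$p_m <- pos(paste0("p_m", seq_len(I)))
  if (I > 1L) blk$delta <- pos(paste0("delta_", pairs[, 1L], pairs[, 2L]))
  if (!pi_known) blk$pi <- pos("pi")
  risk_idx <- c(blk$beta_x, blk$beta_a, blk$beta_ax, blk$beta_d, blk$beta_dx,
                blk$beta_z, blk$beta_az, blk$beta_dz)
  list(names = nm, n_par = length(nm), blk = blk, model_kind = model_kind,
       I = I, has_z = has_z, pi_known = pi_known,
       pi_value = if (pi_known) pi else NA_real_, pairs = pairs,
       risk_idx = risk_idx)
}

# indices of box-constrained coordinates and their (possibly theta-dependent)
# bounds; used by both transforms and finite-difference step control
pl_bounds <- function(theta, skel) {
  blk <- skel$blk
  idx <- c(blk$eta, blk$p_m, blk$pi)
  lo <- rep(0, length(idx)); hi <- rep(1, length(idx))
  if (!is.null(blk$delta)) {
    p <- theta[blk$p_m]
    for (r in seq_len(nrow(skel$pairs))) {
      b <- ld_bounds(p[skel$pairs[r, 1L]], p[skel$pairs[r, 2L]])
      idx <- c(idx, blk$delta[r]); lo <- c(lo, b[1L]); hi <- c(hi, b[2L])
    }
  }
  list(idx = idx, lo = lo, hi = hi)
}

pl_to_unconstrained <- function(theta, skel) {
  u <- theta
  blk <- skel$blk
  for (j in c(blk$eta, blk$p_m, blk$pi)) u[j] <- stats::qlogis(theta[j])
  if (!is.null(blk$delta)) {
    p <- theta[blk$p_m]
    for (r in seq_along(blk$delta)) {
      b <- ld_bounds(p[skel$pairs[r, 1L]], p[skel$pairs[r, 2L]])
      f <- (theta[blk$delta[r]] - b[1L]) / (b[2L] - b[1L])
      u[blk$delta[r]] <- stats::qlogis(min(max(f, 1e-12), 1 - 1e-12))
    }
  }
  u
}

# inverse transform; optionally also the log-Jacobian log|d theta / d u|
# (triangular: allele frequencies feed the LD bounds but not vice versa)
pl_from_unconstrained <- function(u, skel, jacobian = FALSE) {
  theta <- u
  blk <- skel$blk
  lj <- 0
  for (j in c(blk$eta, blk$p_m, blk$pi)) {
    s <- stats::plogis(u[j])
    theta[j] <- s
    if (jacobian) lj <- lj + log(s) + log1p(-s)
  }
  if (!is.null(blk$delta)) {
    p <- theta[blk$p_m]
    for (r in seq_along(blk$delta)) {
      b <- ld_bounds(p[skel$pairs[r, 1L]], p[skel$pairs[r, 2L]])
      s <- stats::plogis(u[blk$delta[r]])
      theta[blk$delta[r]] <- b[1L] + (b[2L] - b[1L]) * s
      if (jacobian) lj <- lj + log(b[2L] - b[1L]) + log(s) + log1p(-s)
    }
  }
  if (jacobian) attr(theta, "log_jacobian") <- lj
  theta
}

## ---- evaluation context ---------------------------------------------------

# Groups the sample by (z value, D, X, observed genotype pattern) once, so
# the per-iteration cost of the likelihood is independent of n.
make_pl_context <- function(data) {
  if (data$K != 1L)
    stop("the shipped estimators support binary disease status (K = 1)")
  I <- data$I
  if (I > 10L)
    stop(sprintf(
      "cannot enumerate %d markers (3^%d genotype vectors); cap is 10 markers", I, I))
  G <- data$G
  key <- apply(G, 1L, function(r) paste(ifelse(is.na(r), "N", r), collapse = ""))
  pats_key <- unique(key)
  pid <- match(key, pats_key)
  pats <- G[match(pats_key, key), , drop = FALSE]
  if (is.vector(pats)) pats <- matrix(pats, ncol = I)
  gp <- genotype_patterns(I)
  C <- matrix(0, nrow(pats), nrow(gp))
  for (p in seq_len(nrow(pats))) {
    ok <- rep(TRUE, nrow(gp))
    for (i in seq_len(I)) if (!is.na(pats[p, i])) ok <- ok & gp[, i] == pats[p, i]
    C[p, ok] <- 1
  }
  zv <- if (is.null(data$Z)) rep(0, length(data$D)) else data$Z
  zu <- sort(unique(zv))
  zid <- match(zv, zu)
  gk <- paste(zid, data$D, data$X, pid)
  gu <- !duplicated(gk)
  groups <- data.frame(zid = zid[gu], d = data$D[gu], x = data$X[gu],
                       pid = pid[gu],
                       count = as.vector(table(factor(gk, levels = gk[gu]))))
  list(I = I, n = length(data$D), n_d = data$n_d,
       A27 = gp - 1L, gp = gp, C = C, groups = groups,
       z_values = zu, has_z = !is.null(data$Z),
       subject_group = match(gk, gk[gu]))
}

# Core evaluator.  Returns the total log pseudolikelihood, or (per_group =
# TRUE) the per-group log L so callers can build per-subject quantities.
# Returns NULL when theta implies an invalid genotype distribution.
pl_loglik_core <- function(theta, ctx, skel, spec, per_group = FALSE) {
  blk <- skel$blk
  I <- skel$I
  p <- theta[blk$p_m]
  if (any(p <= 0) || any(p >= 1)) return(NULL)
  eta <- theta[blk$eta]
  if (eta <= 0 || eta >= 1) return(NULL)
  pi1 <- if (skel$pi_known) skel$pi_value else theta[blk$pi]
  if (pi1 <= 0 || pi1 >= 1) return(NULL)
  Dm <- matrix(0, I, I)
  if (!is.null(blk$delta)) {
    for (r in seq_along(blk$delta)) {
      i <- skel$pairs[r, 1L]; j <- skel$pairs[r, 2L]
      Dm[i, j] <- Dm[j, i] <- theta[blk$delta[r]]
    }
  }
  pg <- genotype_prob_fast(p, Dm)
  if (is.null(pg)) return(NULL)
  lpg <- log(pmax(pg, 1e-300))

  A27 <- ctx$A27
  q <- 1 - p
  B27 <- sapply(seq_len(I), function(i)
    c(-p[i]^2, p[i] * q[i], -q[i]^2)[ctx$gp[, i] + 1L])
  if (is.vector(B27)) B27 <- matrix(B27, ncol = I)

  kappa <- theta[blk$kappa]
  beta0 <- kappa - log(ctx$n_d[2L] / ctx$n_d[1L]) + stats::qlogis(pi1)
  mg0 <- as.vector(A27 %*% theta[blk$beta_a])
  mg1x <- theta[blk$beta_x] + as.vector(A27 %*% theta[blk$beta_ax])
  if (skel$model_kind == "GEM") {
    mg0 <- mg0 + as.vector(B27 %*% theta[blk$beta_d])
    mg1x <- mg1x + as.vector(B27 %*% theta[blk$beta_dx])
  }
  lt1 <- log(eta); lt0 <- log1p(-eta)
  # log p_miss[x + 1, t + 1]
  lpm <- log(matrix(c(p_miss(0, 0, spec), p_miss(0, 1, spec),
                      p_miss(1, 0, spec), p_miss(1, 1, spec)),
                    2L, 2L, byrow = TRUE))

  g <- ctx$groups
  total <- 0
  out <- numeric(nrow(g))
  for (zi in seq_along(ctx$z_values)) {
    zv <- ctx$z_values[zi]
    m0 <- mg0; m1 <- mg0 + mg1x
    if (ctx$has_z) {
      zadd <- zv * (theta[blk$beta_z] + as.vector(A27 %*% theta[blk$beta_az]))
      if (skel$model_kind == "GEM")
        zadd <- zadd + zv * as.vector(B27 %*% theta[blk$beta_dz])
      m0 <- m0 + zadd; m1 <- m1 + zadd
    }
    l0 <- log1pexp(beta0 + m0); l1 <- log1pexp(beta0 + m1)
    # columns: (k=0,t=0), (k=0,t=1), (k=1,t=0), (k=1,t=1)
    S <- cbind(-l0 + lpg, -l1 + lpg, kappa + m0 - l0 + lpg, kappa + m1 - l1 + lpg)
    logden <- logsumexp(c(S[, 1L] + lt0, S[, 2L] + lt1,
                          S[, 3L] + lt0, S[, 4L] + lt1))
    M <- apply(S, 2L, max)
    PS <- log(ctx$C %*% sweep(exp(sweep(S, 2L, M, "-")), 1L, 1, "*"))
    PS <- sweep(PS, 2L, M, "+")
    sel <- which(g$zid == zi)
    gd <- g$d[sel]; gx <- g$x[sel]; gp_ <- g$pid[sel]
    a <- PS[cbind(gp_, 2L * gd + 1L)] + lpm[gx + 1L, 1L] + lt0
    b <- PS[cbind(gp_, 2L * gd + 2L)] + lpm[gx + 1L, 2L] + lt1
    ll <- lse2(a, b) - logden
    out[sel] <- ll
    total <- total + sum(g$count[sel] * ll)
  }
  if (per_group) out else total
}

## ---- reference (pointwise) pseudolikelihood ------------------------------

#' Log pseudolikelihood of one observation
#'
#' Evaluates, for a single subject, the log of
#' \deqn{pr(D = d, G = g, X = x | Z = z, R = 1) =
#'   \frac{\sum_{t^*} S(d, g, t^*, z)\, p_{miss}(x | t^*)\, f_T(t^* | z)}
#'        {\sum_{k^*} \sum_{t^*} \sum_{g' \in \mathcal{G}}
#'          S(k^*, g', t^*, z)\, f_T(t^* | z)}.}
#' Missing genotype entries are marginalized: the numerator additionally
#' sums over all genotype completions compatible with the observed calls,
#' weighted through \eqn{pr(g; \Theta)} inside `S`.
#'
#' This reference implementation enumerates the sums directly via
#' [s_kernel()]; the fitting functions use an equivalent vectorized
#' evaluator.
#'
#' @param d Disease category (0..K).
#' @param g Genotype dosage vector; `NA` entries allowed.
#' @param x Observed exposure (0/1).
#' @param z Optional covariate value.
#' @param params A [risk_params()].
#' @param kappa,beta0 Offset and intercept vectors (length `K`).
#' @param eta Exposure prevalence \eqn{pr(T = 1)}.
#' @param spec A [misclass_spec()].
#' @param panel A [marker_panel()].
#' @return Log probability (scalar).
#' @export
log_pseudolik_obs <- function(d, g, x, z = NULL, params, kappa, beta0, eta,
                              spec, panel) {
  gd <- genotype_distribution(panel)
  lt <- c(log1p(-eta), log(eta))
  compat <- rep(TRUE, nrow(gd$genotypes))
  for (i in seq_along(g))
    if (!is.na(g[i])) compat <- compat & gd$genotypes[, i] == g[i]
  if (!any(compat)) stop("no genotype completion is compatible with 'g'")
  num_terms <- c()
  for (gi in which(compat)) for (t in 0:1)
    num_terms <- c(num_terms,
                   s_kernel(d, gd$genotypes[gi, ], t, z, params, panel,
                            kappa, beta0) +
                     log(p_miss(x, t, spec)) + lt[t + 1L])
  den_terms <- c()
  for (k in 0:params$K) for (gi in seq_len(nrow(gd$genotypes))) for (t in 0:1)
    den_terms <- c(den_terms,
                   s_kernel(k, gd$genotypes[gi, ], t, z, params, panel,
                            kappa, beta0) + lt[t + 1L])
  logsumexp(num_terms) - logsumexp(den_terms)
}

## ---- pseudo-MLE -----------------------------------------------------------

# central-difference gradient on the unconstrained scale
pl_num_grad <- function(fn, u, h = 1e-6) {
  p <- length(u)
  gr <- numeric(p)
  for (j in seq_len(p)) {
    hj <- h * (1 + abs(u[j]))
    up <- u; up[j] <- u[j] + hj
    um <- u; um[j] <- u[j] - hj
    gr[j] <- (fn(up) - fn(um)) / (2 * hj)
  }
  gr
}

# per-subject score matrix on the natural scale (central differences with
# steps kept inside the parameter support)
pl_scores <- function(theta, ctx, skel, spec, h = 1e-5) {
  p <- length(theta)
  bounds <- pl_bounds(theta, skel)
  S <- matrix(0, ctx$n, p, dimnames = list(NULL, skel$names))
  for (j in seq_len(p)) {
    hj <- h * (1 + abs(theta[j]))
    bi <- match(j, bounds$idx)
    if (!is.na(bi))
      hj <- min(hj, (theta[j] - bounds$lo[bi]) / 2,
                (bounds$hi[bi] - theta[j]) / 2)
    tp <- theta; tp[j] <- theta[j] + hj
    tm <- theta; tm[j] <- theta[j] - hj
    lp <- pl_loglik_core(tp, ctx, skel, spec, per_group = TRUE)
    lm <- pl_loglik_core(tm, ctx, skel, spec, per_group = TRUE)
    if (is.null(lp) || is.null(lm))
      stop("score evaluation stepped outside the parameter support")
    S[, j] <- (lp[ctx$subject_group] - lm[ctx$subject_group]) / (2 * hj)
  }
  S
}

solve_psd <- function(A, ridge = 1e-10) {
  out <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(out)) {
    warning("singular matrix: using ridge-regularized inverse")
    out <- solve(A + diag(ridge * max(diag(A)), nrow(A)))
  }
  out
}

pl_start_values <- function(data, skel, spec) {
  theta <- numeric(skel$n_par)
  names(theta) <- skel$names
  blk <- skel$blk
  ctrl <- data$G[data$D == 0L, , drop = FALSE]
  pan <- tryCatch(estimate_panel(ctrl), error = function(e) NULL)
  p0 <- if (is.null(pan)) rep(0.5, skel$I) else pan$p_m
  theta[blk$p_m] <- pmin(pmax(p0, 0.02), 0.98)
  if (!is.null(blk$delta)) {
    for (r in seq_along(blk$delta)) {
      d0 <- if (is.null(pan)) 0 else
        pan$delta[skel$pairs[r, 1L], skel$pairs[r, 2L]]
      b <- ld_bounds(theta[blk$p_m][skel$pairs[r, 1L]],
                     theta[blk$p_m][skel$pairs[r, 2L]])
      theta[blk$delta[r]] <- min(max(d0, 0.8 * b[1L]), 0.8 * b[2L])
    }
  }
  eta0 <- (mean(data$X) - spec$xi1) / (1 - spec$xi0 - spec$xi1)
  theta[blk$eta] <- min(max(eta0, 0.05), 0.95)
  if (!skel$pi_known) theta[blk$pi] <- 0.01
  nv <- tryCatch(fit_naive(data, model_kind = skel$model_kind),
                 error = function(e) NULL)
  if (!is.null(nv)) {
    cf <- stats::coef(nv)
    for (nm in intersect(names(cf), skel$names))
      if (is.finite(cf[nm])) theta[nm] <- cf[nm]
  }
  theta
}

#' Pseudo-maximum-likelihood estimation
#'
#' Maximizes the retrospective pseudolikelihood over the risk parameters
#' (offset \eqn{\kappa}, exposure/genotype main effects and interactions),
#' the true-exposure prevalence \eqn{\eta}, the genotype-distribution
#' parameters (allele frequencies, pairwise LD), and -- when the disease
#' prevalence is not supplied -- \eqn{\pi = pr(D = 1)}.  Misclassification
#' probabilities are treated as known.  Optimization runs on an
#' unconstrained reparameterization (logits for probabilities, a logit map
#' onto the feasibility box for each LD coefficient) with a quasi-Newton
#' method and numerical gradients.
#'
#' Standard errors are the sandwich \eqn{\hat A^{-1} \hat\Sigma \hat
#' A^{-1} / n}, where \eqn{\hat\Sigma = \sum_d (n_d/n)
#' \widehat{Cov}_d(\Psi)} is the within-stratum covariance of the
#' per-subject scores (the variance of the total score under case-control
#' sampling is \eqn{n\hat\Sigma}) and \eqn{\hat A = \hat\Sigma +
#' \hat\Lambda} estimates the information, with the case-control correction
#' \eqn{\hat\Lambda = \sum_d (n_d/n)\bar\Psi_d \bar\Psi_d^T} built from the
#' within-stratum mean scores.
#'
#' @param data A [case_control_data()] object.
#' @param spec A [misclass_spec()] (known misclassification probabilities).
#' @param model_kind `"GEM"` (additive + dominance) or `"AEM"` (additive
#'   only).
#' @param pi Known disease prevalence `pr(D = 1)`; `NULL` (default, unless
#'   `data$pi` is set) estimates it.
#' @param start Optional named vector of starting values on the natural
#'   scale; defaults to moment estimates plus the naive logistic fit.
#' @param compute_vcov Compute scores and the sandwich covariance (default
#'   `TRUE`; skip for speed in large simulation sweeps).
#' @param control List of optimizer settings: `maxit` (default 500),
#'   `gtol` (mean-score convergence tolerance, default 1e-6), `restarts`
#'   (maximum quasi-Newton restarts, default 4).
#' @return Object of class `gxe_pml` with components `coef`, `vcov`,
#'   `loglik`, `convergence`, `scores`, and the model bookkeeping needed by
#'   [asymptotic_posterior()] and [fit_bayes()].
#' @seealso [fit_naive()], [fit_bayes()], [asymptotic_posterior()]
#' @export
fit_pseudo_mle <- function(data, spec, model_kind = c("GEM", "AEM"),
                           pi = NULL, start = NULL, compute_vcov = TRUE,
                           control = list()) {
  model_kind <- match.arg(model_kind)
  if (is.null(pi) && !is.null(data$pi)) pi <- data$pi
  skel <- pl_skeleton(model_kind, data$I, has_z = !is.null(data$Z), pi = pi)
  ctx <- make_pl_context(data)
  ctrl <- utils::modifyList(list(maxit = 500L, gtol = 1e-6, restarts = 4L),
                            control)
  fn <- function(u) {
    th <- pl_from_unconstrained(u, skel)
    ll <- pl_loglik_core(th, ctx, skel, spec)
    if (is.null(ll) || !is.finite(ll)) return(1e10)
    -ll
  }
  gr <- function(u) pl_num_grad(fn, u)
  theta0 <- if (is.null(start)) pl_start_values(data, skel, spec) else {
    t0 <- pl_start_values(data, skel, spec)
    t0[names(start)] <- start
    t0
  }
  u <- pl_to_unconstrained(theta0, skel)
  counts <- 0L; code <- 1L
  for (r in seq_len(ctrl$restarts)) {
    opt <- stats::optim(u, fn, gr, method = "BFGS",
                        control = list(maxit = ctrl$maxit, reltol = 1e-12))
    u <- opt$par; counts <- counts + opt$counts[1L]; code <- opt$convergence
    gmax <- max(abs(gr(u))) / ctx$n
    if (gmax < ctrl$gtol) break
  }
  gmax <- max(abs(gr(u))) / ctx$n
  theta_hat <- pl_from_unconstrained(u, skel)
  names(theta_hat) <- skel$names
  loglik <- pl_loglik_core(theta_hat, ctx, skel, spec)

  boundary <- character(0)
  b <- pl_bounds(theta_hat, skel)
  near <- (theta_hat[b$idx] - b$lo < 1e-4 * (b$hi - b$lo)) |
    (b$hi - theta_hat[b$idx] < 1e-4 * (b$hi - b$lo))
  if (any(near)) {
    boundary <- skel$names[b$idx][near]
    warning("estimates at the boundary of the parameter space: ",
            paste(boundary, collapse = ", "))
  }

  scores <- NULL; V <- NULL; Sigma <- NULL; Lambda <- NULL
  if (compute_vcov) {
    scores <- pl_scores(theta_hat, ctx, skel, spec)
    # within-stratum score covariance (the variance of the total score under
    # case-control sampling is n times this) and the Lambda correction; their
    # sum estimates the information of the iid sampling fiction
    Sigma <- matrix(0, skel$n_par, skel$n_par)
    Lambda <- matrix(0, skel$n_par, skel$n_par)
    for (d in unique(data$D)) {
      sel <- data$D == d
      w_d <- sum(sel) / ctx$n
      Sigma <- Sigma + w_d * stats::cov(scores[sel, , drop = FALSE])
      mu_d <- colMeans(scores[sel, , drop = FALSE])
      Lambda <- Lambda + w_d * tcrossprod(mu_d)
    }
    A <- Sigma + Lambda
    Ainv <- solve_psd(A)
    V <- Ainv %*% Sigma %*% t(Ainv) / ctx$n
    V <- (V + t(V)) / 2
    dimnames(V) <- list(skel$names, skel$names)
    dimnames(Sigma) <- dimnames(Lambda) <- dimnames(V)
  }
  structure(list(coef = theta_hat, vcov = V, loglik = loglik,
                 convergence = list(code = code, grad_max = gmax,
                                    fn_evals = counts,
                                    converged = gmax < 10 * ctrl$gtol,
                                    boundary = boundary),
                 scores = scores, score_cov = Sigma, lambda = Lambda,
                 skel = skel, spec = spec, data = data, n = ctx$n),
            class = "gxe_pml")
}

#' @export
coef.gxe_pml <- function(object, ...) object$coef

#' @export
vcov.gxe_pml <- function(object, ...) object$vcov

#' @export
logLik.gxe_pml <- function(object, ...) {
  structure(object$loglik, df = object$skel$n_par, class = "logLik")
}

#' @export
print.gxe_pml <- function(x, ...) {
  cat(sprintf("Pseudo-MLE (%s, %d markers), n = %d, log pseudolik = %.2f\n",
              x$skel$model_kind, x$skel$I, x$n, x$loglik))
  print(round(x$coef, 4))
  if (!x$convergence$converged)
    cat(sprintf("WARNING: optimizer may not have converged (max mean score %.2g)\n",
                x$convergence$grad_max))
  invisible(x)
}

#' @export
summary.gxe_pml <- function(object, ...) {
  se <- if (is.null(object$vcov)) rep(NA_real_, length(object$coef))
        else sqrt(pmax(diag(object$vcov), 0))
  z <- object$coef / se
  tab <- cbind(Estimate = object$coef, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, loglik = object$loglik,
              convergence = object$convergence, n = object$n,
              model_kind = object$skel$model_kind)
  class(out) <- "summary.gxe_pml"
  out
}

#' @export
print.summary.gxe_pml <- function(x, ...) {
  cat(sprintf("Pseudo-MLE (%s), n = %d, log pseudolik = %.2f\n\n",
              x$model_kind, x$n, x$loglik))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
confint.gxe_pml <- function(object, parm, level = 0.95, ...) {
  cf <- object$coef
  se <- sqrt(pmax(diag(object$vcov), 0))
  if (missing(parm)) parm <- names(cf)
  q <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(cf[parm] - q * se[parm], cf[parm] + q * se[parm])
  colnames(out) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  out
}

## ---- naive comparator -----------------------------------------------------

#' Naive prospective logistic regression ignoring misclassification
#'
#' Fits an ordinary logistic regression of disease status on the observed
#' exposure `X` (treated as if it were the true exposure) and the genotype
#' codes, via `glm`.  Dominance codes use allele frequencies estimated from
#' the controls.  The intercept of this retrospective sample estimates the
#' offset \eqn{\kappa}, and is reported under that name; control-sample
#' allele frequencies are appended to the coefficients for reference.
#'
#' @param data A [case_control_data()] object (binary `D`); subjects with
#'   missing genotypes are dropped.
#' @param model_kind `"GEM"` or `"AEM"`.
#' @return Object of class `gxe_naive` wrapping the `glm` fit, with
#'   coefficients renamed to the package's parameter names.
#' @export
fit_naive <- function(data, model_kind = c("GEM", "AEM")) {
  model_kind <- match.arg(model_kind)
  if (data$K != 1L) stop("fit_naive requires binary disease status")
  cc <- stats::complete.cases(data$G)
  G <- data$G[cc, , drop = FALSE]
  D <- data$D[cc]; X <- data$X[cc]
  panel <- estimate_panel(G[D == 0L, , drop = FALSE])
  A <- encode_additive(G)
  df <- data.frame(D = D, X = X)
  I <- ncol(G)
  nm <- c("kappa", "beta_x")
  for (i in seq_len(I)) df[[paste0("A", i)]] <- A[, i]
  nm <- c(nm, paste0("beta_a", seq_len(I)))
  terms <- c("X", paste0("A", seq_len(I)))
  if (model_kind == "GEM") {
    B <- encode_dominance(G, panel)
    for (i in seq_len(I)) df[[paste0("B", i)]] <- B[, i]
    terms <- c(terms, paste0("B", seq_len(I)))
    nm <- c(nm, paste0("beta_d", seq_len(I)))
  }
  terms <- c(terms, paste0("X:A", seq_len(I)))
  nm <- c(nm, paste0("beta_ax", seq_len(I)))
  if (model_kind == "GEM") {
    terms <- c(terms, paste0("X:B", seq_len(I)))
    nm <- c(nm, paste0("beta_dx", seq_len(I)))
  }
  if (!is.null(data$Z)) {
    df$Z <- data$Z[cc]
    terms <- c(terms, "Z")
    nm <- c(nm, "beta_z")
  }
  fml <- stats::as.formula(paste("D ~", paste(terms, collapse = " + ")))
  fit <- stats::glm(fml, family = stats::binomial(), data = df)
  if (!fit$converged)
    warning("naive logistic regression did not converge (possible separation)")
  cf <- stats::coef(fit)
  names(cf) <- nm[match(names(cf), c("(Intercept)", terms))]
  cf <- c(cf, stats::setNames(panel$p_m, paste0("p_m", seq_len(I))))
  V <- stats::vcov(fit)
  dimnames(V) <- list(names(cf)[seq_len(nrow(V))], names(cf)[seq_len(nrow(V))])
  structure(list(coef = cf, vcov = V, glm = fit, panel = panel,
                 model_kind = model_kind, converged = fit$converged,
                 n = length(D)),
            class = "gxe_naive")
}

#' @export
coef.gxe_naive <- function(object, ...) object$coef

#' @export
vcov.gxe_naive <- function(object, ...) object$vcov

#' @export
print.gxe_naive <- function(x, ...) {
  cat(sprintf("Naive logistic fit (%s, misclassification ignored), n = %d\n",
              x$model_kind, x$n))
  print(round(x$coef, 4))
  invisible(x)
}
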