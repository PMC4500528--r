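# Penetrance model: polytomous logistic risk with additive/dominance
# genotype codes, the retrospective-sampling S kernel, and the
# intercept/offset identities that tie the prospective model to the
# case-control design.

#' Risk-model parameters
#'
#' Collects the coefficients of the polytomous logistic disease model
#' \deqn{pr(D = k \ge 1 | G, T, Z) = \frac{\exp\{\beta_{k0} + m_k\}}
#'   {1 + \sum_j \exp\{\beta_{j0} + m_j\}},}
#' where under the genotype effect model (GEM) the linear predictor is
#' \deqn{m_k = T\beta_{kT} + Z\beta_{kZ} + \sum_i A_i\beta_{kA_i}
#'   + \sum_i T A_i\beta_{kAT_i} + \sum_i Z A_i\beta_{kAZ_i}
#'   + \sum_i B_i\beta_{kD_i} + \sum_i T B_i\beta_{kDT_i}
#'   + \sum_i Z B_i\beta_{kDZ_i},}
#' and the additive effect model (AEM) drops the dominance blocks.
#'
#' Only `K = 1` (binary disease) is exercised by the shipped estimators;
#' the kernels themselves accept general `K` by passing matrices with one
#' row per disease category.
#'
#' @param beta_t Exposure main effect(s), length `K`.
#' @param beta_a Additive main effects (length-`I` vector for `K = 1`, or
#'   `K x I` matrix).
#' @param beta_at Additive-by-exposure interactions, same shape as `beta_a`.
#' @param beta_d,beta_dt Dominance main effects and dominance-by-exposure
#'   interactions (GEM only; must be absent/zero under AEM).
#' @param beta_z,beta_az,beta_dz Coefficients of an (optional) exactly
#'   measured scalar covariate `Z` and its genotype interactions.
#' @param model_kind `"GEM"` or `"AEM"`.
#' @return An object of class `risk_params`.
#' @export
risk_params <- function(beta_t, beta_a, beta_at = NULL, beta_d = NULL,
                        beta_dt = NULL, beta_z = NULL, beta_az = NULL,
                        beta_dz = NULL, model_kind = c("GEM", "AEM")) {
  model_kind <- match.arg(model_kind)
  as_mat <- function(x, I) {
    if (is.null(x)) return(NULL)
    if (is.matrix(x)) x else matrix(x, nrow = 1L)
  }
  beta_a <- as_mat(beta_a)
  I <- ncol(beta_a)
  K <- nrow(beta_a)
  zeros <- matrix(0, K, I)
  fix <- function(x) if (is.null(x)) zeros else as_mat(x)
  beta_at <- fix(beta_at); beta_az <- fix(beta_az)
  beta_d <- fix(beta_d); beta_dt <- fix(beta_dt); beta_dz <- fix(beta_dz)
  for (nm in c("beta_at", "beta_d", "beta_dt", "beta_az", "beta_dz")) {
    m <- get(nm)
    if (!all(dim(m) == c(K, I)))
      stop("'", nm, "' must have the same shape as 'beta_a'")
  }
  if (length(beta_t) != K) stop("'beta_t' must have length K = ", K)
  if (is.null(beta_z)) beta_z <- rep(0, K)
  if (model_kind == "AEM" &&
      (any(beta_d != 0) || any(beta_dt != 0) || any(beta_dz != 0)))
    stop("AEM forbids nonzero dominance coefficients")
  structure(list(K = K, I = I, model_kind = model_kind,
                 beta_t = as.numeric(beta_t), beta_z = as.numeric(beta_z),
                 beta_a = beta_a, beta_at = beta_at, beta_az = beta_az,
                 beta_d = beta_d, beta_dt = beta_dt, beta_dz = beta_dz),
            class = "risk_params")
}

#' @export
print.risk_params <- function(x, ...) {
  cat(sprintf("%s risk parameters: K = %d categories, I = %d markers\n",
              x$model_kind, x$K, x$I))
  cat("  beta_t:", format(x$beta_t), "\n")
  cat("  beta_a:", format(x$beta_a[1, ]), "\n")
  if (any(x$beta_at != 0)) cat("  beta_at:", format(x$beta_at[1, ]), "\n")
  if (x$model_kind == "GEM") {
    cat("  beta_d:", format(x$beta_d[1, ]), "\n")
    if (any(x$beta_dt != 0)) cat("  beta_dt:", format(x$beta_dt[1, ]), "\n")
  }
  invisible(x)
}

#' Linear predictor of the risk model
#'
#' Evaluates \eqn{m_k(A, B, T, Z)} for one subject and one disease
#' category.
#'
#' @param A,B Additive and dominance code vectors (length `I`); `B` is
#'   ignored under AEM and may be `NULL` there.
#' @param t Exposure value (0/1).
#' @param z Optional scalar covariate (default `NULL`, i.e. absent).
#' @param params A [risk_params()].
#' @param k Disease category in `1..K`.
#' @return The scalar linear predictor \eqn{m_k}.
#' @export
linear_predictor <- function(A, B = NULL, t, z = NULL, params, k = 1L) {
  if (k < 1L || k > params$K) stop("category 'k' out of range")
  if (length(A) != params$I) stop("length of 'A' must equal I = ", params$I)
  zv <- if (is.null(z)) 0 else z
  m <- t * params$beta_t[k] + zv * params$beta_z[k] +
    sum(A * params$beta_a[k, ]) + t * sum(A * params$beta_at[k, ]) +
    zv * sum(A * params$beta_az[k, ])
  if (params$model_kind == "GEM") {
    if (is.null(B)) stop("GEM requires the dominance codes 'B'")
    if (length(B) != params$I) stop("length of 'B' must equal I = ", params$I)
    m <- m + sum(B * params$beta_d[k, ]) + t * sum(B * params$beta_dt[k, ]) +
      zv * sum(B * params$beta_dz[k, ])
  }
  m
}

# log(1 + exp(v)) without overflow
log1pexp <- function(v) {
  out <- v
  lo <- v <= 33
  out[lo] <- log1p(exp(v[lo]))
  out
}

# log(exp(a) + exp(b)) elementwise
lse2 <- function(a, b) {
  m <- pmax(a, b)
  d <- pmin(a, b) - m
  ifelse(is.infinite(m) & m < 0, -Inf, m + log1p(exp(d)))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Disease-category probabilities under the polytomous logistic model
#'
#' @inheritParams linear_predictor
#' @param beta0 Vector of intercepts \eqn{\beta_{k0}}, length `K`.
#' @return Probability vector over categories `0..K` (sums to 1).
#' @export
disease_probability <- function(A, B = NULL, t, z = NULL, params, beta0) {
  if (length(beta0) != params$K) stop("'beta0' must have length K")
  m <- vapply(seq_len(params$K),
              function(k) linear_predictor(A, B, t, z, params, k), 0)
  lp <- c(0, beta0 + m)
  p <- exp(lp - logsumexp(lp))
  names(p) <- paste0("D=", 0:params$K)
  p
}

#' Retrospective S kernel (log scale)
#'
#' The building block of the pseudolikelihood:
#' \deqn{S(k, g, t, z) = \frac{\exp[1(k \ge 1)\{\kappa_k + m_k\}]}
#'   {1 + \sum_j \exp\{\beta_{j0} + m_j\}} \, pr(g; \Theta),}
#' returned as `log S`.  The offsets \eqn{\kappa_k = \beta_{k0} +
#' \log(n_k/n_0) - \log(\pi_k/\pi_0)} absorb the case-control sampling
#' fractions and the disease prevalences.
#'
#' @param k Disease category in `0..K`.
#' @param g Genotype dosage vector (no missing values; marginalization over
#'   missing entries happens in the pseudolikelihood).
#' @param t Exposure value.
#' @param z Optional covariate.
#' @param params A [risk_params()].
#' @param panel A [marker_panel()] supplying \eqn{pr(g; \Theta)} and the
#'   dominance coding frequencies.
#' @param kappa Offset vector \eqn{\kappa_k}, length `K`.
#' @param beta0 Intercept vector \eqn{\beta_{k0}}, length `K`.
#' @return `log S` (a scalar).
#' @export
s_kernel <- function(k, g, t, z = NULL, params, panel, kappa, beta0) {
  if (k < 0L || k > params$K) stop("category 'k' out of range")
  if (length(kappa) != params$K || length(beta0) != params$K)
    stop("'kappa' and 'beta0' must have length K")
  gd <- genotype_distribution(panel)
  gi <- as.integer(g %*% 3^(seq_along(g) - 1L)) + 1L
  logpg <- log(gd$prob[gi])
  A <- encode_additive(g)
  B <- encode_dominance(g, panel)
  m <- vapply(seq_len(params$K),
              function(j) linear_predictor(A, B, t, z, params, j), 0)
  logden <- logsumexp(c(0, beta0 + m))
  lognum <- if (k >= 1L) kappa[k] + m[k] else 0
  lognum - logden + logpg
}

#' Convert between the logistic intercept and the case-control offset
#'
#' The identity \eqn{\kappa_k = \beta_{k0} + \log(n_k/n_0) -
#' \log(\pi_k/\pi_0)} links the prospective intercepts to the offsets
#' estimable from retrospectively sampled data; it is invertible when the
#' design counts `n_d` and prevalences \eqn{\pi_k} are known.
#'
#' @param beta0,kappa Vector (length `K`) to convert.
#' @param n_d Case-control counts, length `K + 1` (`n_d[1]` = controls).
#' @param pi Prevalence vector \eqn{(\pi_1, \ldots, \pi_K)};
#'   \eqn{\pi_0 = 1 - \sum_k \pi_k}.
#' @return The converted vector.
#' @export
beta0_to_kappa <- function(beta0, n_d, pi) {
  pi0 <- 1 - sum(pi)
  if (pi0 <= 0 || any(pi <= 0)) stop("invalid prevalences")
  beta0 + log(n_d[-1] / n_d[1]) - log(pi / pi0)
}

#' @rdname beta0_to_kappa
#' @export
kappa_to_beta0 <- function(kappa, n_d, pi) {
  pi0 <- 1 - sum(pi)
  if (pi0 <= 0 || any(pi <= 0)) stop("invalid prevalences")
  kappa - log(n_d[-1] / n_d[1]) + log(pi / pi0)
}
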