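# Misclassification model for the observed binary exposure X given the
# true exposure T, plus the pluggable general (possibly differential)
# misclassification hook.

#' Misclassification specification for a binary exposure
#'
#' \eqn{\xi_0 = pr(X = 0 | T = 1)} is the false-negative probability and
#' \eqn{\xi_1 = pr(X = 1 | T = 0)} the false-positive probability of the
#' observed exposure `X` relative to the true exposure `T`.  The
#' identifiability guard \eqn{\xi_0 + \xi_1 < 1} keeps the observed
#' exposure positively associated with the true one.
#'
#' @param xi0 False-negative probability, in `[0, 1)`.
#' @param xi1 False-positive probability, in `[0, 1)`.
#' @return An object of class `misclass_spec`.
#' @examples
#' misclass_spec(0.20, 0.25)
#' @export
misclass_spec <- function(xi0, xi1) {
  if (!is.finite(xi0) || !is.finite(xi1) || xi0 < 0 || xi1 < 0 ||
      xi0 >= 1 || xi1 >= 1)
    stop("misclassification probabilities must lie in [0, 1)")
  if (xi0 + xi1 >= 1)
    stop("need xi0 + xi1 < 1 for identifiability")
  structure(list(xi0 = xi0, xi1 = xi1), class = "misclass_spec")
}

#' @export
print.misclass_spec <- function(x, ...) {
  cat(sprintf("Exposure misclassification: pr(X=0|T=1) = %.3g, pr(X=1|T=0) = %.3g\n",
              x$xi0, x$xi1))
  invisible(x)
}

#' Misclassification probability pr(X = x | T = t)
#'
#' Nondifferential misclassification kernel:
#' \deqn{f_{mem}(x | t) = \{x\xi_1 + (1-x)(1-\xi_1)\}(1-t)
#'   + \{x(1-\xi_0) + (1-x)\xi_0\}t.}
#'
#' @param x,t Observed and true exposure values in \{0, 1\} (vectorized).
#' @param spec A [misclass_spec()].
#' @return Probability (vectorized over `x`, `t`).
#' @export
p_miss <- function(x, t, spec) {
  if (any(!(x %in% 0:1)) || any(!(t %in% 0:1)))
    stop("'x' and 't' must be 0 or 1")
  (x * spec$xi1 + (1 - x) * (1 - spec$xi1)) * (1 - t) +
    (x * (1 - spec$xi0) + (1 - x) * spec$xi0) * t
}

#' Register a general misclassification model
#'
#' Wraps a user function `pr(X = x | T = t, G = g, Z = z, D = d)` into a
#' validated misclassification model, general enough for differential
#' misclassification (error rates depending on disease status, genotype or
#' covariates).  At registration the function is audited for normalization
#' over `x` on a grid of conditioning values.
#'
#' @param fun Function with signature `function(x, t, g, z, d)` returning a
#'   probability; the default reproduces the nondifferential kernel
#'   [p_miss()] of `spec`.
#' @param spec A [misclass_spec()] used by the default model and kept for
#'   reference.
#' @param check_grid Data frame of conditioning values `(t, g, z, d)` on
#'   which normalization is audited (a small default grid is used when
#'   omitted).
#' @return Object of class `misclass_model`; call it via
#'   [p_miss_general()].
#' @export
misclass_model <- function(fun = NULL, spec = NULL, check_grid = NULL) {
  if (is.null(fun)) {
    if (is.null(spec)) stop("supply 'fun' or 'spec'")
    fun <- function(x, t, g = NULL, z = NULL, d = NULL) p_miss(x, t, spec)
  }
  if (is.null(check_grid))
    check_grid <- expand.grid(t = 0:1, g = 0:2, z = 0, d = 0:1)
  for (r in seq_len(nrow(check_grid))) {
    cg <- check_grid[r, ]
    tot <- fun(0, cg$t, cg$g, cg$z, cg$d) + fun(1, cg$t, cg$g, cg$z, cg$d)
    if (abs(tot - 1) > 1e-10)
      stop(sprintf(
        "misclassification model not normalized over x at (t=%s, g=%s, z=%s, d=%s): sum = %.6f",
        cg$t, cg$g, cg$z, cg$d, tot))
  }
  structure(list(fun = fun, spec = spec), class = "misclass_model")
}

#' Evaluate a general misclassification model
#'
#' @param x,t Observed and true exposure.
#' @param model A [misclass_model()].
#' @param g,z,d Optional conditioning values (genotype summary, covariate,
#'   disease status) forwarded to the registered model.
#' @return Probability `pr(X = x | T = t, ...)`.
#' @export
p_miss_general <- function(x, t, model, g = NULL, z = NULL, d = NULL) {
  if (!inherits(model, "misclass_model")) stop("'model' must be a misclass_model")
  model$fun(x, t, g, z, d)
}

#' Marginal law of the observed exposure
#'
#' Under exposure prevalence \eqn{\eta = pr(T = 1)} and nondifferential
#' misclassification, \eqn{pr(X = 1) = \eta(1 - \xi_0) + (1 - \eta)\xi_1}.
#'
#' @param eta True exposure prevalence.
#' @param spec A [misclass_spec()].
#' @return `pr(X = 1)`.
#' @export
observed_exposure_prevalence <- function(eta, spec) {
  eta * (1 - spec$xi0) + (1 - eta) * spec$xi1
}
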