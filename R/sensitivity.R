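# Misclassification sensitivity analysis: refit the model over a grid of
# assumed (xi0, xi1) values and track how estimates and significance move.

#' Sensitivity sweep over assumed misclassification probabilities
#'
#' The misclassification probabilities are treated as known by the fitting
#' functions; when they are not known externally, the recommended practice
#' is to refit over a grid of plausible values and inspect how the
#' parameter estimates -- in particular the gene-environment interaction
#' coefficients -- respond.  Underestimating the false-negative probability
#' `pr(X=0|T=1)` attenuates interaction estimates (exposed subjects being
#' treated as unexposed weakens the association signal).
#'
#' @param data A [case_control_data()].
#' @param grid Data frame with columns `xi0` and `xi1`; each row is refit.
#' @param model_kind `"GEM"` or `"AEM"`.
#' @param pi Known disease prevalence or `NULL` (estimated).
#' @param level Significance level for the flagged-change summary
#'   (default 0.05).
#' @param ... Passed to [fit_pseudo_mle()].
#' @return Object of class `gxe_sensitivity`: a long data frame with one
#'   row per grid point per parameter (`xi0`, `xi1`, `parameter`,
#'   `estimate`, `se`, `z`, `significant`), with failed cells recorded in
#'   `attr(, "failed")` and parameters whose significance status changes
#'   across the grid in `attr(, "changed")`.
#' @export
sensitivity_sweep <- function(data, grid, model_kind = c("GEM", "AEM"),
                              pi = NULL, level = 0.05, ...) {
  model_kind <- match.arg(model_kind)
  if (!all(c("xi0", "xi1") %in% names(grid)) || nrow(grid) < 1L)
    stop("'grid' must be a nonempty data frame with columns xi0, xi1")
  rows <- list(); failed <- list()
  for (r in seq_len(nrow(grid))) {
    spec <- misclass_spec(grid$xi0[r], grid$xi1[r])
    fit <- suppressWarnings(tryCatch(
      fit_pseudo_mle(data, spec, model_kind = model_kind, pi = pi, ...),
      error = function(e) e))
    if (inherits(fit, "error")) {
      failed[[length(failed) + 1L]] <-
        data.frame(xi0 = grid$xi0[r], xi1 = grid$xi1[r],
                   message = conditionMessage(fit))
      next
    }
    cf <- coef(fit)
    se <- sqrt(pmax(diag(vcov(fit)), 0))
    z <- cf / se
    rows[[length(rows) + 1L]] <- data.frame(
      xi0 = grid$xi0[r], xi1 = grid$xi1[r], parameter = names(cf),
      estimate = unname(cf), se = unname(se), z = unname(z),
      significant = abs(unname(z)) > stats::qnorm(1 - level / 2),
      row.names = NULL)
  }
  out <- do.call(rbind, rows)
  changed <- character(0)
  if (!is.null(out)) {
    for (p in unique(out$parameter)) {
      s <- out$significant[out$parameter == p]
      if (length(unique(s[!is.na(s)])) > 1L) changed <- c(changed, p)
    }
  }
  attr(out, "failed") <- if (length(failed)) do.call(rbind, failed) else NULL
  attr(out, "changed") <- changed
  class(out) <- c("gxe_sensitivity", class(out))
  out
}

#' @export
print.gxe_sensitivity <- function(x, ...) {
  cat(sprintf("Misclassification sensitivity sweep: %d grid point(s)\n",
              length(unique(paste(x$xi0, x$xi1)))))
  ch <- attr(x, "changed")
  if (length(ch))
    cat("  significance status changes across the grid for:",
        paste(ch, collapse = ", "), "\n")
  fa <- attr(x, "failed")
  if (!is.null(fa)) cat(sprintf("  %d grid cell(s) failed to fit\n", nrow(fa)))
  NextMethod()
}
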