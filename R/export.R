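# Flat-file export of fit results.

#' Export a fit to JSON and CSV
#'
#' Serializes a fitted object's estimates, standard errors and metadata to
#' a JSON file, and optionally a flat CSV of estimates/SEs.  Round-trips of
#' the parameter vector are bit-exact (JSON numbers are written at full
#' precision).
#'
#' @param fit A `gxe_pml`, `gxe_naive`, `gxe_mcmc` or `gxe_asymp` object.
#' @param json Path of the JSON file to write, or `NULL` to skip.
#' @param csv Path of the CSV file to write, or `NULL` to skip.
#' @return The exported list, invisibly.
#' @export
write_fit <- function(fit, json = NULL, csv = NULL) {
  cf <- coef(fit)
  se <- switch(class(fit)[1L],
               gxe_pml = , gxe_naive = sqrt(pmax(diag(vcov(fit)), 0)),
               gxe_mcmc = fit$summaries$sd,
               gxe_asymp = fit$se,
               rep(NA_real_, length(cf)))
  se <- stats::setNames(rep(se, length.out = length(cf)), names(cf))
  out <- list(kind = class(fit)[1L], estimates = as.list(cf),
              se = as.list(se))
  if (inherits(fit, "gxe_pml"))
    out$loglik <- fit$loglik
  if (inherits(fit, "gxe_mcmc"))
    out <- c(out, list(seed = fit$seed, n_iter = fit$n_iter,
                       burn_in = fit$burn_in,
                       acceptance_rate = fit$acceptance_rate))
  if (!is.null(json))
    jsonlite::write_json(out, json, auto_unbox = TRUE, digits = I(17))
  if (!is.null(csv))
    utils::write.csv(data.frame(parameter = names(cf), estimate = unname(cf),
                                se = unname(se)),
                     csv, row.names = FALSE)
  invisible(out)
}

#' Read back an exported fit
#'
#' @param json Path to a JSON file written by [write_fit()].
#' @return A list with `estimates` and `se` as named numeric vectors.
#' @export
read_fit <- function(json) {
  x <- jsonlite::read_json(json, simplifyVector = TRUE)
  x$estimates <- unlist(x$estimates)
  x$se <- unlist(x$se)
  x
}
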