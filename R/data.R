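# Case-control data container and plain-text table input/output.

#' Case-control data set
#'
#' Container for one case-control sample: disease status `D` (0 = control,
#' `1..K` = case categories), observed binary exposure `X`, genotype dosage
#' matrix `G` (entries 0/1/2 or `NA` for missing), and an optional exactly
#' measured scalar covariate `Z`.
#'
#' @param D Integer vector of disease categories.
#' @param X Integer vector (0/1) of observed exposure.
#' @param G Matrix of genotype dosages, one column per marker; `NA` marks a
#'   missing genotype call.
#' @param Z Optional numeric covariate vector.
#' @param pi Optional prevalence vector \eqn{(\pi_1, \ldots, \pi_K)} of the
#'   case categories in the source population.
#' @return Object of class `gxe_data` with fields `D`, `X`, `G`, `Z`,
#'   `n_d` (design counts) and `pi`.
#' @export
case_control_data <- function(D, X, G, Z = NULL, pi = NULL) {
  D <- as.integer(D); X <- as.integer(X)
  G <- as.matrix(G); storage.mode(G) <- "integer"
  n <- length(D)
  if (length(X) != n || nrow(G) != n)
    stop("'D', 'X' and rows of 'G' must have equal length")
  if (any(is.na(D)) || any(D < 0L)) stop("'D' must be nonnegative integers")
  if (any(is.na(X)) || any(!(X %in% 0:1))) stop("'X' must be binary (0/1)")
  bad <- !is.na(G) & !(G %in% 0:2)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("genotype value %s at row %d, marker %d is not 0/1/2/NA",
                 G[w[1L], w[2L]], w[1L], w[2L]))
  }
  if (!is.null(Z)) {
    Z <- as.numeric(Z)
    if (length(Z) != n) stop("'Z' must have one value per subject")
  }
  K <- max(D)
  if (K < 1L) stop("need at least one case category")
  n_d <- vapply(0:K, function(d) sum(D == d), 0L)
  if (any(n_d < 1L)) stop("every disease category 0..K must be observed")
  if (!is.null(pi)) {
    pi <- as.numeric(pi)
    if (length(pi) != K || any(pi <= 0) || sum(pi) >= 1)
      stop("'pi' must be K positive prevalences with sum < 1")
  }
  structure(list(D = D, X = X, G = G, Z = Z, n_d = n_d, pi = pi,
                 K = K, I = ncol(G)),
            class = "gxe_data")
}

#' @export
print.gxe_data <- function(x, ...) {
  cat(sprintf("Case-control data: %d subjects (%s), %d marker(s)\n",
              length(x$D),
              paste(sprintf("n%d = %d", seq_along(x$n_d) - 1L, x$n_d),
                    collapse = ", "),
              x$I))
  miss <- mean(is.na(x$G))
  if (miss > 0) cat(sprintf("  missing genotype calls: %.1f%%\n", 100 * miss))
  if (!is.null(x$Z)) cat("  covariate Z present\n")
  invisible(x)
}

#' Read a case-control table from a CSV/TSV file
#'
#' Expected columns: `D` (disease category), `X` (0/1 observed exposure),
#' optionally `Z`, and one column per marker (any other column names),
#' holding dosages 0/1/2 or `NA`.  An `id` column, if present, is ignored.
#'
#' @param path File path; the delimiter is inferred from the extension
#'   (`.tsv`/`.txt` = tab, otherwise comma).
#' @param pi Optional prevalence passed to [case_control_data()].
#' @return A [case_control_data()] object; the marker order is the column
#'   order of the file and is recorded in `attr(, "markers")`.
#' @examples
#' toy <- system.file("extdata", "toy_case_control.csv", package = "gxemis")
#' read_case_control_table(toy)
#' @export
read_case_control_table <- function(path, pi = NULL) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  for (col in c("D", "X"))
    if (!col %in% names(df))
      stop("required column '", col, "' not found in ", path)
  marker_cols <- setdiff(names(df), c("id", "D", "X", "Z"))
  if (!length(marker_cols)) stop("no marker columns found in ", path)
  G <- as.matrix(df[marker_cols])
  bad <- !is.na(G) & !(G %in% 0:2)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid genotype value '%s' at row %d, column '%s'",
                 G[w[1L], w[2L]], w[1L], marker_cols[w[2L]]))
  }
  dat <- case_control_data(df$D, df$X, G,
                           Z = if ("Z" %in% names(df)) df$Z else NULL,
                           pi = pi)
  attr(dat, "markers") <- marker_cols
  dat
}

#' Write a case-control table to CSV/TSV
#'
#' Inverse of [read_case_control_table()].
#'
#' @param data A [case_control_data()] object.
#' @param path Output path; extension selects the delimiter.
#' @return `path`, invisibly.
#' @export
write_case_control_table <- function(data, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  G <- data$G
  markers <- attr(data, "markers")
  if (is.null(markers)) markers <- paste0("g", seq_len(ncol(G)))
  colnames(G) <- markers
  df <- data.frame(id = seq_along(data$D), D = data$D, X = data$X)
  if (!is.null(data$Z)) df$Z <- data$Z
  df <- cbind(df, as.data.frame(G))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert VCF genotypes to a dosage matrix
#'
#' Parses the GT field of a VCF file into a subjects-by-variants dosage
#' matrix counting ALT alleles (the coded allele).  Requires the `vcfR`
#' package.
#'
#' @param path Path to a VCF file.
#' @return Integer dosage matrix (subjects x variants) with `NA` for
#'   missing calls.
#' @export
vcf_to_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("package 'vcfR' is required for VCF input")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(s) {
    if (is.na(s)) return(NA_integer_)
    al <- strsplit(s, "[/|]")[[1L]]
    if (any(al == ".")) return(NA_integer_)
    sum(al != "0")
  }
  out <- t(apply(gt, 1L, function(r) vapply(r, count_alt, 0L)))
  t(out)
}
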