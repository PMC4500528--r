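# Marker panels: allele frequencies, pairwise LD, and the multilocus
# genotype distribution under Hardy-Weinberg equilibrium.

#' Marker panel: allele frequencies and pairwise linkage disequilibrium
#'
#' A marker panel describes `I` biallelic genetic markers by the frequency
#' \eqn{P_{M_i}} of the coded (risk) allele \eqn{M_i} at each marker and a
#' symmetric matrix of pairwise linkage-disequilibrium (LD) coefficients
#' \eqn{\Delta_{ij}}, the covariance between the allele indicators of
#' markers \eqn{i} and \eqn{j} on the same haplotype.  The panel fully
#' determines a multilocus haplotype distribution in which all third- and
#' higher-order disequilibria are zero, and hence (under HWE, genotype =
#' two independent haplotype draws) the joint distribution of unphased
#' genotypes.
#'
#' Each \eqn{\Delta_{ij}} must lie inside the Frechet-type feasibility box
#' \eqn{\max(-P_{M_i}P_{M_j}, -P_{m_i}P_{m_j}) \le \Delta_{ij} \le
#' \min(P_{M_i}P_{m_j}, P_{m_i}P_{M_j})} where \eqn{P_{m_i} = 1 - P_{M_i}};
#' in addition every implied haplotype frequency must be nonnegative, which
#' for three or more markers is a strictly stronger requirement.
#'
#' @param p_m Numeric vector of coded-allele frequencies, each in (0, 1).
#' @param delta Either a single number (used for every pair), or a symmetric
#'   `I x I` matrix of pairwise LD coefficients (diagonal ignored).
#' @return An object of class `marker_panel` with elements `n_markers`,
#'   `p_m` and `delta` (full symmetric matrix, zero diagonal).
#' @examples
#' marker_panel(c(0.25, 0.25, 0.25), delta = 0.03)
#' @export
marker_panel <- function(p_m, delta = 0) {
  p_m <- as.numeric(p_m)
  I <- length(p_m)
  if (I < 1L) stop("need at least one marker")
  if (any(!is.finite(p_m)) || any(p_m <= 0) || any(p_m >= 1))
    stop("allele frequencies must lie strictly inside (0, 1)")
  if (is.matrix(delta)) {
    if (!all(dim(delta) == c(I, I))) stop("'delta' must be ", I, " x ", I)
    if (max(abs(delta - t(delta))) > 1e-12) stop("'delta' must be symmetric")
    D <- delta
  } else {
    if (length(delta) != 1L) stop("'delta' must be a scalar or a matrix")
    D <- matrix(delta, I, I)
  }
  diag(D) <- 0
  panel <- structure(list(n_markers = I, p_m = p_m, delta = D),
                     class = "marker_panel")
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  p <- panel$p_m; q <- 1 - p; D <- panel$delta; I <- panel$n_markers
  if (I > 1L) {
    for (i in seq_len(I - 1L)) for (j in (i + 1L):I) {
      lo <- max(-p[i] * p[j], -q[i] * q[j])
      hi <- min(p[i] * q[j], q[i] * p[j])
      if (D[i, j] < lo - 1e-12 || D[i, j] > hi + 1e-12)
        stop(sprintf(
          "LD coefficient Delta[%d,%d] = %.4g outside feasible range [%.4g, %.4g]",
          i, j, D[i, j], lo, hi))
    }
  }
  # full haplotype-table nonnegativity (stronger than pairwise bounds for I > 2)
  h <- haplotype_frequencies(panel)
  invisible(panel)
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("Marker panel: %d marker(s)\n", x$n_markers))
  cat("  coded-allele frequencies:", paste(format(x$p_m), collapse = ", "), "\n")
  if (x$n_markers > 1L) {
    off <- x$delta[upper.tri(x$delta)]
    cat("  pairwise LD Delta:", paste(format(off), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Feasibility bounds for a pairwise LD coefficient
#'
#' @param p1,p2 Coded-allele frequencies of the two markers.
#' @return Numeric vector `c(lower, upper)`.
#' @export
ld_bounds <- function(p1, p2) {
  c(max(-p1 * p2, -(1 - p1) * (1 - p2)), min(p1 * (1 - p2), (1 - p1) * p2))
}

#' Haplotype frequencies implied by a marker panel
#'
#' Builds the `2^I` haplotype probabilities from the allele frequencies and
#' the pairwise LD coefficients, with all third- and higher-order
#' disequilibria set to zero:
#' \deqn{h(a) = \prod_i p_i(a_i) + \sum_{i<j} s_i s_j \Delta_{ij}
#'   \prod_{k \ne i,j} p_k(a_k),}
#' where \eqn{a_i \in \{0,1\}} indicates the coded allele, \eqn{p_i(1) =
#' P_{M_i}}, \eqn{p_i(0) = P_{m_i}}, and \eqn{s_i = 2a_i - 1}.  Margins
#' reproduce the allele frequencies and pairwise allele-indicator
#' covariances equal \eqn{\Delta_{ij}}.
#'
#' @param panel A [marker_panel()].
#' @return Named numeric vector of length `2^I`; names are allele patterns
#'   such as `"Mm"` (coded allele at marker 1, other allele at marker 2).
#' @export
haplotype_frequencies <- function(panel) {
  I <- panel$n_markers; p <- panel$p_m; D <- panel$delta
  pat <- hap_patterns(I)                 # 2^I x I, 1 = coded allele
  pm <- matrix(rep(p, each = nrow(pat)), ncol = I)
  probs <- ifelse(pat == 1L, pm, 1 - pm) # p_i(a_i)
  base <- apply(probs, 1L, prod)
  corr <- 0
  if (I > 1L) {
    for (i in seq_len(I - 1L)) for (j in (i + 1L):I) {
      if (D[i, j] == 0) next
      s <- (2L * pat[, i] - 1L) * (2L * pat[, j] - 1L)
      rest <- base / (probs[, i] * probs[, j])
      corr <- corr + s * D[i, j] * rest
    }
  }
  h <- base + corr
  names(h) <- apply(pat, 1L, function(a) paste(ifelse(a == 1L, "M", "m"),
                                               collapse = ""))
  bad <- which(h < -1e-12)
  if (length(bad))
    stop(sprintf(
      "invalid LD configuration: implied haplotype frequency of pattern %s is %.4g < 0",
      names(h)[bad[1L]], h[bad[1L]]))
  h[h < 0] <- 0
  h / sum(h)
}

# allele patterns (2^I x I), first column fastest
hap_patterns <- function(I) {
  as.matrix(expand.grid(rep(list(0:1), I), KEEP.OUT.ATTRS = FALSE))
}

# genotype dosage patterns (3^I x I), first column fastest
genotype_patterns <- function(I) {
  as.matrix(expand.grid(rep(list(0:2), I), KEEP.OUT.ATTRS = FALSE))
}

# cache of the (pair -> genotype) index map per marker count
.gxemis_cache <- new.env(parent = emptyenv())

hap_pair_index <- function(I) {
  key <- paste0("pairidx", I)
  if (!is.null(.gxemis_cache[[key]])) return(.gxemis_cache[[key]])
  pat <- hap_patterns(I)
  nh <- nrow(pat)
  i <- rep(seq_len(nh), times = nh)
  j <- rep(seq_len(nh), each = nh)
  g <- pat[i, , drop = FALSE] + pat[j, , drop = FALSE]   # dosage of each pair
  idx <- as.integer(g %*% 3^(seq_len(I) - 1L)) + 1L      # base-3 genotype index
  .gxemis_cache[[key]] <- list(i = i, j = j, idx = idx, n_geno = 3L^I)
  .gxemis_cache[[key]]
}

#' Joint distribution of unphased multilocus genotypes
#'
#' Convolves two independent haplotype draws (HWE at the haplotype level)
#' into the joint probability of every genotype vector in the genotype
#' space.  Enumeration over all `3^I` genotype vectors is required by the
#' pseudolikelihood denominator, so the marker count is capped.
#'
#' @param panel A [marker_panel()].
#' @param max_markers Enumeration cap on the number of markers (default 10).
#' @return A list with `genotypes` (a `3^I x I` integer matrix of dosages,
#'   first marker varying fastest) and `prob` (probabilities summing to 1).
#' @export
genotype_distribution <- function(panel, max_markers = 10L) {
  I <- panel$n_markers
  if (I > max_markers)
    stop(sprintf(
      "cannot enumerate %d markers (3^%d genotype vectors); cap is %d markers",
      I, I, max_markers))
  h <- haplotype_frequencies(panel)
  map <- hap_pair_index(I)
  pp <- h[map$i] * h[map$j]
  prob <- numeric(map$n_geno)
  tmp <- rowsum(pp, group = map$idx)
  prob[as.integer(rownames(tmp))] <- tmp
  list(genotypes = genotype_patterns(I), prob = as.numeric(prob))
}

# fast path used inside optimizers: probabilities only, NULL if any implied
# haplotype frequency is negative (caller treats as out of bounds)
genotype_prob_fast <- function(p, D) {
  I <- length(p)
  pat <- hap_patterns(I)
  pm <- matrix(rep(p, each = nrow(pat)), ncol = I)
  probs <- ifelse(pat == 1L, pm, 1 - pm)
  base <- apply(probs, 1L, prod)
  h <- base
  if (I > 1L) {
    for (i in seq_len(I - 1L)) for (j in (i + 1L):I) {
      if (D[i, j] == 0) next
      s <- (2L * pat[, i] - 1L) * (2L * pat[, j] - 1L)
      h <- h + s * D[i, j] * base / (probs[, i] * probs[, j])
    }
  }
  if (any(h < 0)) return(NULL)
  map <- hap_pair_index(I)
  pp <- h[map$i] * h[map$j]
  prob <- numeric(map$n_geno)
  tmp <- rowsum(pp, group = map$idx)
  prob[as.integer(rownames(tmp))] <- tmp
  prob
}

#' Additive genotype code
#'
#' Maps a genotype dosage vector to the additive (allele-count) code
#' \eqn{A_i}: 1 for the coded-allele homozygote, 0 for the heterozygote,
#' -1 for the other homozygote, i.e. \eqn{A_i = G_i - 1}.
#'
#' @param g Integer vector (or matrix, one row per subject) of dosages in
#'   \{0, 1, 2\}; `NA` is not allowed here (marginalize over the genotype
#'   distribution instead).
#' @return Numeric vector/matrix of the same shape with values in
#'   \{-1, 0, 1\}.
#' @export
encode_additive <- function(g) {
  if (any(is.na(g)))
    stop("missing genotype: additive code undefined; marginalize over the genotype distribution")
  if (any(!(g %in% 0:2))) stop("genotype dosages must be 0, 1 or 2")
  g - 1
}

#' Dominance genotype code
#'
#' Maps a genotype dosage to the dominance code \eqn{B_i}, which has mean
#' zero under HWE: \eqn{-P_{m_i}^2} for the coded-allele homozygote,
#' \eqn{P_{M_i} P_{m_i}} for the heterozygote, and \eqn{-P_{M_i}^2} for the
#' other homozygote.
#'
#' @param g Integer vector of dosages in \{0, 1, 2\} (or a matrix with one
#'   column per marker).
#' @param p_m Coded-allele frequency (scalar, or vector of per-marker
#'   frequencies recycled across the columns of a matrix `g`).  A
#'   [marker_panel()] may be given instead.
#' @return Numeric vector/matrix of dominance codes.
#' @export
encode_dominance <- function(g, p_m) {
  if (inherits(p_m, "marker_panel")) p_m <- p_m$p_m
  if (any(is.na(g)))
    stop("missing genotype: dominance code undefined; marginalize over the genotype distribution")
  if (any(!(g %in% 0:2))) stop("genotype dosages must be 0, 1 or 2")
  if (is.matrix(g)) {
    if (length(p_m) == 1L) p_m <- rep(p_m, ncol(g))
    if (length(p_m) != ncol(g)) stop("length of 'p_m' must match columns of 'g'")
    P <- matrix(rep(p_m, each = nrow(g)), ncol = ncol(g))
  } else {
    if (length(p_m) == 1L) P <- rep(p_m, length(g))
    else if (length(p_m) == length(g)) P <- p_m
    else stop("length of 'p_m' must be 1 or length(g)")
  }
  Q <- 1 - P
  out <- g
  out[] <- ifelse(g == 2L, -Q^2, ifelse(g == 1L, P * Q, -P^2))
  out
}

#' Closed-form moments of the additive and dominance codes
#'
#' Under the panel's genotype distribution: \eqn{E(A_i) = P_{M_i} -
#' P_{m_i}}, \eqn{E(B_i) = 0}, \eqn{Var(A_i) = 2 P_{M_i} P_{m_i}},
#' \eqn{Var(B_i) = P_{M_i}^2 P_{m_i}^2}, \eqn{Cov(A_i, A_j) = 2
#' \Delta_{ij}}, \eqn{Cov(B_i, B_j) = \Delta_{ij}^2}, and
#' \eqn{Cov(A_i, B_j) = 0}.
#'
#' @param panel A [marker_panel()].
#' @return A list with `E_A`, `E_B`, `V_A` (covariance matrix of the
#'   additive codes) and `V_D` (covariance matrix of the dominance codes).
#' @export
coding_moments <- function(panel) {
  p <- panel$p_m; q <- 1 - p; D <- panel$delta
  V_A <- 2 * D; diag(V_A) <- 2 * p * q
  V_D <- D^2;   diag(V_D) <- p^2 * q^2
  list(E_A = p - q, E_B = rep(0, panel$n_markers), V_A = V_A, V_D = V_D)
}

#' Estimate a marker panel from genotype data
#'
#' Allele frequencies are estimated by allele counting and pairwise LD by
#' half the sample covariance of the dosages (the composite-genotypic
#' estimator, exact under HWE).  Typically applied to the control sample.
#'
#' @param G Integer matrix of dosages (subjects x markers), `NA` allowed.
#' @param clamp Shrink estimates strictly inside the feasible region by
#'   this small margin (default `1e-6`) so the result is a valid panel.
#' @return A [marker_panel()].
#' @export
estimate_panel <- function(G, clamp = 1e-6) {
  G <- as.matrix(G)
  I <- ncol(G)
  p <- colMeans(G, na.rm = TRUE) / 2
  p <- pmin(pmax(p, clamp), 1 - clamp)
  D <- matrix(0, I, I)
  if (I > 1L) {
    cv <- stats::cov(G, use = "pairwise.complete.obs") / 2
    for (i in seq_len(I - 1L)) for (j in (i + 1L):I) {
      b <- ld_bounds(p[i], p[j])
      d <- min(max(cv[i, j], b[1] + clamp), b[2] - clamp)
      D[i, j] <- D[j, i] <- d
    }
    # enforce full haplotype-table validity by shrinking LD toward zero
    sh <- 1
    repeat {
      ok <- !is.null(genotype_prob_fast(p, D * sh))
      if (ok || sh < 1e-3) break
      sh <- sh * 0.9
    }
    D <- D * sh
  }
  marker_panel(p, D)
}
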