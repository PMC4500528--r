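# Genotype codes, haplotype/genotype distributions, and code moments.

test_that("additive and dominance codes follow the dummy-variable definitions", {
  expect_equal(encode_additive(c(2L, 1L, 0L)), c(1, 0, -1))
  expect_error(encode_additive(c(1L, NA)), "missing genotype")
  expect_error(encode_additive(c(3L, 1L)), "0, 1 or 2")

  # B = (-P_m^2, P_M P_m, -P_M^2) for dosage (2, 1, 0)
  expect_equal(encode_dominance(2L, 0.25), -0.5625)
  expect_equal(encode_dominance(1L, 0.25), 0.1875)
  expect_equal(encode_dominance(0L, 0.5), -0.25)
  expect_error(encode_dominance(c(1L, NA), 0.25), "missing genotype")

  # matrix input, per-marker frequencies
  G <- rbind(c(2L, 0L), c(1L, 1L))
  B <- encode_dominance(G, c(0.25, 0.5))
  expect_equal(B, rbind(c(-0.5625, -0.25), c(0.1875, 0.25)))
})

test_that("haplotype frequencies honor allele frequencies and pairwise LD", {
  p <- marker_panel(c(0.25, 0.25), delta = 0)
  h <- haplotype_frequencies(p)
  expect_equal(unname(h["MM"]), 0.0625)        # independence product
  expect_equal(sum(h), 1)

  p <- marker_panel(c(0.25, 0.25), delta = 0.03)
  h <- haplotype_frequencies(p)
  expect_equal(unname(h["MM"]), 0.25 * 0.25 + 0.03)
  # margins unchanged by LD
  expect_equal(unname(h["MM"] + h["Mm"]), 0.25)
  expect_equal(sum(h), 1)

  # Delta = 0.2 exceeds min(P_M1 P_m2, P_m1 P_M2) = 0.1875
  expect_error(marker_panel(c(0.25, 0.25), delta = 0.2), "outside feasible range")
})

test_that("three-marker panels reject LD that implies negative haplotype mass", {
  # each pair is inside its pairwise box, but the joint table goes negative
  D <- matrix(0.05, 3, 3); diag(D) <- 0
  D[1, 2] <- D[2, 1] <- -0.05
  expect_error(marker_panel(c(0.3, 0.3, 0.3), delta = D),
               "haplotype frequency")
})

test_that("joint genotype distribution is HWE-consistent and normalized", {
  gd <- genotype_distribution(marker_panel(0.25))
  expect_equal(gd$prob, c(0.5625, 0.375, 0.0625))   # P_m^2, 2 P_M P_m, P_M^2

  panel <- marker_panel(c(0.25, 0.25), delta = 0.03)
  gd <- genotype_distribution(panel)
  expect_equal(sum(gd$prob), 1)
  # per-marker margins equal single-locus HWE despite LD
  for (i in 1:2) {
    marg <- vapply(0:2, function(g) sum(gd$prob[gd$genotypes[, i] == g]), 0)
    expect_equal(marg, c(0.5625, 0.375, 0.0625), tolerance = 1e-12)
  }

  # Delta == 0 factorizes exactly into the product of per-marker HWE laws
  panel0 <- marker_panel(c(0.25, 0.4), delta = 0)
  gd0 <- genotype_distribution(panel0)
  hw <- function(p) c((1 - p)^2, 2 * p * (1 - p), p^2)
  expect_equal(gd0$prob,
               as.vector(outer(hw(0.25), hw(0.4))),
               tolerance = 1e-14)

  expect_error(genotype_distribution(marker_panel(rep(0.5, 11))),
               "cap is 10 markers")
})

test_that("closed-form code moments match the printed formulas and Monte Carlo", {
  panel <- marker_panel(c(0.25, 0.25, 0.25), delta = 0.03)
  mom <- coding_moments(panel)
  expect_equal(mom$E_A, rep(-0.5, 3))            # P_M - P_m
  expect_equal(mom$E_B, rep(0, 3))
  expect_equal(diag(mom$V_A), rep(0.375, 3))     # 2 P_M P_m
  expect_equal(mom$V_A[1, 2], 0.06)              # 2 Delta
  expect_equal(diag(mom$V_D), rep(0.25^2 * 0.75^2, 3))
  expect_equal(mom$V_D[1, 2], 0.0009)            # Delta^2

  # Monte-Carlo audit at 1e5 draws, 3 standard errors
  set.seed(404)
  gd <- genotype_distribution(panel)
  n <- 1e5
  idx <- sample.int(nrow(gd$genotypes), n, replace = TRUE, prob = gd$prob)
  G <- gd$genotypes[idx, ]
  A <- encode_additive(G)
  B <- encode_dominance(G, panel)
  se_mean <- sqrt(diag(mom$V_A) / n)
  expect_true(all(abs(colMeans(A) - mom$E_A) < 3 * se_mean))
  expect_true(all(abs(colMeans(B) - 0) < 3 * sqrt(diag(mom$V_D) / n)))
  # covariances within 3 SE (SE of a sample covariance ~ sqrt((V_ii V_jj + V_ij^2)/n))
  CA <- cov(A); CB <- cov(B)
  for (i in 1:2) for (j in (i + 1):3) {
    se_c <- sqrt((mom$V_A[i, i] * mom$V_A[j, j] + mom$V_A[i, j]^2) / n)
    expect_lt(abs(CA[i, j] - mom$V_A[i, j]), 3 * se_c)
    se_d <- sqrt((mom$V_D[i, i] * mom$V_D[j, j] + mom$V_D[i, j]^2) / n)
    expect_lt(abs(CB[i, j] - mom$V_D[i, j]), 3 * se_d)
  }
  expect_lt(abs(cov(A[, 1], B[, 2])), 3 * sqrt(mom$V_A[1, 1] * mom$V_D[2, 2] / n))
})

test_that("panel estimation recovers frequencies and LD from genotypes", {
  set.seed(11)
  panel <- marker_panel(c(0.25, 0.25), delta = 0.03)
  gd <- genotype_distribution(panel)
  idx <- sample.int(9L, 4e4, replace = TRUE, prob = gd$prob)
  est <- estimate_panel(gd$genotypes[idx, ])
  expect_lt(max(abs(est$p_m - panel$p_m)), 0.02)
  expect_lt(abs(est$delta[1, 2] - 0.03), 0.01)
})
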