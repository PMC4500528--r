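# Scores, the case-control Lambda correction, and the Gaussian posterior
# approximation.

make_small_fit <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      sc <- quick_scenario(n = 400L, model_kind = "AEM", I = 2L)
      dat <- simulate_case_control(sc, seed = 60)
      fit <<- suppressWarnings(
        fit_pseudo_mle(dat, sc$spec, "AEM", pi = sc$pi))
    }
    fit
  }
})

test_that("scores average to zero at the optimum and are scheme-stable", {
  fit <- make_small_fit()
  sm <- score_matrix(fit)
  expect_lt(max(abs(colMeans(sm))), 1e-5)
  # halving the step changes nothing material (central differences are O(h^2))
  sm2 <- score_matrix(fit, h = 5e-6)
  expect_lt(max(abs(sm - sm2)) / max(abs(sm)), 1e-5)
  # permuting the subject order permutes the rows, nothing else
  dat <- fit$data
  perm <- rev(seq_along(dat$D))
  datp <- case_control_data(dat$D[perm], dat$X[perm],
                            dat$G[perm, , drop = FALSE], pi = dat$pi)
  smp <- score_matrix(datp, params = coef(fit), spec = fit$spec,
                      model_kind = "AEM")
  expect_equal(smp, sm[perm, ], tolerance = 1e-10)
})

test_that("Lambda correction equals a brute-force group-by computation", {
  set.seed(9)
  sm <- matrix(rnorm(30 * 4), 30, 4,
               dimnames = list(NULL, paste0("p", 1:4)))
  d <- rep(c(0L, 1L), c(18L, 12L))
  L <- lambda_correction(sm, d)
  brute <- matrix(0, 4, 4)
  for (k in 0:1) {
    mu <- colMeans(sm[d == k, ])
    brute <- brute + (sum(d == k) / 30) * outer(mu, mu)
  }
  expect_equal(unname(L), unname(brute), tolerance = 1e-14)
  expect_gte(min(eigen(L, symmetric = TRUE, only.values = TRUE)$values), -1e-12)
  # single stratum: Lambda is the outer product of the overall mean score
  L1 <- lambda_correction(sm, rep(1L, 30))
  expect_equal(unname(L1), unname(outer(colMeans(sm), colMeans(sm))))
})

test_that("flat prior returns the pseudo-MLE and its sandwich covariance", {
  fit <- make_small_fit()
  ap <- asymptotic_posterior(fit, prior = NULL)
  expect_equal(ap$mean, coef(fit), tolerance = 1e-10)
  expect_equal(ap$cov, vcov(fit), tolerance = 1e-10)
})

test_that("posterior precision decomposes into data plus prior precision", {
  fit <- make_small_fit()
  prior <- prior_spec(mu = 0, sd = 2)
  ap <- asymptotic_posterior(fit, prior = prior)
  n <- ap$pieces$n
  prec <- n * ap$pieces$I_hat + ap$pieces$J
  expect_equal(solve(ap$cov), prec, tolerance = 1e-6)
  # shrinkage: the risk-coefficient block moves from the pseudo-MLE toward
  # the prior mode (0), the more so the tighter the prior
  risk <- c("beta_x", "beta_a1", "beta_a2", "beta_ax1", "beta_ax2")
  expect_lt(sqrt(sum(ap$mean[risk]^2)), sqrt(sum(coef(fit)[risk]^2)))
  tight <- prior_spec(mu = 0, sd = 0.01)
  ap2 <- asymptotic_posterior(fit, prior = tight)
  expect_lt(max(abs(ap2$mean[risk])), 0.02)
  expect_lt(abs(ap2$mean["beta_x"]), abs(ap$mean["beta_x"]))
})

test_that("Hessian- and score-based information estimators agree at large n", {
  sc <- quick_scenario(n = 2500L, model_kind = "AEM", I = 2L)
  dat <- simulate_case_control(sc, seed = 61)
  fit <- fit_pseudo_mle(dat, sc$spec, "AEM", pi = sc$pi)
  ih <- asymptotic_posterior(fit, prior = NULL, info = "hessian")$pieces$I_hat
  is_ <- asymptotic_posterior(fit, prior = NULL, info = "score")$pieces$I_hat
  # elementwise agreement within 10% relative to the information scale
  scale <- sqrt(outer(diag(ih), diag(ih)))
  expect_lt(max(abs(ih - is_) / scale), 0.10)
})
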