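# Priors, log posterior, and the Metropolis-Hastings sampler.

test_that("log posterior enforces support and is additive in prior and likelihood", {
  sc <- quick_scenario(n = 60L, model_kind = "AEM", I = 2L)
  dat <- simulate_case_control(sc, seed = 1)
  prior <- prior_spec()
  skel <- gxemis:::pl_skeleton("AEM", 2L, pi = sc$pi)
  theta <- scenario_truth(sc)[skel$names]

  bad <- theta; bad["eta"] <- 1.2
  expect_identical(log_posterior(bad, dat, prior, sc$spec, "AEM", pi = sc$pi),
                   -Inf)
  bad2 <- theta; bad2["p_m1"] <- -0.1
  expect_identical(log_posterior(bad2, dat, prior, sc$spec, "AEM", pi = sc$pi),
                   -Inf)

  # additivity audit: posterior differences = likelihood + prior differences
  theta2 <- theta; theta2["beta_x"] <- theta["beta_x"] + 0.3
  ctx <- gxemis:::make_pl_context(dat)
  dll <- gxemis:::pl_loglik_core(theta2, ctx, skel, sc$spec) -
    gxemis:::pl_loglik_core(theta, ctx, skel, sc$spec)
  pm <- gxemis:::prior_matrices(prior, skel)
  dlp <- gxemis:::pl_log_prior(theta2, skel, pm) -
    gxemis:::pl_log_prior(theta, skel, pm)
  dpost <- log_posterior(theta2, dat, prior, sc$spec, "AEM", pi = sc$pi) -
    log_posterior(theta, dat, prior, sc$spec, "AEM", pi = sc$pi)
  expect_equal(dpost, dll + dlp, tolerance = 1e-10)
})

test_that("a near-degenerate prior dominates the posterior mean", {
  sc <- quick_scenario(n = 100L, model_kind = "AEM", I = 1L)
  dat <- simulate_case_control(sc, seed = 3)
  mu <- c(0.25, 0.15, 0.35)   # (beta_x, beta_a1, beta_ax1)
  prior <- prior_spec(mu = mu, cov = diag(1e-6, 3))
  ch <- suppressWarnings(
    fit_bayes(dat, sc$spec, prior, "AEM", pi = sc$pi, n_iter = 3000L,
              burn_in = 1000L, seed = 42,
              init = NULL))
  expect_equal(unname(coef(ch)[c("beta_x", "beta_a1", "beta_ax1")]), mu,
               tolerance = 0.02)
})

test_that("chains are reproducible given the seed", {
  sc <- quick_scenario(n = 80L, model_kind = "AEM", I = 1L)
  dat <- simulate_case_control(sc, seed = 4)
  fit <- suppressWarnings(fit_pseudo_mle(dat, sc$spec, "AEM", pi = sc$pi))
  ch1 <- fit_bayes(dat, sc$spec, model_kind = "AEM", pi = sc$pi,
                   n_iter = 800L, burn_in = 300L, seed = 7, init = fit)
  ch2 <- fit_bayes(dat, sc$spec, model_kind = "AEM", pi = sc$pi,
                   n_iter = 800L, burn_in = 300L, seed = 7, init = fit)
  expect_identical(ch1$draws, ch2$draws)
  ch3 <- fit_bayes(dat, sc$spec, model_kind = "AEM", pi = sc$pi,
                   n_iter = 800L, burn_in = 300L, seed = 8, init = fit)
  expect_false(identical(ch1$draws, ch3$draws))
})

test_that("LD-structured prior has the advertised block structure", {
  panel <- marker_panel(c(0.25, 0.25, 0.25), delta = 0.03)
  pr <- build_ld_prior(panel, scale = 3, model_kind = "GEM")
  Sg <- pr$cov
  p <- nrow(Sg)
  expect_equal(p, 1 + 4 * 3)
  expect_equal(diag(Sg), rep(9, p))
  # additive blocks carry corr(A_i, A_j) = 2 Delta / (2 P_M P_m)
  rho_a <- 0.06 / 0.375
  expect_equal(Sg[2, 3], 9 * rho_a)
  # dominance blocks carry corr(B_i, B_j) = Delta^2 / (P_M^2 P_m^2)
  rho_d <- 0.0009 / (0.25^2 * 0.75^2)
  expect_equal(Sg[8, 9], 9 * rho_d)
  # positive definite
  expect_gt(min(eigen(Sg, symmetric = TRUE, only.values = TRUE)$values), 0)
  # no LD -> conservative diagonal prior
  pr0 <- build_ld_prior(marker_panel(c(0.25, 0.25), delta = 0),
                        scale = 3, model_kind = "AEM")
  expect_equal(pr0$cov, diag(9, 5))
})
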