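# The retrospective pseudolikelihood and the pseudo-MLE.

test_that("exp(log pseudolikelihood) sums to one over the outcome space", {
  panel <- marker_panel(0.25)
  params <- risk_params(beta_t = 0.7, beta_a = 0.4, beta_at = 0.9,
                        beta_d = 0.26, beta_dt = 1.1, model_kind = "GEM")
  spec <- misclass_spec(0.20, 0.25)
  for (kappa in c(0.48, -0.3)) {
    beta0 <- kappa_to_beta0(kappa, c(100, 100), 0.01)
    tot <- 0
    for (d in 0:1) for (g in 0:2) for (x in 0:1)
      tot <- tot + exp(log_pseudolik_obs(d, g, x, NULL, params, kappa,
                                         beta0, eta = 0.5, spec, panel))
    expect_equal(tot, 1, tolerance = 1e-10)
  }
})

test_that("vectorized engine equals the brute-force triple-loop oracle", {
  sc <- quick_scenario(n = 25L, model_kind = "GEM", I = 2L,
                       missing_rate = 0.3)
  dat <- simulate_case_control(sc, seed = 91)
  truth <- scenario_truth(sc)
  skel <- gxemis:::pl_skeleton("GEM", 2L, pi = sc$pi)
  theta <- truth[skel$names]
  ctx <- gxemis:::make_pl_context(dat)
  llg <- gxemis:::pl_loglik_core(theta, ctx, skel, sc$spec, per_group = TRUE)
  per_subject <- llg[ctx$subject_group]
  beta0 <- kappa_to_beta0(truth["kappa"], dat$n_d, sc$pi)
  for (i in seq_len(50)) {
    expect_equal(per_subject[i],
                 unname(oracle_log_pseudolik(dat$D[i], dat$G[i, ], dat$X[i],
                                             sc$params, truth["kappa"], beta0,
                                             sc$eta, sc$spec, sc$panel)),
                 tolerance = 1e-10)
  }
})

test_that("error-free misclassification collapses the latent-exposure sum", {
  panel <- marker_panel(0.25)
  params <- risk_params(beta_t = 0.7, beta_a = 0.4, beta_at = 0.9,
                        model_kind = "AEM")
  spec0 <- misclass_spec(0, 0)
  eta <- 0.4; kappa <- 0.2; beta0 <- -2
  # with xi = 0 the numerator keeps only t* = x
  for (d in 0:1) for (g in 0:2) for (x in 0:1) {
    full <- log_pseudolik_obs(d, g, x, NULL, params, kappa, beta0, eta,
                              spec0, panel)
    lt <- c(log1p(-eta), log(eta))[x + 1]
    num <- s_kernel(d, g, x, params = params, panel = panel,
                    kappa = kappa, beta0 = beta0) + lt
    den <- log(sum(vapply(0:1, function(k) sum(vapply(0:2, function(gg)
      sum(vapply(0:1, function(t)
        exp(s_kernel(k, gg, t, params = params, panel = panel,
                     kappa = kappa, beta0 = beta0) +
              c(log1p(-eta), log(eta))[t + 1]), 0)), 0)), 0)))
    expect_equal(full, num - den, tolerance = 1e-12)
  }
})

test_that("fully missing genotypes marginalize out of the likelihood", {
  panel <- marker_panel(0.25)
  params <- risk_params(beta_t = 0.7, beta_a = 0.4, beta_at = 0.9,
                        model_kind = "AEM")
  spec <- misclass_spec(0.2, 0.25)
  # numerator with g = NA equals the sum of the three complete numerators
  all_g <- vapply(0:2, function(g)
    exp(log_pseudolik_obs(1, g, 1, NULL, params, 0.2, -2, 0.5, spec, panel)),
    0)
  missing_g <- exp(log_pseudolik_obs(1, NA_integer_, 1, NULL, params, 0.2,
                                     -2, 0.5, spec, panel))
  expect_equal(missing_g, sum(all_g), tolerance = 1e-12)
})

test_that("pseudo-MLE recovers generative parameters at n = 20,000", {
  sc <- quick_scenario(n = 10000L, model_kind = "GEM", I = 2L)
  dat <- simulate_case_control(sc, seed = 2024)
  fit <- fit_pseudo_mle(dat, sc$spec, model_kind = "GEM", pi = sc$pi)
  expect_true(fit$convergence$converged)
  truth <- scenario_truth(sc)
  se <- sqrt(diag(vcov(fit)))
  z <- (coef(fit) - truth[names(coef(fit))]) / se
  expect_true(all(abs(z) < 3),
              info = paste(names(z)[abs(z) >= 3], collapse = ", "))
  # first-order condition: mean score ~ 0 at the optimum
  sm <- score_matrix(fit)
  expect_lt(max(abs(colMeans(sm))), 1e-5)
})

test_that("duplicating the sample leaves estimates invariant (design-scale invariance)", {
  sc <- quick_scenario(n = 120L, model_kind = "AEM", I = 2L)
  dat <- simulate_case_control(sc, seed = 5)
  dat2 <- case_control_data(rep(dat$D, 2), rep(dat$X, 2),
                            rbind(dat$G, dat$G), pi = sc$pi)
  f1 <- suppressWarnings(fit_pseudo_mle(dat, sc$spec, "AEM", pi = sc$pi,
                                        compute_vcov = FALSE))
  f2 <- suppressWarnings(fit_pseudo_mle(dat2, sc$spec, "AEM", pi = sc$pi,
                                        compute_vcov = FALSE))
  expect_equal(coef(f2), coef(f1), tolerance = 1e-4)
  expect_equal(f2$loglik, 2 * f1$loglik, tolerance = 1e-6)
})

test_that("misclassification-aware fit nests the error-free fit at xi = 0", {
  sc <- quick_scenario(n = 400L, model_kind = "AEM", I = 1L)
  sc$spec <- misclass_spec(0, 0)
  dat <- simulate_case_control(sc, seed = 8)
  # with xi = 0 the observed X is the true exposure; the pseudo-MLE at
  # spec(0,0) and the fit treating X as exact must coincide
  f0 <- fit_pseudo_mle(dat, misclass_spec(0, 0), "AEM", pi = sc$pi,
                       compute_vcov = FALSE)
  f_eps <- fit_pseudo_mle(dat, misclass_spec(1e-12, 1e-12), "AEM",
                          pi = sc$pi, compute_vcov = FALSE)
  expect_equal(coef(f0), coef(f_eps), tolerance = 1e-5)
})

test_that("naive logistic fit is consistent without misclassification and attenuated with it", {
  sc <- quick_scenario(n = 10000L, model_kind = "AEM", I = 2L)
  sc$spec <- misclass_spec(0, 0)
  dat <- simulate_case_control(sc, seed = 77)
  cf <- coef(fit_naive(dat, "AEM"))
  se <- sqrt(diag(vcov(fit_naive(dat, "AEM"))))
  truth <- scenario_truth(sc)
  for (p in c("beta_x", "beta_a1", "beta_ax1"))
    expect_lt(abs(cf[p] - truth[p]), 3 * se[p])

  # with misclassification the exposure effect attenuates on average
  sc2 <- quick_scenario(n = 2000L, model_kind = "AEM", I = 2L)
  set.seed(31)
  bx <- replicate(8, coef(fit_naive(simulate_case_control(sc2), "AEM"))["beta_x"])
  expect_lt(mean(abs(bx)), abs(scenario_truth(sc2)["beta_x"]))
})
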