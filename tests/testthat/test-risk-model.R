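# Polytomous risk model, linear predictors, and the S kernel.

test_that("linear predictor assembles main effects and interactions", {
  pr0 <- risk_params(beta_t = 0, beta_a = c(0, 0), model_kind = "AEM")
  expect_equal(linear_predictor(c(1, -1), NULL, t = 1, params = pr0), 0)

  pr <- risk_params(beta_t = 0.5, beta_a = 0.2, beta_at = 0.3,
                    model_kind = "AEM")
  expect_equal(linear_predictor(A = 1, t = 1, params = pr), 1.0)

  # GEM equals AEM plus the dominance terms
  prg <- risk_params(beta_t = 0.5, beta_a = 0.2, beta_at = 0.3,
                     beta_d = 0.7, beta_dt = 0.4, model_kind = "GEM")
  A <- 1; B <- 0.1875
  expect_equal(linear_predictor(A, B, t = 1, params = prg),
               linear_predictor(A, t = 1, params = pr) + 0.7 * B + 0.4 * B)
  expect_error(linear_predictor(c(1, 0), NULL, t = 1, params = pr),
               "length of 'A'")
})

test_that("AEM constructor rejects dominance terms; GEM with zero dominance equals AEM", {
  expect_error(risk_params(beta_t = 1, beta_a = 0.5, beta_d = 0.2,
                           model_kind = "AEM"),
               "forbids nonzero dominance")
  aem <- risk_params(beta_t = 1, beta_a = c(0.5, 0.2), beta_at = c(0.1, 0.3),
                     model_kind = "AEM")
  gem <- risk_params(beta_t = 1, beta_a = c(0.5, 0.2), beta_at = c(0.1, 0.3),
                     beta_d = c(0, 0), beta_dt = c(0, 0), model_kind = "GEM")
  for (t in 0:1)
    expect_equal(linear_predictor(c(1, -1), c(-0.5, 0.1), t, params = gem),
                 linear_predictor(c(1, -1), t = t, params = aem))
})

test_that("disease probabilities are a proper distribution", {
  pr <- risk_params(beta_t = 0, beta_a = 0, model_kind = "AEM")
  p <- disease_probability(A = 0, t = 0, params = pr, beta0 = 0)
  expect_equal(unname(p["D=1"]), 0.5)
  expect_equal(unname(p["D=1"] + p["D=0"]), 1)
  # extreme intercept drives the case probability to 0 without overflow
  p <- disease_probability(A = 0, t = 0, params = pr, beta0 = -1000)
  expect_equal(unname(p["D=1"]), 0)
  set.seed(3)
  for (r in 1:20) {
    prr <- risk_params(beta_t = rnorm(1, 0, 5), beta_a = rnorm(2, 0, 5),
                       beta_at = rnorm(2, 0, 5), beta_d = rnorm(2, 0, 5),
                       beta_dt = rnorm(2, 0, 5), model_kind = "GEM")
    p <- disease_probability(A = sample(-1:1, 2, TRUE),
                             B = rnorm(2), t = rbinom(1, 1, 0.5),
                             params = prr, beta0 = rnorm(1, 0, 5))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("S kernel matches its closed form and factorizes through pr(g)", {
  panel <- marker_panel(0.25)
  pr0 <- risk_params(beta_t = 0, beta_a = 0, beta_at = 0, beta_d = 0,
                     beta_dt = 0, model_kind = "GEM")
  # k = 0, all beta = 0: S = pr(g = 1) / (1 + e^0) = 0.375 / 2
  expect_equal(exp(s_kernel(0, 1L, t = 0, params = pr0, panel = panel,
                            kappa = 0.3, beta0 = 0)),
               0.1875)
  # S / pr(g) recovers the pure risk kernel (independent of the genotype law)
  panel2 <- marker_panel(0.4)
  pr <- risk_params(beta_t = 0.5, beta_a = 0.3, beta_at = 0.2,
                    model_kind = "AEM")
  for (g in 0:2) for (k in 0:1) {
    r1 <- s_kernel(k, g, 1, params = pr, panel = panel, kappa = 0.3, beta0 = -1) -
      log(genotype_distribution(panel)$prob[g + 1])
    r2 <- s_kernel(k, g, 1, params = pr, panel = panel2, kappa = 0.3, beta0 = -1) -
      log(genotype_distribution(panel2)$prob[g + 1])
    expect_equal(r1, r2, tolerance = 1e-12)
  }
})

test_that("kappa/beta0 conversion round-trips through the design identity", {
  n_d <- c(1500, 1500); pi <- 0.005
  expect_equal(kappa_to_beta0(0.484, n_d, pi), 0.484 + log(0.005 / 0.995))
  for (b0 in c(-4.8, -1, 0.3)) {
    k <- beta0_to_kappa(b0, n_d, pi)
    expect_equal(kappa_to_beta0(k, n_d, pi), b0, tolerance = 1e-14)
  }
  # unbalanced design
  k <- beta0_to_kappa(-2, c(400, 900), 0.02)
  expect_equal(k, -2 + log(900 / 400) - log(0.02 / 0.98))
})
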