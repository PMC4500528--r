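# The case-control simulator and the replicated experiment runner.

test_that("intercept calibration hits the target prevalence", {
  sc <- quick_scenario(n = 100L, pi = 0.02)
  expect_equal(gxemis:::population_prevalence(sc, sc$beta0), 0.02,
               tolerance = 1e-10)
  pop <- simulate_population(sc, 4e4, seed = 14)
  expect_lt(abs(mean(pop$D) - 0.02), 3 * sqrt(0.02 * 0.98 / 4e4))
  # the implied offset obeys the design identity
  truth <- scenario_truth(sc)
  expect_equal(unname(kappa_to_beta0(truth["kappa"],
                                     c(sc$n_controls, sc$n_cases), sc$pi)),
               sc$beta0, tolerance = 1e-12)
  # unattainable prevalence errors out
  expect_error(gxe_scenario(sc$panel, sc$eta, sc$spec, sc$params,
                            100L, 100L, pi = 1 - 1e-12),
               "unattainable")
})

test_that("error-free misclassification gives X identical to T", {
  sc <- quick_scenario(n = 200L)
  sc$spec <- misclass_spec(0, 0)
  dat <- simulate_case_control(sc, seed = 15)
  expect_identical(dat$X, as.integer(attr(dat, "T")))
})

test_that("MCAR masking hits the nominal missingness rate", {
  sc <- quick_scenario(n = 1500L, missing_rate = 0.5)
  dat <- simulate_case_control(sc, seed = 16)
  frac <- mean(is.na(dat$G))
  n_calls <- length(dat$G)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n_calls))
})

test_that("control-sample allele frequencies and LD match the panel", {
  sc <- scenario_gem_large()
  dat <- simulate_case_control(sc, seed = 17)
  ctrl <- dat$G[dat$D == 0L, ]
  n <- nrow(ctrl)
  p_hat <- colMeans(ctrl) / 2
  se_p <- sqrt(0.25 * 0.75 / (2 * n))
  expect_true(all(abs(p_hat - 0.25) < 3.5 * se_p))
  est <- estimate_panel(ctrl)
  expect_lt(abs(est$delta[1, 2] - 0.03), 0.012)
})

test_that("simulation and experiment tables are seed-deterministic", {
  sc <- quick_scenario(n = 80L)
  d1 <- simulate_case_control(sc, seed = 18)
  d2 <- simulate_case_control(sc, seed = 18)
  expect_identical(d1$G, d2$G)
  expect_identical(d1$X, d2$X)
  e1 <- run_experiment(sc, 3L, estimators = "naive", seed = 9)
  e2 <- run_experiment(sc, 3L, estimators = "naive", seed = 9)
  expect_identical(e1$table, e2$table)
})

test_that("all estimators are unbiased at the global null", {
  sc0 <- gxe_scenario(quick_panel(), eta = 0.5,
                      spec = misclass_spec(0.2, 0.25),
                      params = risk_params(beta_t = 0, beta_a = c(0, 0),
                                           beta_at = c(0, 0),
                                           model_kind = "AEM"),
                      n_controls = 300L, n_cases = 300L, pi = 0.01)
  ex <- run_experiment(sc0, 25L, estimators = c("naive", "pml"), seed = 19)
  tab <- ex$table
  tab <- tab[tab$parameter %in% c("beta_x", "beta_a1", "beta_a2",
                                  "beta_ax1", "beta_ax2"), ]
  expect_true(all(abs(tab$bias) < 3 * tab$mc_se))
})

test_that("experiment runner survives estimator failures", {
  # a degenerate two-subject-per-stratum design makes the naive glm separate
  # or the pml unstable in some replicates without killing the sweep
  sc <- quick_scenario(n = 40L, model_kind = "AEM", I = 1L)
  ex <- suppressWarnings(run_experiment(sc, 3L, estimators = "naive",
                                        seed = 20))
  expect_s3_class(ex, "gxe_experiment")
  expect_true(all(c("bias", "rmse", "mc_se") %in% names(ex$table)))
})
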