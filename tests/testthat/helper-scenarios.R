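# Small, fast generative settings used across unit tests (the shipped
# experiment designs scenario_gem_large()/scenario_aem_small() are used
# where the full study conditions matter).

quick_panel <- function() marker_panel(c(0.25, 0.3), delta = 0.02)

quick_scenario <- function(n = 150L, model_kind = "GEM", I = 2L,
                           missing_rate = 0, pi = 0.01) {
  panel <- if (I == 1L) marker_panel(0.25) else quick_panel()
  params <- if (model_kind == "GEM")
    risk_params(beta_t = 0.6, beta_a = rep(0.4, I), beta_at = rep(0.5, I),
                beta_d = rep(0.3, I), beta_dt = rep(0.2, I),
                model_kind = "GEM")
  else
    risk_params(beta_t = 0.6, beta_a = rep(0.4, I), beta_at = rep(0.5, I),
                model_kind = "AEM")
  gxe_scenario(panel, eta = 0.5, spec = misclass_spec(0.20, 0.25),
               params = params, n_controls = n, n_cases = n, pi = pi,
               missing_rate = missing_rate)
}

# brute-force log pseudolikelihood for one subject: plain triple loop over
# (t*, genotype completions) in the numerator and (k*, g, t*) in the
# denominator, written independently of the package's evaluators
oracle_log_pseudolik <- function(d, g, x, params, kappa, beta0, eta, spec,
                                 panel) {
  gd <- genotype_distribution(panel)
  sfun <- function(k, gv, t) {
    A <- gv - 1
    p <- panel$p_m; q <- 1 - p
    B <- ifelse(gv == 2, -q^2, ifelse(gv == 1, p * q, -p^2))
    m <- t * params$beta_t[1] + sum(A * params$beta_a[1, ]) +
      t * sum(A * params$beta_at[1, ]) +
      sum(B * params$beta_d[1, ]) + t * sum(B * params$beta_dt[1, ])
    gi <- sum(gv * 3^(seq_along(gv) - 1)) + 1
    num <- if (k >= 1) exp(kappa + m) else 1
    num / (1 + exp(beta0 + m)) * gd$prob[gi]
  }
  ft <- c(1 - eta, eta)
  num <- 0
  for (gi in seq_len(nrow(gd$genotypes))) {
    gv <- gd$genotypes[gi, ]
    if (any(!is.na(g) & gv != g)) next
    for (t in 0:1)
      num <- num + sfun(d, gv, t) * p_miss(x, t, spec) * ft[t + 1]
  }
  den <- 0
  for (k in 0:1) for (gi in seq_len(nrow(gd$genotypes))) for (t in 0:1)
    den <- den + sfun(k, gd$genotypes[gi, ], t) * ft[t + 1]
  log(num) - log(den)
}
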