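test_that("config validation lists all violations", {
  err <- tryCatch(sim_config("no_mediation", m = 1, n0 = 50000,
                             sigma_E1 = -1),
                  error = conditionMessage)
  expect_match(err, "m must be")
  expect_match(err, "n0 must")
  expect_match(err, "environment SDs")
})

test_that("the no-mediation generator matches its declared moments", {
  cfg <- sim_config("no_mediation", m = 20, n1 = 8000, n2 = 8000, n0 = 4000,
                    seed = 2)
  set.seed(2)
  d <- simulate_no_mediation(cfg)
  expect_equal(dim(d$G), c(12000L, 20L))
  v <- apply(d$G, 2, var)
  expect_true(all(abs(v - 1) < 0.1))            # standardized genotypes
  expect_true(all(abs(colMeans(d$G)) < 0.05))   # centered by default
  expect_lt(abs(cor(d$G[, 1], d$E)), 0.03)      # G and E independent
  # determinism
  set.seed(2)
  d2 <- simulate_no_mediation(cfg)
  expect_identical(d$y, d2$y)
})

test_that("the mediation-panel generator books 0.25% of Var(E) to G", {
  cfg <- sim_config("mediation_panel", n1 = 30000, n2 = 30000, seed = 4)
  # analytic share: coef^2 * Var(G) / (coef^2 * Var(G) + resid var)
  share <- cfg$mediation_coef^2 / (cfg$mediation_coef^2 + cfg$env_resid_var)
  expect_equal(share, 0.0025)
  set.seed(4)
  d <- simulate_mediation_panel(cfg, model = "b")
  expect_lt(abs(var(d$E) - 1), 0.03)            # Var(E) = 1 by construction
  fit <- lm(d$E ~ d$G[, 1])
  expect_lt(abs(coef(fit)[2] - cfg$mediation_coef), 3 * summary(fit)$coef[2, 2])
  # genotypes are scaled but not centered
  expect_gt(mean(d$G[, 1]), 0.8)
  set.seed(4)
  da <- simulate_mediation_panel(cfg, model = "a")
  expect_lt(abs(cor(da$G[, 1], da$E)), 0.03)
  expect_error(simulate_mediation_panel(cfg, model = "z"))
})

test_that("closed-form fits agree with the lm oracle", {
  cfg <- sim_config("no_mediation", m = 5, n1 = 400, n2 = 300, n0 = 200,
                    sigma_beta2 = 0.02, seed = 9)
  set.seed(9)
  d <- simulate_no_mediation(cfg)
  for (adjust in c(FALSE, TRUE)) {
    cfg$adjust_marginal_for_E <- adjust
    panel <- fit_summary_stats(d, cfg)
    for (j in c(1, 3, 5)) {
      yg <- d$y[d$idx_gwas]; gg <- d$G[d$idx_gwas, j]
      fit_marg <- if (adjust) lm(yg ~ gg + d$E[d$idx_gwas]) else lm(yg ~ gg)
      sm <- summary(fit_marg)$coefficients
      expect_equal(panel$alpha_hat[j], unname(sm["gg", 1]), tolerance = 1e-10)
      expect_equal(panel$se_alpha[j], unname(sm["gg", 2]), tolerance = 1e-8)
      yw <- d$y[d$idx_gwis]; gw <- d$G[d$idx_gwis, j]; ew <- d$E[d$idx_gwis]
      fit1 <- lm(yw ~ gw + ew + I(gw * ew))
      sm1 <- summary(fit1)$coefficients
      expect_equal(panel$beta1_hat[j], unname(sm1[2, 1]), tolerance = 1e-10)
      expect_equal(panel$se_beta1[j], unname(sm1[2, 2]), tolerance = 1e-8)
      expect_equal(panel$beta2_hat[j], unname(sm1[3, 1]), tolerance = 1e-10)
      expect_equal(panel$beta3_hat[j], unname(sm1[4, 1]), tolerance = 1e-10)
      expect_equal(panel$se_beta3[j], unname(sm1[4, 2]), tolerance = 1e-8)
    }
  }
})

test_that("null marginal effects have variance near 1/n1", {
  # isolate the theory convention: no environment effect, no interaction,
  # null variants, unit residual variance
  cfg <- sim_config("no_mediation", m = 4, n1 = 2000, n2 = 2000, n0 = 2000,
                    sigma_beta2 = 0, beta2_env = 0, beta3 = 0, seed = 23)
  alphas <- matrix(NA_real_, 300, 4)
  for (i in seq_len(300)) {
    set.seed(cfg$seed + i)
    d <- simulate_no_mediation(cfg)
    alphas[i, ] <- fit_summary_stats(d, cfg)$alpha_hat
  }
  ratio <- apply(alphas, 2, var) * cfg$n1
  expect_true(all(abs(ratio - 1) < 0.3))
})

test_that("replicate studies are deterministic under a fixed seed", {
  cfg <- sim_config("mediation_panel", n1 = 2000, n2 = 2000, seed = 6)
  s1 <- run_replicates(cfg, model = "c", n_reps = 15)
  s2 <- run_replicates(cfg, model = "c", n_reps = 15)
  expect_identical(s1$theta_mean, s2$theta_mean)
  expect_identical(s1$power, s2$power)
  expect_identical(s1$b3_mr_mean, s2$b3_mr_mean)
})

test_that("overlap correlation responds to the shared-subject fraction", {
  cfg_full <- sim_config("mediation_panel", n1 = 4000, n2 = 4000, n0 = 4000,
                         seed = 14)
  s_full <- run_replicates(cfg_full, model = "a", n_reps = 3)
  expect_gt(s_full$overlap_corr, 0.3)
  cfg_none <- sim_config("mediation_panel", n1 = 4000, n2 = 4000, n0 = 0,
                         seed = 14)
  s_none <- run_replicates(cfg_none, model = "a", n_reps = 3)
  expect_lt(abs(s_none$overlap_corr), 0.1)
})

test_that("mean bridging coefficient tracks its expectation over a grid", {
  reps <- 120
  grid <- list(list(s = 1e-4, frac = 0.5, mu = 1),
               list(s = 1e-4, frac = 1.0, mu = 1),
               list(s = 5e-3, frac = 1.0, mu = 0.5))
  for (gset in grid) {
    cfg <- sim_config("no_mediation", n1 = 10000, n2 = 10000,
                      n0 = as.integer(gset$frac * 10000),
                      sigma_beta2 = gset$s, beta3 = 0,
                      mu_E1 = gset$mu, mu_E2 = gset$mu, seed = 41)
    th <- numeric(reps)
    for (i in seq_len(reps)) {
      set.seed(cfg$seed + i)
      d <- simulate_no_mediation(cfg)
      p <- fit_summary_stats(d, cfg)
      th[i] <- ivw_theta(p[p$variant_id %in% paste0("v", cfg$iv_idx), ])$theta_hat
    }
    sh2 <- cfg$resid_var + (cfg$m - 1) * cfg$sigma_beta2 +
      cfg$beta2_env^2 * cfg$sigma_E2^2
    expct <- expected_theta(cfg$sigma_beta2, cfg$n1, cfg$n2, cfg$n0,
                            mu_E0 = cfg$mu_E2, sigma_E0 = cfg$sigma_E2,
                            mu_E2 = cfg$mu_E2, sigma_E2 = cfg$sigma_E2,
                            sigma_shared2 = sh2)
    expect_lt(abs(mean(th) - expct), 2.5 * sd(th) / sqrt(reps))
    expect_lte(mean(th) - 2 * sd(th) / sqrt(reps), 1)
  }
})

test_that("interaction estimators are unbiased across effect-direction scenarios", {
  # at the study scale (n = 20,000) the bridging coefficient is close enough
  # to 1 that a fixed focal main effect leaks nothing detectable into the
  # MR-route estimate; at much smaller n the attenuation of theta_hat would
  reps <- 120
  for (fb in c(-0.05, 0, 0.05)) {   # opposite, absent, aligned main effect
    cfg <- sim_config("no_mediation", n1 = 20000, n2 = 20000, n0 = 20000,
                      focal_beta1 = fb, seed = 51)
    s <- run_replicates(cfg, n_reps = reps)
    expect_lt(abs(s$b3_direct_mean - cfg$beta3), 2.5 * s$b3_direct_mc_se)
    expect_lt(abs(s$b3_mr_mean - cfg$beta3), 2.5 * s$b3_mr_mc_se)
  }
})

test_that("mediation-induced two-step false positives shrink without overlap", {
  reps <- 400
  rates <- vapply(c(4000L, 0L), function(n0) {
    cfg <- sim_config("mediation_panel", n1 = 4000, n2 = 4000, n0 = n0,
                      beta2_env = 5, seed = 61)
    run_replicates(cfg, model = "b", n_reps = reps)$power[["two_step"]][["rate"]]
  }, numeric(1))
  # "power" here is the focal variant passing the G-by-E claim with mediation
  # only: a false positive; shared subjects couple the screen and the direct
  # test and inflate it, so removing overlap must not increase it
  se <- sqrt(0.1 * 0.9 / reps)
  expect_lte(rates[2], rates[1] + 2 * se)
})
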