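test_that("genomic-control lambda follows the chi-square(1) median", {
  expect_equal(gc_lambda(rep(qchisq(0.5, 1), 5)), 1)
  set.seed(1)
  x <- rchisq(1e5, 1)
  expect_lt(abs(gc_lambda(x) - 1), 0.02)       # Monte-Carlo under the null
  expect_lt(abs(gc_lambda(2 * x) - 2), 0.04)   # median scales
  expect_error(gc_lambda(numeric(0)), "at least one")
})

test_that("instrument selection prunes by LD within the window only", {
  z <- c(sqrt(qchisq(1e-20, 1, lower.tail = FALSE)),
         sqrt(qchisq(1e-10, 1, lower.tail = FALSE)),
         sqrt(qchisq(1e-12, 1, lower.tail = FALSE)), rep(0.5, 40))
  n1 <- 50000
  panel <- make_panel(43, alpha = z / sqrt(n1), se_alpha = 1 / sqrt(n1),
                      pos = c(1000000L, 1100000L, 1700000L,
                              3000000L + seq_len(40) * 1000000L))
  ld <- function(a, b) {
    if (setequal(c(a, b), c("v1", "v2"))) 0.5 else 0.9
  }
  ivs <- select_instruments(panel, ld = ld, apply_gc = FALSE)
  # v2 is within 500 kb of the stronger v1 at r2 = 0.5 >= 0.1: pruned;
  # v3 is 600/700 kb away from both: kept despite r2 = 0.9
  expect_setequal(ivs$variant_id, c("v1", "v3"))
})

test_that("GC correction is applied to the selection threshold", {
  # median chi-square twice the null median -> lambda = 2
  m <- 41
  chisq <- rep(2 * qchisq(0.5, 1), m)
  chisq[1] <- 30        # raw p = 4.3e-8 < 5e-8, GC-corrected p(15) = 1.1e-4
  chisq[2] <- 80
  chisq[3] <- 90
  n1 <- 50000
  panel <- make_panel(m, alpha = sqrt(chisq) / sqrt(n1),
                      se_alpha = 1 / sqrt(n1))
  raw <- select_instruments(panel, apply_gc = FALSE)
  expect_true("v1" %in% raw$variant_id)
  corrected <- select_instruments(panel, apply_gc = TRUE)
  expect_false("v1" %in% corrected$variant_id)
  expect_setequal(corrected$variant_id, c("v2", "v3"))
  expect_equal(attr(corrected, "gc_lambda"), 2)
})

test_that("overlap correlation is recovered from null z-scores", {
  panel <- make_panel(5, alpha = c(0.01, -0.02, 0.015, 0.002, -0.01),
                      se_alpha = 0.02)
  panel$beta1_hat <- panel$alpha_hat
  panel$se_beta1 <- panel$se_alpha
  expect_equal(estimate_overlap_corr(panel, min_variants = 5), 1.0)
  set.seed(11)
  indep <- make_null_zpanel(10000, r = 0)
  expect_lt(abs(estimate_overlap_corr(indep)), 0.03)
  shared <- make_null_zpanel(10000, r = 0.6)
  expect_gt(estimate_overlap_corr(shared), 0.4)
  expect_error(estimate_overlap_corr(make_null_zpanel(50, 0)), "null variants")
})

test_that("IVW slope matches the closed-form ratio and is scale-equivariant", {
  p <- make_panel(2, alpha = c(0.2, 0.1), beta1 = c(0.1, 0.05))
  expect_equal(ivw_theta(p)$theta_hat, 2.0)
  p2 <- make_panel(5, alpha = 0.07, beta1 = 0.07)
  expect_equal(ivw_theta(p2)$theta_hat, 1.0)
  set.seed(3)
  p3 <- make_panel(20, alpha = rnorm(20, 0, 0.05), beta1 = rnorm(20, 0, 0.05),
                   se_alpha = runif(20, 0.005, 0.02))
  th <- ivw_theta(p3)$theta_hat
  p3c <- p3
  p3c$alpha_hat <- 3 * p3$alpha_hat
  expect_equal(ivw_theta(p3c)$theta_hat, 3 * th)
  degenerate <- make_panel(2, beta1 = 0)
  expect_error(ivw_theta(degenerate), "degenerate")
})

test_that("the MR screen statistic matches hand computation", {
  v <- make_panel(1, alpha = 0.10, beta1 = 0.05, se_alpha = 0.01,
                  se_beta1 = 0.01)
  eff <- structure(list(theta_hat = 1, overlap_corr = 0),
                   class = "causal_effect")
  out <- t_mr_gxe(v, eff)
  expect_equal(out$t_mr, 12.5)                 # 0.05^2 / 2e-4
  expect_equal(out$residual, 0.05)
  null <- make_panel(1, alpha = 0.06, beta1 = 0.06)
  out0 <- t_mr_gxe(null, eff)
  expect_equal(out0$t_mr, 0)
  expect_equal(out0$p_mr, 1)
  bad <- structure(list(theta_hat = 1, overlap_corr = 1.5),
                   class = "causal_effect")
  expect_error(t_mr_gxe(v, bad), "non-positive")
})

test_that("the screen is chi-square calibrated on null variants", {
  set.seed(19)
  r <- 0.5
  panel <- make_null_zpanel(10000, r = r)
  eff <- structure(list(theta_hat = 1, overlap_corr = r),
                   class = "causal_effect")
  res <- t_mr_gxe(panel, eff)
  obs <- sort(-log10(res$p_mr))
  expdq <- sort(-log10(stats::ppoints(length(obs))))
  slope <- sum(obs * expdq) / sum(expdq^2)
  expect_gt(slope, 0.95)
  expect_lt(slope, 1.05)
})

test_that("iterative pleiotropy removal excises planted outliers", {
  set.seed(5)
  m <- 100
  b1 <- rnorm(m, 0, 0.05)
  n1 <- 5e5
  panel <- make_panel(m, alpha = b1 + rnorm(m, 0, 1 / sqrt(n1)),
                      beta1 = b1, se_alpha = 1 / sqrt(n1), se_beta1 = 1e-6)
  # no pleiotropy: fixed point after one iteration, estimate equals IVW
  clean <- imrp_estimate(panel)
  expect_equal(clean$n_iterations, 1L)
  expect_length(clean$removed_ids, 0)
  expect_equal(clean$theta_hat, ivw_theta(panel)$theta_hat)
  # one instrument with a large planted interaction signal
  dirty <- panel
  dirty$alpha_hat[7] <- dirty$alpha_hat[7] + 0.2
  fit <- imrp_estimate(dirty)
  expect_true("v7" %in% fit$removed_ids)
  expect_lt(abs(fit$theta_hat - 1), abs(ivw_theta(dirty)$theta_hat - 1))
  # pleio_alpha = 0 never removes and reproduces plain IVW
  expect_equal(imrp_estimate(dirty, pleio_alpha = 0)$theta_hat,
               ivw_theta(dirty)$theta_hat)
})

test_that("MR-route interaction estimate scales with the exposure mean", {
  v <- make_panel(1, alpha = 0.10, beta1 = 0.05, se_alpha = 0.01,
                  se_beta1 = 0.01)
  eff <- structure(list(theta_hat = 1, overlap_corr = 0),
                   class = "causal_effect")
  expect_equal(interaction_effect_mr(v, eff, mu_E = 1)$estimate, 0.05)
  expect_equal(interaction_effect_mr(v, eff, mu_E = 2)$estimate, 0.025)
  expect_error(interaction_effect_mr(v, eff, mu_E = 0), "not identifiable")
})

test_that("expected bridging coefficient limits and bound hold", {
  expect_equal(expected_theta(0, n1 = 1e4, n2 = 1e4, n0 = 0), 0)
  expect_equal(expected_theta(0.01, 2e4, 2e4, 2e4, form = "independence"), 1)
  grid <- expand.grid(s = c(1e-4, 1e-3, 1e-2), frac = c(0, 0.5, 1),
                      mu = c(0.5, 1, 2))
  for (i in seq_len(nrow(grid))) {
    for (f in c("covariance", "independence")) {
      e <- expected_theta(grid$s[i], 2e4, 2e4, grid$frac[i] * 2e4,
                          mu_E0 = grid$mu[i], mu_E2 = grid$mu[i],
                          form = f)
      expect_lte(e, 1)
    }
  }
  # stronger instruments and larger samples move the expectation toward 1
  expect_gt(expected_theta(1e-2, 2e4, 2e4, 1e4),
            expected_theta(1e-4, 2e4, 2e4, 1e4))
  expect_gt(expected_theta(1e-3, 2e5, 2e5, 1e5),
            expected_theta(1e-3, 2e4, 2e4, 1e4))
})
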