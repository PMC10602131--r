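#' Simulation configuration
#'
#' Builds a validated configuration for the two generative designs used in
#' the calibration, power, and estimator-bias studies.
#'
#' Design `"no_mediation"`: `m` independent variants with allele frequencies
#' drawn Uniform(0.05, 0.5), genotypes standardized to unit variance; main
#' effects drawn N(0, `sigma_beta2`); the phenotype adds an environment main
#' effect (`beta2_env`) and an interaction (`beta3`) between variant 1 and
#' the exposure. Variant 1 measures power, variant 2 type-I error, and the
#' last 100 variants serve as instruments. Design `"mediation_panel"`: 20
#' variants with allele frequency 0.3, standardized without centering; one
#' focal variant carries a main effect (0.1), optionally mediation through
#' the exposure (`mediation_coef` = 0.05, leaving G responsible for 0.25%
#' of Var(E)) and an interaction (0.1); the phenotype residual variance is
#' 10. GWIS subjects are a subset of (or overlap with) the GWAS sample;
#' non-overlapping GWAS subjects have their exposure mean scaled by
#' `overlap_env_mean_factor`.
#'
#' @param design `"no_mediation"` or `"mediation_panel"`.
#' @param m Variant count (design defaults: 102 / 20).
#' @param n1,n2 GWAS and GWIS sample sizes.
#' @param n0 Overlap count (`0 <= n0 <= min(n1, n2)`).
#' @param mu_E1,sigma_E1 Exposure mean/SD for GWAS-only subjects.
#' @param mu_E2,sigma_E2 Exposure mean/SD for GWIS (and overlap) subjects.
#' @param sigma_beta2 Per-variant trait variance explained (design 1).
#' @param beta2_env Environment main effect (design 1: 0.1; design 2: gamma).
#' @param beta3 Interaction effect at the focal variant.
#' @param mediation_coef Genotype-to-exposure coefficient (design 2).
#' @param env_resid_var Exposure residual variance when mediation is present
#'   (design 2: 0.9975, keeping Var(E) = 1).
#' @param resid_var Phenotype residual variance (design 1: 1; design 2: 10).
#' @param overlap_env_mean_factor Exposure-mean multiplier for
#'   non-overlapping GWAS subjects (design 2: 1.5).
#' @param center_genotypes Center genotypes before scaling (design 1: TRUE;
#'   design 2: FALSE, scaling only).
#' @param adjust_marginal_for_E Include E as a covariate in the marginal
#'   (GWAS) model.
#' @param focal_beta1 Optional fixed main effect for variant 1 (overrides the
#'   random draw in design 1; used for same/opposite/no main-effect
#'   scenarios).
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(design = c("no_mediation", "mediation_panel"),
                       m = NULL, n1 = 20000L, n2 = 20000L, n0 = NULL,
                       mu_E1 = NULL, sigma_E1 = 1, mu_E2 = 1, sigma_E2 = 1,
                       sigma_beta2 = 0.005, beta2_env = NULL, beta3 = NULL,
                       mediation_coef = NULL, env_resid_var = 0.9975,
                       resid_var = NULL, overlap_env_mean_factor = 1.5,
                       center_genotypes = NULL, adjust_marginal_for_E = FALSE,
                       focal_beta1 = NULL, seed = 1L) {
  design <- match.arg(design)
  if (design == "no_mediation") {
    if (is.null(m)) m <- 102L
    if (is.null(n0)) n0 <- n2
    if (is.null(mu_E1)) mu_E1 <- 1
    if (is.null(beta2_env)) beta2_env <- 0.1
    if (is.null(beta3)) beta3 <- 0.05
    if (is.null(mediation_coef)) mediation_coef <- 0
    if (is.null(resid_var)) resid_var <- 1
    if (is.null(center_genotypes)) center_genotypes <- TRUE
    iv_idx <- if (m > 2L) 3:m else integer(0)
  } else {
    if (is.null(m)) m <- 20L
    if (is.null(n0)) n0 <- n2
    if (is.null(mu_E1)) mu_E1 <- overlap_env_mean_factor * mu_E2
    if (is.null(beta2_env)) beta2_env <- 1
    if (is.null(beta3)) beta3 <- 0.1
    if (is.null(mediation_coef)) mediation_coef <- 0.05
    if (is.null(resid_var)) resid_var <- 10
    if (is.null(center_genotypes)) center_genotypes <- FALSE
    iv_idx <- 2:m
  }
  cfg <- list(design = design, m = as.integer(m), n1 = as.integer(n1),
              n2 = as.integer(n2), n0 = as.integer(n0),
              mu_E1 = mu_E1, sigma_E1 = sigma_E1, mu_E2 = mu_E2,
              sigma_E2 = sigma_E2, sigma_beta2 = sigma_beta2,
              beta2_env = beta2_env, beta3 = beta3,
              mediation_coef = mediation_coef, env_resid_var = env_resid_var,
              resid_var = resid_var,
              overlap_env_mean_factor = overlap_env_mean_factor,
              center_genotypes = center_genotypes,
              adjust_marginal_for_E = adjust_marginal_for_E,
              focal_beta1 = focal_beta1, seed = as.integer(seed),
              focal_idx = 1L, null_idx = 2L, iv_idx = iv_idx)
  problems <- character(0)
  if (cfg$m < 2L) problems <- c(problems, "m must be >= 2")
  if (cfg$n0 < 0L || cfg$n0 > min(cfg$n1, cfg$n2))
    problems <- c(problems, "n0 must satisfy 0 <= n0 <= min(n1, n2)")
  if (cfg$sigma_E1 <= 0 || cfg$sigma_E2 <= 0)
    problems <- c(problems, "environment SDs must be positive")
  if (cfg$sigma_beta2 < 0) problems <- c(problems, "sigma_beta2 must be >= 0")
  if (cfg$resid_var <= 0) problems <- c(problems, "resid_var must be positive")
  if (length(problems))
    stop("invalid simulation config: ", paste(problems, collapse = "; "))
  structure(cfg, class = "sim_config")
}

# cohort layout shared by both designs:
#   rows 1..n0            overlap (GWAS and GWIS; exposure from GWIS dist)
#   rows n0+1..n1         GWAS-only (exposure mean mu_E1)
#   rows n1+1..n1+n2-n0   GWIS-only (exposure from GWIS dist)
.cohort_idx <- function(cfg) {
  n_total <- cfg$n1 + cfg$n2 - cfg$n0
  idx_gwis <- if (cfg$n0 < cfg$n2) c(seq_len(cfg$n0), (cfg$n1 + 1):n_total)
              else seq_len(cfg$n0)
  list(n_total = n_total, idx_gwas = seq_len(cfg$n1), idx_gwis = idx_gwis,
       is_gwas_only = c(rep(FALSE, cfg$n0), rep(TRUE, cfg$n1 - cfg$n0),
                        rep(FALSE, n_total - cfg$n1)))
}

#' Generate one replicate of the no-mediation design
#'
#' @param config A `sim_config` with `design = "no_mediation"`.
#' @return List with `G` (standardized genotype matrix), `E`, `y`,
#'   `idx_gwas`, `idx_gwis`, `beta1` (true main effects), `maf`, `config`.
#' @export
simulate_no_mediation <- function(config) {
  stopifnot(inherits(config, "sim_config"), config$design == "no_mediation")
  lay <- .cohort_idx(config)
  n <- lay$n_total
  maf <- stats::runif(config$m, 0.05, 0.5)
  G <- matrix(stats::rbinom(n * config$m, 2L, rep(maf, each = n)),
              nrow = n, ncol = config$m)
  ctr <- if (config$center_genotypes) 2 * maf else rep(0, config$m)
  G <- sweep(G, 2L, ctr, "-")
  G <- sweep(G, 2L, sqrt(2 * maf * (1 - maf)), "/")
  E <- numeric(n)
  E[lay$is_gwas_only] <- stats::rnorm(sum(lay$is_gwas_only),
                                      config$mu_E1, config$sigma_E1)
  E[!lay$is_gwas_only] <- stats::rnorm(sum(!lay$is_gwas_only),
                                       config$mu_E2, config$sigma_E2)
  beta1 <- stats::rnorm(config$m, 0, sqrt(config$sigma_beta2))
  if (!is.null(config$focal_beta1)) beta1[config$focal_idx] <- config$focal_beta1
  y <- as.vector(G %*% beta1) + config$beta2_env * E +
    config$beta3 * G[, config$focal_idx] * E +
    stats::rnorm(n, 0, sqrt(config$resid_var))
  list(G = G, E = E, y = y, idx_gwas = lay$idx_gwas, idx_gwis = lay$idx_gwis,
       beta1 = beta1, maf = maf, config = config)
}

#' Generate one replicate of the mediation-panel design
#'
#' @param config A `sim_config` with `design = "mediation_panel"`.
#' @param model `"a"` (no mediation, no interaction), `"b"` (mediation only),
#'   or `"c"` (mediation and interaction); the focal variant is variant 1.
#' @param gamma Environment main effect (1 or 5 in the reference settings);
#'   defaults to `config$beta2_env`.
#' @return Same structure as [simulate_no_mediation()].
#' @export
simulate_mediation_panel <- function(config, model = c("a", "b", "c"),
                                     gamma = NULL) {
  stopifnot(inherits(config, "sim_config"), config$design == "mediation_panel")
  model <- match.arg(model)
  if (is.null(gamma)) gamma <- config$beta2_env
  lay <- .cohort_idx(config)
  n <- lay$n_total
  maf <- rep(0.3, config$m)
  G <- matrix(stats::rbinom(n * config$m, 2L, 0.3), nrow = n, ncol = config$m)
  if (config$center_genotypes) G <- sweep(G, 2L, 2 * maf, "-")
  G <- G / sqrt(2 * 0.3 * 0.7)
  mu <- ifelse(lay$is_gwas_only, config$mu_E1, config$mu_E2)
  g_focal <- G[, config$focal_idx]
  E <- if (model == "a") {
    stats::rnorm(n, mu, config$sigma_E2)
  } else {
    config$mediation_coef * g_focal +
      stats::rnorm(n, mu, sqrt(config$env_resid_var))
  }
  beta1 <- numeric(config$m)
  beta1[config$focal_idx] <- 0.1
  y <- 0.1 * g_focal + gamma * E +
    (if (model == "c") config$beta3 * g_focal * E else 0) +
    stats::rnorm(n, 0, sqrt(config$resid_var))
  list(G = G, E = E, y = y, idx_gwas = lay$idx_gwas, idx_gwis = lay$idx_gwis,
       beta1 = beta1, maf = maf, config = config, model = model, gamma = gamma)
}

# marginal (GWAS) fits for every variant, closed-form OLS; optionally
# adjusting for E. Returns beta, se, and residual-variance estimates.
.fit_marginal_all <- function(G, y, E = NULL) {
  n <- length(y)
  Gc <- sweep(G, 2L, colMeans(G), "-")
  yc <- y - mean(y)
  if (is.null(E)) {
    Sgg <- colSums(Gc^2)
    Sgy <- as.vector(crossprod(Gc, yc))
    beta <- Sgy / Sgg
    rss <- sum(yc^2) - beta^2 * Sgg
    s2 <- rss / (n - 2)
  } else {
    Ec <- E - mean(E)
    See <- sum(Ec^2)
    gam <- as.vector(crossprod(Gc, Ec)) / See
    yc <- yc - Ec * (sum(Ec * yc) / See)
    Gt_gg <- colSums(Gc^2) - gam^2 * See
    Sgy <- as.vector(crossprod(Gc, yc))   # Ec'yc = 0 after residualizing y
    beta <- Sgy / Gt_gg
    rss <- sum(yc^2) - beta^2 * Gt_gg
    s2 <- rss / (n - 3)
    Sgg <- Gt_gg
  }
  list(beta = beta, se = sqrt(s2 / Sgg))
}

# interaction-model (GWIS) fits for every variant via 4x4 normal equations
# on [1, G_j, E, G_j*E]; returns coefficient and SE matrices (m x 4).
.fit_model1_all <- function(G, E, y) {
  n <- length(y)
  m <- ncol(G)
  G2 <- G * G
  Ey <- E * y
  Sg <- colSums(G); Sg2 <- colSums(G2)
  SgE <- as.vector(crossprod(G, E)); Sg2E <- as.vector(crossprod(G2, E))
  SgE2 <- as.vector(crossprod(G, E^2)); Sg2E2 <- as.vector(crossprod(G2, E^2))
  Sgy <- as.vector(crossprod(G, y)); SgEy <- as.vector(crossprod(G, Ey))
  SE <- sum(E); SE2 <- sum(E^2); Sy <- sum(y); Syy <- sum(y^2); SEy <- sum(Ey)
  coef <- matrix(NA_real_, m, 4)
  se <- matrix(NA_real_, m, 4)
  for (j in seq_len(m)) {
    M <- matrix(c(n,      Sg[j],   SE,      SgE[j],
                  Sg[j],  Sg2[j],  SgE[j],  Sg2E[j],
                  SE,     SgE[j],  SE2,     SgE2[j],
                  SgE[j], Sg2E[j], SgE2[j], Sg2E2[j]), 4, 4)
    v <- c(Sy, Sgy[j], SEy, SgEy[j])
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) next  # singular design for this variant
    b <- backsolve(ch, forwardsolve(t(ch), v))
    rss <- Syy - sum(b * v)
    s2 <- rss / (n - 4)
    coef[j, ] <- b
    se[j, ] <- sqrt(pmax(s2, 0) * diag(chol2inv(ch)))
  }
  list(coef = coef, se = se)
}

#' Fit GWAS and GWIS working models on a simulated dataset
#'
#' Fits, per variant, the marginal model on the GWAS sample (adding E as a
#' covariate iff the config requests it) and the interaction model
#' `y ~ G + E + G:E` on the GWIS sample, and assembles the estimates into a
#' harmonized panel (synthetic alleles A/G; no allele bookkeeping needed).
#'
#' @param dataset Output of [simulate_no_mediation()] or
#'   [simulate_mediation_panel()].
#' @param config The `sim_config` (defaults to the one stored in `dataset`).
#' @return A `harmonized_panel`; variants with singular fits are excluded and
#'   counted in the filter log.
#' @export
fit_summary_stats <- function(dataset, config = dataset$config) {
  Gg <- dataset$G[dataset$idx_gwas, , drop = FALSE]
  yg <- dataset$y[dataset$idx_gwas]
  Eg <- if (config$adjust_marginal_for_E) dataset$E[dataset$idx_gwas] else NULL
  marg <- .fit_marginal_all(Gg, yg, Eg)
  Gw <- dataset$G[dataset$idx_gwis, , drop = FALSE]
  m1 <- .fit_model1_all(Gw, dataset$E[dataset$idx_gwis], dataset$y[dataset$idx_gwis])
  m <- config$m
  chi <- function(b, s) stats::pchisq((b / s)^2, df = 1, lower.tail = FALSE)
  panel <- data.frame(
    variant_id = paste0("v", seq_len(m)), chrom = "1",
    pos = seq_len(m) * 2000000L,
    effect_allele = "A", other_allele = "G",
    alpha_hat = marg$beta, se_alpha = marg$se,
    p_alpha = chi(marg$beta, marg$se),
    n1 = config$n1, eaf_gwas = dataset$maf,
    beta1_hat = m1$coef[, 2], se_beta1 = m1$se[, 2],
    p_beta1 = chi(m1$coef[, 2], m1$se[, 2]),
    beta2_hat = m1$coef[, 3], se_beta2 = m1$se[, 3],
    beta3_hat = m1$coef[, 4], se_beta3 = m1$se[, 4],
    p_beta3 = chi(m1$coef[, 4], m1$se[, 4]),
    n2 = config$n2, eaf_gwis = dataset$maf,
    stringsAsFactors = FALSE
  )
  ok <- stats::complete.cases(panel[, c("alpha_hat", "se_alpha",
                                        "beta1_hat", "se_beta1")])
  log <- c(input_gwas = m, singular_fit = sum(!ok), retained = sum(ok))
  .new_panel(panel[ok, , drop = FALSE], log)
}

# one-off overlap-correlation estimate from a dedicated null panel generated
# under the same cohort/exposure design (emulating the genome-wide estimate
# from null variants used on real data).
.overlap_r_panel <- function(config, n_null = 1000L, seed_offset = 999000L) {
  set.seed(config$seed + seed_offset)
  dataset <- if (config$design == "no_mediation")
    simulate_no_mediation(config) else simulate_mediation_panel(config, "a")
  lay <- .cohort_idx(config)
  G0 <- matrix(stats::rbinom(lay$n_total * n_null, 2L, 0.3),
               nrow = lay$n_total, ncol = n_null) / sqrt(2 * 0.3 * 0.7)
  Eg <- if (config$adjust_marginal_for_E) dataset$E[dataset$idx_gwas] else NULL
  marg <- .fit_marginal_all(G0[dataset$idx_gwas, ], dataset$y[dataset$idx_gwas], Eg)
  m1 <- .fit_model1_all(G0[dataset$idx_gwis, ], dataset$E[dataset$idx_gwis],
                        dataset$y[dataset$idx_gwis])
  # every auxiliary variant is null by construction, so no p-value filter is
  # needed (the filter exists to exclude real signals and would only
  # truncate the z distribution and attenuate the correlation)
  stats::cor(marg$beta / marg$se, m1$coef[, 2] / m1$se[, 2])
}

#' Run a replicate study of calibration, power, and estimator behavior
#'
#' Per replicate: generate a dataset, fit the working models, estimate the
#' bridging coefficient by IVW over the designated instrument variants,
#' evaluate the direct, MR-screen, and two-step procedures, and record the
#' interaction-effect estimates for the focal variant. In the no-mediation
#' design, power and type-I error are evaluated per-variant at level `alpha`
#' on variants 1 and 2; in the mediation-panel design they are family-wise
#' over all `m` variants with Bonferroni correction (`alpha / m` per test;
#' the two-step procedure applies its stage-2 Bonferroni to the screen
#' survivors).
#'
#' @param config A `sim_config`.
#' @param model Mediation-panel model (`"a"`, `"b"`, `"c"`); ignored for the
#'   no-mediation design.
#' @param n_reps Number of replicates.
#' @param alpha Family-wise (or per-variant, design 1) significance level.
#' @param overlap_r `"panel"` (default: estimated once from a dedicated null
#'   panel under the same cohort design), `"per_replicate"` (estimated from
#'   each replicate's null variants), or a fixed numeric value.
#' @return A `replicate_summary` list: rejection rates with 95% binomial
#'   confidence intervals, mean/SD of the bridging coefficient, means of the
#'   direct and MR-route interaction estimators, overlap correlation used,
#'   and failure count.
#' @export
run_replicates <- function(config, model = "a", n_reps = 500L, alpha = 0.05,
                           overlap_r = "panel") {
  stopifnot(n_reps >= 1L)
  design1 <- config$design == "no_mediation"
  r_fixed <- if (is.numeric(overlap_r)) overlap_r
             else if (identical(overlap_r, "panel")) .overlap_r_panel(config)
             else NULL
  rec <- list()
  n_fail <- 0L
  for (rep_i in seq_len(n_reps)) {
    res <- tryCatch({
      set.seed(config$seed + rep_i)
      dataset <- if (design1) simulate_no_mediation(config)
                 else simulate_mediation_panel(config, model)
      panel <- fit_summary_stats(dataset, config)
      r <- if (is.null(r_fixed)) {
        z1 <- panel$alpha_hat / panel$se_alpha
        z2 <- panel$beta1_hat / panel$se_beta1
        nullv <- z1^2 < stats::qchisq(0.95, 1) & z2^2 < stats::qchisq(0.95, 1)
        if (sum(nullv) >= 3L) stats::cor(z1[nullv], z2[nullv]) else 0
      } else r_fixed
      ivs <- panel[panel$variant_id %in% paste0("v", config$iv_idx), ,
                   drop = FALSE]
      eff <- ivw_theta(ivs, overlap_corr = r)
      mr <- t_mr_gxe(panel, eff)
      dir <- t_direct(panel)
      focal <- match(paste0("v", config$focal_idx), panel$variant_id)
      mu_E_gwas <- mean(dataset$E[dataset$idx_gwas])
      est_mr <- mr$residual[focal] / mu_E_gwas
      if (design1) {
        nullv <- match(paste0("v", config$null_idx), panel$variant_id)
        list(theta = eff$theta_hat, r = r,
             b3_direct = panel$beta3_hat[focal], b3_mr = est_mr,
             pow_direct = dir$p_direct[focal] < alpha,
             pow_mr = mr$p_mr[focal] < alpha,
             t1_direct = dir$p_direct[nullv] < alpha,
             t1_mr = mr$p_mr[nullv] < alpha,
             pow_two_step = NA, t1_two_step = NA)
      } else {
        ts <- two_step(panel, eff, screen_alpha = alpha / config$m,
                       n_exposures = 1L, alpha = alpha)
        thr <- alpha / config$m
        # type-I error is measured on the zero-effect variants, family-wise
        # (the focal variant is the designated power variant, as in the
        # two-variant convention of the no-mediation design)
        nullv <- which(panel$variant_id != paste0("v", config$focal_idx))
        list(theta = eff$theta_hat, r = r,
             b3_direct = panel$beta3_hat[focal], b3_mr = est_mr,
             pow_direct = dir$p_direct[focal] < thr,
             pow_mr = mr$p_mr[focal] < thr,
             pow_two_step = ts$two_step_pass[focal],
             t1_direct = any(dir$p_direct[nullv] < thr),
             t1_mr = any(mr$p_mr[nullv] < thr),
             t1_two_step = any(ts$two_step_pass[nullv]))
      }
    }, error = function(e) NULL)
    if (is.null(res)) n_fail <- n_fail + 1L else rec[[length(rec) + 1L]] <- res
  }
  if (!length(rec)) stop("all ", n_reps, " replicates failed")
  col <- function(nm) vapply(rec, function(x) as.numeric(x[[nm]]), numeric(1))
  rate_ci <- function(x) {
    x <- x[!is.na(x)]
    p <- mean(x)
    half <- 1.96 * sqrt(p * (1 - p) / length(x))
    c(rate = p, lo = max(0, p - half), hi = min(1, p + half))
  }
  structure(list(
    design = config$design, model = if (design1) NA_character_ else model,
    n_reps = length(rec), n_failures = n_fail, alpha = alpha,
    overlap_corr = if (is.null(r_fixed)) mean(col("r")) else r_fixed,
    theta_mean = mean(col("theta")), theta_sd = stats::sd(col("theta")),
    theta_mc_se = stats::sd(col("theta")) / sqrt(length(rec)),
    b3_direct_mean = mean(col("b3_direct")),
    b3_direct_mc_se = stats::sd(col("b3_direct")) / sqrt(length(rec)),
    b3_mr_mean = mean(col("b3_mr")),
    b3_mr_mc_se = stats::sd(col("b3_mr")) / sqrt(length(rec)),
    power = list(t_direct = rate_ci(col("pow_direct")),
                 t_mr = rate_ci(col("pow_mr")),
                 two_step = rate_ci(col("pow_two_step"))),
    type1 = list(t_direct = rate_ci(col("t1_direct")),
                 t_mr = rate_ci(col("t1_mr")),
                 two_step = rate_ci(col("t1_two_step")))
  ), class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("replicate study: %s%s, %d replicates (%d failed), alpha = %g\n",
              x$design,
              if (!is.na(x$model)) paste0(" model ", x$model) else "",
              x$n_reps, x$n_failures, x$alpha))
  cat(sprintf("  theta: mean %.4f (sd %.4f); overlap r used: %.3f\n",
              x$theta_mean, x$theta_sd, x$overlap_corr))
  cat(sprintf("  focal interaction: direct %.4f (mc se %.4f), MR-route %.4f (mc se %.4f)\n",
              x$b3_direct_mean, x$b3_direct_mc_se, x$b3_mr_mean, x$b3_mr_mc_se))
  fmt <- function(z) sprintf("%.4f [%.4f, %.4f]", z["rate"], z["lo"], z["hi"])
  for (nm in names(x$power))
    cat(sprintf("  %-9s power %s   type-I %s\n", nm,
                fmt(x$power[[nm]]), fmt(x$type1[[nm]])))
  invisible(x)
}
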