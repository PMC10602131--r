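#' Direct interaction test from GWIS summary statistics
#'
#' Wald chi-square(1) test of the interaction coefficient:
#' `beta3^2 / se_beta3^2`.
#'
#' @param variant One or more harmonized-panel rows carrying `beta3_hat` and
#'   `se_beta3`.
#' @return data.frame with `variant_id`, `t_direct`, `p_direct`.
#' @export
t_direct <- function(variant) {
  if (!all(c("beta3_hat", "se_beta3") %in% names(variant)) ||
      all(is.na(variant$beta3_hat)))
    stop("interaction effect (beta3) not available in this panel")
  stat <- variant$beta3_hat^2 / variant$se_beta3^2
  data.frame(variant_id = variant$variant_id, t_direct = stat,
             p_direct = stats::pchisq(stat, df = 1, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Direct interaction test from individual-level data
#'
#' Ordinary least squares of the phenotype on genotype, exposure, their
#' product, and optional covariates; returns the interaction coefficient and
#' its Wald chi-square(1) test.
#'
#' @param y Phenotype vector.
#' @param g Genotype vector.
#' @param e Exposure vector.
#' @param covariates Optional numeric matrix of extra covariates.
#' @return List with `beta3`, `se`, `statistic`, `p`.
#' @export
t_direct_regression <- function(y, g, e, covariates = NULL) {
  n <- length(y)
  stopifnot(length(g) == n, length(e) == n)
  X <- cbind(g = g, e = e, gxe = g * e)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    X <- cbind(X, covariates)
  }
  fit <- stats::lm(y ~ X)
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    bad <- sub("^X", "", names(beta)[is.na(beta)])
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  b3 <- sm["Xgxe", "Estimate"]
  se <- sm["Xgxe", "Std. Error"]
  stat <- (b3 / se)^2
  list(beta3 = b3, se = se, statistic = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Marginal-vs-main difference test
#'
#' Chi-square(1) test of `alpha - beta1`, accounting for sample overlap:
#' `(alpha - beta1)^2 / (se_a^2 + se_b1^2 - 2 r se_a se_b1)`. Equivalent to
#' the direct interaction test when GWAS and GWIS are run on the same data
#' and the marginal model adjusts for the exposure.
#'
#' @param variant One or more harmonized-panel rows.
#' @param overlap_corr Overlap correlation r.
#' @return data.frame with `variant_id`, `t_diff`, `p_diff`.
#' @export
t_diff <- function(variant, overlap_corr = 0) {
  v <- variant$se_alpha^2 + variant$se_beta1^2 -
    2 * overlap_corr * variant$se_alpha * variant$se_beta1
  if (any(v <= 0)) stop("non-positive var(alpha - beta1)")
  stat <- (variant$alpha_hat - variant$beta1_hat)^2 / v
  data.frame(variant_id = variant$variant_id, t_diff = stat,
             p_diff = stats::pchisq(stat, df = 1, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Two-step interaction testing: MR screen, then direct test
#'
#' Step 1 screens every variant with the MR-based test at `screen_alpha`.
#' Step 2 applies the direct interaction test to the survivors at the
#' Bonferroni threshold `0.05 / (n_survivors * n_exposures)`. A variant
#' passes the two-step procedure iff it passes both.
#'
#' @param panel A harmonized panel (needs `beta3_hat`/`se_beta3`).
#' @param effect A `causal_effect` (theta and overlap correlation).
#' @param screen_alpha Step-1 threshold: 5e-8 for genome-scale panels,
#'   `0.05 / nrow(panel)` for simulation-scale panels. Default picks by
#'   panel size (>= 10000 rows: genome-wide).
#' @param n_exposures Number of environmental exposures tested (default 1).
#' @param alpha Family-wise level for the step-2 Bonferroni correction.
#' @return data.frame with per-variant `t_mr`, `p_mr`, `t_direct`,
#'   `p_direct`, `screen_pass`, `two_step_pass`; attribute
#'   `stage2_threshold`.
#' @export
two_step <- function(panel, effect, screen_alpha = NULL, n_exposures = 1L,
                     alpha = 0.05) {
  if (is.null(screen_alpha))
    screen_alpha <- if (nrow(panel) >= 10000L) 5e-8 else alpha / nrow(panel)
  mr <- t_mr_gxe(panel, effect)
  dir <- t_direct(panel)
  res <- cbind(mr, dir[, c("t_direct", "p_direct")])
  res$screen_pass <- res$p_mr < screen_alpha
  n_surv <- sum(res$screen_pass)
  thr <- if (n_surv > 0) alpha / (n_surv * n_exposures) else NA_real_
  res$two_step_pass <- res$screen_pass & !is.na(res$p_direct) &
    n_surv > 0 & res$p_direct < thr
  attr(res, "stage2_threshold") <- thr
  attr(res, "screen_alpha") <- screen_alpha
  res
}

#' Group screening results into loci and independent signals
#'
#' Iteratively takes the most significant unassigned variant as a lead and
#' assigns every unassigned variant within `window_bp` on its chromosome to
#' that locus. Within each locus, independent signals are selected greedily
#' in ascending p order subject to pairwise r2 below `r2_max`.
#'
#' @param results data.frame with `variant_id`, `chrom`, `pos`, `p_mr`.
#' @param window_bp Locus half-width (default 1 Mb).
#' @param ld LD provider (see [ld_from_genotypes()]); `NULL` = independent.
#' @param r2_max Signal independence threshold (default 0.1).
#' @return data.frame with one row per locus: `locus`, `lead`, `chrom`,
#'   `pos`, `p_lead`, `n_members`, `members`, `signals` (comma-separated).
#' @export
define_loci <- function(results, window_bp = 1000000L, ld = NULL, r2_max = 0.1) {
  ord <- order(results$p_mr)
  assigned <- rep(NA_integer_, nrow(results))
  leads <- integer(0)
  for (i in ord) {
    if (!is.na(assigned[i])) next
    leads <- c(leads, i)
    locus_id <- length(leads)
    member <- is.na(assigned) & results$chrom == results$chrom[i] &
      abs(results$pos - results$pos[i]) <= window_bp
    assigned[member] <- locus_id
  }
  out <- lapply(seq_along(leads), function(k) {
    i <- leads[k]
    members <- which(assigned == k)
    members <- members[order(results$p_mr[members])]
    signals <- integer(0)
    for (j in members) {
      indep <- all(vapply(signals, function(s)
        .ld_r2(ld, results$variant_id[j], results$variant_id[s]) < r2_max,
        logical(1)))
      if (indep) signals <- c(signals, j)
    }
    data.frame(locus = k, lead = results$variant_id[i],
               chrom = results$chrom[i], pos = results$pos[i],
               p_lead = results$p_mr[i], n_members = length(members),
               members = paste(results$variant_id[members], collapse = ","),
               signals = paste(results$variant_id[signals], collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Correlation between main-effect and interaction test statistics
#'
#' In the interaction model the main-effect and interaction estimates are
#' collinear through the exposure; their estimation errors correlate as
#' `-mu_E / sqrt(mu_E^2 + sigma_E^2)`.
#'
#' @param mu_E Exposure mean.
#' @param sigma_E Exposure standard deviation (> 0).
#' @return The correlation coefficient.
#' @export
main_inter_corr <- function(mu_E, sigma_E) {
  if (!is.finite(sigma_E) || sigma_E <= 0) stop("sigma_E must be positive")
  -mu_E / sqrt(mu_E^2 + sigma_E^2)
}
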