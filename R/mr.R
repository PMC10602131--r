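#' Genomic-control lambda
#'
#' Median of the observed one-degree-of-freedom chi-square statistics divided
#' by the chi-square(1) median (0.4549), the standard inflation diagnostic.
#'
#' @param chisq_values Numeric vector of chi-square(1) statistics.
#' @return The genomic-control lambda (values below 1 are returned as-is).
#' @export
gc_lambda <- function(chisq_values) {
  chisq_values <- chisq_values[is.finite(chisq_values)]
  if (!length(chisq_values)) stop("gc_lambda() needs at least one statistic")
  stats::median(chisq_values) / stats::qchisq(0.5, df = 1)
}

# r2 between two variants under the supported LD providers: NULL (all
# independent), a function(id_a, id_b), or a symmetric matrix with dimnames.
.ld_r2 <- function(ld, a, b) {
  if (is.null(ld)) return(0)
  if (is.function(ld)) return(ld(a, b))
  if (is.matrix(ld)) {
    if (a %in% rownames(ld) && b %in% colnames(ld)) return(ld[a, b])
    return(0)
  }
  stop("unsupported LD provider; use NULL, a function(id_a, id_b), or a matrix")
}

#' LD provider from a genotype matrix
#'
#' @param geno Numeric matrix, individuals x variants, with variant ids as
#'   column names.
#' @return A `function(id_a, id_b)` returning the squared Pearson correlation.
#' @export
ld_from_genotypes <- function(geno) {
  r2 <- stats::cor(geno)^2
  function(a, b) if (a %in% rownames(r2) && b %in% colnames(r2)) r2[a, b] else 0
}

#' LD provider from a pairwise r2 table
#'
#' @param tab data.frame with columns `id_a`, `id_b`, `r2` (unordered pairs).
#' @return A `function(id_a, id_b)`; unlisted pairs return 0.
#' @export
ld_from_table <- function(tab) {
  key <- c(paste(tab$id_a, tab$id_b, sep = "\r"),
           paste(tab$id_b, tab$id_a, sep = "\r"))
  val <- c(tab$r2, tab$r2)
  function(a, b) {
    hit <- match(paste(a, b, sep = "\r"), key)
    if (is.na(hit)) 0 else val[hit]
  }
}

#' Select LD-pruned genome-wide-significant instruments
#'
#' Candidate instruments are GWAS-significant variants (p < `p_thresh` after
#' optional genomic-control correction of the marginal chi-square). Greedy
#' pruning in ascending p order keeps a candidate only if its r2 with every
#' already-kept variant within `window_bp` on the same chromosome is below
#' `r2_max`.
#'
#' @param panel A harmonized panel.
#' @param p_thresh Selection threshold on the GWAS p-value (default 5e-8).
#' @param window_bp Pruning window (default 500 kb).
#' @param r2_max Maximum tolerated r2 between kept instruments (default 0.1).
#' @param ld LD provider (see [ld_from_genotypes()]); `NULL` treats all
#'   variants as independent.
#' @param apply_gc If `TRUE`, divide marginal chi-squares by the
#'   genomic-control lambda (when lambda > 1) before selection.
#' @return The panel rows of the selected instruments with attributes
#'   `gc_lambda`, `p_thresh`, `window_bp`, `r2_max`.
#' @export
select_instruments <- function(panel, p_thresh = 5e-8, window_bp = 500000L,
                               r2_max = 0.1, ld = NULL, apply_gc = TRUE) {
  z2 <- (panel$alpha_hat / panel$se_alpha)^2
  lambda <- gc_lambda(z2)
  z2_adj <- if (apply_gc && lambda > 1) z2 / lambda else z2
  p_adj <- stats::pchisq(z2_adj, df = 1, lower.tail = FALSE)
  cand <- which(p_adj < p_thresh)
  cand <- cand[order(p_adj[cand])]
  kept <- integer(0)
  for (i in cand) {
    near <- kept[panel$chrom[kept] == panel$chrom[i] &
                   abs(panel$pos[kept] - panel$pos[i]) <= window_bp]
    indep <- TRUE
    for (k in near) {
      if (.ld_r2(ld, panel$variant_id[i], panel$variant_id[k]) >= r2_max) {
        indep <- FALSE
        break
      }
    }
    if (indep) kept <- c(kept, i)
  }
  if (length(kept) < 2L)
    stop("fewer than 2 instruments survive selection; ",
         "the bridging coefficient is not estimable")
  out <- panel[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "gc_lambda") <- lambda
  attr(out, "p_thresh") <- p_thresh
  attr(out, "window_bp") <- window_bp
  attr(out, "r2_max") <- r2_max
  out
}

#' Overlap correlation between GWAS and GWIS effect estimates
#'
#' Shared subjects between the GWAS and GWIS cohorts correlate the estimation
#' errors of the marginal and main effects. The correlation is estimated as
#' the Pearson correlation of the GWAS and GWIS z-scores over null variants
#' (both p-values above `p_null_min`).
#'
#' @param panel A harmonized panel.
#' @param p_null_min Null-variant p-value floor (default 0.05).
#' @param min_variants Minimum number of null variants required (default 100).
#' @return Correlation in \[-1, 1\].
#' @export
estimate_overlap_corr <- function(panel, p_null_min = 0.05, min_variants = 100L) {
  z_gwas <- panel$alpha_hat / panel$se_alpha
  z_gwis <- panel$beta1_hat / panel$se_beta1
  p_gwas <- stats::pchisq(z_gwas^2, df = 1, lower.tail = FALSE)
  p_gwis <- stats::pchisq(z_gwis^2, df = 1, lower.tail = FALSE)
  nullv <- is.finite(p_gwas) & is.finite(p_gwis) &
    p_gwas > p_null_min & p_gwis > p_null_min
  if (sum(nullv) < min_variants)
    stop("only ", sum(nullv), " null variants with p > ", p_null_min,
         "; relax p_null_min or lower min_variants")
  stats::cor(z_gwas[nullv], z_gwis[nullv])
}

#' Inverse-variance-weighted bridging coefficient
#'
#' Estimates the slope `theta` of the marginal effects on the main effects
#' across instruments: `theta_hat = sum(w a b1) / sum(w b1^2)` with weights
#' `w = 1 / var(alpha_hat)` (no-intercept weighted least squares). `theta`
#' captures the systematic contribution of the main effect to the marginal
#' effect; it converges to 1 when GWAS and GWIS measure phenotype and
#' environment homogeneously.
#'
#' @param instruments Panel rows of the instruments (>= 2).
#' @param overlap_corr Overlap correlation carried through to the result.
#' @param se_method `"model"` (weighted-least-squares, default) or
#'   `"sandwich"` (heteroskedasticity-robust).
#' @return List of class `causal_effect` with `theta_hat`, `se_theta`,
#'   `n_iv`, `overlap_corr`, `n_iterations`, `removed_ids`.
#' @export
ivw_theta <- function(instruments, overlap_corr = 0,
                      se_method = c("model", "sandwich")) {
  se_method <- match.arg(se_method)
  if (nrow(instruments) < 2L) stop("at least 2 instruments are required")
  a <- instruments$alpha_hat
  b <- instruments$beta1_hat
  w <- 1 / instruments$se_alpha^2
  denom <- sum(w * b^2)
  if (denom == 0) stop("degenerate instrument set: sum(w * beta1^2) = 0")
  theta <- sum(w * a * b) / denom
  se <- if (se_method == "model") {
    sqrt(1 / denom)
  } else {
    resid <- a - theta * b
    sqrt(sum(w^2 * b^2 * resid^2)) / denom
  }
  structure(list(theta_hat = theta, se_theta = se, n_iv = nrow(instruments),
                 overlap_corr = overlap_corr, n_iterations = 1L,
                 removed_ids = character(0)),
            class = "causal_effect")
}

#' @export
print.causal_effect <- function(x, ...) {
  cat(sprintf(
    "bridging coefficient theta = %.4f (se %.4f), %d IVs, overlap r = %.3f, %d iteration(s)\n",
    x$theta_hat, x$se_theta, x$n_iv, x$overlap_corr, x$n_iterations))
  if (length(x$removed_ids))
    cat("removed as pleiotropic:", paste(x$removed_ids, collapse = ", "), "\n")
  invisible(x)
}

#' MR-based screen for interaction and mediation at one or more variants
#'
#' The screening statistic is the squared departure of the marginal effect
#' from the bridging line, `(alpha - theta * beta1)^2 / var(alpha - theta *
#' beta1)`, referred to chi-square(1). The variance treats `theta_hat` as a
#' plug-in constant and accounts for GWAS/GWIS sample overlap:
#' `var = se_a^2 + theta^2 se_b1^2 - 2 theta r se_a se_b1`.
#'
#' @param variant One or more harmonized-panel rows.
#' @param effect A `causal_effect` from [ivw_theta()] or [imrp_estimate()].
#' @return data.frame with `variant_id`, `residual`, `se_residual`, `t_mr`,
#'   `p_mr`.
#' @export
t_mr_gxe <- function(variant, effect) {
  theta <- effect$theta_hat
  r <- effect$overlap_corr
  resid <- variant$alpha_hat - theta * variant$beta1_hat
  v <- variant$se_alpha^2 + theta^2 * variant$se_beta1^2 -
    2 * theta * r * variant$se_alpha * variant$se_beta1
  if (any(v <= 0))
    stop("non-positive var(alpha - theta*beta1); overlap correlation invalid")
  t_mr <- resid^2 / v
  data.frame(variant_id = variant$variant_id, residual = resid,
             se_residual = sqrt(v), t_mr = t_mr,
             p_mr = stats::pchisq(t_mr, df = 1, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Iterative MR with pleiotropy removal
#'
#' Alternates (i) IVW estimation of the bridging coefficient on the current
#' instruments and (ii) the per-instrument pleiotropy (screening) test,
#' removing instruments with `p_mr < pleio_alpha`, until no instrument is
#' removed, the estimate changes by less than `tol`, or `max_iter` is reached.
#'
#' @param instruments Panel rows of the initial instruments (>= 2).
#' @param overlap_corr Overlap correlation r.
#' @param pleio_alpha Removal threshold; default `0.05 / m` (Bonferroni over
#'   the initial instrument count).
#' @param max_iter Maximum iterations (default 10).
#' @param tol Convergence tolerance on `theta_hat` (default 1e-6).
#' @inheritParams ivw_theta
#' @return A `causal_effect` with `removed_ids` and `n_iterations` recording
#'   the iteration trace.
#' @export
imrp_estimate <- function(instruments, overlap_corr = 0, pleio_alpha = NULL,
                          max_iter = 10L, tol = 1e-6,
                          se_method = c("model", "sandwich")) {
  se_method <- match.arg(se_method)
  if (is.null(pleio_alpha)) pleio_alpha <- 0.05 / nrow(instruments)
  cur <- instruments
  removed <- character(0)
  eff <- ivw_theta(cur, overlap_corr, se_method)
  for (it in seq_len(max_iter)) {
    eff$n_iterations <- it
    eff$removed_ids <- removed
    tst <- t_mr_gxe(cur, eff)
    out <- tst$p_mr < pleio_alpha
    if (!any(out)) break
    removed <- c(removed, cur$variant_id[out])
    cur <- cur[!out, , drop = FALSE]
    if (nrow(cur) < 2L)
      stop("fewer than 2 instruments remain after pleiotropy removal ",
           "(iteration ", it, "; removed: ", paste(removed, collapse = ", "), ")")
    prev <- eff$theta_hat
    eff <- ivw_theta(cur, overlap_corr, se_method)
    eff$n_iterations <- it
    eff$removed_ids <- removed
    if (abs(eff$theta_hat - prev) < tol) break
  }
  eff
}

#' Interaction effect recovered from the marginal-main residual
#'
#' Under no mediation, the interaction coefficient can be estimated from
#' summary statistics alone as `(alpha - beta1 * theta) / mu_E`, where `mu_E`
#' is the environment mean in the GWAS cohort.
#'
#' @param variant One or more harmonized-panel rows.
#' @param effect A `causal_effect`.
#' @param mu_E Environment mean in the GWAS sample (nonzero).
#' @return data.frame with `estimate` and `se`.
#' @export
interaction_effect_mr <- function(variant, effect, mu_E) {
  if (!is.finite(mu_E) || mu_E == 0)
    stop("mu_E = 0: the interaction is not identifiable from the margin")
  tst <- t_mr_gxe(variant, effect)
  data.frame(variant_id = tst$variant_id,
             estimate = tst$residual / mu_E,
             se = tst$se_residual / abs(mu_E),
             stringsAsFactors = FALSE)
}

#' Expected bridging coefficient under overlap and environment heterogeneity
#'
#' Closed-form expectation of the IVW bridging coefficient when instruments
#' carry no interaction and no mediation, for standardized genotypes and unit
#' residual variance. Both terms are driven by the ratio of the average
#' signal `s` (mean per-instrument trait variance explained) to estimation
#' noise, so the expectation is below 1 for weak instruments and converges to
#' 1 as both samples grow.
#'
#' Two variants of the overlap (numerator) term are provided. `"covariance"`
#' (default) uses the exact covariance between the marginal and main-effect
#' estimates induced by `n0` shared subjects,
#' `cov(alpha_hat, beta1_hat) = n0 sigma_sh^2 / (n1 n2)` with `sigma_sh^2`
#' the residual phenotype variance shared by the two fits, and
#' `var(beta1_hat) = (sigma_sh^2 / n2)(1 + mu2^2 / s2^2)` (the collinearity
#' inflation of the interaction model):
#' `E = (s + (n0/(n1 n2)) sigma_sh^2) / (s + (sigma_sh^2/n2)(1 + mu2^2/s2^2))`.
#' This form reproduces Monte-Carlo means of the estimator. `"independence"`
#' instead treats the main-effect and interaction estimation errors as
#' uncorrelated, which replaces both environment factors by
#' `(1 + mu^2 s^2)`:
#' `E = (s + (n0/(n1 n2))(1 + mu0^2 s0^2)) / (s + (1/n2)(1 + mu2^2 s2^2))`;
#' it overstates the overlap term (the two errors are negatively correlated
#' through the genotype-by-exposure column) but yields the same full-sample
#' limits. Under either form the expectation never exceeds 1 when the
#' overlap environment is no more dispersed than the GWIS environment.
#'
#' @param sigma_beta2 Mean per-instrument trait variance explained (>= 0).
#' @param n1,n2 GWAS and GWIS sample sizes.
#' @param n0 Overlap count, `0 <= n0 <= min(n1, n2)`.
#' @param mu_E0,sigma_E0 Environment mean/SD in the overlap subsample.
#' @param mu_E2,sigma_E2 Environment mean/SD in the GWIS cohort.
#' @param form Overlap-term treatment: `"covariance"` (exact, default) or
#'   `"independence"`.
#' @param sigma_shared2 Residual phenotype variance shared by the two fits
#'   (covariance form only; 1 in the standardized convention).
#' @return The expected bridging coefficient.
#' @export
expected_theta <- function(sigma_beta2, n1, n2, n0,
                           mu_E0 = 1, sigma_E0 = 1, mu_E2 = 1, sigma_E2 = 1,
                           form = c("covariance", "independence"),
                           sigma_shared2 = 1) {
  stopifnot(n1 > 0, n2 > 0, n0 >= 0, n0 <= min(n1, n2), sigma_beta2 >= 0)
  n1 <- as.numeric(n1); n2 <- as.numeric(n2); n0 <- as.numeric(n0)
  form <- match.arg(form)
  if (form == "covariance") {
    num <- sigma_beta2 + (n0 / (n1 * n2)) * sigma_shared2
    den <- sigma_beta2 +
      (sigma_shared2 / n2) * (1 + mu_E2^2 / sigma_E2^2)
  } else {
    num <- sigma_beta2 + (n0 / (n1 * n2)) * (1 + mu_E0^2 * sigma_E0^2)
    den <- sigma_beta2 + (1 / n2) * (1 + mu_E2^2 * sigma_E2^2)
  }
  if (den == 0) stop("zero denominator in expected_theta()")
  num / den
}
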