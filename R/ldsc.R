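#' Per-variant residual effects for heritability estimation
#'
#' Residual of the marginal effect about the bridging line,
#' `alpha - theta * beta1`, with the same standard error as the MR screen.
#' The attached chi-square equals the screening statistic exactly, and is the
#' response in the LD-score regression for the heritability contributed by
#' interaction and mediation.
#'
#' @param panel A harmonized panel.
#' @param effect A `causal_effect`.
#' @return data.frame with `variant_id`, `chrom`, `residual`, `se`, `chisq`.
#' @export
residual_effects <- function(panel, effect) {
  tst <- t_mr_gxe(panel, effect)
  data.frame(variant_id = tst$variant_id, chrom = panel$chrom,
             residual = tst$residual, se = tst$se_residual,
             chisq = tst$t_mr, stringsAsFactors = FALSE)
}

# weighted LDSC fit of chisq on (n/M) * ld with free intercept; block
# jackknife SE on the slope.
.ldsc_fit <- function(chisq, ld, n, M, n_blocks = 20L) {
  x <- (n / M) * ld
  w <- 1 / pmax(ld, 1)
  fit <- stats::lm(chisq ~ x, weights = w)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  n_blocks <- max(2L, min(n_blocks, length(chisq) %/% 25L))
  blocks <- cut(seq_along(chisq), breaks = n_blocks, labels = FALSE)
  jack <- vapply(seq_len(n_blocks), function(b) {
    keep <- blocks != b
    unname(stats::coef(stats::lm(chisq[keep] ~ x[keep],
                                 weights = w[keep]))[2])
  }, numeric(1))
  se <- sqrt((n_blocks - 1) / n_blocks * sum((jack - mean(jack))^2))
  list(h2 = slope, se = se, intercept = intercept, n_snps = length(chisq))
}

#' LD-score regression for interaction and mediation heritability
#'
#' Regresses the residual chi-square statistics on `(n/M) * ld_score` with a
#' free intercept and weights `1 / max(ld_score, 1)`. The slope estimates the
#' heritability tagged by the residual (interaction + mediation) effects.
#' When fitted per chromosome, the total is the sum of the non-negative
#' chromosome-specific estimates; the genome-wide single fit is reported
#' alongside for comparison. Slope standard errors come from a block
#' jackknife.
#'
#' @param residuals Output of [residual_effects()] (needs `chisq`, `chrom`).
#' @param ld LD-score table: data.frame with `variant_id` and `ld_score`.
#' @param sample_size GWAS sample size `n` for the regressor scale.
#' @param M Denominator variant count; defaults to the number of regression
#'   variants.
#' @param per_chromosome Fit each chromosome separately (default TRUE).
#' @param n_blocks Jackknife blocks (default 20; reduced when variants are
#'   scarce).
#' @param min_variants Minimum variants per fitted regression (default 50);
#'   smaller chromosomes are skipped with a warning.
#' @return List of class `h2_estimate`: `per_chrom` (chrom, h2, se,
#'   intercept, n_snps), `total` (sum of non-negative per-chromosome
#'   estimates), `total_se`, `genomewide` (single-fit slope), `intercept`,
#'   `n_snps`, `M`.
#' @export
ldsc_h2 <- function(residuals, ld, sample_size, M = NULL,
                    per_chromosome = TRUE, n_blocks = 20L,
                    min_variants = 50L) {
  tab <- merge(residuals, ld[, c("variant_id", "ld_score")], by = "variant_id")
  tab <- tab[is.finite(tab$chisq) & is.finite(tab$ld_score), , drop = FALSE]
  if (nrow(tab) < min_variants)
    stop("fewer than ", min_variants, " variants with LD scores")
  if (is.null(M)) M <- nrow(tab)
  gw <- .ldsc_fit(tab$chisq, tab$ld_score, sample_size, M, n_blocks)
  per_chrom <- NULL
  total <- max(gw$h2, 0)
  total_se <- gw$se
  if (per_chromosome) {
    rows <- lapply(unique(tab$chrom), function(ch) {
      sub <- tab[tab$chrom == ch, , drop = FALSE]
      if (nrow(sub) < min_variants) {
        warning("chromosome ", ch, " skipped: only ", nrow(sub), " variants")
        return(NULL)
      }
      f <- .ldsc_fit(sub$chisq, sub$ld_score, sample_size, M, n_blocks)
      data.frame(chrom = ch, h2 = f$h2, se = f$se, intercept = f$intercept,
                 n_snps = f$n_snps, stringsAsFactors = FALSE)
    })
    per_chrom <- do.call(rbind, rows)
    if (!is.null(per_chrom) && nrow(per_chrom)) {
      nonneg <- per_chrom$h2 > 0
      total <- sum(per_chrom$h2[nonneg])
      total_se <- sqrt(sum(per_chrom$se[nonneg]^2))
    }
  }
  structure(list(per_chrom = per_chrom, total = total, total_se = total_se,
                 genomewide = gw$h2, genomewide_se = gw$se,
                 intercept = gw$intercept, n_snps = nrow(tab), M = M),
            class = "h2_estimate")
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf(
    "interaction+mediation h2: total %.4f (se %.4f) over %d variants (M = %d)\n",
    x$total, x$total_se, x$n_snps, x$M))
  cat(sprintf("  genome-wide single fit: %.4f (se %.4f), intercept %.3f\n",
              x$genomewide, x$genomewide_se, x$intercept))
  if (!is.null(x$per_chrom)) {
    cat(sprintf("  %d chromosome-specific fits; %d negative (excluded from total)\n",
                nrow(x$per_chrom), sum(x$per_chrom$h2 < 0)))
  }
  invisible(x)
}

#' Synthesize a reproducible LD-score table
#'
#' Shifted-gamma LD scores assigned across chromosomes, for tests and
#' fixtures.
#'
#' @param m Number of variants.
#' @param n_chrom Number of chromosomes to spread variants over.
#' @param min_score Lower bound of the scores (default 1).
#' @param shape,scale Gamma parameters of the shifted part (defaults give a
#'   mean near `min_score + 40`).
#' @param ids Optional variant ids (default `v1..vm`).
#' @param seed Seed for reproducibility.
#' @return data.frame with `variant_id`, `chrom`, `ld_score`.
#' @export
synth_ld_scores <- function(m, n_chrom = 22L, min_score = 1, shape = 4,
                            scale = 10, ids = NULL, seed = 1L) {
  stopifnot(m >= 1)
  set.seed(seed)
  if (is.null(ids)) ids <- paste0("v", seq_len(m))
  data.frame(variant_id = ids,
             chrom = as.character(rep_len(seq_len(n_chrom), m)),
             ld_score = min_score + stats::rgamma(m, shape = shape,
                                                  scale = scale),
             stringsAsFactors = FALSE)
}
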