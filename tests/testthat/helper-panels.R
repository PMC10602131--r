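# in-memory builders for summary-statistic fixtures

make_records <- function(id, chrom = "1", pos = seq_along(id) * 100000L,
                         a1 = "A", a2 = "G", eaf = 0.3, beta = 0.1, se = 0.02,
                         p = 0.5, n = 50000) {
  data.frame(variant_id = id, chrom = chrom, pos = pos,
             effect_allele = a1, other_allele = a2, eaf = eaf, beta = beta,
             se = se, pvalue = p, n = n, stringsAsFactors = FALSE)
}

write_sumstats_file <- function(df, path,
                                header = c("SNP", "CHR", "BP", "A1", "A2",
                                           "FREQ", "BETA", "SE", "P", "N")) {
  names(df) <- header[seq_along(names(df))]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# harmonized panel assembled directly (skipping file I/O) for unit tests
make_panel <- function(m = 10, alpha = 0.1, se_alpha = 0.01, beta1 = 0.1,
                       se_beta1 = 0.01, beta3 = 0, se_beta3 = 0.01,
                       n1 = 50000, n2 = 20000, chrom = "1",
                       pos = seq_len(m) * 1e6, eaf = 0.3) {
  rep_len2 <- function(x) rep_len(x, m)
  df <- data.frame(
    variant_id = paste0("v", seq_len(m)), chrom = rep_len2(chrom),
    pos = pos, effect_allele = "A", other_allele = "G",
    alpha_hat = rep_len2(alpha), se_alpha = rep_len2(se_alpha),
    p_alpha = pchisq((rep_len2(alpha) / rep_len2(se_alpha))^2, 1,
                     lower.tail = FALSE),
    n1 = n1, eaf_gwas = rep_len2(eaf),
    beta1_hat = rep_len2(beta1), se_beta1 = rep_len2(se_beta1),
    p_beta1 = pchisq((rep_len2(beta1) / rep_len2(se_beta1))^2, 1,
                     lower.tail = FALSE),
    beta2_hat = NA_real_, se_beta2 = NA_real_,
    beta3_hat = rep_len2(beta3), se_beta3 = rep_len2(se_beta3),
    p_beta3 = pchisq((rep_len2(beta3) / rep_len2(se_beta3))^2, 1,
                     lower.tail = FALSE),
    n2 = n2, eaf_gwis = rep_len2(eaf), stringsAsFactors = FALSE)
  structure(df, filter_log = c(input_gwas = m, retained = m),
            class = c("harmonized_panel", "data.frame"))
}

# null GWAS/GWIS z-score pairs with a known overlap correlation, converted
# to a panel on the standardized scale (se = 1/sqrt(n))
make_null_zpanel <- function(m, r, n1 = 50000, n2 = 20000) {
  z1 <- rnorm(m)
  z2 <- r * z1 + sqrt(1 - r^2) * rnorm(m)
  p <- make_panel(m, alpha = z1 / sqrt(n1), se_alpha = 1 / sqrt(n1),
                  beta1 = z2 / sqrt(n2), se_beta1 = 1 / sqrt(n2),
                  n1 = n1, n2 = n2)
  p$p_alpha <- pchisq(z1^2, 1, lower.tail = FALSE)
  p$p_beta1 <- pchisq(z2^2, 1, lower.tail = FALSE)
  p
}
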