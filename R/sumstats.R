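#' Read a summary-statistics table into variant records
#'
#' Reads a delimited GWAS or GWIS summary-statistics file and maps its columns
#' onto the standard variant-record roles. Rows with missing or non-finite
#' effect size or standard error are dropped and counted; alleles are
#' uppercased.
#'
#' @param path Path to a delimited text file with a header line.
#' @param column_map Named character vector mapping roles to column names in
#'   the file. Required roles: `id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `beta`, `se`. Optional roles: `eaf`, `pvalue`, `n`.
#'   Defaults follow the common `SNP CHR BP A1 A2 FREQ BETA SE P N` layout.
#' @param delimiter Field separator; `""` (default) means any whitespace.
#' @param n_default Sample size to assign when the file has no `n` column.
#'
#' @return A data.frame of variant records with columns `variant_id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`,
#'   `n`, and an attribute `parse_log` counting dropped rows.
#' @export
read_sumstats <- function(path,
                          column_map = c(id = "SNP", chrom = "CHR", pos = "BP",
                                         effect_allele = "A1", other_allele = "A2",
                                         eaf = "FREQ", beta = "BETA", se = "SE",
                                         pvalue = "P", n = "N"),
                          delimiter = "",
                          n_default = NA_real_) {
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", "na", "NaN", "."))
  required <- c("id", "chrom", "pos", "effect_allele", "other_allele", "beta", "se")
  missing_roles <- setdiff(required, names(column_map))
  if (length(missing_roles))
    stop("column_map does not define required role(s): ",
         paste(missing_roles, collapse = ", "))
  for (role in required) {
    if (!column_map[[role]] %in% names(raw))
      stop("required column for role '", role, "' (", column_map[[role]],
           ") not present in ", path)
  }
  if (nrow(raw) == 0L) {
    warning("empty summary-statistics file: ", path)
  }
  pick <- function(role, default = NA_real_) {
    if (role %in% names(column_map) && column_map[[role]] %in% names(raw))
      raw[[column_map[[role]]]]
    else
      rep(default, nrow(raw))
  }
  rec <- data.frame(
    variant_id    = as.character(pick("id")),
    chrom         = as.character(pick("chrom")),
    pos           = as.integer(round(as.numeric(pick("pos")))),
    effect_allele = toupper(as.character(pick("effect_allele"))),
    other_allele  = toupper(as.character(pick("other_allele"))),
    eaf           = suppressWarnings(as.numeric(pick("eaf"))),
    beta          = suppressWarnings(as.numeric(pick("beta"))),
    se            = suppressWarnings(as.numeric(pick("se"))),
    pvalue        = suppressWarnings(as.numeric(pick("pvalue"))),
    n             = suppressWarnings(as.numeric(pick("n", n_default))),
    stringsAsFactors = FALSE
  )
  usable <- is.finite(rec$beta) & is.finite(rec$se) & rec$se > 0
  dropped <- sum(!usable)
  rec <- rec[usable, , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "parse_log") <- c(rows_in = nrow(raw), dropped_unusable = dropped,
                              retained = nrow(rec))
  rec
}

.ambiguous_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

.new_panel <- function(df, filter_log, provenance = list()) {
  rownames(df) <- NULL
  structure(df, filter_log = filter_log, provenance = provenance,
            class = c("harmonized_panel", "data.frame"))
}

#' Filter log of a harmonized panel
#'
#' @param panel A harmonized panel.
#' @return Named integer vector of per-rule removal counts.
#' @export
filter_log <- function(panel) attr(panel, "filter_log")

#' Harmonize GWAS marginal and GWIS interaction summary statistics
#'
#' Matches variants between a GWAS (marginal model, effect `alpha`) and a GWIS
#' (main/environment/interaction model, effects `beta1`, `beta2`, `beta3`) and
#' aligns them to the GWAS effect allele. When the GWIS effect allele equals
#' the GWAS other allele (and vice versa), the GWIS effect signs are negated
#' and its allele frequency reflected. Strand-ambiguous variants (A/T, C/G)
#' are removed, as are pairs whose allele-frequency difference exceeds
#' `maf_diff_max`. Variants sharing a chromosomal position are matched only if
#' their frequency difference is below `same_pos_maf_max`.
#'
#' @param gwas Variant records of the marginal (GWAS) scan, from
#'   [read_sumstats()].
#' @param gwis Variant records of the interaction (GWIS) scan. `beta`/`se` are
#'   the main effect; optional columns `beta2`/`se_beta2` (environment) and
#'   `beta3`/`se_beta3`/`p_beta3` (interaction) are carried through if present.
#' @param maf_diff_max Maximum tolerated allele-frequency difference
#'   (default 0.15).
#' @param same_pos_maf_max Frequency-match requirement when several variants
#'   share a position (default 0.01).
#'
#' @return A `harmonized_panel`: a data.frame with one row per retained
#'   variant (columns `alpha_hat`, `se_alpha`, `p_alpha`, `n1`, `eaf_gwas`,
#'   `beta1_hat`, `se_beta1`, `beta2_hat`, `se_beta2`, `beta3_hat`,
#'   `se_beta3`, `p_beta1`, `p_beta3`, `n2`, `eaf_gwis`) and a `filter_log`
#'   attribute with per-rule removal counts.
#' @export
harmonize <- function(gwas, gwis, maf_diff_max = 0.15, same_pos_maf_max = 0.01) {
  if (nrow(gwas) == 0L || nrow(gwis) == 0L)
    stop("harmonize() requires nonempty GWAS and GWIS record sets")
  log <- c(input_gwas = nrow(gwas), unmatched = 0L, allele_mismatch = 0L,
           ambiguous = 0L, maf_diff = 0L, same_pos_maf = 0L, retained = 0L)

  gwis_key_id <- gwis$variant_id
  gwis_key_pos <- paste(gwis$chrom, gwis$pos, sep = ":")
  gwas_key_pos <- paste(gwas$chrom, gwas$pos, sep = ":")

  # primary match on id, fallback on chrom:pos
  m <- match(gwas$variant_id, gwis_key_id)
  by_pos <- is.na(m)
  m[by_pos] <- match(gwas_key_pos[by_pos], gwis_key_pos)
  pos_dup <- duplicated(gwis_key_pos) | duplicated(gwis_key_pos, fromLast = TRUE)

  keep <- !is.na(m)
  log["unmatched"] <- sum(!keep)
  g1 <- gwas[keep, , drop = FALSE]
  g2 <- gwis[m[keep], , drop = FALSE]
  same_pos_flag <- (by_pos[keep]) & pos_dup[m[keep]]

  # allele orientation
  direct <- g1$effect_allele == g2$effect_allele & g1$other_allele == g2$other_allele
  swapped <- g1$effect_allele == g2$other_allele & g1$other_allele == g2$effect_allele
  mismatch <- !(direct | swapped)
  log["allele_mismatch"] <- sum(mismatch)

  flip <- swapped
  for (col in intersect(c("beta", "beta2", "beta3"), names(g2)))
    g2[[col]][flip] <- -g2[[col]][flip]
  g2$eaf[flip] <- 1 - g2$eaf[flip]

  ambiguous <- .ambiguous_pair(g1$effect_allele, g1$other_allele)
  log["ambiguous"] <- sum(ambiguous & !mismatch)

  maf_diff <- abs(g1$eaf - g2$eaf)
  bad_maf <- is.finite(maf_diff) & maf_diff > maf_diff_max
  log["maf_diff"] <- sum(bad_maf & !mismatch & !ambiguous)
  bad_same_pos <- same_pos_flag & !(is.finite(maf_diff) & maf_diff < same_pos_maf_max)
  log["same_pos_maf"] <- sum(bad_same_pos & !mismatch & !ambiguous & !bad_maf)

  ok <- !mismatch & !ambiguous & !bad_maf & !bad_same_pos
  # duplicated ids: keep the pair with the smaller MAF difference, first wins ties
  if (any(dup <- duplicated(g1$variant_id[ok]) |
            duplicated(g1$variant_id[ok], fromLast = TRUE))) {
    idx <- which(ok)
    ord <- idx[order(g1$variant_id[idx], maf_diff[idx])]
    drop_dup <- ord[duplicated(g1$variant_id[ord])]
    ok[drop_dup] <- FALSE
    log["same_pos_maf"] <- log["same_pos_maf"] + length(drop_dup)
  }
  log["retained"] <- sum(ok)
  if (!any(ok)) stop("no variants survive harmonization")

  g1 <- g1[ok, , drop = FALSE]
  g2 <- g2[ok, , drop = FALSE]
  opt <- function(col, default = NA_real_)
    if (col %in% names(g2)) g2[[col]] else rep(default, nrow(g2))
  panel <- data.frame(
    variant_id = g1$variant_id, chrom = g1$chrom, pos = g1$pos,
    effect_allele = g1$effect_allele, other_allele = g1$other_allele,
    alpha_hat = g1$beta, se_alpha = g1$se, p_alpha = g1$pvalue,
    n1 = g1$n, eaf_gwas = g1$eaf,
    beta1_hat = g2$beta, se_beta1 = g2$se, p_beta1 = g2$pvalue,
    beta2_hat = opt("beta2"), se_beta2 = opt("se_beta2"),
    beta3_hat = opt("beta3"), se_beta3 = opt("se_beta3"),
    p_beta3 = opt("p_beta3"),
    n2 = g2$n, eaf_gwis = g2$eaf,
    stringsAsFactors = FALSE
  )
  .new_panel(panel, log)
}

.log_step <- function(panel, keep, rule) {
  log <- attr(panel, "filter_log")
  log[rule] <- sum(!keep)
  log["retained"] <- sum(keep)
  .new_panel(panel[keep, , drop = FALSE], log, attr(panel, "provenance"))
}

#' Remove variants with small effective sample sizes
#'
#' Variants with GWAS sample size below `min_n_gwas` or GWIS sample size below
#' `min_n_gwis` are removed (strict less-than).
#'
#' @param panel A harmonized panel.
#' @param min_n_gwas,min_n_gwis Minimum retained sample sizes.
#' @return The filtered panel; removal counts appended to the filter log.
#' @export
filter_effective_n <- function(panel, min_n_gwas = 0, min_n_gwis = 0) {
  stopifnot(min_n_gwas >= 0, min_n_gwis >= 0)
  keep <- !(panel$n1 < min_n_gwas | panel$n2 < min_n_gwis) |
    (is.na(panel$n1) & is.na(panel$n2))
  keep[is.na(keep)] <- TRUE
  if (!any(keep)) warning("no variants survive the effective-n filter")
  .log_step(panel, keep, "low_effective_n")
}

#' Exclude windows around exposure-associated loci
#'
#' Removes every panel variant within `window_bp` (inclusive, both ends) of a
#' supplied exposure-associated lead position. Used to mitigate mediation
#' through the exposure: leads are typically loci reaching p < 5e-7 in a GWAS
#' of the environmental exposure itself.
#'
#' @param panel A harmonized panel.
#' @param exposure_hits data.frame with columns `chrom` and `pos` (1-based).
#' @param window_bp Half-width of the exclusion window (default 500 kb).
#' @return The filtered panel.
#' @export
exclude_exposure_loci <- function(panel, exposure_hits, window_bp = 500000L) {
  if (is.null(exposure_hits) || nrow(exposure_hits) == 0L)
    return(.log_step(panel, rep(TRUE, nrow(panel)), "exposure_locus"))
  drop <- rep(FALSE, nrow(panel))
  for (k in seq_len(nrow(exposure_hits))) {
    drop <- drop | (panel$chrom == as.character(exposure_hits$chrom[k]) &
                      abs(panel$pos - exposure_hits$pos[k]) <= window_bp)
  }
  .log_step(panel, !drop, "exposure_locus")
}

#' Standardize effect sizes to z-score units
#'
#' Replaces each effect/SE pair by `b = z / sqrt(n)`, `se = 1 / sqrt(n)` with
#' `z = beta / se`, putting effects on the phenotype-SD per genotype-SD scale.
#' Every z-statistic (and hence p-value) is preserved exactly. Original values
#' are kept in `*_raw` columns.
#'
#' @param panel A harmonized panel (also accepts a single-row panel).
#' @return The standardized panel; variants with missing sample size are
#'   dropped with a warning.
#' @export
standardize_effects <- function(panel) {
  ok <- is.finite(panel$n1) & panel$n1 > 0 & is.finite(panel$n2) & panel$n2 > 0
  if (!all(ok)) {
    warning(sum(!ok), " variant(s) dropped: missing sample size")
    panel <- .log_step(panel, ok, "missing_n")
  }
  std <- function(beta, se, n) {
    z <- beta / se
    list(b = z / sqrt(n), se = 1 / sqrt(n))
  }
  panel$alpha_hat_raw <- panel$alpha_hat
  panel$se_alpha_raw <- panel$se_alpha
  s <- std(panel$alpha_hat, panel$se_alpha, panel$n1)
  panel$alpha_hat <- s$b; panel$se_alpha <- s$se
  for (eff in c("beta1", "beta2", "beta3")) {
    bcol <- paste0(eff, "_hat"); scol <- paste0("se_", eff)
    panel[[paste0(bcol, "_raw")]] <- panel[[bcol]]
    panel[[paste0(scol, "_raw")]] <- panel[[scol]]
    s <- std(panel[[bcol]], panel[[scol]], panel$n2)
    panel[[bcol]] <- s$b; panel[[scol]] <- s$se
  }
  panel
}

#' Write a harmonized panel and its filter log to disk
#'
#' @param panel A harmonized panel.
#' @param path Output path for the tab-delimited panel table.
#' @param log_path Optional path for the filter-log text file.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, log_path = NULL) {
  utils::write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(log_path)) {
    log <- filter_log(panel)
    writeLines(paste(names(log), log, sep = "\t"), log_path)
  }
  invisible(path)
}
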