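# eQTL-GWAS effect-direction concordance and enrichment tests.
#
# For each screen-hit gene we take the most significant, closest eQTL
# (P < 0.01), harmonize its alternate-allele effect with the skin-colour
# GWAS effect of the same allele (GWAS P < 0.01), and test whether the
# effect directions agree more often than chance (exact binomial against
# 0.5). Enrichment of hits near GWAS-implicated loci uses Fisher's exact
# test; the relation between selection (PBS significance) and GWAS effect
# size is examined with Spearman correlation and a stratified Wilcoxon
# rank-sum test.

#' Lead eQTL per gene
#'
#' Keeps records with `eqtl_p` below the cutoff, then picks per gene the
#' record with minimum p; ties go to the smaller |distance|, then to
#' (chrom, pos) order. Genes with no qualifying record are dropped.
#'
#' @param records data frame with at least `gene_id`, `snp_id`, `eqtl_p`,
#'   `distance`; optional `chrom`, `pos` for the final tie-break.
#' @param p_cut eQTL p-value cutoff (default 0.01).
#' @return one row per retained gene.
#' @export
select_lead_eqtl <- function(records, p_cut = 0.01) {
  need <- c("gene_id", "snp_id", "eqtl_p", "distance")
  .check(all(need %in% names(records)), "eQTL table lacks columns: %s",
         paste(setdiff(need, names(records)), collapse = ", "))
  keep <- records[records$eqtl_p < p_cut, , drop = FALSE]
  if (!nrow(keep)) return(keep)
  chrom <- if ("chrom" %in% names(keep)) as.character(keep$chrom) else rep("", nrow(keep))
  pos <- if ("pos" %in% names(keep)) keep$pos else rep(0, nrow(keep))
  ord <- order(keep$gene_id, keep$eqtl_p, abs(keep$distance), chrom, pos)
  keep <- keep[ord, , drop = FALSE]
  out <- keep[!duplicated(keep$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.AMBIGUOUS <- list(c("A", "T"), c("C", "G"))

#' Harmonize eQTL and GWAS effects to the same allele
#'
#' Joins the per-gene lead eQTLs to a GWAS summary table by SNP. When the
#' GWAS effect allele is the eQTL's other allele, the GWAS beta sign is
#' flipped; strand-ambiguous pairs (A/T, C/G) are dropped, as are SNPs
#' whose allele sets match in neither orientation. Pairs must pass the
#' GWAS p-value cutoff.
#'
#' @param pairs lead-eQTL table with `snp_id`, `ea_eqtl`, `oa_eqtl`,
#'   `eqtl_slope`, `eqtl_p` (plus any carried columns).
#' @param gwas data frame with `snp_id`, `ea_gwas`, `oa_gwas`,
#'   `gwas_beta`, `gwas_p`.
#' @param gwas_p_cut GWAS p-value cutoff (default 0.01).
#' @return harmonized pairs (`gwas_beta` on the eQTL effect allele,
#'   `harmonized = TRUE`); dropped-pair counts in attribute `dropped`.
#' @export
harmonize_and_filter <- function(pairs, gwas, gwas_p_cut = 0.01) {
  .check(all(c("snp_id", "ea_eqtl", "oa_eqtl") %in% names(pairs)),
         "pairs need snp_id, ea_eqtl, oa_eqtl")
  .check(all(c("snp_id", "ea_gwas", "oa_gwas", "gwas_beta", "gwas_p") %in% names(gwas)),
         "gwas needs snp_id, ea_gwas, oa_gwas, gwas_beta, gwas_p")
  m <- merge(pairs, gwas, by = "snp_id")
  if (!nrow(m)) {
    m$harmonized <- logical(0)
    attr(m, "dropped") <- c(ambiguous = 0L, mismatch = 0L, gwas_p = 0L)
    return(m)
  }
  ambig <- mapply(function(a, b) {
    any(vapply(.AMBIGUOUS, function(p) setequal(c(a, b), p), logical(1)))
  }, m$ea_eqtl, m$oa_eqtl)
  same <- m$ea_gwas == m$ea_eqtl & m$oa_gwas == m$oa_eqtl
  flipped <- m$ea_gwas == m$oa_eqtl & m$oa_gwas == m$ea_eqtl
  mismatch <- !same & !flipped
  m$gwas_beta[flipped] <- -m$gwas_beta[flipped]
  m$ea_gwas[flipped] <- m$ea_eqtl[flipped]
  m$oa_gwas[flipped] <- m$oa_eqtl[flipped]
  keep <- !ambig & !mismatch
  fail_p <- keep & !(m$gwas_p < gwas_p_cut)
  out <- m[keep & m$gwas_p < gwas_p_cut, , drop = FALSE]
  out$harmonized <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  attr(out, "dropped") <- c(ambiguous = sum(ambig),
                            mismatch = sum(mismatch & !ambig),
                            gwas_p = sum(fail_p))
  out
}

#' Exact binomial test of effect-direction agreement
#'
#' Counts pairs whose eQTL slope and GWAS beta have the same sign and
#' tests against a chance agreement probability of 0.5. The two-sided p
#' is twice the smaller tail, capped at 1 (so 7 of 7 agreements give
#' p = 2 * (1/2)^7 = 0.015625). Zero effects are dropped with a warning.
#'
#' @param pairs harmonized pairs with `eqtl_slope` and `gwas_beta`.
#' @return list with `n_pairs`, `n_agree`, `binomial_p`.
#' @export
sign_concordance_test <- function(pairs) {
  .check(all(c("eqtl_slope", "gwas_beta") %in% names(pairs)),
         "pairs need eqtl_slope and gwas_beta")
  zero <- pairs$eqtl_slope == 0 | pairs$gwas_beta == 0
  if (any(zero)) warning(sum(zero), " pairs with a zero effect dropped")
  d <- pairs[!zero, , drop = FALSE]
  .check(nrow(d) > 0, "no testable pairs")
  n <- nrow(d)
  k <- sum(sign(d$eqtl_slope) == sign(d$gwas_beta))
  lower <- stats::pbinom(k, n, 0.5)
  upper <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  list(n_pairs = n, n_agree = k,
       binomial_p = min(1, 2 * min(lower, upper)))
}

#' Fisher's exact 2x2 enrichment test
#'
#' For a table (a = hits with the property, b = hits without, c = nonhits
#' with, d = nonhits without) reports the sample odds ratio
#' `(a*d)/(b*c)` (with Inf when `b*c = 0` and `a*d > 0`, and `NA` for
#' 0/0), the conditional-MLE odds ratio, and the two-sided exact p
#' obtained by summing hypergeometric outcomes no more probable than the
#' observed one.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return list with `or_sample`, `or_cmle`, `p`, and the `table`.
#' @export
fisher_enrichment <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  .check(all(cells >= 0) && all(cells == floor(cells)),
         "cells must be non-negative integers")
  tab <- matrix(cells, nrow = 2, byrow = TRUE)
  ad <- a * d; bc <- b * c
  or_sample <- if (bc == 0 && ad == 0) NA_real_
               else if (bc == 0) Inf
               else ad / bc
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(or_sample = or_sample, or_cmle = unname(ft$estimate),
       p = ft$p.value, table = tab)
}

#' Spearman correlation of PBS significance with GWAS effect size
#'
#' Rank correlation (average ranks for ties) between `-log10` PBS
#' empirical p-values and GWAS betas, with a t-approximation p-value on
#' `n - 2` degrees of freedom.
#'
#' @param join data frame with `pbs_neglogp` and `gwas_beta`.
#' @return list with `rho`, `p`, `n`.
#' @export
pbs_gwas_correlation <- function(join) {
  .check(all(c("pbs_neglogp", "gwas_beta") %in% names(join)),
         "join needs pbs_neglogp and gwas_beta")
  x <- join$pbs_neglogp; y <- join$gwas_beta
  n <- length(x)
  .check(n >= 4, "need at least 4 SNPs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; Spearman rho undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  list2 <- spearman_t_test(x, y)
  c(list2, list(n = n))
}

# Spearman rho with midranks + two-sided t-approximation p
spearman_t_test <- function(x, y) {
  rho <- stats::cor(rank(x), rank(y))
  n <- length(x)
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' GWAS effects stratified by PBS significance
#'
#' Two-sided Wilcoxon rank-sum test (normal approximation with tie and
#' continuity correction) comparing GWAS betas of SNPs with PBS empirical
#' p below the cutoff against the rest.
#'
#' @param join data frame with `pbs_p` (PBS empirical p) and `gwas_beta`.
#' @param pbs_p_cut stratification cutoff (default 0.01).
#' @return list with `n_low`, `n_high`, `median_low`, `median_high`,
#'   `statistic` (rank-sum W) and `p`.
#' @export
pbs_gwas_stratified <- function(join, pbs_p_cut = 0.01) {
  .check(all(c("pbs_p", "gwas_beta") %in% names(join)),
         "join needs pbs_p and gwas_beta")
  low <- join$gwas_beta[join$pbs_p < pbs_p_cut]
  high <- join$gwas_beta[join$pbs_p >= pbs_p_cut]
  .check(length(low) > 0, "empty stratum: PBS p < %g", pbs_p_cut)
  .check(length(high) > 0, "empty stratum: PBS p >= %g", pbs_p_cut)
  wt <- stats::wilcox.test(low, high, alternative = "two.sided",
                           exact = FALSE, correct = TRUE)
  list(n_low = length(low), n_high = length(high),
       median_low = stats::median(low), median_high = stats::median(high),
       statistic = unname(wt$statistic), p = wt$p.value)
}
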