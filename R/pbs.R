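# Population branch statistic (PBS) selection scan.
#
# For a target population A against references B and C, per-SNP pairwise
# Hudson F_ST values are transformed into branch lengths T = -ln(1 - F)
# and combined as PBS_A = (T_AB + T_AC - T_BC) / 2. Large PBS flags
# allele-frequency change specific to the target branch. Significance is
# the self-inclusive empirical rank over the genome-wide SNP set, and
# top-quantile flags (0.01% and 0.1%) mark candidate selected loci.

.FST_CAP <- 1 - 1e-6

#' Hudson's per-SNP F_ST estimator
#'
#' Ratio-form Hudson estimator with finite-sample correction:
#' numerator `(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`, denominator
#' `p1(1-p2) + p2(1-p1)`. The raw estimate may be negative; the clamped
#' value lies in `[0, 1 - 1e-6]`. Vectorised over SNPs.
#'
#' @param p1,p2 alternate-allele frequencies in `[0, 1]`.
#' @param n1,n2 chromosome counts (>= 2).
#' @return data frame with `num`, `den`, `fst_raw`, `fst` (clamped) and a
#'   logical `monomorphic` flag for sites with zero denominator.
#' @export
hudson_fst <- function(p1, n1, p2, n2) {
  .check(all(n1 >= 2) && all(n2 >= 2), "chromosome counts must be >= 2")
  .check(all(p1 >= 0 & p1 <= 1) && all(p2 >= 0 & p2 <= 1),
         "frequencies must lie in [0, 1]")
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  raw <- ifelse(den > 0, num / den, 0)
  data.frame(num = num, den = den, fst_raw = raw,
             fst = pmin(pmax(raw, 0), .FST_CAP),
             monomorphic = den == 0)
}

#' Branch length from a clamped F_ST
#'
#' `T = -ln(1 - F)`, the additive divergence transform used to build the
#' three-population tree. Monotone increasing, zero at F = 0.
#'
#' @param fst clamped F_ST values in `[0, 1)`.
#' @return non-negative branch lengths.
#' @export
branch_length <- function(fst) {
  .check(all(fst >= 0 & fst < 1), "F_ST must lie in [0, 1) (clamp upstream)")
  -log(1 - fst)
}

#' Per-SNP population branch statistic
#'
#' Computes all three pairwise Hudson F_ST values, branch lengths, the PBS
#' for the requested target population, the genome-wide self-inclusive
#' empirical p-value, and top-quantile flags.
#'
#' @param freqs data frame with columns `chrom`, `pos`, and per population
#'   `k` in `A`, `B`, `C`: `p_k`, `n_k`. SNPs with a missing frequency are
#'   skipped (count reported via message).
#' @param target which population's branch to score: `"A"`, `"B"` or `"C"`.
#' @param levels quantile flag levels (default `c(1e-4, 1e-3)`, i.e. the
#'   top 0.01% and top 0.1% of genome-wide PBS).
#' @return data frame with per-SNP `fst_ab`, `fst_ac`, `fst_bc`, `t_ab`,
#'   `t_ac`, `t_bc`, `pbs` (raw, possibly negative), `p_emp`, and one
#'   logical flag column per level (`flag_1e4`, `flag_1e3`).
#' @export
compute_pbs <- function(freqs, target = "A", levels = c(1e-4, 1e-3)) {
  pops <- c("A", "B", "C")
  .check(target %in% pops, "target must be one of A, B, C")
  need <- c(paste0("p_", pops), paste0("n_", pops))
  .check(all(need %in% names(freqs)), "frequency table lacks columns: %s",
         paste(setdiff(need, names(freqs)), collapse = ", "))
  ok <- stats::complete.cases(freqs[, need])
  if (any(!ok)) message(sum(!ok), " SNPs skipped (missing frequency)")
  f <- freqs[ok, , drop = FALSE]
  .check(nrow(f) > 0, "no SNPs with complete frequencies")
  others <- setdiff(pops, target)
  fab <- hudson_fst(f$p_A, f$n_A, f$p_B, f$n_B)$fst
  fac <- hudson_fst(f$p_A, f$n_A, f$p_C, f$n_C)$fst
  fbc <- hudson_fst(f$p_B, f$n_B, f$p_C, f$n_C)$fst
  t_ab <- branch_length(fab); t_ac <- branch_length(fac); t_bc <- branch_length(fbc)
  tt <- list(AB = t_ab, BA = t_ab, AC = t_ac, CA = t_ac, BC = t_bc, CB = t_bc)
  pbs <- (tt[[paste0(target, others[1])]] + tt[[paste0(target, others[2])]] -
          tt[[paste0(others[1], others[2])]]) / 2
  out <- cbind(f[, intersect(c("chrom", "pos", "ref", "alt", "snp_id"), names(f)),
                 drop = FALSE],
               data.frame(fst_ab = fab, fst_ac = fac, fst_bc = fbc,
                          t_ab = t_ab, t_ac = t_ac, t_bc = t_bc, pbs = pbs))
  out$p_emp <- empirical_pbs_pvalue(out$pbs)
  genome_quantile_flags(out, levels = levels)
}

#' Genome-wide top-quantile flags
#'
#' For each level, the threshold is the `ceiling(level * N)`-th largest
#' PBS; every SNP with PBS at or above it is flagged (ties included).
#'
#' @param pbs data frame with a `pbs` column (or a numeric vector).
#' @param levels quantile levels, e.g. `c(1e-4, 1e-3)`.
#' @return the input with one logical column per level, named
#'   `flag_<level>` with the level in compact scientific form (`flag_1e4`
#'   for 1e-4); thresholds in attribute `quantile_thresholds`.
#' @export
genome_quantile_flags <- function(pbs, levels = c(1e-4, 1e-3)) {
  vec <- if (is.data.frame(pbs)) pbs$pbs else pbs
  .check(length(vec) > 0, "empty PBS table")
  out <- if (is.data.frame(pbs)) pbs else data.frame(pbs = vec)
  sorted <- sort(vec, decreasing = TRUE)
  thr <- numeric(length(levels))
  for (i in seq_along(levels)) {
    k <- max(1L, ceiling(levels[i] * length(vec)))
    thr[i] <- sorted[min(k, length(vec))]
    nm <- paste0("flag_1e", abs(round(log10(levels[i]))))
    out[[nm]] <- vec >= thr[i]
  }
  attr(out, "quantile_thresholds") <- stats::setNames(thr, levels)
  out
}

#' Self-inclusive empirical p-value over the genome-wide PBS set
#'
#' `p_i = #\{j : PBS_j >= PBS_i\} / N`; the maximum gets `1/N`, the
#' minimum 1, and with all values distinct the p-values are a permutation
#' of `k/N`.
#'
#' @param pbs numeric vector (or data frame with `pbs` column).
#' @return numeric vector of p-values in `(0, 1]`.
#' @export
empirical_pbs_pvalue <- function(pbs) {
  x <- if (is.data.frame(pbs)) pbs$pbs else pbs
  .check(length(x) > 0, "empty PBS table")
  n <- length(x)
  # #{x_j >= x_i} = N - #{x_j < x_i} = N - (min-rank - 1)
  (n - (rank(x, ties.method = "min") - 1L)) / n
}

#' Assign SNPs to +/-100 kb gene windows
#'
#' Each SNP is assigned to every gene whose closed window
#' `[start - flank, end + flank]` (clipped at 1) contains its position; a
#' SNP may therefore appear under several genes. A per-gene summary gives
#' the SNP count, maximum PBS and minimum empirical p.
#'
#' @param pbs per-SNP table with `chrom`, `pos`, `pbs`, `p_emp`.
#' @param windows data frame with `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive gene body coordinates).
#' @param flank flank size in bp (default 1e5).
#' @return list with `snps` (SNP rows annotated with `gene_id`) and
#'   `genes` (per-gene summary: `gene_id`, `n_snps`, `max_pbs`,
#'   `min_p_emp`).
#' @export
annotate_gene_windows <- function(pbs, windows, flank = 1e5) {
  need <- c("gene_id", "chrom", "start", "end")
  .check(all(need %in% names(windows)), "window table lacks columns: %s",
         paste(setdiff(need, names(windows)), collapse = ", "))
  .check(all(windows$start <= windows$end), "gene start must be <= end")
  missing_chrom <- setdiff(unique(windows$chrom), unique(pbs$chrom))
  .check(length(missing_chrom) == 0,
         "window chromosomes absent from the SNP table: %s",
         paste(missing_chrom, collapse = ", "))
  lo <- pmax(1, windows$start - flank)
  hi <- windows$end + flank
  pieces <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    sel <- pbs$chrom == windows$chrom[i] & pbs$pos >= lo[i] & pbs$pos <= hi[i]
    if (any(sel)) {
      piece <- pbs[sel, , drop = FALSE]
      piece$gene_id <- windows$gene_id[i]
      pieces[[i]] <- piece
    }
  }
  snps <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  if (is.null(snps)) {
    snps <- cbind(pbs[0, , drop = FALSE], gene_id = character())
  }
  genes <- do.call(rbind, lapply(split(snps, snps$gene_id), function(d) {
    data.frame(gene_id = d$gene_id[1], n_snps = nrow(d),
               max_pbs = max(d$pbs), min_p_emp = min(d$p_emp),
               stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  list(snps = snps, genes = genes)
}
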