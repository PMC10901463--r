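# Synthetic-data generators with known ground truth.
#
# Each generator emulates the statistical structure one pipeline stage
# assumes: a two-bin sorted sgRNA screen with uniform guide efficacies, a
# three-population Balding-Nichols drift model with planted high-PBS
# loci, sign-linked eQTL/GWAS effect pairs, and a melanin-linked TPM
# expression matrix. All generators are deterministic under their seed
# and return the planted truth alongside the data.

# ---- screen ----------------------------------------------------------------

#' Configuration for the sorted-screen generator
#'
#' @param n_genes number of targeted genes.
#' @param guides_per_gene targeting guides per gene (default 10, matching
#'   a genome-wide 10-guide library).
#' @param n_safe_controls number of safe-targeting control guides.
#' @param n_nontargeting number of nontargeting control guides.
#' @param effect_dist named numeric vector gene -> true effect theta in
#'   log2 units (positive = knockout lowers side scatter, guide enriched
#'   in the low bin). Genes absent from the vector get theta = 0; if
#'   unnamed and of length `n_genes` it is used positionally.
#' @param depth expected reads per guide per bin.
#' @param dispersion negative-binomial overdispersion of counts
#'   (variance = mu + dispersion * mu^2; 0 = Poisson). Default 0.1.
#' @param abundance_sd lognormal sd (log2 scale) of guide library skew.
#' @param n_replicates number of biological replicates (default 2); the
#'   true effects are shared, guide efficacies and counts are drawn
#'   independently per replicate.
#' @param seed integer seed.
#' @return list of class `"screen_sim_config"`.
#' @export
screen_sim_config <- function(n_genes, guides_per_gene = 10L,
                              n_safe_controls = 500L, n_nontargeting = 500L,
                              effect_dist = NULL, depth = 500,
                              dispersion = 0.1, abundance_sd = 0.5,
                              n_replicates = 2L, seed = 1L) {
  .check(.is_count(n_genes), "n_genes must be a positive integer")
  .check(.is_count(guides_per_gene), "guides_per_gene must be >= 1")
  .check(.is_count(n_safe_controls, 0) && .is_count(n_nontargeting, 0),
         "control counts must be non-negative integers")
  .check(.is_number(depth) && depth > 0, "depth must be positive")
  .check(.is_number(dispersion) && dispersion >= 0, "dispersion must be >= 0")
  .check(.is_count(n_replicates), "n_replicates must be >= 1")
  genes <- sprintf("gene%04d", seq_len(n_genes))
  theta <- stats::setNames(numeric(n_genes), genes)
  if (!is.null(effect_dist)) {
    if (is.null(names(effect_dist))) {
      .check(length(effect_dist) == n_genes,
             "unnamed effect_dist must have length n_genes")
      theta[] <- effect_dist
    } else {
      .check(all(names(effect_dist) %in% genes),
             "effect_dist names outside the gene universe")
      theta[names(effect_dist)] <- effect_dist
    }
  }
  structure(list(n_genes = n_genes, guides_per_gene = as.integer(guides_per_gene),
                 n_safe_controls = as.integer(n_safe_controls),
                 n_nontargeting = as.integer(n_nontargeting),
                 genes = genes, theta = theta, depth = depth,
                 dispersion = dispersion, abundance_sd = abundance_sd,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "screen_sim_config")
}

#' Simulate a two-bin FACS-sorted CRISPR screen
#'
#' Per guide i of gene g, an efficacy `u_i ~ Uniform(0, 1)` scales the
#' true effect so that the expected log2 low/high frequency ratio is
#' `u_i * theta(g)`; control guides have theta = 0. Guide abundances are
#' lognormal; reads per bin are negative-binomial around the bin-specific
#' expected frequencies at the configured depth. Replicates share theta
#' but draw efficacies and counts independently.
#'
#' @param cfg a [screen_sim_config()].
#' @return list with `replicates` (list of guide count tables: `guide_id`,
#'   `gene_id`, `class`, `count_low`, `count_high`), `truth` (data frame
#'   `gene`, `theta_true`), `efficacies` (per-replicate list of per-guide
#'   u), and `config`.
#' @export
simulate_screen <- function(cfg) {
  .check(inherits(cfg, "screen_sim_config"), "cfg must be a screen_sim_config")
  set.seed(cfg$seed)
  gpg <- cfg$guides_per_gene
  gene_id <- c(rep(cfg$genes, each = gpg),
               rep("safe_control", cfg$n_safe_controls),
               rep("nontargeting_control", cfg$n_nontargeting))
  class <- c(rep("targeting", cfg$n_genes * gpg),
             rep("safe", cfg$n_safe_controls),
             rep("nontargeting", cfg$n_nontargeting))
  g <- length(gene_id)
  guide_id <- sprintf("guide%06d", seq_len(g))
  theta_guide <- c(rep(unname(cfg$theta), each = gpg),
                   numeric(cfg$n_safe_controls + cfg$n_nontargeting))
  reps <- vector("list", cfg$n_replicates)
  effs <- vector("list", cfg$n_replicates)
  for (r in seq_len(cfg$n_replicates)) {
    u <- stats::runif(g)
    shift <- u * theta_guide                     # expected log2(f_low/f_high)
    abund <- 2^stats::rnorm(g, 0, cfg$abundance_sd)
    f_low <- abund * 2^(shift / 2)
    f_high <- abund * 2^(-shift / 2)
    mu_low <- cfg$depth * g * f_low / sum(f_low)
    mu_high <- cfg$depth * g * f_high / sum(f_high)
    draw <- function(mu) {
      if (cfg$dispersion > 0) stats::rnbinom(g, size = 1 / cfg$dispersion, mu = mu)
      else stats::rpois(g, mu)
    }
    reps[[r]] <- data.frame(guide_id = guide_id, gene_id = gene_id,
                            class = class, count_low = draw(mu_low),
                            count_high = draw(mu_high),
                            stringsAsFactors = FALSE)
    effs[[r]] <- u
  }
  list(replicates = reps,
       truth = data.frame(gene = cfg$genes, theta_true = unname(cfg$theta),
                          stringsAsFactors = FALSE),
       efficacies = effs, config = cfg)
}

# ---- three-population frequencies ------------------------------------------

#' Configuration for the three-population drift generator
#'
#' Balding-Nichols drift: population frequencies are Beta draws around a
#' uniform ancestral frequency, with drift parameter F per population.
#' The default per-branch F of 0.01 scales the neutral background so
#' that a planted sweep-scale shift (0.4) stands ~6 sigma above drift,
#' matching the genome-wide standing of strong pigmentation sweeps under
#' a desk-scale SNP panel (see the methods vignette); 1000 sampled
#' chromosomes per population emulate a 1000-Genomes-sized panel.
#'
#' @param n_snps number of neutral SNPs.
#' @param drift_F length-3 numeric in (0,1): drift for populations A, B, C.
#' @param ancestral_freq_range ancestral-frequency interval within (0,1).
#' @param n_selected number of planted selected loci (appended after the
#'   neutral SNPs).
#' @param selection_shift frequency increment added in the target
#'   population at selected loci, then clipped to
#'   `[1/(2*sample_n), 1 - 1/(2*sample_n)]`.
#' @param target population receiving the shift (default `"A"`).
#' @param sample_n chromosomes per population.
#' @param seed integer seed.
#' @return list of class `"pop_sim_config"`.
#' @export
pop_sim_config <- function(n_snps, drift_F = c(0.01, 0.01, 0.01),
                           ancestral_freq_range = c(0.05, 0.95),
                           n_selected = 0L, selection_shift = 0.4,
                           target = "A", sample_n = 1000L, seed = 1L) {
  .check(.is_count(n_snps), "n_snps must be a positive integer")
  .check(length(drift_F) == 3 && all(drift_F > 0 & drift_F < 1),
         "drift_F must be three values in (0,1)")
  .check(length(ancestral_freq_range) == 2 &&
           all(ancestral_freq_range > 0 & ancestral_freq_range < 1) &&
           ancestral_freq_range[1] < ancestral_freq_range[2],
         "ancestral_freq_range must be an interval within (0,1)")
  .check(.is_count(n_selected, 0), "n_selected must be >= 0")
  .check(target %in% c("A", "B", "C"), "target must be A, B or C")
  .check(.is_count(sample_n, 2), "sample_n must be >= 2")
  structure(list(n_snps = n_snps, drift_F = stats::setNames(drift_F, c("A", "B", "C")),
                 ancestral_freq_range = ancestral_freq_range,
                 n_selected = as.integer(n_selected),
                 selection_shift = selection_shift, target = target,
                 sample_n = as.integer(sample_n), seed = as.integer(seed)),
            class = "pop_sim_config")
}

#' Simulate three-population allele frequencies with planted selection
#'
#' Neutral SNPs drift independently in each population under the
#' Balding-Nichols Beta model; selected loci additionally receive a
#' frequency shift in the target population (clipped away from 0/1 at
#' half a chromosome count). A warning is raised if the clip removed the
#' entire shift at every selected locus.
#'
#' @param cfg a [pop_sim_config()].
#' @return list with `freqs` (data frame `chrom`, `pos`, `ref`, `alt`,
#'   `p_A`, `n_A`, ..., `selected`) and `truth` (indices + positions of
#'   selected loci).
#' @export
simulate_three_pop_freqs <- function(cfg) {
  .check(inherits(cfg, "pop_sim_config"), "cfg must be a pop_sim_config")
  set.seed(cfg$seed)
  n <- cfg$n_snps + cfg$n_selected
  p_anc <- stats::runif(n, cfg$ancestral_freq_range[1], cfg$ancestral_freq_range[2])
  draw_pop <- function(F) {
    a <- p_anc * (1 - F) / F
    b <- (1 - p_anc) * (1 - F) / F
    stats::rbeta(n, a, b)
  }
  p <- list(A = draw_pop(cfg$drift_F["A"]),
            B = draw_pop(cfg$drift_F["B"]),
            C = draw_pop(cfg$drift_F["C"]))
  sel <- if (cfg$n_selected > 0) cfg$n_snps + seq_len(cfg$n_selected) else integer()
  if (length(sel)) {
    lo <- 1 / (2 * cfg$sample_n); hi <- 1 - lo
    before <- p[[cfg$target]][sel]
    raw <- before + cfg$selection_shift
    shifted <- pmin(pmax(raw, lo), hi)
    if (all(raw > hi | raw < lo))
      warning("selection shift clipped at every selected locus")
    p[[cfg$target]][sel] <- shifted
  }
  freqs <- data.frame(chrom = "1", pos = seq_len(n) * 1000L,
                      ref = "A", alt = "G",
                      p_A = p$A, n_A = cfg$sample_n,
                      p_B = p$B, n_B = cfg$sample_n,
                      p_C = p$C, n_C = cfg$sample_n,
                      selected = seq_len(n) %in% sel,
                      stringsAsFactors = FALSE)
  list(freqs = freqs,
       truth = data.frame(index = sel, pos = freqs$pos[sel]))
}

# ---- eQTL / GWAS effect pairs ----------------------------------------------

#' Configuration for the eQTL-GWAS pair generator
#'
#' @param n_genes number of gene-SNP pairs.
#' @param slope_sd sd of the eQTL slope (expression change per alt
#'   allele; default 0.5, a typical log-expression scale).
#' @param link coupling kappa from slope to GWAS beta (default 0.2).
#' @param noise_sd sd of the GWAS beta residual (default 0.05).
#' @param discord_prob probability of flipping the beta sign (0 = fully
#'   concordant truth).
#' @param se_eqtl,se_gwas standard errors used by the p-value rule
#'   `p = 2 * pnorm(-|effect| / se)`, so p decreases with effect size.
#' @param swap_prob probability that the GWAS row reports the opposite
#'   allele orientation (exercises harmonization).
#' @param seed integer seed.
#' @return list of class `"pair_sim_config"`.
#' @export
pair_sim_config <- function(n_genes, slope_sd = 0.5, link = 0.2,
                            noise_sd = 0.05, discord_prob = 0,
                            se_eqtl = 0.1, se_gwas = 0.02,
                            swap_prob = 0.5, seed = 1L) {
  .check(.is_count(n_genes), "n_genes must be a positive integer")
  .check(discord_prob >= 0 && discord_prob <= 1, "discord_prob must be in [0,1]")
  .check(slope_sd > 0 && noise_sd >= 0 && se_eqtl > 0 && se_gwas > 0,
         "scales must be positive (noise_sd may be 0)")
  structure(list(n_genes = n_genes, slope_sd = slope_sd, link = link,
                 noise_sd = noise_sd, discord_prob = discord_prob,
                 se_eqtl = se_eqtl, se_gwas = se_gwas,
                 swap_prob = swap_prob, seed = as.integer(seed)),
            class = "pair_sim_config")
}

#' Simulate sign-linked eQTL and GWAS summary tables
#'
#' `slope ~ N(0, slope_sd^2)`; `beta = s * kappa * slope + N(0,
#' noise_sd^2)` with `s = -1` with probability `discord_prob`, else `+1`.
#' P-values decrease with effect magnitude via a normal-score rule.
#' Alleles are non-ambiguous (A/G or C/T); with probability `swap_prob`
#' the GWAS table reports the swapped orientation (its beta negated
#' accordingly), so harmonization is required before comparing signs.
#'
#' @param cfg a [pair_sim_config()].
#' @return list with `eqtl` (gene_id, snp_id, ea_eqtl, oa_eqtl,
#'   eqtl_slope, eqtl_p, distance, chrom, pos), `gwas` (snp_id, ea_gwas,
#'   oa_gwas, gwas_beta, gwas_p), and `truth` (per pair: concordant flag
#'   on the harmonized scale).
#' @export
simulate_eqtl_gwas_pairs <- function(cfg) {
  .check(inherits(cfg, "pair_sim_config"), "cfg must be a pair_sim_config")
  set.seed(cfg$seed)
  n <- cfg$n_genes
  slope <- stats::rnorm(n, 0, cfg$slope_sd)
  s <- ifelse(stats::runif(n) < cfg$discord_prob, -1, 1)
  beta <- s * cfg$link * slope + stats::rnorm(n, 0, cfg$noise_sd)
  alleles <- rbind(c("A", "G"), c("C", "T"))[sample(1:2, n, replace = TRUE), ,
                                             drop = FALSE]
  swap <- stats::runif(n) < cfg$swap_prob
  eqtl <- data.frame(gene_id = sprintf("gene%04d", seq_len(n)),
                     snp_id = sprintf("rs%06d", seq_len(n)),
                     ea_eqtl = alleles[, 1], oa_eqtl = alleles[, 2],
                     eqtl_slope = slope,
                     eqtl_p = 2 * stats::pnorm(-abs(slope) / cfg$se_eqtl),
                     distance = sample.int(100000L, n, replace = TRUE),
                     chrom = "1", pos = seq_len(n) * 1000L,
                     stringsAsFactors = FALSE)
  gwas <- data.frame(snp_id = eqtl$snp_id,
                     ea_gwas = ifelse(swap, alleles[, 2], alleles[, 1]),
                     oa_gwas = ifelse(swap, alleles[, 1], alleles[, 2]),
                     gwas_beta = ifelse(swap, -beta, beta),
                     gwas_p = 2 * stats::pnorm(-abs(beta) / cfg$se_gwas),
                     stringsAsFactors = FALSE)
  list(eqtl = eqtl, gwas = gwas,
       truth = data.frame(snp_id = eqtl$snp_id, concordant = s > 0,
                          beta_harmonized = beta))
}

# ---- expression x melanin ---------------------------------------------------

#' Configuration for the expression-melanin generator
#'
#' Defaults mirror the screen-hit expression survey: 158 genes measurable
#' in 30 donor melanocyte samples, with roughly two thirds of genes truly
#' positively melanin-linked and a small negatively linked minority.
#'
#' @param n_genes number of genes (default 158).
#' @param n_samples number of samples (default 30).
#' @param frac_positive,frac_negative fractions of genes with truly
#'   positive / negative melanin association (defaults 0.68 and 0.08;
#'   must sum to at most 1).
#' @param slope_sd scale of the per-gene log2-TPM slope on melanin
#'   (default 5 log2 units per OD unit; together with `noise_sd` this
#'   puts most truly linked genes clearly past the ~0.33 |rho| detection
#'   boundary at 30 samples, so the q < 0.1 call fractions of a default
#'   simulation match those observed in the donor-melanocyte survey the
#'   generator emulates).
#' @param noise_sd residual sd of log2 TPM (default 0.5).
#' @param melanin_range range of per-sample OD400 draws (uniform;
#'   default 0.1 to 1.2 absorbance units).
#' @param seed integer seed.
#' @return list of class `"expr_sim_config"`.
#' @export
expr_sim_config <- function(n_genes = 158L, n_samples = 30L,
                            frac_positive = 0.68, frac_negative = 0.08,
                            slope_sd = 5, noise_sd = 0.5,
                            melanin_range = c(0.1, 1.2), seed = 1L) {
  .check(.is_count(n_genes) && .is_count(n_samples, 4),
         "n_genes must be >= 1, n_samples >= 4")
  .check(frac_positive >= 0 && frac_negative >= 0 &&
           frac_positive + frac_negative <= 1,
         "frac_positive + frac_negative must be <= 1")
  .check(noise_sd >= 0 && slope_sd >= 0, "scales must be >= 0")
  structure(list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
                 frac_positive = frac_positive, frac_negative = frac_negative,
                 slope_sd = slope_sd, noise_sd = noise_sd,
                 melanin_range = melanin_range, seed = as.integer(seed)),
            class = "expr_sim_config")
}

#' Simulate a melanin-linked TPM matrix
#'
#' Per-sample melanin `m_s ~ Uniform(melanin_range)`; per-gene
#' `log2 TPM_gs = a_g + b_g * m_s + eps` with `b_g` positive / negative /
#' zero according to the planted class, `|b_g| ~ |N(0, slope_sd^2)|`, and
#' `eps ~ N(0, noise_sd^2)`. TPM is strictly positive by construction.
#'
#' @param cfg an [expr_sim_config()].
#' @return list with `expr` (genes x samples TPM matrix), `melanin`
#'   (named OD400 vector), and `truth` (data frame `gene`, `b`,
#'   `class_true`).
#' @export
simulate_expression_melanin <- function(cfg) {
  .check(inherits(cfg, "expr_sim_config"), "cfg must be an expr_sim_config")
  set.seed(cfg$seed)
  ng <- cfg$n_genes; ns <- cfg$n_samples
  m <- stats::runif(ns, cfg$melanin_range[1], cfg$melanin_range[2])
  names(m) <- sprintf("sample%02d", seq_len(ns))
  n_pos <- round(cfg$frac_positive * ng)
  n_neg <- round(cfg$frac_negative * ng)
  cls <- c(rep("positive", n_pos), rep("negative", n_neg),
           rep("ns", ng - n_pos - n_neg))
  cls <- sample(cls)
  b <- abs(stats::rnorm(ng, 0, cfg$slope_sd)) *
    (cls == "positive") - abs(stats::rnorm(ng, 0, cfg$slope_sd)) * (cls == "negative")
  a <- stats::runif(ng, 1, 8)
  log2tpm <- outer(b, m) + a + matrix(stats::rnorm(ng * ns, 0, cfg$noise_sd), ng, ns)
  expr <- 2^log2tpm
  rownames(expr) <- sprintf("gene%04d", seq_len(ng))
  colnames(expr) <- names(m)
  list(expr = expr, melanin = m,
       truth = data.frame(gene = rownames(expr), b = b, class_true = cls,
                          stringsAsFactors = FALSE))
}
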