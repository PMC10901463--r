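test_that("lead eQTL selection filters and breaks ties as documented", {
  rec <- data.frame(gene_id = c("g1", "g1", "g2", "g3"),
                    snp_id = c("rs1", "rs2", "rs3", "rs4"),
                    eqtl_p = c(1e-5, 1e-5, 0.02, 5e-4),
                    distance = c(50000, 5000, 100, 200),
                    stringsAsFactors = FALSE)
  out <- select_lead_eqtl(rec, p_cut = 0.01)
  # p-tie resolved by smaller |distance|; g2 fails the p filter entirely
  expect_equal(out$snp_id[out$gene_id == "g1"], "rs2")
  expect_false("g2" %in% out$gene_id)
  expect_equal(out$snp_id[out$gene_id == "g3"], "rs4")
  expect_equal(nrow(select_lead_eqtl(transform(rec, eqtl_p = 0.5))), 0)
})

test_that("harmonization aligns alleles, flips beta, drops ambiguous", {
  pairs <- data.frame(gene_id = c("g1", "g2", "g3"),
                      snp_id = c("rs1", "rs2", "rs3"),
                      ea_eqtl = c("G", "G", "A"), oa_eqtl = c("A", "A", "T"),
                      eqtl_slope = c(1, 1, 1), eqtl_p = 1e-4,
                      stringsAsFactors = FALSE)
  gwas <- data.frame(snp_id = c("rs1", "rs2", "rs3"),
                     ea_gwas = c("G", "A", "A"), oa_gwas = c("A", "G", "T"),
                     gwas_beta = c(0.5, 0.5, 0.5), gwas_p = 1e-4,
                     stringsAsFactors = FALSE)
  out <- harmonize_and_filter(pairs, gwas)
  expect_setequal(out$snp_id, c("rs1", "rs2"))    # A/T pair rs3 is ambiguous
  expect_equal(out$gwas_beta[out$snp_id == "rs1"], 0.5)   # same orientation
  expect_equal(out$gwas_beta[out$snp_id == "rs2"], -0.5)  # swapped: flipped
  expect_equal(unname(attr(out, "dropped")["ambiguous"]), 1L)
  # involution: harmonizing the already-harmonized table changes nothing
  gwas2 <- data.frame(snp_id = out$snp_id, ea_gwas = out$ea_gwas,
                      oa_gwas = out$oa_gwas, gwas_beta = out$gwas_beta,
                      gwas_p = out$gwas_p,
                      stringsAsFactors = FALSE)
  again <- harmonize_and_filter(pairs[pairs$snp_id %in% out$snp_id, ], gwas2)
  expect_equal(again$gwas_beta[order(again$snp_id)],
               out$gwas_beta[order(out$snp_id)])
  # mismatched allele sets are dropped with a reason
  gwas3 <- transform(gwas, ea_gwas = "C", oa_gwas = "T")
  out3 <- harmonize_and_filter(pairs[1, ], gwas3[1, ])
  expect_equal(nrow(out3), 0)
  expect_equal(unname(attr(out3, "dropped")["mismatch"]), 1L)
  # GWAS p filter applies after orientation
  gwas4 <- transform(gwas, gwas_p = 0.5)
  expect_equal(nrow(harmonize_and_filter(pairs, gwas4)), 0)
})

test_that("sign concordance uses the twice-smaller-tail exact binomial", {
  mk <- function(slopes, betas) data.frame(eqtl_slope = slopes, gwas_beta = betas)
  # seven of seven agreements
  r <- sign_concordance_test(mk(rep(1, 7), rep(1, 7)))
  expect_equal(r$n_agree, 7)
  expect_equal(r$binomial_p, 0.015625)
  expect_equal(round(r$binomial_p, 5), 0.01563)
  # perfectly split: p capped at 1
  r <- sign_concordance_test(mk(c(1, 1, -1, 1), c(1, 1, 1, -1)))
  expect_equal(r$n_agree, 2)
  expect_equal(r$binomial_p, 1)
  # two-sided symmetry: 0 of 7 is as extreme as 7 of 7
  r <- sign_concordance_test(mk(rep(1, 7), rep(-1, 7)))
  expect_equal(r$binomial_p, 0.015625)
  # k of n and n-k of n coincide for general k
  p1 <- sign_concordance_test(mk(rep(1, 10), c(rep(1, 8), -1, -1)))$binomial_p
  p2 <- sign_concordance_test(mk(rep(1, 10), c(rep(-1, 8), 1, 1)))$binomial_p
  expect_equal(p1, p2)
  # zero effects are dropped with a warning; empty after dropping errors
  expect_warning(r <- sign_concordance_test(mk(c(1, 0), c(1, 1))), "zero")
  expect_equal(r$n_pairs, 1)
  expect_error(suppressWarnings(sign_concordance_test(mk(0, 1))), "no testable")
})

test_that("Fisher enrichment reports sample OR and exact two-sided p", {
  # proportional table: no association
  r <- fisher_enrichment(10, 90, 20, 180)
  expect_equal(r$or_sample, 1)
  expect_equal(r$p, 1)
  # screen-hit enrichment table: sample OR by direct arithmetic
  r <- fisher_enrichment(8, 161, 322, 19722)
  expect_equal(r$or_sample, 8 * 19722 / (161 * 322), tolerance = 1e-12)
  expect_equal(r$or_sample, 3.04, tolerance = 1e-2)
  expect_lt(r$p, 0.01)
  # full hypergeometric enumeration for the 2/0/0/2 margin gives p = 1/3
  r <- fisher_enrichment(2, 0, 0, 2)
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)
  expect_equal(r$or_sample, Inf)
  expect_true(is.na(fisher_enrichment(0, 5, 0, 5)$or_sample))
  # transposing the table leaves the exact p unchanged
  expect_equal(fisher_enrichment(8, 161, 322, 19722)$p,
               fisher_enrichment(8, 322, 161, 19722)$p)
  expect_error(fisher_enrichment(-1, 2, 3, 4), "non-negative")
})

test_that("PBS-GWAS Spearman correlation handles monotone and tied data", {
  d <- data.frame(pbs_neglogp = 1:10, gwas_beta = -(1:10))
  r <- pbs_gwas_correlation(d)
  expect_equal(r$rho, -1)
  expect_equal(r$p, 0)
  # duplicate-value ties match an explicit midrank computation
  set.seed(8)
  d <- data.frame(pbs_neglogp = sample(c(1, 1, 2, 2, 3, 3, 4, 5, 6, 6)),
                  gwas_beta = sample(c(0.1, 0.1, 0.2, 0.3, 0.3, 0.4, 0.5, 0.5, 0.6, 0.7)))
  r <- pbs_gwas_correlation(d)
  expect_equal(r$rho, cor(midrank(d$pbs_neglogp), midrank(d$gwas_beta)),
               tolerance = 1e-12)
  expect_warning(r <- pbs_gwas_correlation(data.frame(pbs_neglogp = rep(1, 5),
                                                      gwas_beta = 1:5)),
                 "constant")
  expect_true(is.na(r$rho))
  expect_error(pbs_gwas_correlation(d[1:3, ]), "at least 4")
})

test_that("stratified Wilcoxon compares GWAS betas across PBS strata", {
  # identical beta values in both strata: p = 1
  d <- data.frame(pbs_p = c(rep(0.001, 5), rep(0.5, 5)),
                  gwas_beta = rep(c(1, 2, 3, 4, 5), 2))
  r <- pbs_gwas_stratified(d)
  expect_equal(r$p, 1)
  expect_equal(r$n_low, 5)
  # minimal strata with distinct values: continuity correction gives p = 1
  d <- data.frame(pbs_p = c(0.001, 0.5), gwas_beta = c(0, 1))
  expect_equal(pbs_gwas_stratified(d)$p, 1)
  # a clearly shifted stratum is detected
  set.seed(21)
  d <- data.frame(pbs_p = c(rep(0.001, 200), rep(0.5, 2000)),
                  gwas_beta = c(rnorm(200, -1), rnorm(2000)))
  r <- pbs_gwas_stratified(d)
  expect_lt(r$p, 1e-3)
  expect_lt(r$median_low, r$median_high)
  expect_error(pbs_gwas_stratified(data.frame(pbs_p = 0.5, gwas_beta = 1)),
               "empty stratum")
})
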