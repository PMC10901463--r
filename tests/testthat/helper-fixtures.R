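# shared fixture builders

# minimal guide count table: counts given per class
make_counts <- function(count_low, count_high, gene_id = NULL, class = NULL) {
  g <- length(count_low)
  if (is.null(gene_id)) gene_id <- sprintf("g%03d", seq_len(g))
  if (is.null(class)) class <- rep("targeting", g)
  data.frame(guide_id = sprintf("gd%04d", seq_len(g)), gene_id = gene_id,
             class = class, count_low = count_low, count_high = count_high,
             stringsAsFactors = FALSE)
}

# standard-normal empirical null shared by estimator tests
std_normal_null <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(424242)
      cache <<- fit_null_density(rnorm(20000))
    }
    cache
  }
})

# independent midrank implementation (oracle for Spearman tie handling)
midrank <- function(x) {
  vapply(x, function(v) sum(x < v) + (1 + sum(x == v)) / 2, numeric(1))
}

# write a small VCF from genotype strings; gt is a matrix samples x sites
write_test_vcf <- function(path, chrom, pos, ref, alt, gt) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(gt)), collapse = "\t"))
  body <- vapply(seq_along(pos), function(i) {
    paste(c(chrom[i], pos[i], ".", ref[i], alt[i], ".", "PASS", ".", "GT",
            gt[, i]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}
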