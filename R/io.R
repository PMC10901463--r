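# Table readers/writers and VCF frequency extraction.
#
# TSV with a header row is the universal table dialect of the package.
# Floats are written with 12 significant digits so that write -> read
# round-trips preserve values to textual precision. Reads are
# gzip-transparent (read.delim handles .gz connections natively).

#' Write a data frame as tab-separated values
#'
#' Columns of type double are formatted with 12 significant digits;
#' everything else is written as-is. No quoting, no row names.
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  .check(is.data.frame(x), "write_tsv() needs a data frame")
  y <- x
  for (j in seq_along(y)) {
    if (is.double(y[[j]])) y[[j]] <- formatC(y[[j]], digits = 12, format = "g")
  }
  utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table with header
#'
#' @param path input path; `.gz` files are read transparently.
#' @return data frame with character columns left unconverted.
#' @export
read_tsv <- function(path) {
  .check(file.exists(path), "no such file: %s", path)
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a sample-to-population map
#'
#' Expects a two-column TSV with header `sample`, `pop`.
#'
#' @param path TSV path.
#' @return data frame with columns `sample` and `pop`.
#' @export
read_popmap <- function(path) {
  pm <- read_tsv(path)
  .check(all(c("sample", "pop") %in% names(pm)),
         "population map must have columns 'sample' and 'pop'")
  .check(!anyDuplicated(pm$sample), "duplicated sample in population map")
  pm
}

#' Per-population alternate-allele frequencies from a VCF
#'
#' Reads biallelic SNP records from a VCF (4.2, GT fields required) and
#' computes, for each population in the map, the alternate-allele frequency
#' and the number of called chromosomes. Missing genotypes are excluded from
#' the denominator; multiallelic and non-SNP records are skipped and
#' counted. A site is dropped when any population has zero called
#' chromosomes there.
#'
#' @param vcf_path path to a VCF file (plain or gzipped).
#' @param popmap data frame with columns `sample`, `pop` covering every
#'   sample used; populations are taken from its `pop` values.
#' @return data frame with columns `chrom`, `pos`, `ref`, `alt` and, per
#'   population `k`, `p_k` (alt frequency) and `n_k` (called chromosomes).
#'   Attribute `skipped` holds the counts of records skipped by reason.
#' @export
read_vcf_frequencies <- function(vcf_path, popmap) {
  .check(all(c("sample", "pop") %in% names(popmap)),
         "popmap must have columns 'sample' and 'pop'")
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  unmapped <- setdiff(samples, popmap$sample)
  .check(length(unmapped) == 0, "unmapped VCF samples: %s",
         paste(unmapped, collapse = ", "))
  pops <- sort(unique(popmap$pop))
  pop_of <- stats::setNames(popmap$pop, popmap$sample)[samples]

  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  nonsnp <- !multi & (nchar(ref) != 1L | nchar(alt) != 1L)
  keep <- !multi & !nonsnp
  skipped <- c(multiallelic = sum(multi), non_snp = sum(nonsnp))

  rows <- list()
  dropped_zero_n <- 0L
  for (i in which(keep)) {
    g <- gt[i, ]
    # count alt alleles and called chromosomes per genotype string
    row <- list(chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
                ref = ref[i], alt = alt[i])
    ok <- TRUE
    for (k in pops) {
      gk <- g[pop_of == k]
      al <- unlist(strsplit(gk[!is.na(gk)], "[/|]"))
      al <- al[al != "."]
      n <- length(al)
      if (n == 0L) { ok <- FALSE; break }
      row[[paste0("p_", k)]] <- sum(al == "1") / n
      row[[paste0("n_", k)]] <- n
    }
    if (ok) rows[[length(rows) + 1L]] <- row else dropped_zero_n <- dropped_zero_n + 1L
  }
  out <- if (length(rows)) {
    do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  } else {
    stop("no usable biallelic SNP records in ", vcf_path, call. = FALSE)
  }
  attr(out, "skipped") <- c(skipped, zero_called = dropped_zero_n)
  out
}

#' Write a three-population frequency table as a minimal VCF
#'
#' Emits VCF 4.2 sites-only records carrying per-population alternate
#' allele frequencies and chromosome counts as INFO fields
#' (`AF_A`/`AF_B`/`AF_C`, `AN_A`/`AN_B`/`AN_C`).
#'
#' @param freqs frequency table as produced by [simulate_three_pop_freqs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_freq_vcf <- function(freqs, path) {
  pops <- c("A", "B", "C")
  need <- c("chrom", "pos", "ref", "alt", paste0("p_", pops), paste0("n_", pops))
  .check(all(need %in% names(freqs)), "frequency table lacks columns: %s",
         paste(setdiff(need, names(freqs)), collapse = ", "))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##INFO=<ID=AF_%s,Number=1,Type=Float,Description=\"Alt allele frequency, population %s\">", pops, pops),
           sprintf("##INFO=<ID=AN_%s,Number=1,Type=Integer,Description=\"Called chromosomes, population %s\">", pops, pops),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- sprintf("AF_A=%s;AF_B=%s;AF_C=%s;AN_A=%d;AN_B=%d;AN_C=%d",
                  formatC(freqs$p_A, digits = 12, format = "g"),
                  formatC(freqs$p_B, digits = 12, format = "g"),
                  formatC(freqs$p_C, digits = 12, format = "g"),
                  as.integer(freqs$n_A), as.integer(freqs$n_B), as.integer(freqs$n_C))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                  freqs$chrom, as.integer(freqs$pos), freqs$ref, freqs$alt, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}
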