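# Expression-melanin correlation screening.
#
# Per-gene Spearman rank correlation between TPM expression and per-sample
# melanin content (OD at 400 nm), Benjamini-Hochberg q-values over all
# tested genes, and a three-way classification: positive (q < 0.1 and
# rho > 0), negative (q < 0.1 and rho < 0), or not significant.

#' Keep genes measurable in every sample
#'
#' Measurability is TPM > 0 in all samples; genes failing anywhere are
#' removed (count reported via message).
#'
#' @param expr numeric matrix genes x samples (TPM), with row and column
#'   names.
#' @return the filtered matrix.
#' @export
filter_measurable <- function(expr) {
  .check(is.matrix(expr) && is.numeric(expr), "expr must be a numeric matrix")
  .check(!anyNA(expr), "expression matrix has missing cells")
  keep <- apply(expr > 0, 1, all)
  if (any(!keep)) message(sum(!keep), " genes removed (zero TPM in some sample)")
  out <- expr[keep, , drop = FALSE]
  .check(nrow(out) > 0, "no measurable genes remain")
  out
}

#' Spearman correlation of expression with melanin content
#'
#' For each gene, Spearman's rho (midrank ties) between TPM and OD400,
#' a two-sided p from the t-approximation on n - 2 degrees of freedom,
#' a BH q-value over all tested genes, and the class label.
#'
#' @param expr numeric genes x samples TPM matrix.
#' @param melanin named numeric vector of per-sample OD400 values; names
#'   must match `colnames(expr)` as a set.
#' @param q_cut significance cutoff on the q-value (default 0.1, strict
#'   inequality).
#' @return data frame with `gene`, `rho`, `p`, `q`, `class`
#'   (`"positive"`, `"negative"`, `"ns"`). Constant genes get `NA` rho
#'   and class `"ns"` (with a warning).
#' @export
correlate_expression_melanin <- function(expr, melanin, q_cut = 0.1) {
  .check(is.matrix(expr) && !is.null(colnames(expr)), "expr must have column names")
  .check(!is.null(names(melanin)), "melanin must be a named vector")
  .check(setequal(colnames(expr), names(melanin)),
         "sample sets of expression and melanin differ")
  .check(ncol(expr) >= 4, "need at least 4 samples")
  m <- melanin[colnames(expr)]
  rho <- rep(NA_real_, nrow(expr)); p <- rep(NA_real_, nrow(expr))
  n_const <- 0L
  for (i in seq_len(nrow(expr))) {
    x <- expr[i, ]
    if (stats::sd(x) == 0) { n_const <- n_const + 1L; next }
    st <- spearman_t_test(x, m)
    rho[i] <- st$rho; p[i] <- st$p
  }
  if (n_const > 0) warning(n_const, " constant genes: rho undefined, class ns")
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  cls <- rep("ns", length(p))
  cls[!is.na(q) & q < q_cut & rho > 0] <- "positive"
  cls[!is.na(q) & q < q_cut & rho < 0] <- "negative"
  data.frame(gene = rownames(expr), rho = rho, p = p, q = q, class = cls,
             stringsAsFactors = FALSE)
}

#' Class counts for correlation results
#'
#' @param correlations output of [correlate_expression_melanin()].
#' @param q_cut q-value cutoff used for reporting (classes were assigned
#'   at correlation time; recomputed here from `q` and `rho` so a
#'   different cutoff can be applied).
#' @return list with `n_positive`, `n_negative`, `n_ns`, `n_total`,
#'   `fraction_positive`, and the reclassified `table`.
#' @export
classify_hits <- function(correlations, q_cut = 0.1) {
  .check(all(c("gene", "rho", "q") %in% names(correlations)),
         "correlations need gene, rho, q")
  d <- correlations
  cls <- rep("ns", nrow(d))
  ok <- !is.na(d$q)
  cls[ok & d$q < q_cut & d$rho > 0] <- "positive"
  cls[ok & d$q < q_cut & d$rho < 0] <- "negative"
  d$class <- cls
  list(n_positive = sum(cls == "positive"),
       n_negative = sum(cls == "negative"),
       n_ns = sum(cls == "ns"),
       n_total = nrow(d),
       fraction_positive = sum(cls == "positive") / nrow(d),
       table = d)
}

#' Implied |rho| rejection boundary of the BH-Spearman screen
#'
#' Given that `n_reject` of `m` Spearman tests on `n` samples are rejected
#' by Benjamini-Hochberg at level `alpha`, the largest rejected p-value is
#' at the step-up boundary `n_reject * alpha / m`; inverting the
#' two-sided t-approximation gives the corresponding |rho| cutoff.
#'
#' @param m number of tests.
#' @param n_reject number of BH rejections.
#' @param n number of samples per test.
#' @param alpha FDR level (default 0.1).
#' @return the implied absolute-correlation rejection boundary.
#' @export
spearman_bh_cutoff <- function(m, n_reject, n, alpha = 0.1) {
  .check(.is_count(m) && .is_count(n_reject) && .is_count(n, 4),
         "m, n_reject must be counts; n >= 4")
  .check(n_reject <= m, "n_reject cannot exceed m")
  p_boundary <- n_reject * alpha / m
  tcrit <- stats::qt(1 - p_boundary / 2, df = n - 2)
  tcrit / sqrt(n - 2 + tcrit^2)
}
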