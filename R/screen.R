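# Gene-effect estimation from two-bin FACS-sorted sgRNA counts.
#
# The model follows the casTLE family of pooled-screen estimators. Each
# guide i of a gene carries an unknown efficacy u_i; conditional on a gene
# effect theta (log2 units), the guide's expected bin-ratio shift is
# u_i * theta with u_i uniform on (0, 1). Marginalising over u_i gives the
# per-guide likelihood
#
#   p_theta(e) = (1/|theta|) * Integral_0^theta p0(e - t) dt,
#
# where p0 is an empirical null density estimated from negative-control
# guides. The gene effect is the grid argmax of the summed log likelihood;
# the score is the likelihood-ratio statistic 2*(L(theta_hat) - L(0)).
#
# Sign convention: e = log2(f_low / f_high), so knockouts that *reduce*
# side scatter (melanin-promoting genes) enrich in the low bin and get
# positive effects.

DEFAULT_THETA_GRID <- seq(-8, 8, length.out = 401)
.DENS_FLOOR <- 1e-10
.CHISQ1_95 <- 3.841459  # qchisq(.95, 1)

#' Per-guide log2 enrichment between sort bins
#'
#' Converts raw low/high-bin counts into pseudocounted log2 frequency
#' ratios, optionally centred so that the median enrichment of
#' safe-targeting control guides is zero.
#'
#' @param records data frame with columns `guide_id`, `gene_id`, `class`
#'   (one of `"targeting"`, `"safe"`, `"nontargeting"`), `count_low`,
#'   `count_high`.
#' @param pseudocount positive pseudocount added to each guide count
#'   (and `G` times to each bin total). Default 0.5.
#' @param center subtract the median control enrichment? Default `TRUE`.
#'   Safe-targeting guides are preferred for centring, falling back to
#'   nontargeting guides, then to both pooled.
#' @return the input with an added numeric column `e`; attributes
#'   `center_offset` and `pseudocount` record the centring.
#' @export
compute_enrichments <- function(records, pseudocount = 0.5, center = TRUE) {
  need <- c("guide_id", "gene_id", "class", "count_low", "count_high")
  .check(is.data.frame(records) && nrow(records) > 0, "empty guide table")
  .check(all(need %in% names(records)), "guide table lacks columns: %s",
         paste(setdiff(need, names(records)), collapse = ", "))
  .check(!anyDuplicated(records$guide_id), "duplicated guide_id")
  .check(all(records$count_low >= 0) && all(records$count_high >= 0),
         "negative counts")
  .check(.is_number(pseudocount) && pseudocount > 0, "pseudocount must be > 0")
  n_low <- sum(records$count_low); n_high <- sum(records$count_high)
  .check(n_low > 0 && n_high > 0, "both bin totals must be positive")
  g <- nrow(records)
  e <- log2((records$count_low + pseudocount) / (n_low + pseudocount * g)) -
       log2((records$count_high + pseudocount) / (n_high + pseudocount * g))
  offset <- 0
  if (center) {
    ctrl <- which(records$class == "safe")
    if (!length(ctrl)) ctrl <- which(records$class == "nontargeting")
    if (!length(ctrl)) ctrl <- which(records$class %in% c("safe", "nontargeting"))
    .check(length(ctrl) > 0,
           "centering requested but no control guides (class 'safe' or 'nontargeting')")
    offset <- stats::median(e[ctrl])
    e <- e - offset
  }
  out <- records
  out$e <- e
  attr(out, "center_offset") <- offset
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Empirical null density from control-guide enrichments
#'
#' Gaussian kernel density with Silverman's rule-of-thumb bandwidth,
#' evaluated on a uniform grid spanning the data range plus three
#' bandwidths on each side, renormalised by the trapezoid rule and floored
#' at 1e-10.
#'
#' @param control_enrichments numeric vector of at least 50 control-guide
#'   enrichments.
#' @param n_grid number of grid points (>= 512).
#' @return object of class `"null_density"`: list with `grid`, `dens`,
#'   `bw` and the cumulative distribution `cdf` on the grid.
#' @export
fit_null_density <- function(control_enrichments, n_grid = 512L) {
  x <- control_enrichments[is.finite(control_enrichments)]
  .check(length(x) >= 50,
         "need >= 50 control enrichments for a stable null (got %d); pool control classes or add controls",
         length(x))
  .check(stats::sd(x) > 0, "control enrichments are constant; bandwidth would be zero")
  .check(.is_count(n_grid, 512), "n_grid must be an integer >= 512")
  h <- stats::bw.nrd0(x)
  d <- stats::density(x, bw = h, kernel = "gaussian",
                      from = min(x) - 3 * h, to = max(x) + 3 * h, n = n_grid)
  dens <- d$y / .trapz(d$x, d$y)
  dens <- pmax(dens, .DENS_FLOOR)
  obj <- list(grid = d$x, dens = dens, bw = h, cdf = .cumtrapz(d$x, dens))
  class(obj) <- "null_density"
  obj
}

# Null CDF at arbitrary points: piecewise-quadratic, i.e. the exact
# integral of the linearly-interpolated density, so that the theta -> 0
# limit of the convolution likelihood agrees with the density branch.
# Clamped to [0, total mass] outside the grid.
.null_cdf <- function(null, x) {
  g <- null$grid; n <- length(g)
  i <- findInterval(x, g)
  y <- numeric(length(x))
  mid <- i >= 1L & i < n
  ii <- i[mid]
  dx <- x[mid] - g[ii]
  slope <- (null$dens[ii + 1L] - null$dens[ii]) / (g[ii + 1L] - g[ii])
  y[mid] <- null$cdf[ii] + null$dens[ii] * dx + slope * dx^2 / 2
  y[i >= n] <- null$cdf[n]
  y
}

# interpolate the null density; outside the grid fall to the floor
.null_dens <- function(null, x) {
  y <- stats::approx(null$grid, null$dens, xout = x, rule = 2)$y
  out <- x < null$grid[1] | x > null$grid[length(null$grid)]
  y[out] <- .DENS_FLOOR
  pmax(y, .DENS_FLOOR)
}

# Per-guide likelihood matrix: rows = enrichments e, cols = theta values.
# theta = 0 columns use the null density itself (the theta -> 0 limit).
.guide_loglik <- function(e, null, thetas) {
  p0e <- .null_cdf(null, e)
  m <- matrix(0, length(e), length(thetas))
  nz <- thetas != 0
  if (any(nz)) {
    shift <- outer(e, thetas[nz], "-")            # e - theta
    pm <- (p0e - .null_cdf(null, shift)) / rep(thetas[nz], each = length(e))
    m[, nz] <- pm
  }
  if (any(!nz)) m[, !nz] <- .null_dens(null, e)
  log(pmax(m, .DENS_FLOOR))
}

#' Maximum-likelihood gene effect from guide enrichments
#'
#' Profiles the uniform-efficacy convolution likelihood over a grid of
#' candidate effects, returning the ML effect, the likelihood-ratio score
#' against theta = 0, and a 95% profile-likelihood confidence interval
#' (chi-square(1) cutoff 3.841). Argmax ties are broken toward the
#' smaller absolute effect.
#'
#' @param gene_enrichments numeric vector of the gene's guide enrichments.
#' @param null a `"null_density"` from [fit_null_density()].
#' @param theta_grid ascending grid of candidate effects spanning 0.
#' @return list with `effect`, `score`, `ci` (length-2), `n_guides`,
#'   and the profile `loglik` over `theta_grid`.
#' @export
estimate_gene_effect <- function(gene_enrichments, null,
                                 theta_grid = DEFAULT_THETA_GRID) {
  e <- gene_enrichments
  .check(length(e) >= 1, "need at least one guide")
  .check(inherits(null, "null_density"), "null must be a null_density object")
  .check(!is.unsorted(theta_grid, strictly = TRUE), "theta_grid must be strictly ascending")
  .check(min(theta_grid) <= 0 && max(theta_grid) >= 0, "theta_grid must span 0")
  if (any(e < null$grid[1] | e > null$grid[length(null$grid)]))
    warning("enrichment outside null support; floor density used")
  ll <- colSums(.guide_loglik(e, null, theta_grid))
  ll0 <- sum(log(.null_dens(null, e)))
  best <- which(ll == max(ll))
  best <- best[which.min(abs(theta_grid[best]))]
  theta_hat <- theta_grid[best]
  score <- max(0, 2 * (ll[best] - ll0))
  inside <- which(2 * (ll[best] - ll) <= .CHISQ1_95)
  ci <- c(theta_grid[min(inside)], theta_grid[max(inside)])
  list(effect = theta_hat, score = score, ci = ci,
       n_guides = length(e), loglik = ll)
}

# Batched scoring of many genes sharing one null/theta grid.
# e: all enrichments; gene: factor of the same length. Returns a data
# frame (gene, effect, score, ci_lo, ci_hi, n_guides). Identical to
# looping estimate_gene_effect over genes, but one interpolation pass.
.score_genes <- function(e, gene, null, theta_grid) {
  gene <- factor(gene, levels = unique(as.character(gene)))
  lg <- .guide_loglik(e, null, theta_grid)
  ll <- rowsum(lg, gene, reorder = FALSE)           # genes x thetas
  ll0 <- rowsum(log(.null_dens(null, e)), gene, reorder = FALSE)[, 1]
  n_guides <- as.integer(table(gene)[levels(gene)])
  k <- nrow(ll)
  effect <- numeric(k); score <- numeric(k)
  ci_lo <- numeric(k); ci_hi <- numeric(k)
  ord <- order(abs(theta_grid))  # tie-break toward small |theta|
  for (i in seq_len(k)) {
    row <- ll[i, ]
    best <- ord[which.max(row[ord])]
    effect[i] <- theta_grid[best]
    score[i] <- max(0, 2 * (row[best] - ll0[i]))
    inside <- which(2 * (row[best] - row) <= .CHISQ1_95)
    ci_lo[i] <- theta_grid[min(inside)]
    ci_hi[i] <- theta_grid[max(inside)]
  }
  data.frame(gene = levels(gene), effect = effect, score = score,
             ci_lo = ci_lo, ci_hi = ci_hi, n_guides = n_guides,
             stringsAsFactors = FALSE)
}

#' Fit gene effects for one screen replicate
#'
#' The main fitting entry point: computes enrichments, builds the control
#' null, estimates every targeting gene's effect, score and confidence
#' interval, and attaches permutation-based empirical FDRs.
#'
#' @param records guide count table (see [compute_enrichments()]).
#' @param pseudocount pseudocount for enrichments.
#' @param theta_grid candidate-effect grid.
#' @param n_pseudo number of pseudo-genes for the empirical FDR; default
#'   10 times the number of genes.
#' @param fdr_threshold hit threshold on the empirical FDR (default 0.1,
#'   i.e. <10% FDR) combined with a positive effect.
#' @param seed integer seed for pseudo-gene resampling.
#' @return object of class `"castle_screen"`: list with `results` (per-gene
#'   data frame: gene, effect, score, ci_lo, ci_hi, n_guides, fdr, hit),
#'   the `null` density, `enrichments`, and the call parameters.
#' @seealso [estimate_fdr()], [intersect_replicates()]
#' @export
castle_screen <- function(records, pseudocount = 0.5,
                          theta_grid = DEFAULT_THETA_GRID,
                          n_pseudo = NULL, fdr_threshold = 0.1, seed = 1L) {
  enr <- compute_enrichments(records, pseudocount = pseudocount)
  is_target <- enr$class == "targeting"
  is_ctrl <- enr$class == "safe"
  if (!any(is_ctrl)) is_ctrl <- enr$class == "nontargeting"
  if (!any(is_ctrl)) stop("no control guides for the null", call. = FALSE)
  null <- fit_null_density(enr$e[is_ctrl])
  res <- .score_genes(enr$e[is_target], enr$gene_id[is_target], null, theta_grid)
  if (is.null(n_pseudo)) n_pseudo <- 10L * nrow(res)
  res <- estimate_fdr(res, null, enr$e[is_ctrl], n_pseudo = n_pseudo,
                      seed = seed, theta_grid = theta_grid,
                      fdr_threshold = fdr_threshold)
  out <- list(results = res, null = null, enrichments = enr,
              theta_grid = theta_grid, fdr_threshold = fdr_threshold,
              n_pseudo = n_pseudo, seed = seed)
  class(out) <- "castle_screen"
  out
}

#' Empirical FDR by control-guide pseudo-gene permutation
#'
#' Pseudo-genes are assembled by resampling control-guide enrichments with
#' replacement, with guide counts drawn from the real genes' guide-count
#' distribution, and scored with the same likelihood machinery. The FDR at
#' score s is the pseudo-gene exceedance rate divided by the real-gene
#' exceedance rate, capped at 1 and monotonised by cumulative minimum from
#' the top score down.
#'
#' @param results per-gene data frame with `gene`, `effect`, `score`,
#'   `n_guides` (as from the fitting step).
#' @param null `"null_density"` object.
#' @param control_enrichments control-guide enrichments to resample.
#' @param n_pseudo number of pseudo-genes (>= 10x genes recommended).
#' @param seed integer seed for the resampling.
#' @param theta_grid candidate-effect grid used for scoring.
#' @param fdr_threshold hit threshold; hits additionally require a
#'   positive effect.
#' @return `results` with columns `fdr` and `hit` added.
#' @export
estimate_fdr <- function(results, null, control_enrichments, n_pseudo,
                         seed = 1L, theta_grid = DEFAULT_THETA_GRID,
                         fdr_threshold = 0.1) {
  .check(nrow(results) > 0, "no gene results")
  .check(.is_count(n_pseudo), "n_pseudo must be a positive integer")
  set.seed(as.integer(seed))
  nc <- length(control_enrichments)
  # log-likelihood of every control value at every theta, computed once
  lg <- .guide_loglik(control_enrichments, null, theta_grid)
  lg0 <- log(.null_dens(null, control_enrichments))
  sizes <- sample(results$n_guides, n_pseudo, replace = TRUE)
  pseudo_scores <- numeric(n_pseudo)
  for (b in seq_len(n_pseudo)) {
    idx <- sample.int(nc, sizes[b], replace = TRUE)
    ll <- if (length(idx) == 1L) lg[idx, ] else colSums(lg[idx, , drop = FALSE])
    pseudo_scores[b] <- max(0, max(ll) - sum(lg0[idx])) * 2
  }
  s <- results$score
  ps <- sort(pseudo_scores)
  n_real <- length(s)
  # exceedance counts via sorted lookup
  n_pseudo_ge <- n_pseudo - findInterval(s - 1e-12, ps)
  rs <- sort(s)
  n_real_ge <- n_real - findInterval(s - 1e-12, rs)
  fdr <- pmin(1, (n_pseudo_ge / n_pseudo) / (n_real_ge / n_real))
  # monotonise: running minimum in score order, so the final FDR is
  # non-increasing as the score increases
  ord <- order(s)
  fdr[ord] <- cummin(fdr[ord])
  results$fdr <- fdr
  results$hit <- results$effect > 0 & fdr < fdr_threshold
  results
}

#' Replicate-intersected hit list
#'
#' Genes called as hits (positive effect, FDR below threshold) in every
#' replicate, ordered by the minimum cross-replicate score, descending.
#'
#' @param fits list of two or more `"castle_screen"` fits (or their
#'   `results` data frames) over the same gene universe.
#' @param threshold FDR threshold re-applied per replicate (default 0.1).
#' @return data frame with `gene` and `min_score`.
#' @export
intersect_replicates <- function(fits, threshold = 0.1) {
  .check(length(fits) >= 2, "need at least two replicates")
  tabs <- lapply(fits, function(f) if (inherits(f, "castle_screen")) f$results else f)
  universe <- tabs[[1]]$gene
  for (t in tabs[-1]) {
    if (!setequal(t$gene, universe)) {
      diffs <- c(setdiff(universe, t$gene), setdiff(t$gene, universe))
      stop("replicates differ in gene universe: ",
           paste(utils::head(diffs, 20), collapse = ", "), call. = FALSE)
    }
  }
  hit_sets <- lapply(tabs, function(t) t$gene[t$effect > 0 & t$fdr < threshold])
  hits <- Reduce(intersect, hit_sets)
  if (!length(hits)) {
    return(data.frame(gene = character(), min_score = numeric(),
                      stringsAsFactors = FALSE))
  }
  min_score <- sapply(hits, function(g) {
    min(sapply(tabs, function(t) t$score[match(g, t$gene)]))
  })
  out <- data.frame(gene = hits, min_score = unname(min_score),
                    stringsAsFactors = FALSE)
  out[order(-out$min_score), , drop = FALSE]
}

#' @export
print.castle_screen <- function(x, ...) {
  r <- x$results
  cat("casTLE-style two-bin screen fit\n")
  cat(sprintf("  genes: %d   guides: %d (%d controls)\n",
              nrow(r), nrow(x$enrichments),
              sum(x$enrichments$class != "targeting")))
  cat(sprintf("  null bandwidth: %.4f   pseudo-genes: %d\n",
              x$null$bw, x$n_pseudo))
  cat(sprintf("  hits (effect > 0, FDR < %.2g): %d\n",
              x$fdr_threshold, sum(r$hit)))
  invisible(x)
}

#' @export
summary.castle_screen <- function(object, ...) {
  r <- object$results
  top <- r[order(-r$score), ]
  cat("Top genes by likelihood-ratio score:\n")
  print(utils::head(top[, c("gene", "effect", "score", "ci_lo", "ci_hi", "fdr", "hit")], 10),
        row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
coef.castle_screen <- function(object, ...) {
  stats::setNames(object$results$effect, object$results$gene)
}

#' @export
confint.castle_screen <- function(object, parm, level = 0.95, ...) {
  r <- object$results
  m <- cbind(r$ci_lo, r$ci_hi)
  rownames(m) <- r$gene
  colnames(m) <- c("2.5 %", "97.5 %")
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' @export
plot.castle_screen <- function(x, ...) {
  r <- x$results
  graphics::plot(r$effect, r$score,
                 col = ifelse(r$hit, "firebrick", "grey50"),
                 pch = 16, cex = 0.6,
                 xlab = "effect (log2 low/high bin shift)",
                 ylab = "likelihood-ratio score", ...)
  graphics::abline(v = 0, lty = 2, col = "grey70")
  invisible(x)
}
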