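test_that("enrichments follow the pseudocounted log-ratio closed form", {
  # symmetric counts with equal bin totals give zero enrichment
  tab <- make_counts(rep(10, 6), rep(10, 6),
                     class = c(rep("targeting", 3), rep("safe", 3)))
  enr <- compute_enrichments(tab)
  expect_equal(enr$e, rep(0, 6))
  expect_equal(attr(enr, "center_offset"), 0)

  # hand-evaluated closed form: c_low 15, c_high 0, equal totals, pc 0.5
  g <- 100
  cl <- c(15, rep((1e6 - 15) / (g - 1), g - 1))
  ch <- c(0, rep(1e6 / (g - 1), g - 1))
  enr <- compute_enrichments(make_counts(cl, ch), pseudocount = 0.5,
                             center = FALSE)
  expect_equal(enr$e[1], log2(15.5 / 0.5), tolerance = 1e-12)

  # all-control table has median zero after centering
  set.seed(1)
  tab <- make_counts(rpois(60, 100), rpois(60, 100),
                     gene_id = rep("safe_ctl", 60), class = rep("safe", 60))
  enr <- compute_enrichments(tab)
  expect_equal(median(enr$e), 0)
})

test_that("enrichment computation validates its inputs", {
  expect_error(compute_enrichments(data.frame()), "empty")
  tab <- make_counts(c(5, 5), c(5, 5))
  expect_error(compute_enrichments(tab, center = TRUE), "control")
  expect_silent(compute_enrichments(tab, center = FALSE))
  expect_error(compute_enrichments(make_counts(c(0, 0), c(1, 1)),
                                   center = FALSE), "totals")
})

test_that("null density is a proper, floored, Silverman-bandwidth KDE", {
  set.seed(7)
  x <- rnorm(10000)
  null <- fit_null_density(x)
  expect_equal(null$bw, bw.nrd0(x))
  # integral 1 within 1e-3 (trapezoid renormalization)
  expect_equal(melscreen:::.trapz(null$grid, null$dens), 1, tolerance = 1e-3)
  expect_true(all(null$dens >= 1e-10))
  # max density within 20% of the standard normal mode 1/sqrt(2*pi)
  expect_equal(max(null$dens), dnorm(0), tolerance = 0.2)
  expect_error(fit_null_density(rnorm(20)), ">= 50")
  expect_error(fit_null_density(rep(1, 100)), "constant")
})

test_that("gene effect estimation matches an independent convolution oracle", {
  null <- std_normal_null()
  # oracle: dense optimisation of the closed-form normal-convolution
  # likelihood p_theta(e) = (Phi(e) - Phi(e - theta)) / theta
  oracle <- optimize(function(th) log((pnorm(2) - pnorm(2 - th)) / th),
                     c(0.1, 8), maximum = TRUE)$maximum
  fit <- estimate_gene_effect(rep(2, 10), null)
  expect_equal(fit$effect, oracle, tolerance = 0.1)
  expect_gt(fit$score, 10)
  expect_true(fit$ci[1] <= fit$effect && fit$effect <= fit$ci[2])
})

test_that("null-mode guides give a null fit with a CI spanning zero", {
  null <- std_normal_null()
  mode <- null$grid[which.max(null$dens)]
  fit <- estimate_gene_effect(rep(mode, 8), null)
  expect_lt(abs(fit$effect), 0.1)
  expect_lt(fit$score, 0.5)
  expect_true(fit$ci[1] <= 0 && fit$ci[2] >= 0)
  # a single central guide is uninformative: wide CI including zero
  single <- estimate_gene_effect(0, null)
  expect_true(single$ci[1] < -1 && single$ci[2] > 1)
})

test_that("likelihood is continuous at theta -> 0", {
  null <- std_normal_null()
  grid <- c(-1, -1e-4, 0, 1e-4, 1)
  mode <- null$grid[which.max(null$dens)]
  ll <- estimate_gene_effect(mode, null, theta_grid = grid)$loglik
  expect_lt(abs(ll[4] - ll[3]), 1e-6)   # theta -> 0+ at the null mode
  ll2 <- estimate_gene_effect(c(0.3, -0.2, 0.5), null, theta_grid = grid)$loglik
  expect_lt(abs(ll2[4] - ll2[3]), 1e-3) # off-mode: O(theta) agreement
  expect_lt(abs(ll2[2] - ll2[3]), 1e-3)
})

test_that("score is invariant to translating data and null together", {
  null <- std_normal_null()
  shifted <- null
  shifted$grid <- null$grid + 3.7
  f1 <- estimate_gene_effect(c(1.2, 0.4, 2.2), null)
  f2 <- estimate_gene_effect(c(1.2, 0.4, 2.2) + 3.7, shifted)
  expect_equal(f1$score, f2$score, tolerance = 1e-9)
  expect_equal(f1$effect, f2$effect)
})

test_that("batched gene scoring equals the per-gene estimator", {
  null <- std_normal_null()
  set.seed(31)
  e <- rnorm(30, sd = 1.4)
  gene <- rep(sprintf("g%02d", 1:6), each = 5)
  batch <- melscreen:::.score_genes(e, gene, null, DEFAULT_THETA_GRID)
  for (i in 1:6) {
    single <- estimate_gene_effect(e[gene == batch$gene[i]], null)
    expect_equal(batch$effect[i], single$effect)
    expect_equal(batch$score[i], single$score, tolerance = 1e-9)
    expect_equal(c(batch$ci_lo[i], batch$ci_hi[i]), single$ci)
  }
})

test_that("empirical FDR is seeded, monotone, and calibrated under the null", {
  null <- std_normal_null()
  set.seed(91)
  ctrl <- rnorm(400)
  e <- rnorm(200)
  gene <- rep(sprintf("g%03d", 1:40), each = 5)
  res <- melscreen:::.score_genes(e, gene, null, DEFAULT_THETA_GRID)
  f1 <- estimate_fdr(res, null, ctrl, n_pseudo = 400, seed = 5)
  f2 <- estimate_fdr(res, null, ctrl, n_pseudo = 400, seed = 5)
  expect_identical(f1$fdr, f2$fdr)
  ord <- order(f1$score)
  expect_true(all(diff(f1$fdr[ord]) <= 1e-12))
  expect_true(all(f1$fdr >= 0 & f1$fdr <= 1))
})

test_that("replicate intersection follows set semantics and score order", {
  mk <- function(genes, effects, fdrs, scores) {
    data.frame(gene = genes, effect = effects, score = scores,
               fdr = fdrs, stringsAsFactors = FALSE)
  }
  a <- mk(c("x", "y", "z"), c(2, 2, -1), c(0.01, 0.02, 0.01), c(30, 20, 25))
  b <- mk(c("x", "y", "z"), c(-2, 2, 2), c(0.01, 0.05, 0.01), c(10, 40, 15))
  out <- intersect_replicates(list(a, b))
  expect_equal(out$gene, "y")       # x fails sign in b, z fails sign in a
  expect_equal(out$min_score, 20)
  expect_equal(intersect_replicates(list(a, a))$gene, c("x", "y"))
  bad <- mk(c("x", "y", "w"), c(1, 1, 1), c(1, 1, 1), c(1, 1, 1))
  expect_error(intersect_replicates(list(a, bad)), "universe")
})

test_that("castle_screen methods expose the fit", {
  set.seed(12)
  theta <- setNames(rep(2.5, 5), sprintf("gene%04d", 1:5))
  sim <- simulate_screen(screen_sim_config(n_genes = 20, n_safe_controls = 200,
                                           n_nontargeting = 0,
                                           effect_dist = theta, seed = 3))
  fit <- castle_screen(sim$replicates[[1]], seed = 9)
  expect_s3_class(fit, "castle_screen")
  expect_named(coef(fit), sim$truth$gene, ignore.order = TRUE)
  ci <- confint(fit)
  expect_true(all(ci[, 1] <= coef(fit)[rownames(ci)]))
  expect_output(print(fit), "hits")
  expect_output(summary(fit), "score")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
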