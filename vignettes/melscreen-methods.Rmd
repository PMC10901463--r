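---
title: "Models and methods behind melscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind melscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melscreen)
```

This vignette explains the statistical models the package implements,
the assumptions behind them, the tunable parameters and the numerical
choices, and what the synthetic-data generators do and do not emulate.

## The two-bin sorted-screen likelihood

A pooled knockout screen sorted into the low and high tails of a
side-scatter (SSC) distribution yields, per sgRNA, read counts in the
two bins. Guides against a gene whose loss lowers melanin (and hence
SSC) enrich in the low bin. The per-guide summary statistic is the
centred, pseudocounted log-ratio of bin frequencies

$$e_i = \log_2\frac{(c_{\text{low},i} + \lambda)/(N_\text{low} + \lambda G)}
                    {(c_{\text{high},i} + \lambda)/(N_\text{high} + \lambda G)}
        - \operatorname{median}_\text{controls}(e),$$

with pseudocount $\lambda = 0.5$ and $G$ the number of guides. Centring
on the safe-targeting controls removes the compositional offset that
bin-wise normalisation leaves behind.

The gene model is the casTLE-family convolution likelihood: guide $i$
has an unknown efficacy $u_i \sim \mathrm{Uniform}(0,1)$ scaling the
gene effect $\theta$ (log2 units), so conditional on $\theta$ the guide
enrichment is a draw from the control null $p_0$ shifted by
$u_i\theta$. Marginalising $u_i$,

$$p_\theta(e) = \frac{1}{|\theta|}\int_0^\theta p_0(e - t)\,dt,
  \qquad p_{\theta=0}(e) = p_0(e).$$

The key assumptions are (i) the control guides characterise the
enrichment noise of inert guides, (ii) guide efficacies are exchangeable
and uniform, and (iii) guides act independently given $\theta$. The
gene's log likelihood $L(\theta)$ is maximised over a fixed grid;
the score $S = 2\{L(\hat\theta) - L(0)\}$ is a likelihood-ratio
statistic, and the 95% confidence interval collects grid points with
$2\{L(\hat\theta) - L(\theta)\} \le 3.841$ ($\chi^2_1$).

**Numerical choices.** The null is a Gaussian KDE with Silverman
bandwidth on a 512-point uniform grid spanning the control range ±3
bandwidths, trapezoid-renormalised and floored at $10^{-10}$. The
convolution is evaluated through the null's cumulative distribution,
interpolated piecewise-quadratically (the exact integral of the
linearly-interpolated density) so that $p_\theta \to p_0$ as
$\theta \to 0$ without a discontinuity at the grid scale. Enrichments
outside the null support fall to the floor density with a warning. The
default $\theta$ grid is 401 points on $[-8, 8]$ log2 units (0.04
spacing, which bounds the effect quantisation); argmax ties break toward
the smaller $|\theta|$.

**Error control.** The empirical FDR resamples pseudo-genes from the
control enrichments (guide counts drawn from the real genes' guide-count
distribution; default $10\times$ as many pseudo-genes as genes), scores
them identically, and sets
$\mathrm{FDR}(s) = \frac{\#\{\text{pseudo} \ge s\}/n_\text{pseudo}}
{\#\{\text{real} \ge s\}/n_\text{real}}$, capped at 1. The final FDR
column is the running minimum taken upward in score, which makes it
non-increasing in the score — the direction required for a threshold
rule "call everything with FDR below $\alpha$" to be coherent. Hits
require a *positive* effect (the melanin-promoting tail) and FDR below
10%; replicate intersection requires the rule to pass in every
replicate independently.

## The population branch statistic

For target population A against references B and C, each SNP gets the
three pairwise Hudson $F_\mathrm{ST}$ estimates

$$\hat N = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1},
  \qquad \hat D = p_1(1-p_2) + p_2(1-p_1),$$

branch lengths $T = -\ln(1-F)$, and
$\mathrm{PBS}_A = (T_{AB} + T_{AC} - T_{BC})/2$. Hudson's ratio
estimator was chosen because it is the standard per-SNP two-population
estimator without weighting choices; the log base only rescales PBS
monotonically, so ranks, quantile flags and empirical p-values are
base-invariant. Negative $\hat F$ is clamped to 0 and $\hat F = 1$ to
$1 - 10^{-6}$ before the log, preventing infinite branches; raw
(possibly negative) PBS is retained. Empirical significance is the
self-inclusive rank over the genome-wide SNP set
($p_i = \#\{j: \mathrm{PBS}_j \ge \mathrm{PBS}_i\}/N$), and the
top-$10^{-4}$ / top-$10^{-3}$ flags use the $\lceil \ell N\rceil$-th
largest value as a closed threshold (ties included). Gene annotation
uses closed ±100 kb windows around gene bodies, 1-based inclusive, with
multi-assignment when windows overlap. No MAF filter is applied by
default.

## Concordance and enrichment tests

The eQTL–GWAS direction test asks whether the expression-increasing
allele of each screen hit's lead eQTL also darkens skin colour in GWAS.
Lead selection filters at eQTL $P < 0.01$, then takes minimum p with
ties broken by distance and genomic position. Harmonization aligns the
GWAS effect to the eQTL's effect allele, flipping the sign for swapped
orientations and excluding strand-ambiguous (A/T, C/G) pairs — without
strand information their orientation is undecidable. The two-sided
exact binomial is defined as twice the smaller tail, capped at 1; for 7
agreements out of 7 this gives $2 \cdot 2^{-7} = 0.015625$. Zero
effects carry no direction and are dropped with a count.

Fisher's exact test reports both the sample odds ratio $(ad)/(bc)$ and
the conditional-MLE estimate, with the usual two-sided p summing
hypergeometric outcomes no more probable than the observed table. For
the hit-proximity table (8, 161, 322, 19722) both estimators give
$\approx 3.04$.

Spearman correlations use midranks and the t-approximation on $n-2$
degrees of freedom — at the sample sizes involved (30 donors; hundreds
to thousands of SNPs) the exact permutation null is unnecessary. The
stratified comparison of GWAS effects by PBS significance uses the
Wilcoxon rank-sum normal approximation with tie and continuity
correction; the continuity correction keeps minimal strata honest
(two singleton strata give $p = 1$, not 0.32).

The expression screen classifies a gene as positively (negatively)
melanin-associated when its BH q-value is strictly below 0.1 and
$\rho > 0$ ($< 0$). "q value" means Benjamini–Hochberg step-up — the
conservative default when the multiple-testing procedure is otherwise
unspecified. Measurability means TPM strictly positive in every
sample. A useful analytic identity: if $k$ of $m$ tests are rejected at
FDR $\alpha$, the BH rejection boundary sits at $p^* = k\alpha/m$, and
inverting the t-approximation turns $p^*$ into an implied $|\rho|$
cutoff (`spearman_bh_cutoff()`); for 119 of 158 tests at $\alpha=0.1$
with 30 samples this gives 0.33.

## What the generators emulate — and what they do not

**Screen generator.** Lognormal guide abundances (library skew, log2 sd
0.5), uniform per-guide efficacies multiplying the gene effect — the
same efficacy model the estimator assumes, so estimator and generator
are self-consistent — and negative-binomial counts with dispersion 0.1
around bin-specific expectations at a configurable depth (default 500
reads/guide/bin). Depth and dispersion are free parameters: the
sequencing-noise profile of a real screen is screen-specific, and these
defaults represent a well-powered experiment. The generator does not
model guide-specific off-target effects, cell-cycle or fitness
coupling, or sort-purity errors; passing recovery tests therefore shows
correctness of the inference given the model, not robustness to those
real-data pathologies.

**Population generator.** Balding–Nichols Beta drift around a uniform
ancestral frequency, independent across SNPs (no linkage
disequilibrium, no coalescent history), with planted selection as an
additive frequency shift in the target population, clipped half a
chromosome away from fixation. The default per-branch drift F = 0.01
deserves a note: at desk scale ($10^4$ SNPs) the top-0.1% threshold
sits at a far less extreme tail quantile than in a real genome-wide
panel, so for a planted sweep-scale shift (Δ = 0.4) to hold the same
standing that strong pigmentation sweeps have against the real
genome-wide background — several standard deviations clear of drift —
the neutral background must be proportionally tighter. With F = 0.01
the shift is a ≈6σ excursion and planted loci dominate the extreme
tail, which is the regime the scan is designed to detect.

**Pair generator.** eQTL slopes are Gaussian (sd 0.5); GWAS betas are a
linear image (κ = 0.2) plus noise, with a configurable sign-flip
probability, and p-values fall monotonically with effect magnitude
through a normal-score rule. Allele orientations are randomly swapped
between the two tables so harmonization is always exercised.

**Expression generator.** Per-sample melanin OD400 is uniform on
[0.1, 1.2] absorbance units (the spread of diversely pigmented donor
melanocytes); log2 TPM is linear in melanin with half-normal slopes
(sd 5 log2 units per OD unit) and residual sd 0.5. The default class
fractions (68% positive, 8% negative) and the signal-to-noise were set
so that a default 158-gene × 30-sample simulation reproduces the
observed call fractions of the donor-melanocyte survey it emulates
(~107 positive and ~12 negative calls at q < 0.1). Real RNA-seq
features not modelled: library-size and batch effects, count noise at
low TPM, and correlated co-expression modules.

All generators are deterministic given their seed, and every stochastic
stage of the pipeline takes an explicit seed.

## Problem sizes and runtime

The test suite and the acceptance script run screens of 1,100 genes ×
10 guides at depth 500 with two replicates (seconds per replicate with
the batched scorer), 20 null screens of 100 genes for calibration,
$10^4$-SNP selection scans, and Monte-Carlo calibrations of 1,000
replicates per test — sizes at which every recovery and calibration
property is measurable with comfortable margins while the whole suite
runs in well under a minute.

## Known limitations

* Negative (melanin-suppressing) effects are estimated but never called
  as hits; the hit rule targets the positive tail only.
* The screen likelihood treats guides as exchangeable: no guide-level
  variance shrinkage across genes, no modelling of guide-specific
  efficacy covariates.
* The PBS empirical p-value is a genome-wide rank, not a model-based
  tail probability; with $N$ SNPs its resolution is $1/N$.
* Fisher's printed odds ratio convention differs between software
  conventions (sample vs conditional-MLE); both are reported.
* The concordance analysis assumes summary statistics are on the same
  genome build and strand conventions apart from allele swaps; no
  liftover is provided.
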