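# Umbrella pipeline: runs requested stages in dependency order from a
# YAML (or list) configuration, writes every stage's tables under the
# output directory, and records a manifest (package version, per-stage
# seeds, output checksums and row counts). Identical config + seeds give
# identical outputs.

.PIPELINE_STAGES <- c("synth_screen", "screen", "synth_expr", "exprcorr",
                      "synth_pops", "pbs", "synth_pairs", "concord")

#' Run the analysis pipeline from a configuration
#'
#' The configuration is a YAML file (or an equivalent nested list) with
#' top-level keys `out_dir`, optional `seed` (master seed; per-stage seeds
#' default to values derived from it) and `stages`, a named block per
#' requested stage. Recognised stages, run in this order when present:
#' `synth_screen`, `screen`, `synth_expr`, `exprcorr`, `synth_pops`,
#' `pbs`, `synth_pairs`, `concord`. Synthetic stages feed the matching
#' analysis stage; analysis stages can instead name input files
#' (`counts`, `tpm`/`melanin`, `freqs` or `vcf`+`popmap`, `eqtl`/`gwas`).
#' Unknown top-level or stage keys are rejected.
#'
#' @param config path to a YAML file, or a list.
#' @return invisibly, the manifest list (also written as
#'   `manifest.json` in `out_dir`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .check(is.list(config), "config must be a list or a YAML path")
  known_top <- c("out_dir", "seed", "stages")
  extra <- setdiff(names(config), known_top)
  .check(length(extra) == 0, "unknown config keys: %s", paste(extra, collapse = ", "))
  .check(!is.null(config$out_dir), "config field missing: out_dir")
  .check(!is.null(config$stages) && length(config$stages) > 0,
         "config field missing: stages")
  bad <- setdiff(names(config$stages), .PIPELINE_STAGES)
  .check(length(bad) == 0, "unknown stages: %s", paste(bad, collapse = ", "))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  master <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stage_seed <- function(block, k) {
    if (!is.null(block$seed)) as.integer(block$seed) else .subseed(master, k)
  }
  env <- new.env(parent = emptyenv())
  manifest <- list(package = "melscreen",
                   version = as.character(utils::packageVersion("melscreen")),
                   master_seed = master, stages = list())
  files <- character()
  note <- function(path, n) {
    files[[path]] <<- path
    list(file = basename(path), rows = n)
  }
  run_one <- function(stage) {
    block <- config$stages[[stage]]
    if (is.null(block)) block <- list()
    k <- match(stage, .PIPELINE_STAGES)
    seed <- stage_seed(block, k)
    info <- list(seed = seed)
    get_arg <- function(name, default) if (is.null(block[[name]])) default else block[[name]]
    switch(stage,
      synth_screen = {
        cfg <- screen_sim_config(
          n_genes = get_arg("n_genes", 100L),
          guides_per_gene = get_arg("guides_per_gene", 10L),
          n_safe_controls = get_arg("n_safe_controls", 500L),
          n_nontargeting = get_arg("n_nontargeting", 500L),
          effect_dist = unlist(block$effect_dist),
          depth = get_arg("depth", 500),
          dispersion = get_arg("dispersion", 0.1),
          n_replicates = get_arg("n_replicates", 2L),
          seed = seed)
        env$screen_sim <- simulate_screen(cfg)
        for (r in seq_along(env$screen_sim$replicates)) {
          p <- file.path(out_dir, sprintf("screen_counts_rep%d.tsv", r))
          write_tsv(env$screen_sim$replicates[[r]], p)
          info[[sprintf("rep%d", r)]] <- note(p, nrow(env$screen_sim$replicates[[r]]))
        }
        p <- file.path(out_dir, "screen_truth.tsv")
        write_tsv(env$screen_sim$truth, p)
        info$truth <- note(p, nrow(env$screen_sim$truth))
      },
      screen = {
        counts <- if (!is.null(env$screen_sim)) {
          env$screen_sim$replicates
        } else {
          .check(!is.null(block$counts), "screen stage needs 'counts' paths or a synth_screen stage")
          lapply(block$counts, read_tsv)
        }
        fits <- lapply(seq_along(counts), function(r) {
          castle_screen(counts[[r]], fdr_threshold = get_arg("fdr", 0.1),
                        seed = .subseed(seed, r))
        })
        env$screen_fits <- fits
        for (r in seq_along(fits)) {
          p <- file.path(out_dir, sprintf("screen_results_rep%d.tsv", r))
          write_tsv(fits[[r]]$results, p)
          info[[sprintf("results_rep%d", r)]] <- note(p, nrow(fits[[r]]$results))
        }
        hits <- intersect_replicates(fits, threshold = get_arg("fdr", 0.1))
        env$screen_hits <- hits
        p <- file.path(out_dir, "screen_hits.tsv")
        write_tsv(hits, p)
        info$hits <- note(p, nrow(hits))
      },
      synth_expr = {
        cfg <- expr_sim_config(n_genes = get_arg("n_genes", 158L),
                               n_samples = get_arg("n_samples", 30L),
                               seed = seed)
        env$expr_sim <- simulate_expression_melanin(cfg)
        p <- file.path(out_dir, "tpm.tsv")
        tab <- data.frame(gene = rownames(env$expr_sim$expr), env$expr_sim$expr,
                          check.names = FALSE)
        write_tsv(tab, p); info$tpm <- note(p, nrow(tab))
        p <- file.path(out_dir, "melanin.tsv")
        mel <- data.frame(sample = names(env$expr_sim$melanin),
                          od400 = unname(env$expr_sim$melanin))
        write_tsv(mel, p); info$melanin <- note(p, nrow(mel))
      },
      exprcorr = {
        if (!is.null(env$expr_sim)) {
          expr <- env$expr_sim$expr; mel <- env$expr_sim$melanin
        } else {
          .check(!is.null(block$tpm) && !is.null(block$melanin),
                 "exprcorr stage needs 'tpm' and 'melanin' paths or a synth_expr stage")
          tab <- read_tsv(block$tpm)
          expr <- as.matrix(tab[, -1]); rownames(expr) <- tab[[1]]
          mtab <- read_tsv(block$melanin)
          mel <- stats::setNames(mtab$od400, mtab$sample)
        }
        expr <- filter_measurable(expr)
        corr <- correlate_expression_melanin(expr, mel,
                                             q_cut = get_arg("q_cut", 0.1))
        cls <- classify_hits(corr, q_cut = get_arg("q_cut", 0.1))
        p <- file.path(out_dir, "expr_correlations.tsv")
        write_tsv(corr, p); info$correlations <- note(p, nrow(corr))
        p <- file.path(out_dir, "expr_summary.json")
        jsonlite::write_json(cls[c("n_positive", "n_negative", "n_ns",
                                   "n_total", "fraction_positive")],
                             p, auto_unbox = TRUE, digits = NA)
        info$summary <- note(p, 1L)
      },
      synth_pops = {
        cfg <- pop_sim_config(n_snps = get_arg("n_snps", 10000L),
                              n_selected = get_arg("n_selected", 0L),
                              selection_shift = get_arg("selection_shift", 0.4),
                              target = get_arg("target", "A"),
                              seed = seed)
        env$pop_sim <- simulate_three_pop_freqs(cfg)
        p <- file.path(out_dir, "pop_freqs.tsv")
        write_tsv(env$pop_sim$freqs, p)
        info$freqs <- note(p, nrow(env$pop_sim$freqs))
      },
      pbs = {
        freqs <- if (!is.null(env$pop_sim)) {
          env$pop_sim$freqs
        } else if (!is.null(block$freqs)) {
          read_tsv(block$freqs)
        } else {
          .check(!is.null(block$vcf) && !is.null(block$popmap),
                 "pbs stage needs 'freqs' or 'vcf'+'popmap' or a synth_pops stage")
          read_vcf_frequencies(block$vcf, read_popmap(block$popmap))
        }
        res <- compute_pbs(freqs, target = get_arg("target", "A"))
        env$pbs <- res
        p <- file.path(out_dir, "pbs.tsv")
        write_tsv(res, p); info$pbs <- note(p, nrow(res))
        if (!is.null(block$windows)) {
          ann <- annotate_gene_windows(res, read_tsv(block$windows))
          p <- file.path(out_dir, "pbs_gene_summary.tsv")
          write_tsv(ann$genes, p); info$gene_summary <- note(p, nrow(ann$genes))
        }
      },
      synth_pairs = {
        cfg <- pair_sim_config(n_genes = get_arg("n_genes", 100L),
                               discord_prob = get_arg("discord_prob", 0),
                               seed = seed)
        env$pair_sim <- simulate_eqtl_gwas_pairs(cfg)
        p <- file.path(out_dir, "eqtl.tsv")
        write_tsv(env$pair_sim$eqtl, p); info$eqtl <- note(p, nrow(env$pair_sim$eqtl))
        p <- file.path(out_dir, "gwas.tsv")
        write_tsv(env$pair_sim$gwas, p); info$gwas <- note(p, nrow(env$pair_sim$gwas))
      },
      concord = {
        if (!is.null(env$pair_sim)) {
          eqtl <- env$pair_sim$eqtl; gwas <- env$pair_sim$gwas
        } else {
          .check(!is.null(block$eqtl) && !is.null(block$gwas),
                 "concord stage needs 'eqtl' and 'gwas' paths or a synth_pairs stage")
          eqtl <- read_tsv(block$eqtl); gwas <- read_tsv(block$gwas)
        }
        lead <- select_lead_eqtl(eqtl, p_cut = get_arg("eqtl_p_cut", 0.01))
        harm <- harmonize_and_filter(lead, gwas,
                                     gwas_p_cut = get_arg("gwas_p_cut", 0.01))
        p <- file.path(out_dir, "concordance_pairs.tsv")
        write_tsv(harm, p); info$pairs <- note(p, nrow(harm))
        res <- tryCatch(sign_concordance_test(harm),
                        error = function(e) list(n_pairs = 0L, n_agree = 0L,
                                                 binomial_p = NA))
        p <- file.path(out_dir, "concordance.json")
        jsonlite::write_json(res, p, auto_unbox = TRUE, digits = NA)
        info$summary <- note(p, 1L)
      })
    manifest$stages[[stage]] <<- info
  }
  for (stage in intersect(.PIPELINE_STAGES, names(config$stages))) {
    tryCatch(run_one(stage), error = function(e) {
      stop(sprintf("stage '%s' failed: %s (earlier stage outputs remain in %s)",
                   stage, conditionMessage(e), out_dir), call. = FALSE)
    })
  }
  manifest$checksums <- as.list(tools::md5sum(unname(unlist(files))))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
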