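#' Default pipeline configuration
#'
#' Desk-scale defaults: 8 parents (8 crosses) x 400 segregants x 2,000
#' markers, 200 permutations per stepwise step. Every stochastic stage gets
#' an explicit seed derived from the master seed.
#'
#' @param seed master seed.
#' @param ... named overrides of any default.
#' @return a named list (class \code{pipeline_config}).
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_strains = 200L, n_markers = 2000L, n_chroms = 8L,
    n_parents = 8L, n_progeny = 400L,
    rare_target = 0.278, sfs_shape = 0.5,
    n_qtl = 20L, coupling_tau = -0.3, effect_scale = 0.25,
    sign_bias_recent = 0.75,
    h2_additive = 0.5, repeatability = 0.8, n_replicates = 2L,
    alpha = 0.05, B = 200L,
    maf_cutoff = 0.01, window_kb = 50, n_sims = 200L,
    effect_gate = effect_threshold_from_variance(0.02),
    out_dir = NULL
  )
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' simulate -> within-cross stepwise QTL scans -> additive variance
#' components per cross -> joint QTL mapping with per-cross effects ->
#' PICS fine-mapping of strong overlapping QTL -> population-frequency
#' summaries. All stage outputs are returned in a manifest (and written as
#' TSV/JSON when \code{out_dir} is set). A rerun with the same configuration
#' reproduces identical outputs.
#'
#' @param config a \code{pipeline_config}.
#' @return an object of class \code{run_manifest}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  t0 <- Sys.time()
  cfg <- config
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  # --- simulate ----------------------------------------------------------
  sim <- stage("simulate", {
    panel <- simulate_panel(cfg$n_strains, cfg$n_markers, cfg$n_chroms,
                            sfs_shape = cfg$sfs_shape,
                            rare_target = cfg$rare_target,
                            ascertain_in = cfg$n_parents,
                            seed = .subseed(cfg$seed, 1))
    design <- build_round_robin(panel, cfg$n_parents)
    G <- simulate_cross_genotypes(panel, design, cfg$n_progeny,
                                  seed = .subseed(cfg$seed, 2))
    truth <- assign_effects(panel, cfg$n_qtl, coupling_tau = cfg$coupling_tau,
                            effect_scale = cfg$effect_scale,
                            sign_bias_recent = cfg$sign_bias_recent,
                            seed = .subseed(cfg$seed, 3))
    ph <- simulate_phenotypes(G, truth, h2_additive = cfg$h2_additive,
                              repeatability = cfg$repeatability,
                              n_replicates = cfg$n_replicates,
                              seed = .subseed(cfg$seed, 4))
    list(panel = panel, design = design, G = G, truth = truth, pheno = ph)
  })
  y <- sim$pheno$segregant_means
  G <- sim$G
  # --- within-cross scans ------------------------------------------------
  within <- stage("scan", {
    out <- list()
    for (cr in levels(G$cross)) {
      rows <- which(G$cross == cr)
      segc <- which(!is.na(G$values[rows[1], ]))
      Vc <- G$values[rows, segc, drop = FALSE]
      keep <- apply(Vc, 2L, function(v) stats::var(v) > 0)
      tr <- forward_stepwise(.std(y[rows]), Vc[, keep, drop = FALSE],
                             alpha = cfg$alpha, B = cfg$B,
                             seed = .subseed(cfg$seed, 10 + match(cr, levels(G$cross))))
      sel <- segc[keep][tr$selected]
      eff <- if (length(sel))
        stats::lm.fit(cbind(1, G$values[rows, sel, drop = FALSE]),
                      .std(y[rows]))$coefficients[-1] else numeric(0)
      out[[cr]] <- list(trace = tr, index = sel, effect = eff)
    }
    out
  })
  # --- variance components ----------------------------------------------
  vc <- stage("vc", {
    out <- list()
    for (cr in levels(G$cross)) {
      rows <- which(G$cross == cr)
      segc <- which(!is.na(G$values[rows[1], ]))
      M <- standardize_markers(G$values[rows, segc, drop = FALSE])
      out[[cr]] <- additive_model(y[rows], kinship_gower(M))
    }
    out
  })
  # --- joint mapping -----------------------------------------------------
  joint <- stage("jointmap", {
    wq <- lapply(within, function(w) list(index = w$index, effect = w$effect))
    jq <- joint_forward_stepwise(y, G, within_qtl = wq, alpha = cfg$alpha,
                                 B = cfg$B, seed = .subseed(cfg$seed, 30))
    effects <- if (length(jq$selected))
      estimate_effects_per_cross(y, G, jq$selected) else NULL
    list(trace = jq, effects = effects)
  })
  # --- fine-mapping ------------------------------------------------------
  fm <- stage("finemap", {
    qtl_rows <- list()
    for (cr in names(within)) {
      rows <- which(G$cross == cr)
      sel <- within[[cr]]$index
      eff <- within[[cr]]$effect
      for (i in seq_along(sel)) {
        if (abs(eff[i]) < cfg$effect_gate) next
        ci <- lod_drop_interval(.std(y[rows]),
                                list(values = G$values[rows, , drop = FALSE],
                                     markers = G$markers),
                                peak = sel[i], covariates = sel[-i])
        qtl_rows[[length(qtl_rows) + 1L]] <-
          data.frame(cross = cr, peak = sel[i], chrom = G$markers$chrom[sel[i]],
                     left_bp = ci$left_bp, right_bp = ci$right_bp,
                     effect = eff[i], stringsAsFactors = FALSE)
      }
    }
    qtl <- if (length(qtl_rows)) do.call(rbind, qtl_rows) else NULL
    genes <- NULL; gene_table <- NULL
    if (!is.null(qtl) && nrow(qtl) >= 2) {
      pairs <- find_overlapping_qtl(qtl, sim$design)
      scores <- list()
      for (r in seq_len(nrow(pairs))) {
        i <- pairs$i[r]; j <- pairs$j[r]
        wins <- lapply(c(i, j), function(k) {
          cr <- qtl$cross[k]
          rows <- which(G$cross == cr)
          yc <- .std(y[rows])
          sel <- within[[cr]]$index
          res <- stats::lm.fit(cbind(1, G$values[rows, sel, drop = FALSE]),
                               yc)$residuals
          pics_window(list(values = G$values[rows, , drop = FALSE],
                           markers = G$markers),
                      peak = qtl$peak[k], effect = qtl$effect[k],
                      residuals = res, n_sims = cfg$n_sims,
                      window_kb = cfg$window_kb,
                      seed = .subseed(cfg$seed, 50 + r))
        })
        comb <- combine_cross_pair(wins[[1]], wins[[2]])
        if (is.null(comb)) next
        ann <- synthetic_gene_annotation(sim$panel, genes_per_chrom = 20L)
        gs <- aggregate_to_genes(comb, ann, G$markers)
        gs <- gs[gs$ppc_gene > 0, , drop = FALSE]
        if (nrow(gs)) scores[[length(scores) + 1L]] <- gs
      }
      if (length(scores)) gene_table <- gene_fdr(do.call(rbind, scores))
    }
    list(qtl = qtl, gene_table = gene_table)
  })
  # --- population-frequency summaries -----------------------------------
  pg <- stage("popgen", {
    mk <- G$markers
    cls <- classify_rare_common(mk$panel_maf, cfg$maf_cutoff)
    eff_tab <- joint$effects
    summ <- NULL
    if (!is.null(eff_tab) && nrow(eff_tab) >= 2) {
      summ <- bin_effects_by_frequency(eff_tab$panel_maf, eff_tab$mean_beta,
                                       bin_size = max(2L, nrow(eff_tab) %/% 3L))
    }
    list(class_counts = table(cls), effect_bins = summ)
  })
  manifest <- structure(list(
    config = cfg,
    n_segregants = length(y),
    within_qtl = lapply(within, function(w) w$index),
    h2_by_cross = vapply(vc, function(f) f$h2, numeric(1)),
    joint = joint, finemap = fm, popgen = pg,
    truth = sim$truth, pheno = sim$pheno, G = G, panel = sim$panel,
    wallclock_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "run_manifest")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_genotypes_tsv(G, file.path(cfg$out_dir, "genotypes.tsv"))
    write_marker_map(G$markers, file.path(cfg$out_dir, "markers.tsv"))
    write_phenotypes_tsv(sim$pheno$pheno,
                         file.path(cfg$out_dir, "phenotypes.tsv"))
    write_truth_json(sim$truth, file.path(cfg$out_dir, "truth.json"))
    if (!is.null(joint$effects))
      utils::write.table(joint$effects,
                         file.path(cfg$out_dir, "joint_qtl.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(fm$gene_table))
      utils::write.table(fm$gene_table,
                         file.path(cfg$out_dir, "genes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run:", x$n_segregants, "segregants,",
      length(x$within_qtl), "crosses\n")
  cat("  within-cross QTL:", sum(lengths(x$within_qtl)),
      "; joint QTL:", length(x$joint$trace$selected), "\n")
  cat(sprintf("  mean additive h2 estimate: %.3f\n", mean(x$h2_by_cross)))
  cat(sprintf("  wall clock: %.1f s\n", x$wallclock_sec))
  invisible(x)
}

#' Synthetic gene annotation for a simulated panel
#'
#' Non-overlapping open reading frames tiled along each chromosome, for use
#' in gene-level fine-mapping of synthetic data (no real genome involved).
#'
#' @param panel a \code{pop_panel}.
#' @param genes_per_chrom ORFs per chromosome.
#' @param orf_frac fraction of each tile covered by the ORF.
#' @return data frame: gene, chrom, start, end.
#' @export
synthetic_gene_annotation <- function(panel, genes_per_chrom = 20L,
                                      orf_frac = 0.7) {
  out <- list()
  for (ci in seq_along(panel$chrom_len_cM)) {
    mk <- panel$markers[panel$markers$chrom == ci, ]
    L <- max(mk$pos_bp) + 1000
    tile <- L / genes_per_chrom
    start <- round((seq_len(genes_per_chrom) - 1) * tile +
                     tile * (1 - orf_frac) / 2) + 1
    end <- round(start + tile * orf_frac)
    out[[ci]] <- data.frame(
      gene = sprintf("g%02d_%03d", ci, seq_len(genes_per_chrom)),
      chrom = ci, start = start, end = end, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
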