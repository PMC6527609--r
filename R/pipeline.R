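# Orchestration: runs the synthetic-cohort demo pipeline end to end and
# records a manifest. Stage parameters mirror each module's defaults.

.pipeline_defaults <- function() {
  list(
    out_dir = "rpeqtl_run",
    seed = 1L,
    stages = c("simulate", "qc", "selectivity", "eqtl", "sqtl", "coloc",
               "specificity", "nmd"),
    log_level = "info",
    simulate = list(n_samples = 23L, n_loci = 10L, variants_per_locus = 20L,
                    maf_range = c(0.1, 0.5), ld_copy_prob = 0.9,
                    depth_mean = 500, depth_dispersion = 10, ase_depth = 50,
                    gwas_n = 1e5, prop_causal = 0.5, prop_shared = 0.6,
                    beta = 1.5, pi = 0.75),
    qc = list(max_missing = 0.05, min_imputation_r2 = 0.8),
    selectivity = list(n_tissues = 40L, n_genes = 200L, z_target = 5,
                       z_threshold = 4, tissue = "fRPE"),
    eqtl = list(window_bp = 500000L, q = 0.05),
    sqtl = list(window_bp = 100000L, min_cluster_reads = 30L,
                min_fraction = 0.001, max_intron_bp = 100000L,
                perms = c(100L, 1000L), q = 0.05),
    coloc = list(gwas_p_max = 1e-4, qtl_p_max = 1e-5, window_bp = 500000L,
                 max_causal = 2L, clpp_threshold = 0.01),
    specificity = list(q_discovery = 0.05, q_replication = 0.1),
    nmd = list(k_hom = 100, k_het = 25, r = 3)
  )
}

.merge_config <- function(user, defaults, path = "config") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("validation error: unknown ", path, " key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      defaults[[k]] <- .merge_config(user[[k]], defaults[[k]],
                                     paste0(path, "$", k))
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

.log <- function(level, cfg, ...) {
  if (cfg$log_level == "quiet") return(invisible())
  message(sprintf("[rpeqtl %s] %s", level, paste0(...)))
}

#' Run the synthetic-data demonstration pipeline
#'
#' Executes the stages in dependency order (simulate -> qc ->
#' selectivity / eqtl / sqtl -> coloc / specificity -> nmd) on a
#' generated cohort, writing TSV outputs and a JSON manifest recording
#' package version, per-stage seeds, parameter hashes and output row
#' counts. The global seed fans out to per-stage seeds by a fixed
#' counter so stages are independently reproducible. Configuration keys
#' not present in the defaults are rejected before any stage runs.
#'
#' @param config Named list overriding any subset of the defaults (see
#'   \code{rpeqtl:::.pipeline_defaults}), or a path to a JSON file of the
#'   same shape.
#' @return Invisibly, the manifest list (also written to
#'   \code{out_dir/manifest.json}); element \code{status} is "ok" when
#'   every requested stage completed.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- .merge_config(config, .pipeline_defaults())
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(version = .rpe_version(), seed = cfg$seed,
                   stages = list(), status = "ok")
  stage_seed <- function(i) as.integer(cfg$seed + 101L * i)

  state <- new.env(parent = emptyenv())
  run_stage <- function(name, idx, fn) {
    if (!name %in% cfg$stages) return(invisible())
    .log("info", cfg, "stage ", name, " (seed ", stage_seed(idx), ")")
    rec <- tryCatch({
      counts <- fn(stage_seed(idx))
      list(status = "ok", seed = stage_seed(idx),
           params = .param_hash(cfg[[if (name == "simulate") "simulate"
                                     else name]]),
           rows = counts)
    }, error = function(e) {
      manifest$status <<- "failed"
      file.create(file.path(cfg$out_dir, paste0(name, ".partial")))
      list(status = "failed", error = conditionMessage(e))
    })
    manifest$stages[[name]] <<- rec
    invisible()
  }

  run_stage("simulate", 1L, function(seed) {
    p <- cfg$simulate
    sc <- sim_config(n_samples = p$n_samples, n_loci = p$n_loci,
                     variants_per_locus = p$variants_per_locus,
                     maf_range = p$maf_range, ld_copy_prob = p$ld_copy_prob,
                     depth_mean = p$depth_mean,
                     depth_dispersion = p$depth_dispersion,
                     ase_depth = p$ase_depth, gwas_n = p$gwas_n, seed = seed)
    state$config <- sc
    state$cohort <- simulate_cohort(sc)
    state$truth <- simulate_truth(state$cohort, sc, prop_causal = p$prop_causal,
                                  prop_shared = p$prop_shared, beta = p$beta,
                                  pi = p$pi)
    state$expr_sim <- simulate_expression(state$cohort, state$truth, sc)
    state$junc_sim <- simulate_junctions(state$cohort, state$truth, sc)
    write_vcf(state$cohort, file.path(cfg$out_dir, "cohort.vcf"))
    for (cond in sc$condition_names) {
      write_counts_tsv(state$expr_sim[[cond]]$counts,
                       file.path(cfg$out_dir, paste0("counts_", cond, ".tsv")),
                       seed = seed, params = p)
      write_ase_tsv(state$expr_sim[[cond]]$ase,
                    file.path(cfg$out_dir, paste0("ase_", cond, ".tsv")),
                    seed = seed, params = p)
    }
    c(variants = nrow(state$cohort$variant_meta),
      samples = nrow(state$cohort$sample_meta))
  })

  run_stage("qc", 2L, function(seed) {
    g <- as_geno(state$cohort)
    fv <- filter_variants(g, max_missing = cfg$qc$max_missing,
                          min_imputation_r2 = cfg$qc$min_imputation_r2)
    state$geno <- fv$geno
    tt <- tstv_ratio(state$geno)
    dup <- detect_duplicates(state$geno)
    pca <- genotype_pca(state$geno)
    qc <- data.frame(sample = rownames(pca$components), pca$components)
    data.table::fwrite(qc, file.path(cfg$out_dir, "sample_qc.tsv"), sep = "\t")
    utils::write.table(
      data.frame(chrom = names(tt), tstv = as.numeric(tt)),
      file.path(cfg$out_dir, "tstv.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
    c(variants_pass = sum(fv$report$per_variant$pass), duplicates = nrow(dup))
  })

  run_stage("selectivity", 3L, function(seed) {
    p <- cfg$selectivity
    sel_genes <- paste0("rpe_gene_", 1:5)
    panel <- simulate_tissue_panel(
      n_tissues = p$n_tissues, n_genes = p$n_genes,
      selective_sets = stats::setNames(list(sel_genes), p$tissue),
      z_target = p$z_target, seed = seed)
    scores <- selectivity_zscores(panel)
    calls <- call_selective(scores, p$tissue, p$z_threshold,
                            gene_meta = panel$gene_meta)
    data.table::fwrite(scores, file.path(cfg$out_dir, "selectivity.tsv"),
                       sep = "\t")
    writeLines(calls, file.path(cfg$out_dir, "selective_genes.txt"))
    c(scored = nrow(scores), called = length(calls))
  })

  run_stage("eqtl", 4L, function(seed) {
    geno <- if (!is.null(state$geno)) state$geno else as_geno(state$cohort)
    recs <- list()
    for (cond in state$config$condition_names) {
      expr <- expression_matrix(state$expr_sim[[cond]]$counts,
                                state$truth$genes)
      recs[[cond]] <- cis_scan(expr, geno, ase = state$expr_sim[[cond]]$ase,
                               window_bp = cfg$eqtl$window_bp,
                               condition = cond)
    }
    state$eqtl_records <- recs
    mc <- multi_condition_fdr(recs, q = cfg$eqtl$q)
    state$eqtl_calls <- mc
    data.table::fwrite(do.call(rbind, recs),
                       file.path(cfg$out_dir, "eqtl_associations.tsv"),
                       sep = "\t")
    data.table::fwrite(mc$genes, file.path(cfg$out_dir, "eqtl_genes.tsv"),
                       sep = "\t")
    c(records = sum(vapply(recs, nrow, integer(1))),
      egenes = sum(mc$genes$selected))
  })

  run_stage("sqtl", 5L, function(seed) {
    geno <- if (!is.null(state$geno)) state$geno else as_geno(state$cohort)
    p <- cfg$sqtl
    res_all <- list()
    for (cond in state$config$condition_names) {
      cl <- cluster_introns(state$junc_sim[[cond]],
                            min_cluster_reads = p$min_cluster_reads,
                            min_fraction = p$min_fraction,
                            max_intron_bp = p$max_intron_bp)
      rt <- excision_ratios(cl, state$junc_sim[[cond]])
      sq <- sqtl_scan(rt, geno, window_bp = p$window_bp, perms = p$perms,
                      seed = seed)
      res_all[[cond]] <- cluster_correction(sq, q = p$q)
    }
    state$sqtl_calls <- res_all
    for (cond in names(res_all))
      data.table::fwrite(res_all[[cond]],
                         file.path(cfg$out_dir, paste0("sqtl_", cond, ".tsv")),
                         sep = "\t")
    vapply(res_all, function(x) sum(x$significant), integer(1))
  })

  run_stage("coloc", 6L, function(seed) {
    set.seed(seed)
    p <- cfg$coloc
    geno <- if (!is.null(state$geno)) state$geno else as_geno(state$cohort)
    results <- list()
    for (g in unique(state$truth$gwas$gene[state$truth$gwas$shared_with_qtl])) {
      locus <- state$truth$gwas$locus[state$truth$gwas$gene == g]
      gw <- simulate_gwas_summary(state$cohort, state$truth, locus,
                                  state$config)
      cl <- rep(NA_real_, length(state$config$condition_names))
      names(cl) <- state$config$condition_names
      for (cond in state$config$condition_names) {
        qtl <- state$eqtl_records[[cond]]
        loci <- select_loci(gw, qtl[qtl$gene == g, ], geno$variant_meta,
                            gwas_p_max = p$gwas_p_max,
                            qtl_p_max = p$qtl_p_max,
                            window_bp = p$window_bp)
        if (!length(loci)) { cl[cond] <- 0; next }
        vars <- loci[[1]]$variants
        d <- geno$dosage[, vars, drop = FALSE]
        R <- ld_matrix(d)
        fc <- finemap_config(max_causal = p$max_causal)
        zq <- stats::qnorm(
          qtl$p_combined[qtl$gene == g][match(vars, qtl$variant[qtl$gene == g])] / 2,
          lower.tail = FALSE) * sign(qtl$beta[qtl$gene == g][
            match(vars, qtl$variant[qtl$gene == g])])
        zg <- gw$z[match(vars, gw$variant)]
        names(zq) <- names(zg) <- vars
        cl[cond] <- clpp(finemap_posteriors(zg, R, fc),
                         finemap_posteriors(zq, R, fc))
      }
      results[[g]] <- data.frame(gene = g, t(cl),
                                 label = classify_colocalization(
                                   cl, threshold = p$clpp_threshold),
                                 stringsAsFactors = FALSE)
    }
    out <- if (length(results)) do.call(rbind, results) else
      data.frame(gene = character(), label = character())
    data.table::fwrite(out, file.path(cfg$out_dir, "coloc.tsv"), sep = "\t")
    c(loci = nrow(out))
  })

  run_stage("specificity", 7L, function(seed) {
    mc <- state$eqtl_calls
    calls <- mc$gene_conditions
    calls$q_value <- calls$p_adj
    shared <- shared_egenes(calls, q = cfg$specificity$q_discovery)
    set.seed(seed)
    panel <- matrix(stats::runif(length(shared) * 5), ncol = 5,
                    dimnames = list(shared, paste0("ref_tissue_", 1:5)))
    selective <- tissue_selective_egenes(shared, panel,
                                         cfg$specificity$q_replication)
    writeLines(selective, file.path(cfg$out_dir, "selective_egenes.txt"))
    c(shared = length(shared), selective = length(selective))
  })

  run_stage("nmd", 8L, function(seed) {
    p <- cfg$nmd
    sol <- solve_isoform_model(nmd_inputs(p$k_hom, p$k_het, p$r))
    fr <- implied_fractions(sol)
    out <- c(n_c = sol$n_c, n_a = sol$n_a, p_m = sol$p_m, unlist(fr))
    jsonlite::write_json(as.list(out), file.path(cfg$out_dir, "nmd.json"),
                         auto_unbox = TRUE, digits = NA)
    c(solved = 1L)
  })

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
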