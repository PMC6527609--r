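#' Simulation configuration for a synthetic two-condition QTL cohort
#'
#' Bundles and validates all parameters of the synthetic-cohort generator.
#' Defaults emulate a small paired-design cohort: ~23 lines assayed under
#' two metabolic conditions ("glucose", "galactose") with shared genotypes
#' and independent expression noise.
#'
#' @param n_samples Number of individuals (default 23).
#' @param n_loci Number of independent loci; each locus hosts one gene.
#' @param variants_per_locus Variants simulated per locus.
#' @param maf_range Length-2 numeric in (0, 0.5]; per-variant MAF is drawn
#'   uniformly from this interval.
#' @param ld_copy_prob Probability that a haplotype copies the previous
#'   variant's allele at the next variant of the same locus (tunable LD).
#' @param n_conditions Number of expression conditions (default 2).
#' @param condition_names Labels for the conditions.
#' @param depth_mean,depth_dispersion Negative-binomial mean and dispersion
#'   (\code{size}) for per-gene total read counts.
#' @param ase_depth Expected read depth over the heterozygous transcribed
#'   SNP used for allele-specific counts.
#' @param ase_overdispersion If \code{TRUE}, allelic counts are drawn
#'   beta-binomial instead of binomial (default off).
#' @param gwas_n GWAS sample size used by \code{\link{simulate_gwas_summary}}.
#' @param seed Integer seed; all generators are pure functions of
#'   (config, seed).
#' @return An object of class \code{rpe_sim_config} (a validated list).
#' @export
sim_config <- function(n_samples = 23L, n_loci = 10L, variants_per_locus = 20L,
                       maf_range = c(0.1, 0.5), ld_copy_prob = 0.9,
                       n_conditions = 2L,
                       condition_names = c("glucose", "galactose"),
                       depth_mean = 500, depth_dispersion = 10,
                       ase_depth = 50, ase_overdispersion = FALSE,
                       gwas_n = 1e5, seed = 1L) {
  counts <- c(n_samples = n_samples, n_loci = n_loci,
              variants_per_locus = variants_per_locus,
              n_conditions = n_conditions)
  if (any(!is.finite(counts)) || any(counts < 1))
    stop("configuration error: all counts must be >= 1", call. = FALSE)
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("configuration error: maf_range must lie in (0, 0.5]", call. = FALSE)
  if (ld_copy_prob < 0 || ld_copy_prob > 1)
    stop("configuration error: ld_copy_prob must be in [0,1]", call. = FALSE)
  if (depth_mean <= 0 || depth_dispersion <= 0 || ase_depth <= 0 || gwas_n < 1)
    stop("configuration error: depth parameters must be positive", call. = FALSE)
  if (length(condition_names) != n_conditions)
    stop("configuration error: condition_names length != n_conditions",
         call. = FALSE)
  structure(list(
    n_samples = as.integer(n_samples), n_loci = as.integer(n_loci),
    variants_per_locus = as.integer(variants_per_locus),
    maf_range = as.numeric(maf_range), ld_copy_prob = ld_copy_prob,
    n_conditions = as.integer(n_conditions),
    condition_names = as.character(condition_names),
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    ase_depth = ase_depth, ase_overdispersion = isTRUE(ase_overdispersion),
    gwas_n = gwas_n, seed = as.integer(seed)
  ), class = "rpe_sim_config")
}

#' Simulate phased haplotypes for a synthetic cohort
#'
#' Haplotypes are generated per locus by a copying model: the first variant
#' of a locus draws its allele Bernoulli(MAF); every subsequent variant
#' copies the previous variant's allele on the same haplotype with
#' probability \code{ld_copy_prob}, otherwise draws fresh from its own MAF.
#' This yields LD that decays geometrically with variant distance.
#'
#' @param config An \code{\link{sim_config}} object.
#' @return An object of class \code{rpe_cohort}: list with \code{h1},
#'   \code{h2} (samples x variants 0/1 matrices, the two phased haplotypes),
#'   \code{variant_meta} (chrom, pos, ref, alt, imputation_quality, locus),
#'   \code{sample_meta} (id, sex, population_label) and \code{conditions}.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "rpe_sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  m_per <- config$variants_per_locus
  m <- config$n_loci * m_per
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  locus <- rep(seq_len(config$n_loci), each = m_per)

  draw_hap <- function() {
    h <- matrix(0L, n, m)
    for (j in seq_len(m)) {
      fresh <- stats::rbinom(n, 1L, maf[j])
      if (j > 1L && locus[j] == locus[j - 1L]) {
        copy <- stats::runif(n) < config$ld_copy_prob
        h[, j] <- ifelse(copy, h[, j - 1L], fresh)
      } else {
        h[, j] <- fresh
      }
    }
    h
  }
  h1 <- draw_hap()
  h2 <- draw_hap()

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  # loci spaced 1 Mb apart, variants every 1 kb; all on chr1
  pos <- (locus - 1L) * 1000000L + (seq_len(m) - (locus - 1L) * m_per) * 1000L
  variant_meta <- data.frame(
    variant = paste0("var_", seq_len(m)), chrom = "chr1", pos = pos,
    ref = ref, alt = alt,
    imputation_quality = round(stats::runif(m, 0.85, 1), 3),
    maf_target = maf, locus = locus, stringsAsFactors = FALSE
  )
  sample_meta <- data.frame(
    id = sprintf("sample_%02d", seq_len(n)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    population_label = sample(c("AFR", "EUR"), n, replace = TRUE,
                              prob = c(0.8, 0.2)),
    stringsAsFactors = FALSE
  )
  dimnames(h1) <- dimnames(h2) <- list(sample_meta$id, variant_meta$variant)
  structure(list(h1 = h1, h2 = h2, variant_meta = variant_meta,
                 sample_meta = sample_meta,
                 conditions = config$condition_names),
            class = "rpe_cohort")
}

#' Allele dosage matrix of a cohort
#'
#' @param cohort An \code{rpe_cohort}.
#' @return Integer matrix (samples x variants) of alternative-allele
#'   dosages in \{0,1,2\}.
#' @export
dosage <- function(cohort) {
  stopifnot(inherits(cohort, "rpe_cohort"))
  cohort$h1 + cohort$h2
}

#' Plant ground-truth genetic effects into a synthetic cohort
#'
#' Assigns one gene per locus (TSS at the locus midpoint) and draws, per
#' gene and condition, a causal variant, a log-scale effect size beta and
#' an allelic ratio pi (alternative/total among transcribed reads of
#' heterozygotes). A fraction of genes are null (beta = 0, pi = 0.5);
#' non-null genes are shared across conditions with probability
#' \code{prop_shared}, otherwise specific to one condition. One
#' exon-skipping intron cluster is planted per sQTL gene, and one GWAS
#' locus description per gene marked for colocalization testing.
#'
#' @param cohort An \code{rpe_cohort}.
#' @param config The \code{\link{sim_config}} used to build the cohort.
#' @param prop_causal Fraction of genes with a real eQTL.
#' @param prop_shared Among causal genes, fraction shared across conditions.
#' @param beta Effect size for causal genes (log2 scale per alt allele).
#' @param pi Allelic ratio for causal genes.
#' @param skip_effect Log-odds increase of exon skipping per alt allele at
#'   sQTL clusters (0 = null).
#' @param gwas_shared Logical; should GWAS loci share the QTL causal
#'   variant (else an independent variant in the locus is chosen)?
#' @param gwas_beta Standardized GWAS effect at the causal variant.
#' @return Object of class \code{rpe_truth} with elements \code{genes},
#'   \code{eqtl}, \code{sqtl}, \code{gwas}.
#' @export
simulate_truth <- function(cohort, config, prop_causal = 0.5,
                           prop_shared = 0.6, beta = 1.5, pi = 0.75,
                           skip_effect = log(3), gwas_shared = TRUE,
                           gwas_beta = 0.06) {
  stopifnot(inherits(cohort, "rpe_cohort"))
  set.seed(config$seed + 1000L)
  vm <- cohort$variant_meta
  loci <- sort(unique(vm$locus))
  genes <- data.frame(
    gene = paste0("gene_", loci), locus = loci, chrom = "chr1",
    tss = vapply(loci, function(l) as.integer(round(mean(vm$pos[vm$locus == l]))),
                 integer(1)),
    stringsAsFactors = FALSE
  )
  n_genes <- nrow(genes)
  causal <- stats::runif(n_genes) < prop_causal
  shared <- causal & stats::runif(n_genes) < prop_shared
  specific_cond <- sample(config$condition_names, n_genes, replace = TRUE)

  # pick the causal variant: the most central common variant of the locus
  pick_causal <- function(l) {
    cand <- vm[vm$locus == l, ]
    d <- dosage(cohort)[, cand$variant, drop = FALSE]
    f <- colMeans(d) / 2
    common <- cand$variant[f >= 0.15 & f <= 0.85]
    if (!length(common)) common <- cand$variant
    common[ceiling(length(common) / 2)]
  }
  causal_var <- vapply(genes$locus, pick_causal, character(1))

  eqtl <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    data.frame(
      gene = genes$gene[i],
      condition = config$condition_names,
      causal_variant = causal_var[i],
      beta = ifelse(causal[i] & (shared[i] |
               specific_cond[i] == config$condition_names), beta, 0),
      pi = ifelse(causal[i] & (shared[i] |
               specific_cond[i] == config$condition_names), pi, 0.5),
      stringsAsFactors = FALSE
    )
  }))
  sqtl <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
    data.frame(
      cluster = paste0("clu_", i), gene = genes$gene[i],
      condition = config$condition_names,
      causal_variant = causal_var[i],
      skip_effect = ifelse(causal[i] & (shared[i] |
               specific_cond[i] == config$condition_names), skip_effect, 0),
      baseline_skip = 0.05,
      stringsAsFactors = FALSE
    )
  }))
  gwas <- data.frame(
    locus = genes$locus, gene = genes$gene,
    causal_variant = ifelse(causal, causal_var, NA_character_),
    gwas_beta = ifelse(causal, gwas_beta, 0),
    shared_with_qtl = gwas_shared & causal,
    stringsAsFactors = FALSE
  )
  structure(list(genes = genes, eqtl = eqtl, sqtl = sqtl, gwas = gwas),
            class = "rpe_truth")
}

.check_truth <- function(cohort, truth) {
  if (!all(truth$eqtl$causal_variant %in% cohort$variant_meta$variant))
    stop("consistency error: truth references unknown variant", call. = FALSE)
  if (!all(truth$eqtl$gene %in% truth$genes$gene))
    stop("consistency error: truth references unknown gene", call. = FALSE)
  if (any(truth$eqtl$pi <= 0 | truth$eqtl$pi >= 1))
    stop("consistency error: pi must lie in (0,1)", call. = FALSE)
  invisible(TRUE)
}

#' Simulate gene-level and allele-specific expression counts
#'
#' For every condition, per-gene totals are drawn negative binomial with
#' log-mean shifted by \code{beta * dosage} at the gene's causal variant.
#' For samples heterozygous at the causal variant, allelic read counts are
#' drawn so the alternative-haplotype fraction has expectation pi;
#' homozygotes contribute no allelic rows. Conditions share genotypes but
#' use independent noise, mirroring a paired culture design.
#'
#' @param cohort An \code{rpe_cohort}.
#' @param truth An \code{rpe_truth} consistent with the cohort.
#' @param config The generating \code{\link{sim_config}}.
#' @return Named list per condition, each with \code{counts} (gene x sample
#'   integer matrix) and \code{ase} (data.table: gene, sample, variant,
#'   hap_ref_count, hap_alt_count).
#' @export
simulate_expression <- function(cohort, truth, config) {
  .check_truth(cohort, truth)
  set.seed(config$seed + 2000L)
  d <- dosage(cohort)
  n <- nrow(d)
  out <- list()
  for (cond in config$condition_names) {
    tr <- truth$eqtl[truth$eqtl$condition == cond, ]
    tr <- tr[match(truth$genes$gene, tr$gene), ]
    counts <- matrix(0L, nrow(truth$genes), n,
                     dimnames = list(truth$genes$gene, rownames(d)))
    ase <- vector("list", nrow(tr))
    for (i in seq_len(nrow(tr))) {
      g <- tr$causal_variant[i]
      dos <- d[, g]
      mu <- config$depth_mean * 2^(tr$beta[i] * dos)
      counts[i, ] <- stats::rnbinom(n, mu = mu, size = config$depth_dispersion)
      het <- which(dos == 1L)
      if (length(het)) {
        depth <- stats::rpois(length(het), config$ase_depth)
        p <- tr$pi[i]
        if (config$ase_overdispersion) {
          p <- stats::rbeta(length(het), p * 20, (1 - p) * 20)
        }
        alt <- stats::rbinom(length(het), depth, p)
        ase[[i]] <- data.table::data.table(
          gene = tr$gene[i], sample = rownames(d)[het], variant = g,
          hap_ref_count = depth - alt, hap_alt_count = alt)
      }
    }
    out[[cond]] <- list(counts = counts,
                        ase = data.table::rbindlist(ase))
  }
  out
}

#' Simulate splice-junction counts with planted exon-skipping sQTLs
#'
#' Each planted cluster has the canonical three-junction exon-skipping
#' topology: two inclusion junctions (exon2-3 and exon3-4) and one
#' skipping junction (exon2-4) that shares its donor site with the first
#' and its acceptor site with the second. The skipping fraction follows a
#' logistic dose model: \code{logit(f) = logit(baseline) + skip_effect *
#' dosage}, so \code{skip_effect = 0} is the exact null.
#'
#' @param cohort An \code{rpe_cohort}.
#' @param truth An \code{rpe_truth}.
#' @param config The generating \code{\link{sim_config}}.
#' @param cluster_depth Expected junction-spanning reads per cluster/sample.
#' @return Named list per condition of junction data.tables (chrom,
#'   intron_start, intron_end, strand, sample, count, cluster_hint),
#'   coordinates 1-based inclusive.
#' @export
simulate_junctions <- function(cohort, truth, config, cluster_depth = 200) {
  .check_truth(cohort, truth)
  set.seed(config$seed + 3000L)
  d <- dosage(cohort)
  vm <- cohort$variant_meta
  out <- list()
  for (cond in config$condition_names) {
    tr <- truth$sqtl[truth$sqtl$condition == cond, ]
    rows <- vector("list", nrow(tr) * 3L)
    k <- 0L
    for (i in seq_len(nrow(tr))) {
      dos <- d[, tr$causal_variant[i]]
      anchor <- truth$genes$tss[match(tr$gene[i], truth$genes$gene)]
      # exon2-3 intron [a1, a2], exon3-4 intron [b1, b2], skip [a1, b2]
      a1 <- anchor + 100L; a2 <- anchor + 2000L
      b1 <- anchor + 2200L; b2 <- anchor + 4000L
      f <- stats::plogis(stats::qlogis(tr$baseline_skip[i]) +
                           tr$skip_effect[i] * dos)
      total <- stats::rpois(length(dos), cluster_depth)
      skip <- stats::rbinom(length(dos), total, f)
      inc1 <- stats::rbinom(length(dos), total - skip, 0.5)
      inc2 <- total - skip - inc1
      samp <- rownames(d)
      rows[[k + 1L]] <- data.table::data.table(
        chrom = "chr1", intron_start = a1, intron_end = a2, strand = "+",
        sample = samp, count = inc1, cluster_hint = tr$cluster[i])
      rows[[k + 2L]] <- data.table::data.table(
        chrom = "chr1", intron_start = b1, intron_end = b2, strand = "+",
        sample = samp, count = inc2, cluster_hint = tr$cluster[i])
      rows[[k + 3L]] <- data.table::data.table(
        chrom = "chr1", intron_start = a1, intron_end = b2, strand = "+",
        sample = samp, count = skip, cluster_hint = tr$cluster[i])
      k <- k + 3L
    }
    out[[cond]] <- data.table::rbindlist(rows)
  }
  out
}

#' Simulate GWAS summary statistics at one locus
#'
#' Draws z-scores from the standard multivariate summary-statistic model:
#' \code{z ~ MVN(sqrt(n) * R lambda, R)} where R is the in-sample LD
#' (dosage correlation) of the locus and lambda the standardized causal
#' effects. When the truth marks the locus \code{shared_with_qtl}, the
#' GWAS causal variant coincides with the QTL causal variant.
#'
#' @param cohort An \code{rpe_cohort}.
#' @param truth An \code{rpe_truth}.
#' @param locus Locus id (integer as in \code{variant_meta$locus}).
#' @param config The generating \code{\link{sim_config}}.
#' @param causal_variant Optional override of the causal variant (or NA for
#'   a null locus).
#' @param gwas_beta Optional override of the standardized effect size.
#' @return data.table with variant, chrom, pos, ref, alt, beta, se, z, p, n.
#' @export
simulate_gwas_summary <- function(cohort, truth, locus, config,
                                  causal_variant = NULL, gwas_beta = NULL) {
  stopifnot(inherits(cohort, "rpe_cohort"))
  gw <- truth$gwas[truth$gwas$locus == locus, ]
  if (!nrow(gw)) stop("lookup error: unknown locus ", locus, call. = FALSE)
  vm <- cohort$variant_meta[cohort$variant_meta$locus == locus, ]
  d <- dosage(cohort)[, vm$variant, drop = FALSE]
  R <- ld_matrix(d)
  cv <- if (is.null(causal_variant)) gw$causal_variant[1] else causal_variant
  b <- if (is.null(gwas_beta)) gw$gwas_beta[1] else gwas_beta
  lambda <- numeric(nrow(vm))
  if (!is.na(cv) && b != 0) lambda[match(cv, vm$variant)] <- b
  mu <- sqrt(config$gwas_n) * as.vector(R %*% lambda)
  z <- mu + .rmvn_chol(1L, R)[1L, ]
  se <- 1 / sqrt(config$gwas_n)
  data.table::data.table(
    variant = vm$variant, chrom = vm$chrom, pos = vm$pos,
    ref = vm$ref, alt = vm$alt,
    beta = z * se, se = se, z = z,
    p = 2 * stats::pnorm(-abs(z)), n = config$gwas_n)
}

# LD (correlation) matrix from a dosage matrix; ridge keeps it PSD and
# invertible when variants are perfectly correlated or monomorphic.
#' Dosage correlation (LD) matrix
#'
#' @param d Samples x variants dosage matrix.
#' @param ridge Diagonal inflation added after zero-variance columns are
#'   mapped to zero correlation.
#' @return Symmetric positive-definite correlation matrix.
#' @export
ld_matrix <- function(d, ridge = 1e-3) {
  R <- suppressWarnings(stats::cor(d))
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  R <- (1 - ridge) * R
  diag(R) <- 1
  R
}

# MVN(0, S) sampler via Cholesky (S must be PD).
.rmvn_chol <- function(n, S) {
  L <- chol(S)
  matrix(stats::rnorm(n * ncol(S)), n) %*% L
}

#' Simulate a multi-tissue median-expression panel with planted
#' tissue-selective genes
#'
#' Background genes are exchangeable across tissues (log-normal noise
#' around a gene-specific baseline). For each planted (tissue, gene) pair
#' the focal tissue's median is raised by root-finding so that the
#' realized selectivity z-score (recomputed with the planted value
#' included in the mean and standard deviation) equals \code{z_target}.
#'
#' @param n_tissues,n_genes Panel dimensions.
#' @param selective_sets Named list tissue -> character vector of genes to
#'   plant; sets must be disjoint across tissues.
#' @param z_target Realized selectivity z for planted genes; must be > 0
#'   and below the attainable maximum (n-1)/sqrt(n).
#' @param seed Integer seed.
#' @return Object of class \code{rpe_tissue_panel}: list with
#'   \code{expr} (gene x tissue nonnegative matrix of medians) and
#'   \code{gene_meta} (gene, chrom, start, end, gene_type).
#' @export
simulate_tissue_panel <- function(n_tissues = 53L, n_genes = 500L,
                                  selective_sets = list(), z_target = 5,
                                  seed = 1L) {
  if (z_target <= 0)
    stop("configuration error: z_target must be > 0", call. = FALSE)
  if (z_target >= (n_tissues - 1) / sqrt(n_tissues))
    stop("configuration error: z_target unattainable with ", n_tissues,
         " tissues (max ", round((n_tissues - 1) / sqrt(n_tissues), 2), ")",
         call. = FALSE)
  planted_genes <- unlist(selective_sets, use.names = FALSE)
  if (anyDuplicated(planted_genes))
    stop("configuration error: selective sets must be disjoint", call. = FALSE)
  set.seed(seed)
  tissues <- c(names(selective_sets),
               setdiff(sprintf("tissue_%02d", seq_len(n_tissues)),
                       names(selective_sets)))[seq_len(n_tissues)]
  genes <- sprintf("panelgene_%04d", seq_len(n_genes))
  if (!all(planted_genes %in% genes))
    genes <- union(genes, planted_genes)
  baseline <- stats::rlnorm(length(genes), meanlog = 2, sdlog = 1)
  expr <- matrix(stats::rlnorm(length(genes) * n_tissues,
                               meanlog = log(baseline), sdlog = 0.3),
                 nrow = length(genes), dimnames = list(genes, tissues))
  for (tis in names(selective_sets)) {
    for (g in selective_sets[[tis]]) {
      others <- expr[g, setdiff(tissues, tis)]
      zfun <- function(x) {
        v <- c(x, others)
        (x - mean(v)) / stats::sd(v) - z_target
      }
      hi <- max(others) + 1
      while (zfun(hi) < 0) hi <- hi * 4
      expr[g, tis] <- stats::uniroot(zfun, c(max(others), hi),
                                     tol = 1e-10)$root
    }
  }
  gene_meta <- data.frame(
    gene = genes, chrom = "chr2",
    start = seq_along(genes) * 10000L,
    end = seq_along(genes) * 10000L + 5000L,
    gene_type = "protein_coding", stringsAsFactors = FALSE
  )
  structure(list(expr = expr, gene_meta = gene_meta),
            class = "rpe_tissue_panel")
}
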