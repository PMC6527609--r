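#' Expression matrix with normalization and TSS annotation
#'
#' Wraps a gene x sample count matrix together with median-of-ratios size
#' factors and a log2-normalized matrix, log2(count / size_factor + 1).
#' A rank-based inverse-normal transform is available behind a flag.
#'
#' @param counts Nonnegative integer gene x sample matrix.
#' @param tss data.frame (gene, chrom, tss) covering the rows of counts.
#' @param rank_normal If TRUE, replace each gene's normalized values by
#'   inverse-normal-transformed ranks (default off).
#' @return Object of class \code{rpe_expr}: counts, norm, size_factors, tss.
#' @export
expression_matrix <- function(counts, tss, rank_normal = FALSE) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  if (!all(rownames(counts) %in% tss$gene))
    stop("tss annotation missing for some genes", call. = FALSE)
  # median-of-ratios size factors (genes with a positive geometric mean)
  logc <- log(counts)
  ok <- is.finite(rowMeans(logc))
  if (sum(ok) >= 1L) {
    loggeo <- rowMeans(logc[ok, , drop = FALSE])
    sf <- apply(logc[ok, , drop = FALSE], 2,
                function(x) exp(stats::median(x - loggeo)))
  } else {
    sf <- colSums(counts) / mean(colSums(counts))
  }
  if (any(sf <= 0)) stop("nonpositive size factor", call. = FALSE)
  norm <- log2(sweep(counts, 2, sf, "/") + 1)
  if (rank_normal) {
    norm <- t(apply(norm, 1, function(x)
      stats::qnorm((rank(x) - 0.5) / length(x))))
    colnames(norm) <- colnames(counts)
  }
  structure(list(counts = counts, norm = norm, size_factors = sf,
                 tss = tss[match(rownames(counts), tss$gene), ]),
            class = "rpe_expr")
}

# Residualize columns of M against the column space of X (QR-based
# Frisch-Waugh projection; exact for OLS coefficient and its t-statistic).
.residualize <- function(M, qrX) {
  M - qr.fitted(qrX, M)
}

#' Allele-aware cis-eQTL scan for one condition
#'
#' For every gene and every variant whose position is within
#' \code{window_bp} of the gene's TSS, three association signals are
#' computed: \itemize{
#'   \item \code{p_total}: two-sided t-test on the dosage coefficient of an
#'     OLS fit of normalized expression on dosage plus covariates;
#'   \item \code{p_ase}: exact two-sided binomial test of aggregated
#'     alternative-haplotype read counts versus 0.5 over samples
#'     heterozygous at the tested variant (requires >= \code{min_het}
#'     heterozygotes and >= \code{min_ase_depth} total reads);
#'   \item \code{p_combined}: Fisher's combination of the two when both
#'     exist, otherwise the available one.
#' }
#' The allelic ratio pi is estimated with +1/+1 pseudocounts:
#' pi = (alt + 1) / (alt + ref + 2).
#'
#' @param expr An \code{rpe_expr}.
#' @param geno An \code{rpe_geno}; samples must match expr columns.
#' @param ase data.table/data.frame (gene, sample, variant, hap_ref_count,
#'   hap_alt_count) or NULL to skip allelic testing.
#' @param covariates Optional samples x k numeric matrix (no intercept
#'   column; one is added). Must be full rank.
#' @param window_bp Cis window around the TSS (default 500 kb).
#' @param condition Condition label stamped on the records.
#' @param min_het,min_ase_depth Gates for the allelic test (2 and 10).
#' @return data.frame of class \code{rpe_assoc}: gene, variant, condition,
#'   beta, se, p_total, p_ase, p_combined, pi, n_het, tss_dist.
#' @export
cis_scan <- function(expr, geno, ase = NULL, covariates = NULL,
                     window_bp = 500000L, condition = "condition1",
                     min_het = 2L, min_ase_depth = 10L) {
  stopifnot(inherits(expr, "rpe_expr"), inherits(geno, "rpe_geno"))
  samples <- colnames(expr$norm)
  if (!all(samples %in% rownames(geno$dosage)))
    stop("expression samples missing from genotype table", call. = FALSE)
  D <- geno$dosage[samples, , drop = FALSE]
  n <- length(samples)
  X <- cbind(intercept = rep(1, n), covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient covariate matrix", call. = FALSE)
  df <- n - ncol(X) - 1L
  if (df < 1L) stop("not enough residual degrees of freedom", call. = FALSE)

  Gres <- .residualize(D, qrX)
  Yres <- .residualize(t(expr$norm), qrX)  # samples x genes
  gss <- colSums(Gres^2)

  if (!is.null(ase)) {
    ase <- data.table::as.data.table(ase)
    asek <- ase[, list(alt = sum(hap_alt_count), ref = sum(hap_ref_count),
                       n_het = .N), by = c("gene", "variant")]
  }

  vm <- geno$variant_meta
  out <- vector("list", nrow(expr$tss))
  for (i in seq_len(nrow(expr$tss))) {
    g <- expr$tss$gene[i]
    hit <- which(vm$chrom == expr$tss$chrom[i] &
                   abs(vm$pos - expr$tss$tss[i]) <= window_bp &
                   gss > 1e-12)
    if (!length(hit)) next
    y <- Yres[, i]
    yss <- sum(y^2)
    bet <- colSums(Gres[, hit, drop = FALSE] * y) / gss[hit]
    rss <- pmax(yss - bet^2 * gss[hit], 0)
    se <- sqrt(rss / df / gss[hit])
    tstat <- bet / se
    p_total <- 2 * stats::pt(-abs(tstat), df)
    p_total <- pmin(pmax(p_total, .Machine$double.xmin), 1)

    p_ase <- rep(NA_real_, length(hit))
    pi_hat <- rep(NA_real_, length(hit))
    n_het <- rep(0L, length(hit))
    if (!is.null(ase)) {
      ga <- asek[asek$gene == g & asek$variant %in% vm$variant[hit], ]
      if (nrow(ga)) {
        j <- match(ga$variant, vm$variant[hit])
        n_het[j] <- ga$n_het
        pi_hat[j] <- (ga$alt + 1) / (ga$alt + ga$ref + 2)
        test_ok <- ga$n_het >= min_het & (ga$alt + ga$ref) >= min_ase_depth
        if (any(test_ok)) {
          p_ase[j[test_ok]] <- mapply(function(a, tot)
            stats::binom.test(a, tot, 0.5)$p.value,
            ga$alt[test_ok], ga$alt[test_ok] + ga$ref[test_ok])
        }
      }
    }
    p_comb <- ifelse(
      is.na(p_ase), p_total,
      stats::pchisq(-2 * (log(p_total) + log(p_ase)), df = 4,
                    lower.tail = FALSE))
    p_comb <- pmin(pmax(p_comb, .Machine$double.xmin), 1)
    out[[i]] <- data.frame(
      gene = g, variant = vm$variant[hit], condition = condition,
      beta = bet, se = se, p_total = p_total, p_ase = p_ase,
      p_combined = p_comb, pi = pi_hat, n_het = n_het,
      tss_dist = vm$pos[hit] - expr$tss$tss[i],
      stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene = character(), variant = character(),
                      condition = character(), beta = numeric(),
                      se = numeric(), p_total = numeric(),
                      p_ase = numeric(), p_combined = numeric(),
                      pi = numeric(), n_het = integer(),
                      tss_dist = integer(), stringsAsFactors = FALSE)
  class(res) <- c("rpe_assoc", "data.frame")
  res
}

#' Simes combination of a vector of p-values
#'
#' min over k of m * p_(k) / k; the gene-level p-value used throughout the
#' hierarchical procedures.
#'
#' @param p Numeric vector of p-values.
#' @return Single combined p-value.
#' @export
simes_p <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) return(NA_real_)
  m <- length(p)
  min(1, min(m * sort(p) / seq_len(m)))
}

#' Hierarchical (two-level) FDR for a single condition
#'
#' Gene-level p-values via Simes over each gene's cis variants; BH across
#' genes at \code{q_gene}; within each selected gene, BH across its
#' associations at the propagated level q_assoc * R / m (R = selected
#' genes, m = genes tested), following the Benjamini-Bogomolov rule.
#'
#' @param records An \code{rpe_assoc} table with p_combined.
#' @param q_gene,q_assoc FDR levels (default 0.05 each).
#' @return List of class \code{rpe_callset}: \code{egenes} (gene, p_simes,
#'   q_value, selected), \code{eassociations} (selected records with
#'   adjusted p), \code{level_assoc} (the propagated association level).
#' @export
hierarchical_fdr <- function(records, q_gene = 0.05, q_assoc = 0.05) {
  if (!nrow(records)) {
    return(structure(list(
      egenes = data.frame(gene = character(), p_simes = numeric(),
                          q_value = numeric(), selected = logical()),
      eassociations = records, level_assoc = NA_real_),
      class = "rpe_callset"))
  }
  psim <- tapply(records$p_combined, records$gene, simes_p)
  genes <- names(psim)
  qv <- stats::p.adjust(psim, method = "BH")
  sel <- qv <= q_gene
  R <- sum(sel); m <- length(genes)
  level <- q_assoc * R / m
  keep <- list()
  for (g in genes[sel]) {
    rg <- records[records$gene == g, , drop = FALSE]
    adj <- stats::p.adjust(rg$p_combined, method = "BH")
    rg$p_adj_assoc <- adj
    keep[[g]] <- rg[adj <= level, , drop = FALSE]
  }
  eassoc <- if (length(keep)) do.call(rbind, keep) else
    cbind(records[0, ], p_adj_assoc = numeric())
  rownames(eassoc) <- NULL
  structure(list(
    egenes = data.frame(gene = genes, p_simes = as.numeric(psim),
                        q_value = as.numeric(qv), selected = as.logical(sel),
                        row.names = NULL, stringsAsFactors = FALSE),
    eassociations = eassoc, level_assoc = level),
    class = "rpe_callset")
}

#' Multi-condition hierarchical FDR with shared/specific labels
#'
#' Three-level tree: gene -> condition -> (gene, condition, variant).
#' Level 1: Simes over all of a gene's (condition, variant) p-values, BH
#' across genes at q. Level 2: per selected gene, Simes per condition, BH
#' at q * R1 / m1. Level 3: per selected gene-condition, BH across
#' variants at q * R2 / m2 (R2 = selected gene-conditions, m2 =
#' gene-conditions tested under selected genes). A selected gene is
#' labeled "shared" iff selected in every condition, else
#' "<condition>-specific".
#'
#' @param records_by_condition Named list of \code{rpe_assoc} tables.
#' @param q FDR level for all three tree levels (default 0.05).
#' @return List of class \code{rpe_callset_mc}: \code{genes} (gene,
#'   p_simes, q_value, selected, label), \code{gene_conditions},
#'   \code{eassociations}.
#' @export
multi_condition_fdr <- function(records_by_condition, q = 0.05) {
  conds <- names(records_by_condition)
  if (length(conds) < 2L) {
    warning("single condition supplied; delegating to hierarchical_fdr")
    return(hierarchical_fdr(records_by_condition[[1]], q, q))
  }
  all_rec <- do.call(rbind, lapply(conds, function(cn) {
    r <- records_by_condition[[cn]]
    r$condition <- cn
    r
  }))
  # level 1: genes
  psim <- tapply(all_rec$p_combined, all_rec$gene, simes_p)
  genes <- names(psim)
  qv <- stats::p.adjust(psim, method = "BH")
  sel1 <- qv <= q
  R1 <- sum(sel1); m1 <- length(genes)
  level2 <- q * R1 / m1

  gc_rows <- list(); assoc_rows <- list()
  gc_all <- list()
  for (g in genes[sel1]) {
    rg <- all_rec[all_rec$gene == g, , drop = FALSE]
    pc <- vapply(split(rg$p_combined, rg$condition), simes_p, numeric(1))
    gc_all[[g]] <- data.frame(gene = g, condition = names(pc),
                              p_simes = as.numeric(pc),
                              stringsAsFactors = FALSE)
  }
  gc_tab <- do.call(rbind, gc_all)
  if (!is.null(gc_tab) && nrow(gc_tab)) {
    gc_tab$p_adj <- NA_real_
    gc_tab$selected <- FALSE
    for (g in unique(gc_tab$gene)) {
      i <- gc_tab$gene == g
      adj <- stats::p.adjust(gc_tab$p_simes[i], method = "BH")
      gc_tab$p_adj[i] <- adj
      gc_tab$selected[i] <- adj <= level2
    }
    R2 <- sum(gc_tab$selected); m2 <- nrow(gc_tab)
    level3 <- q * R2 / m2
    selgc <- gc_tab[gc_tab$selected, , drop = FALSE]
    for (i in seq_len(nrow(selgc))) {
      rg <- all_rec[all_rec$gene == selgc$gene[i] &
                      all_rec$condition == selgc$condition[i], , drop = FALSE]
      adj <- stats::p.adjust(rg$p_combined, method = "BH")
      rg$p_adj_assoc <- adj
      assoc_rows[[length(assoc_rows) + 1L]] <- rg[adj <= level3, , drop = FALSE]
    }
  } else {
    gc_tab <- data.frame(gene = character(), condition = character(),
                         p_simes = numeric(), p_adj = numeric(),
                         selected = logical(), stringsAsFactors = FALSE)
    level3 <- NA_real_
  }
  eassoc <- if (length(assoc_rows)) do.call(rbind, assoc_rows) else
    cbind(all_rec[0, ], p_adj_assoc = numeric())
  rownames(eassoc) <- NULL

  label <- rep(NA_character_, length(genes))
  for (i in which(sel1)) {
    g <- genes[i]
    sc <- gc_tab$condition[gc_tab$gene == g & gc_tab$selected]
    label[i] <- if (length(sc) == 0L) "none"
      else if (all(conds %in% sc)) "shared"
      else paste0(paste(sort(sc), collapse = "+"), "-specific")
  }
  structure(list(
    genes = data.frame(gene = genes, p_simes = as.numeric(psim),
                       q_value = as.numeric(qv), selected = as.logical(sel1),
                       label = label, row.names = NULL,
                       stringsAsFactors = FALSE),
    gene_conditions = gc_tab, eassociations = eassoc,
    levels = c(gene = q, condition = level2, association = level3)),
    class = "rpe_callset_mc")
}

#' Change in allelic imbalance across two conditions
#'
#' delta |pi - 0.5| = | |pi_a - 0.5| - |pi_b - 0.5| |, the cross-condition
#' change in eQTL effect size used to rank condition-specific eQTLs.
#'
#' @param pi_a,pi_b Allelic ratios of the same gene/variant in two
#'   conditions (vectors allowed). NA where either is missing.
#' @return Numeric vector of delta imbalance values.
#' @export
delta_imbalance <- function(pi_a, pi_b) {
  abs(abs(pi_a - 0.5) - abs(pi_b - 0.5))
}

#' Empirical covariate selection by maximizing eQTL discoveries
#'
#' Evaluates nested covariate sets (candidates added in the given order)
#' on a seeded random subset of probe genes, scoring each set by the
#' number of significant associations after \code{\link{cis_scan}} +
#' \code{\link{hierarchical_fdr}}. Returns the set with the most
#' discoveries; ties break to the smaller set. Candidates collinear with
#' the previously accepted ones are dropped with a warning.
#'
#' @param expr An \code{rpe_expr}.
#' @param geno An \code{rpe_geno}.
#' @param candidate_covariates Named list of numeric sample-length vectors
#'   (or single-column matrices), in addition order.
#' @param ase Optional allelic count table passed to cis_scan.
#' @param probe_genes Number of probe genes (default 50, capped at the
#'   gene count).
#' @param seed Seed for the probe-gene subset.
#' @param window_bp,q_gene,q_assoc Passed through to the scan/FDR.
#' @return List: \code{chosen} (names of selected candidates),
#'   \code{counts} (discoveries per nested set), \code{probe_genes}.
#' @export
select_covariates <- function(expr, geno, candidate_covariates, ase = NULL,
                              probe_genes = 50L, seed = 1L,
                              window_bp = 500000L,
                              q_gene = 0.05, q_assoc = 0.05) {
  stopifnot(inherits(expr, "rpe_expr"))
  set.seed(seed)
  ng <- nrow(expr$counts)
  probe <- sort(sample(ng, min(probe_genes, ng)))
  sub <- expression_matrix(expr$counts[probe, , drop = FALSE], expr$tss)
  n <- ncol(expr$counts)

  accepted <- list()
  for (nm in names(candidate_covariates)) {
    v <- as.numeric(candidate_covariates[[nm]])
    Xtest <- cbind(1, do.call(cbind, accepted), v)
    if (qr(Xtest)$rank < ncol(Xtest)) {
      warning("candidate '", nm, "' collinear with previous covariates; dropped")
      next
    }
    accepted[[nm]] <- v
  }

  sets <- c(list(character(0)),
            lapply(seq_along(accepted), function(k) names(accepted)[seq_len(k)]))
  counts <- integer(length(sets))
  for (i in seq_along(sets)) {
    cv <- if (length(sets[[i]]))
      do.call(cbind, accepted[sets[[i]]]) else NULL
    rec <- cis_scan(sub, geno, ase = ase, covariates = cv,
                    window_bp = window_bp)
    cs <- hierarchical_fdr(rec, q_gene, q_assoc)
    counts[i] <- nrow(cs$eassociations)
  }
  best <- which(counts == max(counts))[1]  # ties -> smaller (earlier) set
  list(chosen = sets[[best]], counts = counts, probe_genes = probe)
}

#' Build motif-scan target and background sequences around lead eQTL SNPs
#'
#' For each lead record, extracts the reference sequence \code{flank}
#' bases either side of the variant (length 2*flank+1) and substitutes
#' the center base: the target sequence carries the expression-increasing
#' allele (alt if beta > 0, else ref) and the background the
#' expression-decreasing allele. Variants too close to a contig edge are
#' skipped with a warning.
#'
#' @param lead_records \code{rpe_assoc} rows (one per lead SNP) with beta.
#' @param reference Named character vector/list: contig name -> sequence.
#' @param variant_meta data.frame (variant, chrom, pos, ref, alt).
#' @param flank Flank size in bp (default 15).
#' @return List with \code{target} and \code{background}, named character
#'   vectors of sequences.
#' @export
build_motif_inputs <- function(lead_records, reference, variant_meta,
                               flank = 15L) {
  tgt <- bg <- character(0)
  for (i in seq_len(nrow(lead_records))) {
    v <- lead_records$variant[i]
    vm <- variant_meta[variant_meta$variant == v, ]
    if (!nrow(vm)) stop("variant not annotated: ", v, call. = FALSE)
    chromseq <- reference[[vm$chrom]]
    if (is.null(chromseq)) stop("no reference for ", vm$chrom, call. = FALSE)
    if (vm$pos - flank < 1L || vm$pos + flank > nchar(chromseq)) {
      warning("variant ", v, " within ", flank, " bp of contig edge; skipped")
      next
    }
    s <- substr(chromseq, vm$pos - flank, vm$pos + flank)
    up_allele <- if (lead_records$beta[i] > 0) vm$alt else vm$ref
    dn_allele <- if (lead_records$beta[i] > 0) vm$ref else vm$alt
    mid <- flank + 1L
    tgt[v] <- paste0(substr(s, 1, mid - 1), up_allele,
                     substr(s, mid + 1, nchar(s)))
    bg[v] <- paste0(substr(s, 1, mid - 1), dn_allele,
                    substr(s, mid + 1, nchar(s)))
  }
  list(target = tgt, background = bg)
}
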