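#' Tissue-selectivity z-scores from a multi-tissue median-expression panel
#'
#' For each gene, the per-tissue median expression x is standardized
#' against the mean and sample (n-1) standard deviation of that gene's
#' medians across all tissues (the focal tissue included):
#' z = (x - mu) / sigma. Genes that are flat across tissues (sigma = 0)
#' get NA z-scores and are excluded from downstream calling.
#'
#' @param panel An \code{rpe_tissue_panel} (see
#'   \code{\link{simulate_tissue_panel}}) or a nonnegative gene x tissue
#'   matrix of median expression.
#' @return data.frame of class \code{rpe_selectivity}: gene, tissue, x,
#'   mu, sigma, z (long format, one row per gene x tissue).
#' @export
selectivity_zscores <- function(panel) {
  expr <- if (inherits(panel, "rpe_tissue_panel")) panel$expr else panel
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 3L) stop("need >= 3 tissues", call. = FALSE)
  if (any(expr < 0)) stop("expression must be nonnegative", call. = FALSE)
  mu <- rowMeans(expr)
  sigma <- apply(expr, 1, stats::sd)
  z <- (expr - mu) / sigma  # sigma == 0 -> NaN, normalized to NA below
  z[sigma == 0, ] <- NA_real_
  out <- data.frame(
    gene = rep(rownames(expr), times = ncol(expr)),
    tissue = rep(colnames(expr), each = nrow(expr)),
    x = as.vector(expr), mu = rep(mu, times = ncol(expr)),
    sigma = rep(sigma, times = ncol(expr)), z = as.vector(z),
    stringsAsFactors = FALSE
  )
  class(out) <- c("rpe_selectivity", "data.frame")
  out
}

# Default extended-MHC interval used for the low-mappability HLA filter
# (hg19 coordinates; configurable in call_selective).
.default_hla <- list(chrom = "chr6", start = 28477797L, end = 33448354L)

#' Call tissue-selective genes
#'
#' Genes with z strictly greater than \code{z_threshold} in the target
#' tissue, after removing genes on sex chromosomes and the mitochondrial
#' chromosome, and genes inside the (low-mappability) HLA region. Genes
#' with undefined z (flat across tissues) are never called.
#'
#' @param scores An \code{rpe_selectivity} table.
#' @param tissue Target tissue name.
#' @param z_threshold Strict threshold (default 4).
#' @param gene_meta Optional data.frame (gene, chrom, start, end) used for
#'   the chromosome/region filters; genes absent from it are kept.
#' @param exclude_chroms Chromosomes removed before calling.
#' @param hla Named list (chrom, start, end) of the HLA interval, or NULL
#'   to disable.
#' @return Character vector of selective genes.
#' @export
call_selective <- function(scores, tissue, z_threshold = 4,
                           gene_meta = NULL,
                           exclude_chroms = c("chrX", "chrY", "chrM"),
                           hla = .default_hla) {
  stopifnot(inherits(scores, "rpe_selectivity"))
  if (!tissue %in% scores$tissue)
    stop("unknown tissue: ", tissue, call. = FALSE)
  s <- scores[scores$tissue == tissue & !is.na(scores$z), ]
  genes <- s$gene[s$z > z_threshold]
  if (!is.null(gene_meta)) {
    gm <- gene_meta[match(genes, gene_meta$gene), ]
    drop <- !is.na(gm$chrom) & gm$chrom %in% exclude_chroms
    if (!is.null(hla)) {
      in_hla <- !is.na(gm$chrom) & gm$chrom == hla$chrom &
        gm$end >= hla$start & gm$start <= hla$end
      drop <- drop | in_hla
    }
    genes <- genes[!drop]
  }
  genes
}

#' Observed-versus-expected z QQ pairing for one tissue
#'
#' Genes are ranked within each tissue by z; the expected z at rank k is
#' the mean over tissues of each tissue's k-th order statistic. A tissue
#' whose curve departs from the diagonal carries a systematically
#' different z distribution (e.g. inflation from batch effects).
#'
#' @param scores An \code{rpe_selectivity} table covering all tissues.
#' @param tissue Focal tissue.
#' @return data.frame (rank, observed, expected), observed sorted
#'   increasing; expected is non-decreasing by construction.
#' @export
expected_z_qq <- function(scores, tissue) {
  stopifnot(inherits(scores, "rpe_selectivity"))
  if (!tissue %in% scores$tissue)
    stop("unknown tissue: ", tissue, call. = FALSE)
  ok <- !is.na(scores$z)
  s <- scores[ok, ]
  tabs <- split(s$z, s$tissue)
  n <- lengths(tabs)
  if (length(unique(n)) != 1L)
    stop("unequal gene sets across tissues", call. = FALSE)
  sorted <- vapply(tabs, sort, numeric(n[[1]]))
  expected <- rowMeans(sorted)
  data.frame(rank = seq_len(n[[1]]),
             observed = sorted[, tissue],
             expected = expected)
}

#' Compare selectivity of a gene set against a background
#'
#' Welch two-sided t-test on the z-scores of a gene set versus a disjoint
#' background set within the target tissue — e.g. testing whether ocular
#' disease genes are more selective to RPE than other protein-coding genes.
#'
#' @param scores An \code{rpe_selectivity} table.
#' @param tissue Target tissue.
#' @param gene_set,background Disjoint character vectors of gene ids with
#'   >= 2 scored genes each.
#' @return List: mean_difference (set minus background), t_statistic,
#'   p_value, n_set, n_background.
#' @export
gene_set_specificity <- function(scores, tissue, gene_set, background) {
  stopifnot(inherits(scores, "rpe_selectivity"))
  if (length(intersect(gene_set, background)))
    stop("gene_set and background overlap", call. = FALSE)
  s <- scores[scores$tissue == tissue & !is.na(scores$z), ]
  za <- s$z[s$gene %in% gene_set]
  zb <- s$z[s$gene %in% background]
  if (length(za) < 2L || length(zb) < 2L)
    stop("need >= 2 scored genes in both groups", call. = FALSE)
  if (stats::sd(za) == 0 && stats::sd(zb) == 0 && mean(za) == mean(zb))
    return(list(mean_difference = 0, t_statistic = 0, p_value = 1,
                n_set = length(za), n_background = length(zb)))
  tt <- stats::t.test(za, zb, alternative = "two.sided", var.equal = FALSE)
  list(mean_difference = mean(za) - mean(zb),
       t_statistic = unname(tt$statistic), p_value = tt$p.value,
       n_set = length(za), n_background = length(zb))
}
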