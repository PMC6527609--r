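#' Genotype table container
#'
#' Normalized in-memory representation of a (possibly phased) genotype
#' call set: an NA-tolerant dosage matrix plus per-variant metadata.
#' Built by \code{\link{read_vcf}} or from a synthetic cohort.
#'
#' @param dosage Samples x variants matrix of alt-allele dosages (0/1/2,
#'   NA = missing).
#' @param variant_meta data.frame with at least chrom, pos, ref, alt;
#'   optional imputation_quality and n_alleles.
#' @param h1,h2 Optional phased haplotype matrices (samples x variants).
#' @return Object of class \code{rpe_geno}.
#' @export
geno_table <- function(dosage, variant_meta, h1 = NULL, h2 = NULL) {
  stopifnot(is.matrix(dosage), nrow(variant_meta) == ncol(dosage))
  if (is.null(variant_meta$n_alleles)) variant_meta$n_alleles <- 2L
  structure(list(dosage = dosage, variant_meta = variant_meta,
                 h1 = h1, h2 = h2), class = "rpe_geno")
}

#' @rdname geno_table
#' @param cohort An \code{rpe_cohort}.
#' @export
as_geno <- function(cohort) {
  stopifnot(inherits(cohort, "rpe_cohort"))
  geno_table(dosage(cohort), cohort$variant_meta,
             h1 = cohort$h1, h2 = cohort$h2)
}

#' Variant-level quality filters
#'
#' Removes variants that (i) are missing in more than \code{max_missing}
#' of samples (strict >, so exactly-at-threshold sites are retained),
#' (ii) have imputation allelic r-squared below \code{min_imputation_r2}
#' (sites at exactly the threshold are retained), or (iii) are not
#' biallelic. Filters are applied independently; the report counts each.
#'
#' @param geno An \code{rpe_geno}.
#' @param max_missing Maximum tolerated missingness fraction (default 0.05).
#' @param min_imputation_r2 Minimum imputation quality (default 0.8); set
#'   to NULL to disable. An enabled filter with no imputation_quality
#'   column is an error.
#' @param biallelic_only Drop multi-allelic sites (default TRUE).
#' @return List with \code{geno} (filtered table) and \code{report}
#'   (class \code{rpe_variant_qc}): per-variant flags and removal counts.
#' @export
filter_variants <- function(geno, max_missing = 0.05,
                            min_imputation_r2 = 0.8,
                            biallelic_only = TRUE) {
  stopifnot(inherits(geno, "rpe_geno"))
  vm <- geno$variant_meta
  miss <- colMeans(is.na(geno$dosage))
  fail_miss <- miss > max_missing
  if (!is.null(min_imputation_r2)) {
    if (is.null(vm$imputation_quality))
      stop("imputation-quality filter enabled but no 'imputation_quality' ",
           "(AR2) field present", call. = FALSE)
    fail_ar2 <- vm$imputation_quality < min_imputation_r2
  } else fail_ar2 <- rep(FALSE, nrow(vm))
  fail_multi <- if (biallelic_only) vm$n_alleles > 2L else rep(FALSE, nrow(vm))
  keep <- !(fail_miss | fail_ar2 | fail_multi)

  report <- structure(list(
    per_variant = data.frame(variant = if (!is.null(vm$variant)) vm$variant
                             else seq_len(nrow(vm)),
                             missingness = miss,
                             biallelic = vm$n_alleles == 2L,
                             imputation_quality =
                               if (!is.null(vm$imputation_quality))
                                 vm$imputation_quality else NA_real_,
                             pass = keep),
    removed = c(missingness = sum(fail_miss), imputation = sum(fail_ar2),
                multiallelic = sum(fail_multi), total = sum(!keep))
  ), class = "rpe_variant_qc")

  filtered <- geno_table(geno$dosage[, keep, drop = FALSE],
                         vm[keep, , drop = FALSE],
                         h1 = if (!is.null(geno$h1)) geno$h1[, keep, drop = FALSE],
                         h2 = if (!is.null(geno$h2)) geno$h2[, keep, drop = FALSE])
  list(geno = filtered, report = report)
}

#' Transition/transversion ratio per chromosome
#'
#' Transitions are A<->G and C<->T; everything else among single-base
#' substitutions is a transversion. A group with zero transversions
#' yields +Inf with a warning rather than an error.
#'
#' @param geno An \code{rpe_geno} restricted to SNVs.
#' @param by Grouping: "chromosome" (default) or "all".
#' @return Named numeric vector of Ts/Tv ratios.
#' @export
tstv_ratio <- function(geno, by = c("chromosome", "all")) {
  by <- match.arg(by)
  vm <- geno$variant_meta
  snv <- nchar(vm$ref) == 1L & nchar(vm$alt) == 1L
  vm <- vm[snv, , drop = FALSE]
  pair <- paste(pmin(vm$ref, vm$alt), pmax(vm$ref, vm$alt))
  is_ts <- pair %in% c("A G", "C T")
  grp <- if (by == "chromosome") vm$chrom else rep("all", nrow(vm))
  ts <- tapply(is_ts, grp, sum)
  tv <- tapply(!is_ts, grp, sum)
  if (any(tv == 0))
    warning("zero transversions in group(s): ",
            paste(names(tv)[tv == 0], collapse = ", "),
            "; Ts/Tv reported as Inf")
  out <- as.numeric(ts) / as.numeric(tv)
  names(out) <- names(ts)
  out
}

#' Infer genetic sex from chromosome X heterozygosity
#'
#' Males carry one X, so their chrX heterozygous proportion is ~0; an
#' autosome provides the per-sample baseline. A sample is called male iff
#' its chrX heterozygosity is below \code{threshold} times its baseline
#' heterozygosity.
#'
#' @param geno An \code{rpe_geno}.
#' @param x_chrom,baseline_chrom Chromosome names (e.g. "chrX", "chr1").
#' @param threshold Fraction of baseline below which a sample is male.
#' @param min_variants Minimum variants required per chromosome.
#' @return Object of class \code{rpe_sample_qc}: data.frame with sample,
#'   het_prop_chrX, het_prop_baseline, sex_call.
#' @export
infer_sex <- function(geno, x_chrom = "chrX", baseline_chrom = "chr1",
                      threshold = 0.1, min_variants = 50L) {
  stopifnot(inherits(geno, "rpe_geno"))
  vm <- geno$variant_meta
  ix <- vm$chrom == x_chrom
  ib <- vm$chrom == baseline_chrom
  if (sum(ix) < min_variants || sum(ib) < min_variants)
    stop("insufficient data: need >= ", min_variants,
         " variants on both chromosomes", call. = FALSE)
  het_prop <- function(cols) {
    d <- geno$dosage[, cols, drop = FALSE]
    rowMeans(d == 1L, na.rm = TRUE)
  }
  hx <- het_prop(ix); hb <- het_prop(ib)
  structure(data.frame(
    sample = rownames(geno$dosage),
    het_prop_chrX = hx, het_prop_baseline = hb,
    sex_call = ifelse(hx < threshold * hb, "male", "female"),
    stringsAsFactors = FALSE, row.names = NULL
  ), class = c("rpe_sample_qc", "data.frame"))
}

#' Detect duplicated samples by pairwise genotype correlation
#'
#' @param geno An \code{rpe_geno}.
#' @param min_corr Pearson-correlation threshold for flagging (default 0.9).
#' @return data.frame of flagged pairs (sample_a, sample_b, correlation);
#'   zero rows when none. Pairs with an undefined correlation (constant
#'   dosage vector) are skipped with a warning.
#' @export
detect_duplicates <- function(geno, min_corr = 0.9) {
  stopifnot(inherits(geno, "rpe_geno"))
  d <- t(geno$dosage)  # variants x samples
  if (ncol(d) < 2L) stop("need >= 2 samples", call. = FALSE)
  cc <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))
  if (any(is.na(cc[upper.tri(cc)])))
    warning("correlation undefined for some pair(s) (constant dosages); skipped")
  idx <- which(upper.tri(cc) & !is.na(cc) & cc >= min_corr, arr.ind = TRUE)
  data.frame(sample_a = colnames(d)[idx[, 1]],
             sample_b = colnames(d)[idx[, 2]],
             correlation = cc[idx],
             stringsAsFactors = FALSE)
}

#' Principal components of standardized genotype dosages
#'
#' Dosages are centered at 2p and scaled by sqrt(2p(1-p)) (p = sample
#' allele frequency); zero-variance variants are dropped before the SVD.
#'
#' @param geno An \code{rpe_geno}.
#' @param n_components Number of components to return (default 3).
#' @return List with \code{components} (samples x n_components scores) and
#'   \code{variance_explained} (fractions, non-increasing).
#' @export
genotype_pca <- function(geno, n_components = 3L) {
  stopifnot(inherits(geno, "rpe_geno"))
  d <- geno$dosage
  if (n_components > min(dim(d)))
    stop("n_components exceeds min(samples, variants)", call. = FALSE)
  p <- colMeans(d, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1 & apply(d, 2, function(x) stats::var(x, na.rm = TRUE)) > 0
  d <- d[, keep, drop = FALSE]
  p <- p[keep]
  z <- sweep(sweep(d, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  z[is.na(z)] <- 0
  sv <- svd(z, nu = n_components, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  rownames(scores) <- rownames(d)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  list(components = scores,
       variance_explained = (sv$d^2 / sum(sv$d^2))[seq_len(n_components)])
}
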