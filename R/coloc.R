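#' Fine-mapping configuration
#'
#' @param max_causal Maximum number of causal variants per configuration
#'   (exhaustive enumeration; default 2).
#' @param p_prior Per-variant prior inclusion probability; default 1/m
#'   (set at solve time when NULL).
#' @param effect_scale Prior standard deviation of the per-causal-variant
#'   non-centrality (default 3.7).
#' @param ridge Diagonal ridge added to the LD matrix (default 1e-3).
#' @return Object of class \code{rpe_finemap_config}.
#' @export
finemap_config <- function(max_causal = 2L, p_prior = NULL,
                           effect_scale = 3.7, ridge = 1e-3) {
  if (max_causal < 1L) stop("max_causal must be >= 1", call. = FALSE)
  if (!is.null(p_prior) && (p_prior <= 0 || p_prior >= 1))
    stop("p_prior must lie in (0,1)", call. = FALSE)
  if (effect_scale <= 0) stop("effect_scale must be > 0", call. = FALSE)
  structure(list(max_causal = as.integer(max_causal), p_prior = p_prior,
                 effect_scale = effect_scale, ridge = ridge),
            class = "rpe_finemap_config")
}

#' Select candidate colocalization loci
#'
#' A locus is emitted for every QTL signal with p below \code{qtl_p_max}
#' that has at least one GWAS variant with p below \code{gwas_p_max}
#' within \code{window_bp} of the QTL lead variant. The locus variant set
#' is the GWAS/QTL intersection within the window.
#'
#' @param gwas data.frame with variant, pos, p (GWAS summary statistics).
#' @param qtl An \code{rpe_assoc}-like data.frame with gene, variant,
#'   p_combined; variant positions taken from \code{variant_meta}.
#' @param variant_meta data.frame (variant, chrom, pos).
#' @param gwas_p_max,qtl_p_max Signal thresholds (1e-4, 1e-5).
#' @param window_bp Window around the QTL lead (500 kb).
#' @return List of loci, each a list(gene, lead_variant, variants).
#' @export
select_loci <- function(gwas, qtl, variant_meta, gwas_p_max = 1e-4,
                        qtl_p_max = 1e-5, window_bp = 500000L) {
  loci <- list()
  sig <- qtl[qtl$p_combined < qtl_p_max, , drop = FALSE]
  if (!nrow(sig)) return(loci)
  for (g in unique(sig$gene)) {
    sg <- sig[sig$gene == g, , drop = FALSE]
    lead <- sg$variant[which.min(sg$p_combined)]
    lead_pos <- variant_meta$pos[match(lead, variant_meta$variant)]
    inwin <- gwas[abs(gwas$pos - lead_pos) <= window_bp, , drop = FALSE]
    if (!any(inwin$p < gwas_p_max)) next
    qtl_win_vars <- variant_meta$variant[
      abs(variant_meta$pos - lead_pos) <= window_bp]
    shared <- intersect(intersect(inwin$variant, qtl$variant[qtl$gene == g]),
                        qtl_win_vars)
    if (!length(shared)) {
      warning("locus at ", g, ": empty GWAS/QTL variant intersection; skipped")
      next
    }
    loci[[g]] <- list(gene = g, lead_variant = lead, variants = shared)
  }
  loci
}

# log MVN(0, S) density of z, dropping the shared (2*pi) constant
.lmvn0 <- function(z, S) {
  L <- tryCatch(chol(S), error = function(e)
    stop("LD matrix not positive definite after ridge adjustment",
         call. = FALSE))
  u <- backsolve(L, z, transpose = TRUE)
  -sum(log(diag(L))) - 0.5 * sum(u^2)
}

# all causal configurations of size <= k over m variants (list of index
# vectors; the empty/null configuration included first)
.enumerate_configs <- function(m, k) {
  configs <- list(integer(0))
  for (size in seq_len(k)) {
    if (size > m) break
    cmb <- utils::combn(m, size)
    configs <- c(configs, lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
  }
  configs
}

#' Exhaustive Bayesian fine-mapping of summary statistics
#'
#' Enumerates all causal configurations of size up to
#' \code{config$max_causal}. For a configuration c, the z-scores are
#' modeled MVN(0, R + s^2 R_c) with R_c = R diag(c) R (the standard
#' summary-statistic likelihood with a Gaussian non-centrality prior of
#' scale s on each causal variant). The prior over configurations is
#' independent Bernoulli(p_prior) per variant; the null configuration is
#' included in the normalization. Per-variant posterior inclusion
#' probabilities (PIPs) are obtained by marginalizing over
#' configurations.
#'
#' @param z Numeric vector of association z-scores.
#' @param R LD (correlation) matrix matching z.
#' @param config An \code{\link{finemap_config}}.
#' @return Object of class \code{rpe_posterior}: list with \code{pip}
#'   (named per variant), \code{config_posterior}, \code{configs},
#'   \code{null_mass}.
#' @export
finemap_posteriors <- function(z, R, config = finemap_config()) {
  m <- length(z)
  stopifnot(nrow(R) == m, ncol(R) == m)
  if (any(!is.finite(z))) stop("z-scores must be finite", call. = FALSE)
  if (m > 1000L && config$max_causal >= 2L)
    stop("locus too large for exhaustive k>=2 enumeration; use max_causal=1",
         call. = FALSE)
  Rr <- R
  diag(Rr) <- diag(Rr) + config$ridge
  # default prior 1/m, clamped away from 1 so the single-variant locus
  # keeps a proper null mass
  p_prior <- if (is.null(config$p_prior)) min(1 / m, 0.5) else config$p_prior
  s2 <- config$effect_scale^2
  configs <- .enumerate_configs(m, config$max_causal)
  logpost <- vapply(configs, function(cc) {
    S <- Rr
    if (length(cc))
      S <- S + s2 * (Rr[, cc, drop = FALSE] %*% Rr[cc, , drop = FALSE])
    .lmvn0(z, S) + length(cc) * log(p_prior) +
      (m - length(cc)) * log(1 - p_prior)
  }, numeric(1))
  logpost <- logpost - max(logpost)
  post <- exp(logpost) / sum(exp(logpost))
  pip <- numeric(m)
  for (i in seq_along(configs)) pip[configs[[i]]] <- pip[configs[[i]]] + post[i]
  names(pip) <- if (!is.null(names(z))) names(z) else
    if (!is.null(colnames(R))) colnames(R) else paste0("v", seq_len(m))
  structure(list(pip = pip, config_posterior = post, configs = configs,
                 null_mass = post[1]),
            class = "rpe_posterior")
}

#' Colocalization posterior probability (CLPP)
#'
#' Locus-level CLPP is the sum over variants of the product of the GWAS
#' and QTL posterior inclusion probabilities (the modified eCAVIAR
#' convention); \code{method = "max"} returns the per-variant maximum
#' product instead.
#'
#' @param post_gwas,post_qtl \code{rpe_posterior} objects over the same
#'   variant list.
#' @param method "sum" (default) or "max".
#' @return CLPP in [0, 1].
#' @export
clpp <- function(post_gwas, post_qtl, method = c("sum", "max")) {
  method <- match.arg(method)
  a <- post_gwas$pip; b <- post_qtl$pip
  if (length(a) != length(b) || !identical(names(a), names(b)))
    stop("mismatched variant lists between posteriors", call. = FALSE)
  prod <- a * b
  if (method == "sum") sum(prod) else max(prod)
}

#' Classify a two-condition colocalization result
#'
#' Shared if both conditions exceed \code{threshold}; condition-specific
#' if exactly one exceeds it while the other is below the threshold and
#' at least \code{fold} times smaller than the larger (inclusive); "none"
#' otherwise.
#'
#' @param clpp_by_condition Named numeric length 2 of CLPP values.
#' @param threshold Significance cutoff (default 0.01).
#' @param fold Required order-of-magnitude separation (default 10).
#' @return One of "shared", "<condition>-specific", "none".
#' @export
classify_colocalization <- function(clpp_by_condition, threshold = 0.01,
                                    fold = 10) {
  if (length(clpp_by_condition) != 2L)
    stop("exactly two conditions required", call. = FALSE)
  if (any(clpp_by_condition < 0))
    stop("CLPP values must be nonnegative", call. = FALSE)
  v <- clpp_by_condition
  hi <- which.max(v); lo <- which.min(v)
  if (all(v > threshold)) return("shared")
  if (v[hi] > threshold && v[lo] < threshold && v[lo] <= v[hi] / fold)
    return(paste0(names(v)[hi], "-specific"))
  "none"
}
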