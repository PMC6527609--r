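#' Cluster splice junctions by shared donor/acceptor sites
#'
#' Junctions (introns) are aggregated across samples and grouped into
#' connected components where two introns are linked if they share a
#' start (donor) or end (acceptor) coordinate on the same chromosome and
#' strand. Introns longer than \code{max_intron_bp} are removed first;
#' then, iteratively to a fixpoint, junctions supported by less than
#' \code{min_fraction} of their cluster's total reads are dropped and
#' components re-formed. Finally clusters with fewer than
#' \code{min_cluster_reads} total reads or fewer than 2 introns are
#' discarded.
#'
#' @param junctions data.frame/data.table with chrom, intron_start,
#'   intron_end, strand, sample, count (1-based inclusive coordinates).
#' @param min_cluster_reads Minimum aggregate reads per cluster (30).
#' @param min_fraction Minimum junction share of its cluster (0.001).
#' @param max_intron_bp Maximum intron length (100000).
#' @return Object of class \code{rpe_clusters}: data.table of member
#'   introns (intron id, chrom, intron_start, intron_end, strand, cluster,
#'   total_count).
#' @export
cluster_introns <- function(junctions, min_cluster_reads = 30L,
                            min_fraction = 0.001, max_intron_bp = 100000L) {
  j <- data.table::as.data.table(junctions)
  agg <- j[, list(total_count = sum(count)),
           by = c("chrom", "intron_start", "intron_end", "strand")]
  data.table::setorder(agg, chrom, intron_start, intron_end)
  agg <- agg[(agg$intron_end - agg$intron_start + 1L) <= max_intron_bp, ]

  components <- function(a) {
    # union-find over shared start or end coordinates per chrom+strand
    n <- nrow(a)
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    link_by <- function(key) {
      for (grp in split(seq_len(n), key)) {
        if (length(grp) > 1L) {
          r <- find(grp[1])
          for (g in grp[-1]) parent[find(g)] <<- r
        }
      }
    }
    link_by(paste(a$chrom, a$strand, a$intron_start, sep = ":"))
    link_by(paste(a$chrom, a$strand, "e", a$intron_end, sep = ":"))
    vapply(seq_len(n), find, integer(1))
  }

  repeat {
    if (!nrow(agg)) break
    comp <- components(agg)
    ctot <- tapply(agg$total_count, comp, sum)
    frac <- agg$total_count / as.numeric(ctot[as.character(comp)])
    drop <- frac < min_fraction
    if (!any(drop)) { agg$comp <- comp; break }
    agg <- agg[!drop, ]
  }
  if (!nrow(agg)) {
    out <- data.table::data.table(intron = character(), chrom = character(),
      intron_start = integer(), intron_end = integer(), strand = character(),
      cluster = character(), total_count = numeric())
    class(out) <- c("rpe_clusters", class(out))
    return(out)
  }
  ctot <- tapply(agg$total_count, agg$comp, sum)
  csize <- table(agg$comp)
  ok <- as.numeric(ctot[as.character(agg$comp)]) >= min_cluster_reads &
    as.integer(csize[as.character(agg$comp)]) >= 2L
  agg <- agg[ok, ]
  # stable cluster ids ordered by genomic position of first member
  ids <- unique(agg$comp)
  cluster_id <- paste0("clu_", match(agg$comp, ids))
  out <- data.table::data.table(
    intron = paste0(agg$chrom, ":", agg$intron_start, "-", agg$intron_end,
                    ":", agg$strand),
    chrom = agg$chrom, intron_start = agg$intron_start,
    intron_end = agg$intron_end, strand = agg$strand,
    cluster = cluster_id, total_count = as.numeric(agg$total_count))
  class(out) <- c("rpe_clusters", class(out))
  out
}

#' Intron-excision ratio matrix
#'
#' Per sample, each member intron's ratio is its junction count divided by
#' the total count of its cluster in that sample; NA where the cluster has
#' zero reads in that sample. A per-intron centered-and-scaled copy is
#' provided for association testing; raw ratios are retained.
#'
#' @param clusters An \code{rpe_clusters} table.
#' @param junctions The junction table the clusters were built from.
#' @return Object of class \code{rpe_ratios}: list with \code{ratio}
#'   (intron x sample), \code{scaled}, \code{intron_meta},
#'   \code{cluster_totals}.
#' @export
excision_ratios <- function(clusters, junctions) {
  j <- data.table::as.data.table(junctions)
  samples <- sort(unique(j$sample))
  key <- paste0(j$chrom, ":", j$intron_start, "-", j$intron_end, ":", j$strand)
  j$intron <- key
  j <- j[j$intron %in% clusters$intron, ]
  counts <- matrix(0, nrow(clusters), length(samples),
                   dimnames = list(clusters$intron, samples))
  idx <- cbind(match(j$intron, clusters$intron), match(j$sample, samples))
  counts[idx] <- counts[idx] + j$count
  totals <- rowsum(counts, clusters$cluster)
  denom <- totals[clusters$cluster, , drop = FALSE]
  ratio <- counts / denom
  ratio[denom == 0] <- NA_real_
  scaled <- t(scale(t(ratio)))
  scaled[!is.finite(scaled)] <- NA_real_
  structure(list(ratio = ratio, scaled = scaled,
                 intron_meta = data.table::copy(clusters),
                 cluster_totals = totals),
            class = "rpe_ratios")
}

# two-sided slope p for simple regression of y on each column of G,
# vectorized via the correlation form of the t-test (df = n - 2)
.slope_pmin <- function(y, G) {
  ok <- is.finite(y)
  y <- y[ok]; G <- G[ok, , drop = FALSE]
  n <- length(y)
  if (n < 3L) return(NA_real_)
  ys <- y - mean(y)
  denom_y <- sqrt(sum(ys^2))
  if (denom_y == 0) return(NA_real_)
  Gc <- sweep(G, 2, colMeans(G))
  gnorm <- sqrt(colSums(Gc^2))
  use <- gnorm > 1e-12
  if (!any(use)) return(NA_real_)
  r <- (colSums(Gc[, use, drop = FALSE] * ys) / (gnorm[use] * denom_y))
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  min(2 * stats::pt(-abs(tt), n - 2))
}

#' Adaptive-permutation cis-sQTL scan
#'
#' For each intron, nominal p is the two-sided slope t-test of simple
#' linear regression of the standardized excision ratio on dosage,
#' minimized over variants within \code{window_bp} of the cluster
#' midpoint (no covariates; taking within-cluster ratios already cancels
#' sample-level confounders). The permutation p-value is
#' (k + 1) / (M + 1), where k counts permutations of the sample labels of
#' the ratio vector whose minimum nominal p beats the observed minimum;
#' permutation stops adaptively once k >= \code{stop_exceedances} after
#' at least \code{perms[1]} permutations, or at \code{perms[2]}.
#'
#' @param ratios An \code{rpe_ratios}.
#' @param geno An \code{rpe_geno} sharing sample names.
#' @param window_bp Cis window around the cluster midpoint (100 kb).
#' @param perms Length-2 integer (min, max) permutations, default
#'   c(100, 10000).
#' @param seed Permutation seed.
#' @param stop_exceedances Adaptive stopping count (default 30).
#' @return data.frame of class \code{rpe_sqtl}: intron, cluster,
#'   lead_variant, nominal_p, perm_p, n_perm.
#' @export
sqtl_scan <- function(ratios, geno, window_bp = 100000L,
                      perms = c(100L, 10000L), seed = 1L,
                      stop_exceedances = 30L) {
  stopifnot(inherits(ratios, "rpe_ratios"), inherits(geno, "rpe_geno"))
  samples <- colnames(ratios$ratio)
  if (!all(samples %in% rownames(geno$dosage)))
    stop("ratio samples missing from genotype table", call. = FALSE)
  D <- geno$dosage[samples, , drop = FALSE]
  vm <- geno$variant_meta
  im <- ratios$intron_meta
  set.seed(seed)
  res <- vector("list", nrow(im))
  for (i in seq_len(nrow(im))) {
    members <- im[im$cluster == im$cluster[i], ]
    mid <- mean(c(min(members$intron_start), max(members$intron_end)))
    hit <- which(vm$chrom == im$chrom[i] & abs(vm$pos - mid) <= window_bp)
    if (!length(hit)) next
    y <- ratios$scaled[i, ]
    if (all(!is.finite(y)) || stats::sd(y, na.rm = TRUE) == 0 ||
        sum(is.finite(y)) < 3L) next  # zero-variance / tiny vectors skipped
    G <- D[, hit, drop = FALSE]
    obs <- .slope_pmin(y, G)
    if (is.na(obs)) next
    # identify the lead variant
    ok <- is.finite(y)
    Gc <- sweep(G[ok, , drop = FALSE], 2, colMeans(G[ok, , drop = FALSE]))
    ys <- y[ok] - mean(y[ok])
    gn <- sqrt(colSums(Gc^2)); gn[gn < 1e-12] <- NA
    rvec <- abs(colSums(Gc * ys)) / (gn * sqrt(sum(ys^2)))
    lead <- vm$variant[hit[which.max(rvec)]]

    k <- 0L; M <- 0L
    batch <- perms[1]
    while (M < perms[2]) {
      b <- min(batch, perms[2] - M)
      pm <- vapply(seq_len(b), function(j) .slope_pmin(sample(y), G),
                   numeric(1))
      k <- k + sum(pm <= obs, na.rm = TRUE)
      M <- M + b
      if (M >= perms[1] && k >= stop_exceedances) break
      batch <- min(batch * 2L, 1000L)
    }
    res[[i]] <- data.frame(intron = im$intron[i], cluster = im$cluster[i],
                           lead_variant = lead, nominal_p = obs,
                           perm_p = (k + 1) / (M + 1), n_perm = M,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(intron = character(), cluster = character(),
                      lead_variant = character(), nominal_p = numeric(),
                      perm_p = numeric(), n_perm = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("rpe_sqtl", "data.frame")
  out
}

#' Within-cluster Bonferroni correction and global FDR for sQTL results
#'
#' Each intron's permutation p is Bonferroni-corrected by the number of
#' introns tested in its cluster (capped at 1); the cluster p-value is
#' the minimum corrected p over members; BH across cluster p-values gives
#' the global q.
#'
#' @param results An \code{rpe_sqtl} table.
#' @param q FDR level (default 0.05).
#' @return data.frame: cluster, lead_intron, lead_variant, cluster_p,
#'   q_value, significant.
#' @export
cluster_correction <- function(results, q = 0.05) {
  if (!nrow(results))
    return(data.frame(cluster = character(), lead_intron = character(),
                      lead_variant = character(), cluster_p = numeric(),
                      q_value = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  nin <- table(results$cluster)
  p_bonf <- pmin(results$perm_p * as.integer(nin[results$cluster]), 1)
  # permutation p-values are granular, so ties at the floor are common;
  # break them by the nominal p of the intron's best variant
  lead <- tapply(seq_len(nrow(results)), results$cluster,
                 function(ii) ii[order(p_bonf[ii], results$nominal_p[ii])[1]])
  cl <- data.frame(
    cluster = names(lead),
    lead_intron = results$intron[unlist(lead)],
    lead_variant = results$lead_variant[unlist(lead)],
    cluster_p = as.numeric(tapply(p_bonf, results$cluster, min)),
    stringsAsFactors = FALSE, row.names = NULL)
  cl$q_value <- stats::p.adjust(cl$cluster_p, method = "BH")
  cl$significant <- cl$q_value <= q
  cl[order(cl$cluster_p), ]
}
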