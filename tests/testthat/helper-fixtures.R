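# Shared fixture builders and independent oracles.

# tiny genotype table straight from matrices
make_geno <- function(dos, chrom = "chr1", pos = NULL, ref = NULL,
                      alt = NULL, ar2 = NULL, n_alleles = NULL) {
  m <- ncol(dos)
  if (is.null(rownames(dos))) rownames(dos) <- paste0("s", seq_len(nrow(dos)))
  vm <- data.frame(
    variant = paste0("v", seq_len(m)),
    chrom = rep_len(chrom, m),
    pos = if (is.null(pos)) seq_len(m) * 1000L else pos,
    ref = if (is.null(ref)) rep("A", m) else ref,
    alt = if (is.null(alt)) rep("G", m) else alt,
    stringsAsFactors = FALSE)
  if (!is.null(ar2)) vm$imputation_quality <- ar2
  if (!is.null(n_alleles)) vm$n_alleles <- n_alleles
  colnames(dos) <- vm$variant
  geno_table(dos, vm)
}

# independent brute-force fine-mapping oracle: explicit config loops and
# solve()/determinant()-based MVN density (package uses Cholesky)
oracle_finemap <- function(z, R, k = 2, s = 3.7, p_prior = NULL,
                           ridge = 1e-3) {
  m <- length(z)
  if (is.null(p_prior)) p_prior <- min(1 / m, 0.5)
  Rr <- R; diag(Rr) <- diag(Rr) + ridge
  ldens <- function(S) {
    -0.5 * as.numeric(determinant(S, logarithm = TRUE)$modulus) -
      0.5 * as.numeric(t(z) %*% solve(S) %*% z) -
      0.5 * m * log(2 * pi)
  }
  configs <- list(integer(0))
  if (k >= 1) for (i in seq_len(m)) configs[[length(configs) + 1]] <- i
  if (k >= 2 && m >= 2)
    for (i in 1:(m - 1)) for (j in (i + 1):m)
      configs[[length(configs) + 1]] <- c(i, j)
  lp <- sapply(configs, function(cc) {
    S <- Rr
    if (length(cc)) {
      for (a in cc) S <- S + s^2 * (Rr[, a] %o% Rr[a, ])
    }
    ldens(S) + length(cc) * log(p_prior) + (m - length(cc)) * log(1 - p_prior)
  })
  w <- exp(lp - max(lp)); w <- w / sum(w)
  pip <- numeric(m)
  for (i in seq_along(configs)) for (a in configs[[i]])
    pip[a] <- pip[a] + w[i]
  list(pip = pip, post = w)
}

# long junction table from a compact spec list: list(c(start, end, count))
make_junctions <- function(introns, sample = "s1", chrom = "chr1",
                           strand = "+") {
  do.call(rbind, lapply(introns, function(x)
    data.frame(chrom = chrom, intron_start = x[1], intron_end = x[2],
               strand = strand, sample = sample, count = x[3],
               stringsAsFactors = FALSE)))
}

# selectivity score table from a gene x tissue matrix (bypasses the
# nonnegativity of expression; used for synthetic z fixtures)
scores_from_matrix <- function(expr) selectivity_zscores(expr)
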