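cohort_fixture <- function(n = 60, n_loci = 4, seed = 21, beta = 1.5,
                           pi = 0.8, prop_causal = 1) {
  cfg <- sim_config(n_samples = n, n_loci = n_loci, variants_per_locus = 8,
                    seed = seed)
  co <- simulate_cohort(cfg)
  tr <- simulate_truth(co, cfg, prop_causal = prop_causal, prop_shared = 1,
                       beta = beta, pi = pi)
  ex <- simulate_expression(co, tr, cfg)
  list(cfg = cfg, co = co, tr = tr, ex = ex, geno = as_geno(co))
}

test_that("cis_scan matches an independent lm() oracle for p_total", {
  f <- cohort_fixture(n = 40, n_loci = 2)
  covs <- cbind(cov1 = rnorm(40), cov2 = runif(40))
  expr <- expression_matrix(f$ex$glucose$counts, f$tr$genes)
  rec <- cis_scan(expr, f$geno, ase = NULL, covariates = covs)
  for (i in sample(nrow(rec), 10)) {
    y <- expr$norm[rec$gene[i], ]
    g <- f$geno$dosage[, rec$variant[i]]
    fit <- summary(lm(y ~ g + covs))$coefficients
    expect_equal(rec$p_total[i], fit["g", "Pr(>|t|)"], tolerance = 1e-10)
    expect_equal(rec$beta[i], fit["g", "Estimate"], tolerance = 1e-10)
  }
})

test_that("cis window and allelic gates are respected", {
  f <- cohort_fixture(n = 30, n_loci = 2)
  expr <- expression_matrix(f$ex$glucose$counts, f$tr$genes)
  rec <- cis_scan(expr, f$geno, ase = f$ex$glucose$ase, window_bp = 3000)
  expect_true(all(abs(rec$tss_dist) <= 3000))
  # variants far outside the window are never tested
  wide <- cis_scan(expr, f$geno, ase = f$ex$glucose$ase, window_bp = 500000)
  far <- f$geno$variant_meta$variant[
    abs(f$geno$variant_meta$pos - f$tr$genes$tss[1]) > 600000 &
      f$geno$variant_meta$locus == 1]
  expect_false(any(wide$variant[wide$gene == "gene_1"] %in% far))
  # ASE p only where the table covers the tested variant
  has_ase <- !is.na(wide$p_ase)
  expect_true(all(wide$variant[has_ase] %in% f$ex$glucose$ase$variant))
  expect_true(all(wide$n_het[has_ase] >= 2))
  # rank-deficient covariates error
  expect_error(cis_scan(expr, f$geno,
                        covariates = cbind(a = rep(1, 30), b = rep(2, 30))),
               "rank")
})

test_that("planted eQTLs reach extreme combined significance", {
  f <- cohort_fixture(n = 100, n_loci = 3, beta = 2, pi = 0.8)
  expr <- expression_matrix(f$ex$glucose$counts, f$tr$genes)
  rec <- cis_scan(expr, f$geno, ase = f$ex$glucose$ase)
  for (g in f$tr$genes$gene) {
    cv <- f$tr$eqtl$causal_variant[f$tr$eqtl$gene == g][1]
    expect_lt(rec$p_combined[rec$gene == g & rec$variant == cv], 1e-8)
  }
  # direction concordance: sign(beta) agrees with sign(pi - 0.5)
  lead <- rec[!is.na(rec$pi) & rec$p_combined < 1e-8, ]
  expect_gte(mean(sign(lead$beta) == sign(lead$pi - 0.5)), 0.95)
})

test_that("Simes combination reproduces the worked example", {
  expect_equal(simes_p(c(0.01, 0.04, 0.9)), 0.03)
  expect_equal(simes_p(c(1, 1, 1)), 1)
  expect_true(is.na(simes_p(numeric(0))))
})

test_that("hierarchical FDR respects the gene hierarchy and null input", {
  rec <- data.frame(
    gene = rep(c("gA", "gB"), each = 3),
    variant = rep(paste0("v", 1:3), 2), condition = "x",
    p_combined = c(1e-6, 0.2, 0.9, 0.8, 0.9, 1.0))
  cs <- hierarchical_fdr(rec)
  expect_true(cs$egenes$selected[cs$egenes$gene == "gA"])
  expect_false(cs$egenes$selected[cs$egenes$gene == "gB"])
  # no association reported for an unselected gene
  expect_true(all(cs$eassociations$gene == "gA"))
  # all-ones input selects nothing
  rec1 <- rec; rec1$p_combined <- 1
  expect_equal(sum(hierarchical_fdr(rec1)$egenes$selected), 0)
  empty <- hierarchical_fdr(rec[0, ])
  expect_equal(nrow(empty$egenes), 0)
})

test_that("multi-condition FDR labels shared and specific genes", {
  set.seed(31)
  mk <- function(pA) data.frame(
    gene = rep(c("gShared", "gSpec", paste0("null", 1:8)), each = 4),
    variant = rep(paste0("v", 1:4), 10), condition = "x",
    p_combined = c(rep(1e-8, 4), pA, runif(32, 0.2, 1)))
  recs <- list(glucose = mk(rep(1e-8, 4)), galactose = mk(runif(4, 0.5, 1)))
  mc <- multi_condition_fdr(recs)
  lab <- setNames(mc$genes$label, mc$genes$gene)
  expect_equal(unname(lab["gShared"]), "shared")
  expect_equal(unname(lab["gSpec"]), "glucose-specific")
  # identical records in both conditions -> shared
  recs2 <- list(glucose = mk(rep(1e-8, 4)), galactose = mk(rep(1e-8, 4)))
  mc2 <- multi_condition_fdr(recs2)
  expect_equal(mc2$genes$label[mc2$genes$gene == "gSpec"], "shared")
  expect_warning(multi_condition_fdr(recs[1]), "single condition")
})

test_that("condition-specific planted effects are labeled correctly", {
  cfg <- sim_config(n_samples = 80, n_loci = 6, variants_per_locus = 8,
                    seed = 33)
  co <- simulate_cohort(cfg)
  tr <- simulate_truth(co, cfg, prop_causal = 1, prop_shared = 0,
                       beta = 2, pi = 0.8)
  ex <- simulate_expression(co, tr, cfg)
  recs <- lapply(cfg$condition_names, function(cond) {
    cis_scan(expression_matrix(ex[[cond]]$counts, tr$genes), as_geno(co),
             ase = ex[[cond]]$ase, condition = cond)
  })
  names(recs) <- cfg$condition_names
  mc <- multi_condition_fdr(recs)
  hits <- 0; tot <- 0
  for (g in tr$genes$gene) {
    cond <- tr$eqtl$condition[tr$eqtl$gene == g & tr$eqtl$beta != 0]
    if (!length(cond)) next
    tot <- tot + 1
    lab <- mc$genes$label[mc$genes$gene == g]
    if (length(lab) && !is.na(lab) && lab == paste0(cond, "-specific"))
      hits <- hits + 1
  }
  expect_gte(hits / tot, 0.8)
})

test_that("delta imbalance follows the arithmetic examples", {
  expect_equal(delta_imbalance(0.8, 0.5), 0.3)
  expect_equal(delta_imbalance(0.2, 0.8), 0.0)
  expect_equal(delta_imbalance(0.65, 0.65), 0.0)
  expect_true(is.na(delta_imbalance(NA, 0.6)))
})

test_that("pi estimator stays within the binomial confidence band", {
  f <- cohort_fixture(n = 100, n_loci = 5, beta = 1, pi = 0.75)
  expr <- expression_matrix(f$ex$glucose$counts, f$tr$genes)
  rec <- cis_scan(expr, f$geno, ase = f$ex$glucose$ase)
  covered <- 0; tot <- 0
  for (g in f$tr$genes$gene) {
    cv <- f$tr$eqtl$causal_variant[f$tr$eqtl$gene == g][1]
    r <- rec[rec$gene == g & rec$variant == cv, ]
    if (!nrow(r) || is.na(r$pi)) next
    ase <- f$ex$glucose$ase
    a <- ase[ase$gene == g & ase$variant == cv, ]
    ci <- binom.test(sum(a$hap_alt_count),
                     sum(a$hap_alt_count + a$hap_ref_count))$conf.int
    tot <- tot + 1
    if (0.75 >= ci[1] && 0.75 <= ci[2]) covered <- covered + 1
  }
  expect_gte(covered / tot, 0.6)  # 5 genes; exact binomial coverage check
})

test_that("covariate selection finds a planted confounder deterministically", {
  cfg <- sim_config(n_samples = 60, n_loci = 5, variants_per_locus = 6,
                    seed = 41)
  co <- simulate_cohort(cfg)
  tr <- simulate_truth(co, cfg, prop_causal = 1, prop_shared = 1,
                       beta = 1, pi = 0.7)
  ex <- simulate_expression(co, tr, cfg)
  counts <- ex$glucose$counts
  set.seed(42)
  batch <- rnorm(60, sd = 1.5)
  # gene-specific loadings: a global scale factor would be absorbed by the
  # size factors, so half the genes load on the batch and half do not
  loadings <- rep(c(0, 2), length.out = nrow(counts))
  confounded <- round(counts * 2^outer(loadings, batch))
  expr <- expression_matrix(confounded, tr$genes)
  cands <- list(batch = batch, noise = rnorm(60))
  sel <- select_covariates(expr, as_geno(co), cands, ase = ex$glucose$ase,
                           probe_genes = 5, seed = 7)
  expect_true("batch" %in% sel$chosen)
  expect_gt(sel$counts[2], sel$counts[1])  # adding the confounder helps
  sel2 <- select_covariates(expr, as_geno(co), cands, ase = ex$glucose$ase,
                            probe_genes = 5, seed = 7)
  expect_identical(sel, sel2)
  # collinear candidate dropped with a warning
  expect_warning(
    select_covariates(expr, as_geno(co),
                      list(batch = batch, twice = 2 * batch),
                      probe_genes = 3, seed = 7),
    "collinear")
})

test_that("motif input construction follows the allele sign rule", {
  ref <- list(chr1 = paste(rep("ACGT", 20), collapse = ""))
  vm <- data.frame(variant = c("vPos", "vNeg", "vEdge"), chrom = "chr1",
                   pos = c(40L, 40L, 3L), ref = "A", alt = "G")
  lead <- data.frame(variant = c("vPos", "vNeg"), beta = c(2, -2))
  out <- build_motif_inputs(lead, ref, vm, flank = 15)
  expect_equal(nchar(out$target[["vPos"]]), 31)
  expect_equal(substr(out$target[["vPos"]], 16, 16), "G")     # beta>0: alt up
  expect_equal(substr(out$background[["vPos"]], 16, 16), "A")
  expect_equal(substr(out$target[["vNeg"]], 16, 16), "A")     # beta<0: swap
  expect_equal(substr(out$background[["vNeg"]], 16, 16), "G")
  expect_warning(
    build_motif_inputs(data.frame(variant = "vEdge", beta = 1), ref, vm),
    "edge")
})
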