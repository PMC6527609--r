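test_that("finemap posteriors match the brute-force oracle to 1e-10", {
  set.seed(61)
  for (m in c(2, 3, 5)) {
    A <- matrix(rnorm(m * m), m)
    R <- cov2cor(crossprod(A) + diag(m))
    z <- rnorm(m, sd = 2)
    ps <- finemap_posteriors(z, R, finemap_config(max_causal = 2))
    orc <- oracle_finemap(z, R, k = 2)
    expect_equal(unname(ps$pip), orc$pip, tolerance = 1e-10)
    expect_equal(unname(ps$config_posterior), unname(orc$post),
                 tolerance = 1e-10)
    expect_equal(sum(ps$config_posterior), 1, tolerance = 1e-12)
    expect_true(all(ps$pip >= 0 & ps$pip <= 1))
  }
})

test_that("single strong variant and exchangeability behave as expected", {
  ps <- finemap_posteriors(c(v1 = 10), matrix(1, 1, 1),
                           finemap_config(max_causal = 1))
  expect_gt(ps$pip[["v1"]], 0.99)
  # perfect LD with equal z: PIPs equal by symmetry
  R <- matrix(c(1, 1, 1, 1), 2)
  ps2 <- finemap_posteriors(c(a = 6, b = 6), R, finemap_config())
  expect_equal(unname(ps2$pip[1]), unname(ps2$pip[2]), tolerance = 1e-10)
})

test_that("k=1 with diagonal LD reduces to a softmax of log Bayes factors", {
  set.seed(62)
  m <- 4
  z <- rnorm(m, sd = 3)
  s <- 3.7
  ridge <- 0
  cfgf <- finemap_config(max_causal = 1, ridge = ridge)
  ps <- finemap_posteriors(z, diag(m), cfgf)
  # closed form: per-config loglik for diagonal R
  p_prior <- min(1 / m, 0.5)
  lbf <- -0.5 * log(1 + s^2) + 0.5 * z^2 * s^2 / (1 + s^2) +
    log(p_prior) - log(1 - p_prior)
  w <- exp(c(0, lbf)); w <- w / sum(w)
  expect_equal(unname(ps$pip), w[-1], tolerance = 1e-10)
})

test_that("CLPP arithmetic and guardrails", {
  mkpost <- function(pip) structure(list(pip = pip), class = "rpe_posterior")
  a <- mkpost(c(v1 = 1, v2 = 0)); b <- mkpost(c(v1 = 1, v2 = 0))
  expect_equal(clpp(a, b), 1.0)
  expect_equal(clpp(mkpost(c(v1 = 1, v2 = 0)), mkpost(c(v1 = 0, v2 = 1))), 0)
  expect_equal(clpp(mkpost(c(v1 = 0.6, v2 = 0.4)),
                    mkpost(c(v1 = 0.5, v2 = 0.5))), 0.5)
  expect_error(clpp(mkpost(c(v1 = 1)), mkpost(c(x = 1))), "mismatch")
  # CLPP bounded by total posterior mass
  expect_lte(clpp(mkpost(c(v1 = 0.3, v2 = 0.2)),
                  mkpost(c(v1 = 0.9, v2 = 0.05))), 0.5)
})

test_that("colocalization classification reproduces the worked CLPP pairs", {
  expect_equal(classify_colocalization(c(glucose = 0.033, galactose = 0.002)),
               "glucose-specific")
  expect_equal(classify_colocalization(c(glucose = 0.0004, galactose = 0.014)),
               "galactose-specific")
  expect_equal(classify_colocalization(c(glucose = 0.5, galactose = 0.4)),
               "shared")
  expect_equal(classify_colocalization(c(glucose = 0.005, galactose = 0.004)),
               "none")
  # fold rule: 0.02 vs 0.009 is above threshold/under 10x -> none
  expect_equal(classify_colocalization(c(a = 0.02, b = 0.009)), "none")
  expect_error(classify_colocalization(c(a = -0.1, b = 0.5)), "nonnegative")
  expect_error(classify_colocalization(c(a = 0.1)), "two conditions")
})

test_that("locus selection honors thresholds and windows", {
  vm <- data.frame(variant = paste0("v", 1:5), chrom = "chr1",
                   pos = c(1e6, 1.2e6, 1.4e6, 1.45e6, 2.7e6))
  qtl <- data.frame(gene = "g1", variant = paste0("v", 1:5),
                    p_combined = c(1e-6, 0.5, 0.5, 0.5, 0.5))
  gwas <- data.frame(variant = paste0("v", 1:5), pos = vm$pos,
                     p = c(0.9, 0.9, 0.9, 5e-5, 0.9))
  loci <- select_loci(gwas, qtl, vm)
  expect_equal(length(loci), 1L)           # GWAS hit at 450 kb: in window
  expect_true("v4" %in% loci$g1$variants)
  # GWAS hit beyond 500 kb -> no locus
  gwas2 <- gwas; gwas2$p <- c(0.9, 0.9, 0.9, 0.9, 5e-5)
  expect_equal(length(select_loci(gwas2, qtl, vm)), 0L)
  # QTL below threshold -> no locus
  qtl2 <- qtl; qtl2$p_combined <- rep(1e-4, 5)
  expect_equal(length(select_loci(gwas, qtl2, vm)), 0L)
})

test_that("shared and distinct causal variants separate by CLPP", {
  cfg <- sim_config(n_samples = 100, n_loci = 20, variants_per_locus = 8,
                    maf_range = c(0.2, 0.5), ld_copy_prob = 0.4,
                    gwas_n = 5e5, seed = 71)
  co <- simulate_cohort(cfg)
  tr <- simulate_truth(co, cfg, prop_causal = 1, prop_shared = 1,
                       beta = 2, pi = 0.8, gwas_beta = 0.08)
  ex <- simulate_expression(co, tr, cfg)
  expr <- expression_matrix(ex$glucose$counts, tr$genes)
  geno <- as_geno(co)
  rec <- cis_scan(expr, geno, ase = ex$glucose$ase)
  fc <- finemap_config(max_causal = 1)

  locus_clpp <- function(locus, gene, shared) {
    vm <- co$variant_meta[co$variant_meta$locus == locus, ]
    cv <- tr$eqtl$causal_variant[tr$eqtl$gene == gene][1]
    if (shared) {
      gw_cv <- cv
    } else {
      # pick the variant least correlated with the QTL causal variant
      d <- dosage(co)[, vm$variant]
      r2 <- cor(d)[, cv]^2
      cand <- names(which(r2 < 0.05))
      if (!length(cand)) return(NA_real_)
      gw_cv <- cand[1]
    }
    gw <- simulate_gwas_summary(co, tr, locus, cfg, causal_variant = gw_cv)
    rg <- rec[rec$gene == gene, ]
    vars <- intersect(gw$variant, rg$variant)
    R <- ld_matrix(dosage(co)[, vars, drop = FALSE])
    zq <- qnorm(rg$p_combined[match(vars, rg$variant)] / 2,
                lower.tail = FALSE) * sign(rg$beta[match(vars, rg$variant)])
    zg <- gw$z[match(vars, gw$variant)]
    names(zq) <- names(zg) <- vars
    clpp(finemap_posteriors(zg, R, fc), finemap_posteriors(zq, R, fc))
  }

  set.seed(72)
  shared_clpp <- vapply(1:20, function(l)
    locus_clpp(l, paste0("gene_", l), TRUE), numeric(1))
  set.seed(73)
  distinct_clpp <- vapply(1:20, function(l)
    locus_clpp(l, paste0("gene_", l), FALSE), numeric(1))
  expect_gte(mean(shared_clpp > 0.01, na.rm = TRUE), 0.8)
  expect_gte(mean(distinct_clpp < 0.01, na.rm = TRUE), 0.9)
})
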