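test_that("config validation rejects bad dimensions and ranges", {
  expect_error(sim_config(n_samples = 0), "counts")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(ld_copy_prob = 1.2), "ld_copy_prob")
})

test_that("cohort generation is deterministic and honors the LD model", {
  cfg <- sim_config(n_samples = 40, n_loci = 2, variants_per_locus = 10,
                    seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  expect_true(all(dosage(a) %in% 0:2))
  expect_true(all(diff(a$variant_meta$pos) > 0))

  # forced copying: adjacent variants within a locus in perfect LD
  cfg1 <- sim_config(n_samples = 60, n_loci = 2, variants_per_locus = 5,
                     ld_copy_prob = 1, seed = 3)
  co <- simulate_cohort(cfg1)
  d <- dosage(co)
  for (j in c(2:5, 7:10))
    expect_equal(abs(cor(d[, j - 1], d[, j])), 1, tolerance = 1e-12)
})

test_that("empirical MAF matches the binomial oracle at maf 0.5", {
  cfg <- sim_config(n_samples = 10000, n_loci = 1, variants_per_locus = 5,
                    maf_range = c(0.5, 0.5), ld_copy_prob = 0, seed = 2)
  co <- simulate_cohort(cfg)
  expect_true(all(abs(colMeans(dosage(co)) - 1) < 0.02))
})

test_that("expression generator encodes pi in allelic counts and skips homozygotes", {
  cfg <- sim_config(n_samples = 200, n_loci = 2, variants_per_locus = 5,
                    ase_depth = 50, seed = 4)
  co <- simulate_cohort(cfg)
  tr <- simulate_truth(co, cfg, prop_causal = 1, prop_shared = 1,
                       beta = 1, pi = 0.75)
  ex <- simulate_expression(co, tr, cfg)
  ase <- ex$glucose$ase
  # no allelic rows for homozygous samples
  d <- dosage(co)
  for (i in seq_len(nrow(ase)))
    expect_equal(d[ase$sample[i], ase$variant[i]], 1L)
  # aggregated alt fraction near pi (total het depth >> 10,000 / gene pool)
  frac <- sum(ase$hap_alt_count) / sum(ase$hap_alt_count + ase$hap_ref_count)
  expect_equal(frac, 0.75, tolerance = 0.02)
})

test_that("null expression yields no discoveries beyond the nominal rate", {
  cfg <- sim_config(n_samples = 30, n_loci = 20, variants_per_locus = 10,
                    seed = 5)
  co <- simulate_cohort(cfg)
  tr <- simulate_truth(co, cfg, prop_causal = 0)
  expect_true(all(tr$eqtl$beta == 0) && all(tr$eqtl$pi == 0.5))
  ex <- simulate_expression(co, tr, cfg)
  expr <- expression_matrix(ex$glucose$counts, tr$genes)
  rec <- cis_scan(expr, as_geno(co), ase = ex$glucose$ase,
                  condition = "glucose")
  cs <- hierarchical_fdr(rec)
  expect_lte(sum(cs$egenes$selected), 2)
})

test_that("junction skipping follows the dose model", {
  cfg <- sim_config(n_samples = 400, n_loci = 2, variants_per_locus = 5,
                    maf_range = c(0.4, 0.5), seed = 6)
  co <- simulate_cohort(cfg)
  tr <- simulate_truth(co, cfg, prop_causal = 1, prop_shared = 1,
                       skip_effect = log(3))
  tr$sqtl$baseline_skip <- 0.01  # small baseline: logit ~ log-linear
  jt <- simulate_junctions(co, tr, cfg, cluster_depth = 2000)$glucose
  d <- dosage(co)[, tr$sqtl$causal_variant[1]]
  tot <- jt[jt$cluster_hint == "clu_1",
            list(total = sum(count)), by = "sample"]
  sk <- jt[jt$cluster_hint == "clu_1" & (jt$intron_end - jt$intron_start) > 3000,
           list(skip = sum(count)), by = "sample"]
  m <- merge(tot, sk, by = "sample")
  m$dos <- d[m$sample]
  f0 <- sum(m$skip[m$dos == 0]) / sum(m$total[m$dos == 0])
  f1 <- sum(m$skip[m$dos == 1]) / sum(m$total[m$dos == 1])
  expect_equal(f1 / f0, 3, tolerance = 0.10)

  # null: equal skip fractions across genotype groups
  tr0 <- tr; tr0$sqtl$skip_effect <- 0
  jt0 <- simulate_junctions(co, tr0, cfg, cluster_depth = 2000)$glucose
  sk0 <- jt0[jt0$cluster_hint == "clu_1" &
               (jt0$intron_end - jt0$intron_start) > 3000,
             list(skip = sum(count)), by = "sample"]
  tot0 <- jt0[jt0$cluster_hint == "clu_1",
              list(total = sum(count)), by = "sample"]
  m0 <- merge(tot0, sk0, by = "sample"); m0$dos <- d[m0$sample]
  g0 <- sum(m0$skip[m0$dos == 0]) / sum(m0$total[m0$dos == 0])
  g1 <- sum(m0$skip[m0$dos >= 1]) / sum(m0$total[m0$dos >= 1])
  expect_equal(g1 / g0, 1, tolerance = 0.25)
})

test_that("null GWAS locus rarely shows |z| > 5 (MVN oracle)", {
  cfg <- sim_config(n_samples = 100, n_loci = 1, variants_per_locus = 10,
                    seed = 7)
  co <- simulate_cohort(cfg)
  tr <- simulate_truth(co, cfg, prop_causal = 1)
  hits <- 0L
  set.seed(42)
  for (i in 1:100) {
    gw <- simulate_gwas_summary(co, tr, 1, cfg, causal_variant = NA)
    if (max(abs(gw$z)) >= 5) hits <- hits + 1L
  }
  expect_lte(hits, 1L)
})

test_that("tissue panel plants callable selective genes and is deterministic", {
  p1 <- simulate_tissue_panel(40, 100, list(fRPE = c("panelgene_0001",
                                                     "panelgene_0002")),
                              z_target = 5, seed = 9)
  p2 <- simulate_tissue_panel(40, 100, list(fRPE = c("panelgene_0001",
                                                     "panelgene_0002")),
                              z_target = 5, seed = 9)
  expect_identical(p1, p2)
  sc <- selectivity_zscores(p1)
  called <- call_selective(sc, "fRPE", 4, gene_meta = p1$gene_meta)
  expect_setequal(called, c("panelgene_0001", "panelgene_0002"))

  # no planted sets: z > 4 calls match the normal-tail null expectation
  p0 <- simulate_tissue_panel(40, 2000, list(), z_target = 5, seed = 10)
  n_called <- length(call_selective(selectivity_zscores(p0), "tissue_01", 4))
  # 2000 genes x P(z>4) under approximate normality; generous upper bound
  expect_lte(n_called, 2000 * pnorm(4, lower.tail = FALSE) * 40 + 3)
  expect_error(simulate_tissue_panel(40, 100, z_target = -1),
               "z_target")
  expect_error(simulate_tissue_panel(10, 100, z_target = 5),
               "unattainable")
})

test_that("allelic count haplotype sums equal the generated depth", {
  cfg <- sim_config(n_samples = 50, n_loci = 3, variants_per_locus = 5,
                    ase_depth = 30, seed = 12)
  co <- simulate_cohort(cfg)
  tr <- simulate_truth(co, cfg, prop_causal = 1)
  ex <- simulate_expression(co, tr, cfg)
  ase <- ex$glucose$ase
  tot <- ase$hap_ref_count + ase$hap_alt_count
  expect_true(all(tot >= 0))
  expect_equal(mean(tot), cfg$ase_depth, tolerance = 0.1)
})
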