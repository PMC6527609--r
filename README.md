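# rpeqtl

Allele-aware e/sQTL mapping, fine-mapping colocalization and
nonsense-mediated-decay (NMD) isoform modeling for small paired-design
cohorts — built around the analysis of cultured human fetal retinal
pigment epithelium (fRPE) assayed under two metabolic conditions
(glycolytic "glucose" vs. oxidative "galactose" media).

The RPE is poorly represented in large functional-genomics panels, yet
variants acting on its transcriptome are implicated in both monogenic
retinal disease and polygenic disorders such as age-related macular
degeneration (AMD) and myopia. This package provides the full
statistical toolchain such a study needs, with a synthetic-cohort
generator carrying known ground truth so that every stage is testable
without access to protected genotype data.

## What it computes

- **Tissue selectivity** — for gene medians *x* across tissues,
  *z = (x − μ)/σ*; genes with *z* > 4 in the focal tissue are selective
  (after sex-chromosome / mitochondrial / HLA filters), with rank-average
  expected-*z* QQ diagnostics and a Welch *t* comparison of disease gene
  sets.
- **Genotype QC** — missingness (> 5% removed), imputation allelic
  *r²* (< 0.8 removed), biallelic filter, per-chromosome Ts/Tv, sex from
  chrX heterozygosity, duplicate detection by pairwise dosage
  correlation, ancestry PCA on standardized dosages.
- **Allele-aware cis-eQTLs** — per gene × variant (± 500 kb of the TSS):
  OLS of normalized expression on dosage + covariates (*p_total*), an
  exact binomial test of aggregated alt-haplotype counts vs. 0.5 over
  heterozygotes (*p_ase*), Fisher-combined; allelic ratio
  *π = (alt+1)/(alt+ref+2)* and cross-condition imbalance change
  δ|π − 0.5|.
- **Hierarchical FDR** — Simes gene-level *p*, Benjamini–Hochberg across
  genes, Benjamini–Bogomolov level propagation to conditions and
  associations; genes labeled shared / condition-specific.
- **sQTLs** — LeafCutter-style intron clustering (shared donor/acceptor
  sites; ≥ 30 reads, ≥ 0.1% support, ≤ 100 kbp introns), intron-excision
  ratios, adaptive permutation scan (100–10,000 permutations,
  *p = (k+1)/(M+1)*), within-cluster Bonferroni + global BH.
- **Colocalization** — exhaustive Bayesian fine-mapping of GWAS and QTL
  z-scores (configurations up to *k* = 2, MVN summary-statistic
  likelihood), CLPP = Σᵢ PIP_gwas(i)·PIP_qtl(i); CLPP > 0.01 is
  colocalized, with an order-of-magnitude rule for condition-specific
  calls.
- **Two-step FDR specificity** — eGenes at FDR < 0.05 in both conditions
  and in no reference tissue at FDR < 0.1 are tissue-selective.
- **NMD isoform model** — closed-form solution of the three-constraint
  system (c_n = k_hom·c_m; c_n + a_n = k_het(c_m + a_m); c_t = r·a_t
  with p_n = 1) for the normally spliced fractions n_c, n_a of the two
  haplotypes and the NMD survival probability p_m of the mis-spliced
  isoform.

## Worked example

```r
library(rpeqtl)

## NMD model at the RDH5-style constants: 100:1 surviving normal to
## mis-spliced in reference homozygotes, 25:1 in heterozygotes, 3:1
## haplotype expression ratio
sol <- solve_isoform_model(nmd_inputs(k_hom = 100, k_het = 25, r = 3))
fr  <- implied_fractions(sol)
round(c(n_c = sol$n_c, n_a = sol$n_a, p_m = sol$p_m), 6)
#>      n_c      n_a      p_m
#> 0.818482 0.241347 0.045091
round(unlist(fr), 2)
#>       cc_mis_pct      het_mis_pct        hap_ratio nmd_degraded_pct
#>             0.99             3.85             3.00            95.49
```

So ~82% of reference-haplotype transcripts but only ~24% of
minor-haplotype transcripts are spliced normally, and NMD removes ~95%
of the mis-spliced isoform — which is why the mis-spliced form is ~1% of
surviving transcripts in reference homozygotes and ~4% in heterozygotes.

```r
## two-condition synthetic cohort: scan, then joint FDR with labels
cfg <- sim_config(n_samples = 23, n_loci = 8, variants_per_locus = 15,
                  seed = 5)
co <- simulate_cohort(cfg)
tr <- simulate_truth(co, cfg, prop_causal = 0.5)     # half the genes causal
ex <- simulate_expression(co, tr, cfg)
recs <- lapply(cfg$condition_names, function(cd)
  cis_scan(expression_matrix(ex[[cd]]$counts, tr$genes), as_geno(co),
           ase = ex[[cd]]$ase, condition = cd))
names(recs) <- cfg$condition_names
mc <- multi_condition_fdr(recs, q = 0.05)
mc$genes[mc$genes$selected, c("gene", "q_value", "label")]
#>     gene  q_value            label
#>   gene_1 5.23e-30           shared
#>   gene_3 1.40e-28           shared
#>   gene_4 2.86e-02 glucose-specific
#>   gene_7 7.99e-19 glucose-specific
#>   gene_8 7.27e-48           shared
```

At n = 23 the strongly planted eQTLs (β = 1.5, π = 0.75) are recovered
with extreme q-values (gene_7 is planted glucose-only); borderline
selections near q = 0.05 (gene_4, a null gene here) can be false
positives, which is exactly what the FDR level licenses.

An end-to-end demonstration (simulate → QC → selectivity → eQTL → sQTL →
coloc → specificity → NMD) with a JSON manifest:

```r
run_pipeline(system.file("extdata", "demo_config.json", package = "rpeqtl"))
```

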