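---
title: "Models and methods in rpeqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in rpeqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpeqtl)
```

# Scope

`rpeqtl` implements the statistical core of a two-condition quantitative
trait locus study in a specialized cell type: tissue-selectivity
scoring, genotype quality control, allele-aware cis-eQTL mapping under
hierarchical multi-condition FDR, intron-excision sQTL mapping,
fine-mapping-based colocalization with GWAS summary statistics, two-step
FDR tissue-specificity of eGenes, and a closed-form isoform-proportion
model for an exon-skipping variant subject to nonsense-mediated decay
(NMD). A synthetic-cohort generator with explicit ground truth makes
each stage testable end to end.

# Tissue-selectivity z-scores

For each gene, the per-tissue median expression $x$ is standardized
against the mean $\mu$ and the *sample* ($n-1$) standard deviation
$\sigma$ of that gene's medians across all tissues:
$z = (x - \mu)/\sigma$. Genes with $z$ strictly greater than 4 in the
focal tissue are called selective, after removing genes on sex
chromosomes, the mitochondrial chromosome, and the extended MHC/HLA
interval (default chr6:28,477,797–33,448,354, hg19; configurable), whose
low mappability inflates apparent expression.

Two choices were genuinely open and are fixed here:

- the focal tissue's own median is **included** in $\mu$ and $\sigma$,
  since the moments are defined "across tissues" without exclusion. This
  bounds the attainable $z$ at $(n-1)/\sqrt{n}$ for $n$ tissues, which
  is why the panel generator refuses targets above that bound;
- genes flat across tissues ($\sigma = 0$) get an undefined $z$ and are
  excluded from calling — "selective" has no meaning for them — rather
  than being assigned $z = 0$.

The QQ diagnostic pairs each tissue's sorted $z$ values with the
rank-wise mean over tissues of the corresponding order statistics; a
tissue inflated by technical structure separates from the diagonal at
the upper tail.

# Genotype quality control

Variant filters follow fixed boundary conventions: missingness uses a
strict greater-than at 5% (a site missing in exactly 5% of samples is
kept), while imputation quality retains sites at exactly the 0.8
allelic-$r^2$ threshold (removal is "< 0.8"). Hardy–Weinberg filtering
is deliberately omitted — in an admixed cohort HWE cannot distinguish
genotyping error from population structure — and multi-allelic variants
are removed instead. Transitions are A↔G and C↔T; a chromosome with zero
transversions reports Ts/Tv = +Inf with a warning rather than failing.

Sex is inferred from chrX heterozygosity relative to a per-sample
autosomal baseline; "approximately zero" is operationalized as
chrX heterozygosity below 10% of the baseline (configurable). Duplicate
detection flags sample pairs with Pearson dosage correlation at or above
0.9 — far above the null for thousands of variants. PCA standardizes
dosages by $\sqrt{2p(1-p)}$, the conventional variance under
Hardy–Weinberg, dropping monomorphic sites.

# Allele-aware cis-eQTL scan

The scan replaces a joint total/allelic likelihood (RASQUAL-style) with
two exactly testable components sharing its information structure:

1. **Total counts.** Expression is normalized as
   $\log_2(\mathrm{count}/s_j + 1)$ with median-of-ratios size factors
   $s_j$; a rank inverse-normal transform is available behind a flag.
   $p_{\mathrm{total}}$ is the two-sided $t$-test on the dosage
   coefficient of an OLS fit with covariates, computed by
   Frisch–Waugh residualization (exact, and vectorized across cis
   variants).
2. **Allelic imbalance.** Over samples heterozygous at the tested
   variant, alt-haplotype and ref-haplotype read counts are aggregated
   and tested against 0.5 with an exact two-sided binomial test, gated
   at $\ge 2$ heterozygotes and $\ge 10$ reads. The allelic ratio is
   reported with +1/+1 pseudocounts, $\pi = (a+1)/(a+r+2)$, avoiding
   degenerate 0/1 estimates at low depth.

The two p-values are Fisher-combined ($\chi^2_4$). Independence of the
total-count and allelic signals is an approximation — both derive from
the same reads — documented rather than corrected; the combined p-value
is used for ranking and hierarchical selection, where its calibration is
verified by simulation. The cis window is ±500 kb of the TSS, a decision
(echoing the colocalization window) since the source analysis never
states its eQTL window.

One consequence of median-of-ratios normalization worth knowing: a
confounder acting as a uniform per-sample scale factor is absorbed
entirely by the size factors. Only confounders with gene-specific
loadings need covariate correction, and the covariate-selection
procedure (empirically maximizing discoveries over nested candidate
sets on a seeded probe-gene subset, ties to the smaller set) is tested
against exactly that kind of plant.

# Hierarchical and multi-condition FDR

Gene-level p-values combine each gene's cis variants by Simes:
$p_{\mathrm{gene}} = \min_k m\, p_{(k)}/k$. Selection is
Benjamini–Hochberg across genes at $q$; within selected genes,
associations are BH-selected at the Benjamini–Bogomolov propagated
level $q \cdot R/m$ ($R$ selected of $m$ tested genes). The
multi-condition tree adds a condition level: Simes over all of a gene's
(condition, variant) p-values at level 1, per-condition Simes within
selected genes at level $q R_1/m_1$, and associations within selected
gene-conditions at $q R_2/m_2$, with $R_2/m_2$ counted over the
gene-condition pairs under selected genes. A gene selected in every
condition is "shared"; otherwise it is labeled specific to its selected
condition(s). Condition-specific eQTLs are ranked by the change in
allelic imbalance, $\delta|\pi - 0.5|$.

# sQTL mapping

Junction clustering mirrors LeafCutter: introns sharing a donor or
acceptor site (same chromosome and strand) form connected components;
introns longer than 100 kbp are removed, junctions below 0.1% of their
cluster total are dropped and components re-formed to a fixpoint, and
clusters need $\ge 30$ reads and $\ge 2$ introns. Note an emergent
behavior of the fixpoint: if the dropped junction was the only bridge,
the remainder disconnects and dissolves under the $\ge 2$-intron rule —
both outcomes are tested.

The phenotype is the intron-excision ratio (count over cluster total per
sample, NA when the cluster has no reads), centered and scaled per
intron. Association is simple linear regression on dosage with **no
covariates**: within-cluster ratios cancel sample-level effects, and
adding covariates was observed (in the source analysis) to reduce
discoveries. Significance uses adaptive permutations of the sample
labels: batches continue until 30 exceedances of the observed minimum
p-value have accumulated (after at least 100 permutations) or 10,000
permutations are reached; $p = (k+1)/(M+1)$. The "stop at 30
exceedances" rule is this package's concretization of "adaptively
permute 100–10,000 times"; a beta-approximation of the permutation null
is deliberately not the default. Within each cluster, intron p-values
are Bonferroni-corrected by the number of tested introns, the cluster
p is the minimum (ties on the granular permutation p broken by nominal
p when naming the lead intron), and BH across clusters gives the global
q. The sQTL window is ±100 kb of the cluster midpoint — smaller than the
eQTL window because splicing regulation is proximal; configurable.

# Fine-mapping and colocalization

For a locus with z-scores $z$ and LD matrix $R$ (in-sample dosage
correlation, ridge $10^{-3}$ on the diagonal for positive
definiteness), every causal configuration $c$ with $|c| \le k$
(default 2, exhaustive) is scored by the standard summary-statistic
likelihood $z \sim \mathcal{N}(0,\, R + s^2 R\,\mathrm{diag}(c)\,R)$
with non-centrality prior scale $s = 3.7$, and an independent
Bernoulli($p$) prior over variants, $p = \min(1/m, 0.5)$ by default
(the clamp matters only for single-variant loci, where $p = 1/m = 1$
would leave no null mass). The null configuration is included in the
normalization — no conditioning on at least one causal variant. PIPs
marginalize over configurations; the locus CLPP is
$\sum_i \mathrm{PIP}^{\mathrm{GWAS}}_i\,\mathrm{PIP}^{\mathrm{QTL}}_i$
(a max-over-variants option exists behind a flag). CLPP > 0.01 is
colocalized; a condition-specific call requires one condition above the
threshold and the other both below it and at least a factor of 10
smaller (inclusive). Exhaustive enumeration replaces stochastic shotgun
search: exact at locus scale ($m \le 1000$ for $k = 2$) and directly
checkable against brute force, which the test suite does to $10^{-10}$.

# Two-step FDR specificity

Discovery eGenes must be significant (q < 0.05, strict) in **both**
conditions — condition-shared signals are unlikely to be treatment
artifacts. A discovery gene is tissue-selective if no reference tissue
replicates it at the relaxed q < 0.1; genes missing from the reference
panel count as not significant, the only workable convention for genes
untested in a tissue.

# The NMD isoform-proportion model

Let $n_c, n_a$ be the fractions of reference- and minor-haplotype
transcripts spliced normally, and $p_m$ the probability that a
mis-spliced (frameshifted, PTC-bearing) transcript escapes NMD; the
normal isoform is assumed immune ($p_n = 1$). Three observables
constrain the model (defaults in parentheses): surviving
normal:mis-spliced of $k_{hom}$:1 in reference homozygotes (100),
$k_{het}$:1 in heterozygotes (25), and a surviving haplotype ratio $r$
(3). With $u = (1-n_c)p_m$ and $v = (1-n_a)p_m$ the system is linear up
to the closure $u(1-n_a) = v(1-n_c)$ and is solved by elimination at
runtime — no transcribed closed-form constants — giving, at the
defaults, the exact rationals $n_c = 6200/7575 \approx 0.8185$,
$n_a \approx 0.2413$, $p_m = 62/1375 \approx 0.0451$. A 1-D
root-finding reduction of the original nonlinear system cross-checks
every solve. Two identities fall out for any feasible inputs and serve
as tests: the surviving mis-spliced share is exactly $100/(k_{hom}+1)$%
in reference homozygotes and $100/(k_{het}+1)$% in heterozygotes.

Degeneracies are diagnosed rather than silently returned:
$k_{hom} = k_{het}$ forces $n_c = n_a$, which contradicts any
$r \neq 1$ and is under-determined at $r = 1$ — a singular-system
error; solutions escaping $(0,1)$ raise an infeasibility error; the
sensitivity scanner flags such cells and completes.

# The synthetic cohort: what it is and is not

The generator states a world and the tests live in it:

- **Genotypes**: haplotypes from a copying model — first variant of a
  locus Bernoulli(MAF), subsequent variants copy the previous allele
  with probability `ld_copy_prob` (default 0.9), giving geometrically
  decaying LD. Defaults emulate the paired design: 23 samples, two
  conditions sharing genotypes with independent expression noise.
- **Expression**: gene totals negative binomial with log-mean shifted by
  $\beta \cdot$ dosage at the causal variant (`depth_mean` 500,
  dispersion 10); allelic counts binomial($\mathrm{Pois}(50)$, $\pi$)
  per heterozygote, beta-binomial overdispersion behind a flag, default
  off. Homozygotes contribute no allelic rows.
- **Splicing**: each planted cluster has the canonical three-junction
  exon-skipping topology (two inclusion junctions and one skipping
  junction sharing a donor with one and an acceptor with the other);
  the skipping fraction follows
  $\mathrm{logit}(f) = \mathrm{logit}(f_0) + \mathrm{skip\_effect}
  \cdot \mathrm{dosage}$, so 0 is the exact null and the planted
  heterozygote/homozygote skipping ratio approaches
  $e^{\mathrm{skip\_effect}}$ at small baselines.
- **GWAS**: $z \sim \mathcal{N}(\sqrt{n}\,R\lambda,\, R)$ with the
  causal variant shared with the QTL or deliberately placed in low LD.
- Effect sizes, windows and the eQTL effect distribution are free
  parameters of the generator, not calibrated to any real cohort — the
  source analysis does not publish them. Coordinates are 1-based
  inclusive everywhere in memory; 0-based half-open conversion happens
  only at the junction-BED boundary.

What a green test does **not** establish: the generator has no read-level
error, no GC or mappability structure, no imputation uncertainty beyond
a stored quality score, no population demography, and condition effects
are independent noise rather than correlated treatment response. Counts
of discoveries from the real cohort (hundreds of e/sQTLs, specific gene
lists) are therefore out of reach by construction and are not asserted
anywhere; what is asserted is calibration (FDR control under the global
null), power on planted effects, and exact agreement of the analytical
components with independent oracles.

# Numerical choices

- p-values are clipped to $[\texttt{.Machine\$double.xmin}, 1]$ before
  Fisher combination; Simes returns NA on empty input.
- The OLS path loses one degree of freedom per covariate plus the
  intercept and the dosage; scans refuse rank-deficient covariate
  matrices.
- Permutation p-values are bounded below by $1/(M+1)$ by construction;
  tests assert the bound and the floor.
- `ld_matrix` maps undefined correlations (monomorphic variants) to 0
  and shrinks off-diagonals by the ridge before restoring the unit
  diagonal.
- Reproducibility: every generator is a pure function of (config, seed);
  the pipeline derives per-stage seeds from the global seed by a fixed
  counter, and manifests contain no timestamps so reruns are
  byte-identical.

# Known limitations

- Fisher combination overstates independence of the total and allelic
  signals; combined p-values are conservative-to-liberal depending on
  depth, which is why FDR calibration is tested on the combined path.
- The binomial ASE test ignores overdispersion unless the generator's
  beta-binomial flag is used; real allelic data are usually
  overdispersed.
- Exhaustive fine-mapping is quadratic in locus size at $k = 2$; larger
  loci need $k = 1$ or an external fine-mapper.
- The NMD model treats the three input constants as known; in practice
  they are themselves estimates (from allelic ratios and junction
  proportions) with sampling error the model does not propagate.
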