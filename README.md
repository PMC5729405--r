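# polyQTL

Genome-wide mapping of the genetic control of gene expression in
family-structured cohorts, combining two complementary analyses:

* an **expression GWAS (eGWAS)** — every expressed probe tested against
  every SNP under a polygenic mixed model (fixed batch/sex effects, genomic
  kinship random effect, family-based score test), with two-level
  Benjamini–Hochberg FDR (per probe and global), conditional pruning of
  linkage-redundant SNPs to lead **eQTL-SNPs** within a 5 Mb window, and
  local/distant classification at an inclusive 1 Mb boundary (the standard
  proxies for *cis*/*trans* regulation);
* an **allele-specific expression (ASE)** caller — exact two-sided binomial
  tests of ref/alt read counts at heterozygous sites, per-animal FDR, and
  aggregation to ASE-SNPs when more than a third of heterozygous animals
  show significant imbalance, mapped to overlapping genes.

Downstream, significant associations become directed bipartite SNP→gene
networks with component summaries, master-regulator detection (SNPs with
≥ 10 targets), and PCIT filtering of co-expression edges. A synthetic
half-sib cohort generator with known cis/trans architecture backs the whole
pipeline with ground-truth calibration and power studies.

## The model in brief

For a probe's expression $y$ over $n$ related animals:

$$y = X\beta + u + e,\qquad u \sim N(0, \sigma_g^2 K),\quad
  e \sim N(0, \sigma_e^2 I)$$

with $K$ the per-SNP-standardized genomic kinship matrix. The null model is
fit by REML profiled over $h^2$ on the eigenbasis of $K$ (shared across
probes), and each SNP $g$ is screened with the score statistic

$$T = \frac{(\tilde g^\top \hat V^{-1}\tilde y)^2}
           {\tilde g^\top \hat V^{-1}\tilde g}\ \sim\ \chi^2_1 .$$

An association is significant when its p-value clears both the per-probe
and the global BH thresholds; significant SNPs within 5 Mb of a lead SNP
must stay significant conditional on that lead's dosage or they are pruned
as redundant.

## Worked example

```r
library(polyQTL)

cfg <- simConfig(nSires = 8, progenyPerSire = 30, nSnps = 120, nProbes = 15,
                 nCisEffects = 2, nTransEffects = 1, h2Polygenic = 0.4,
                 seed = 42)
cohort <- simulateCohort(cfg)           # genotypes + expression + allele counts

qc <- filterGenotypes(cohort$geno)      # call rate, MAF, exact HWE w/ BH
K  <- computeGenomicKinship(qc$geno)
eg <- twoLevelFdr(runEgwas(cohort$expr, qc$geno, K = K))
eg
#> EgwasResult: 15 probes x 120 SNPs = 1800 tests
#>   significant associations: 3

eqtl <- classifyLocalDistant(pruneToEqtlSnps(eg), probeAnnotation(cohort$expr))
eqtl$ratio <- effectSdRatio(eqtl$beta, intensities(cohort$expr),
                            probe = eqtl$probe)
eqtl[, c("probe", "snp", "chrom", "pos", "p", "regulation", "ratio")]
#>       probe     snp chrom      pos        p regulation ratio
#> 1 probe0001 snp0055     1 43814988 3.81e-05      local 1.130
#> 2 probe0002 snp0102     2 35272222 6.42e-07      local 0.911
#> 3 probe0003 snp0007     1  5322648 9.88e-11    distant 0.805
```

The cohort was simulated with exactly three 1-SD effects — cis SNPs
`snp0055` and `snp0102`, trans SNP `snp0007` — and all three are recovered
as eQTL-SNPs at the causal SNP with the correct local/distant label. The
`ratio` column is the eQTL effect over the probe's expression SD (≈ 1 here
because effects were simulated at 1 SD). The ASE caller independently
confirms the two cis sites:

```r
ase <- runAse(cohort$alleleCounts)
ase$calls[which(ase$calls$is_ase), ]
#>   contig position ref alt n_het n_significant is_ase
#> 1      1 43814988   A   G    32            28   TRUE
#> 2      2 35272222   A   G    57            47   TRUE
```

`runPipeline(inputDir, outDir)` drives the full chain (QC → probe filter →
eGWAS → ASE → integration → networks) from TSV inputs, writing every result
table with a provenance header plus `network.sif`, per-stage counts and a
JSON summary; `writeCohort()` serializes a simulated cohort into that input
layout, including `truth.json`.

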