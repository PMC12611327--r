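# methyLink

Integration of RRBS methylomes with matched transcriptomes and amyloid
neuropathology in mouse models of Alzheimer's disease.

## What problem this solves

Reduced representation bisulfite sequencing (RRBS) yields, for every CpG and
sample, a pair of read counts (methylated, total). Studies of AD-model mice
under dietary intervention ask a chain of questions of such data: which CpGs
are differentially methylated between genotypes or diets after adjusting for
sex, age and cell composition; which of those CpGs are statistically linked
to the expression of a gene, nearby or far away on the same chromosome;
whether those expression-linked CpGs (ECpGs) cluster into regions and sit
near distal enhancer or CTCF elements; which CpGs track amyloid plaque
burden; and which genes the intervention "protects" from genotype-driven
expression change. methyLink implements that full chain as composable R
functions for epigenomics analysts, with a synthetic-data generator that
reproduces the study design (2 genotypes x 2 diets x 4 ages x 2 sexes x 3
replicates, two brain regions) with planted effects, so every stage has
parameter-recovery tests.

## The models

* **Differential methylation** (per CpG): binomial logistic regression of
  (methylated, unmethylated) counts,

  `logit P(meth) = b0 + b1 * contrast + b2 * sex + b3..k * LMCs (+ b * age)`

  Wald test on the contrast term, Benjamini-Hochberg FDR across sites, DMC
  iff q < 0.05. Sites are pre-filtered (depth >= 10, below the per-sample
  99.9th depth percentile, covered in >= 50% of samples).

* **ECpG regression** (per CpG-gene pair): ordinary least squares of
  z-scaled variance-stabilized expression on z-scaled percent methylation
  plus age, sex and latent cell-proportion covariates, so the reported
  `beta_methylation` is standardized. One outlier pass removes points with
  Cook's distance > 4/n *and* |standardized residual| > 3, then refits once.
  Local pairs (CpG mapped to the gene; |delta| > 2.5 points, DE gene with
  |log2FC| > 0.1) are called at raw p < 0.05; distal pairs (same chromosome,
  |delta| > 5 points, top-1000 DE genes, cis windows excluded) at BH
  q < 0.05.

* **DMRs**: single-linkage chaining of ECpGs with consecutive gaps
  <= 500 bp, at least 2 CpGs per region.

* **Regulatory enrichment**: permutation test of the count of ECpGs whose
  +/-1 kb window hits an EnhD/CTCF element, null drawn from the tested-CpG
  universe preserving per-chromosome counts.

* **Plaque-associated CpGs** (PACs): binomial GLM of methylation proportion
  with prior weights = read depth and a logarithmic link,

  `log P(meth) = b0 + beta_amyloid * Abeta42_pct_area + age + sex + diet`

  fit in mutant samples, with a logistic fallback when the log link pins at
  the boundary, BH FDR over the tested ECpG set, and diet-stratified
  classification (control_only / supplemented_only / both / neither).

* **Choline-protected genes**: DE (FDR < 0.05) in mutant-vs-WT under the
  control diet but not (FDR > 0.05) under the supplemented diet; ranked by
  control-contrast FDR, top 2000 kept, joined to gene-level methylation.

## Worked example

```r
library(methyLink)

cfg   <- simulationConfig(seed = 42, n_cpgs = 800, n_genes = 150,
                          regions = "cortex")
study <- simulateStudy(cfg)
study$mm
#> MethylMatrix with 800 CpG sites x 96 samples
#>   mean covered depth: 30.1 | uncovered cells: 2

mm  <- filterSites(study$mm)
dmc <- testDmc(mm, contrast = "genotype", genes = geneModel(study$genes))
sum(dmc$is_dmc, na.rm = TRUE)
#> 101                      # of 800 tested CpGs; ~100 carry planted effects

ecpg <- runIntegration("local", dmc, study$expr$de$cortex$genotype,
                       study$expr$vst, mm)
sum(ecpg$is_ecpg)
#> 73                       # of 104 candidate CpG-gene pairs
head(ecpg[ecpg$is_ecpg, c("pos", "gene_id", "beta_methylation", "p_value")], 2)
#>     pos  gene_id beta_methylation      p_value
#>   24947 gene0001       -0.8396575 1.859612e-11
#>   72537 gene0005        0.6445741 9.152805e-05

buildDmrs(data.frame(chrom = "chr1", pos = c(100, 550, 560, 2000),
                     delta_pct = 5))
#>   chrom start end n_cpgs mean_delta_pct ...   # one region, 3 members;
#>   chr1    100 560      3              5       # 2000 is > 500 bp away

pac <- testPacs(mm, unique(ecpg[ecpg$is_ecpg, c("chrom", "pos")]))
sum(pac$is_pac, na.rm = TRUE); pac$beta_amyloid[which(pac$is_pac)[1]]
#> 15
#> -0.229                   # planted amyloid effect is -0.2 per % area
```

The `beta_methylation` column is the standardized methylation coefficient of
the expression regression (negative: higher methylation, lower expression);
`beta_amyloid` is on the log link scale per unit percent plaque area.
`runPipeline(out_dir, sim = cfg)` runs every stage for both contrasts and
regions and writes per-stage TSVs plus a hash manifest.

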