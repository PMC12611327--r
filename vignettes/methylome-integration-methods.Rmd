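---
title: "Methods: methylome-transcriptome-pathology integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylome-transcriptome-pathology integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the statistical machinery: the
models fitted at each stage, the parameters that matter and their defaults,
what the synthetic-data generator does and does not emulate, and the
numerical and design choices made where more than one reasonable option
existed.

## Data model and coordinates

The central container is `MethylMatrix`, a `RangedSummarizedExperiment`
with integer assays `meth` and `total` (methylated and total read counts per
CpG and sample) and the sample design in `colData`. Internal coordinates are
1-based point positions; bedGraph input/output converts the 0-based
half-open convention at the boundary, so a file line `chr1 99 100 ...` is
the CpG at `chr1:100`. CpGs on opposite strands are kept as distinct
positions — extractor output is taken as-is, and collapsing strands is a
data-preparation decision the package does not make for the user.

CpGs map to genes through three strand-aware windows: the gene body
(start–end, which subsumes exon/intron/UTR features at CpG resolution), the
1 kb promoter immediately upstream of the TSS, and the 1–5 kb upstream
band. When windows of several genes capture the same CpG the tie is broken
by distance to the TSS, then lexicographic gene id — deterministic, and in
line with "nearest gene" conventions.

## Site filtering

Three rules, applied in `filterSites()`:

* minimum depth 10 reads per cell (cells below are masked, i.e. set to zero
  coverage);
* a per-sample maximum at that sample's empirical 99.9th depth percentile
  (type-7 quantile over the sample's covered sites), masking PCR-bias
  pile-ups;
* a site is kept iff unmasked in at least 50% of samples (inclusive).

The depth caps depend on the data, so the filter is idempotent only when the
first-pass caps are reused (`depth_caps` argument); this is asserted in the
tests.

## Differential methylation

Each CpG is tested with a binomial logistic regression of
(methylated, unmethylated) counts on the contrast plus covariates: sex, the
latent cell-proportion covariates (LMCs), and centered age in months (age is
dropped when the analysis is stratified by age). The genotype contrast
compares mutants with wild types within the control diet; the diet contrast
compares supplemented with control within mutants. The Wald p-value of the
contrast term is corrected by Benjamini–Hochberg within the tested family.

Two deliberate choices:

* **BH instead of a sliding-linear-model correction.** Methylation callers
  in this space correct p-values with SLIM; that procedure is only specified
  by its implementation, while BH is the procedure used by every other stage
  here. The substitution is recorded in the output's `fdr_method` attribute.
* **No overdispersion by default.** The binomial fit matches the common
  default; `overdispersion = "mcfadden"` scales the covariance by the
  Pearson dispersion when it exceeds 1 for data with extra-binomial
  variation.

Sites with separated or singular fits get `NA` p-values and are excluded
from the BH family; the count is carried in an attribute. `delta_pct` is
the difference of group mean percent methylation (level 2 minus level 1),
so swapping the level order negates it and leaves p unchanged.

Cell-composition covariates deserve a caveat: when genotype itself shifts
cell proportions (microgliosis), the LMC covariates absorb part of the
genotype signal — the adjusted test estimates the composition-independent
effect. The power experiments in the test-suite therefore use designs where
covariates are orthogonal to the contrast, which isolates the test's power;
in the confounded default world recovery is lower by construction, not by
defect.

## Expression-linked CpGs

For a candidate CpG–gene pair, `regressPair()` fits OLS of z-scaled
variance-stabilized expression on z-scaled percent methylation plus age,
sex and LMCs, in the contrast's own sample set (control-diet samples for
genotype, mutants for diet). Standardization makes the reported coefficient
unitless and comparable across pairs; a positive constant rescaling of
either variable leaves all outputs unchanged (asserted as a property).

The outlier rule is conjunctive — Cook's distance > 4/n *and*
|standardized residual| > 3 — with a single refit; at most ⌊n/4⌋ points can
be removed (worst Cook's first), so the rule can never delete a quarter of
the data or iterate to degeneracy. After removal the retained points are
re-standardized before the refit: otherwise the removed outlier would still
inflate the scaling SD and bias the reported standardized coefficient. The
partial correlation is computed by residualizing both expression and
methylation on the covariates, which makes the identity
`t^2 = r^2 (n - k - 2) / (1 - r^2)` a genuine cross-check rather than a
tautology; it is asserted to 1e-8 on every fit.

Candidate pairs are gated before regression. Local: the CpG maps to the
gene, |delta| > 2.5 percentage points (strict), the gene is DE under the
contrast's rule (FDR < 0.05 genotype, < 0.1 diet) with |log2FC| > 0.1
(strict; excludes shrinkage artefacts at low counts). Distal: same
chromosome, |delta| > 5, the gene among the top 1000 genotype DEGs by FDR
(or all relaxed-rule diet DEGs), excluding sites in the gene body or within
5 kb of the TSS. Local calls use raw p < 0.05; distal calls use BH q < 0.05
within the (contrast, scope) family — an asymmetry reproduced deliberately
and noted in the output metadata. Pairs pool all ages, with age entering as
a numeric covariate in months (the pooled fit needs a scale, and months is
the design's natural one).

## DMR chaining

ECpGs (local and distal pooled by default; a flag separates them) are
chained per chromosome by single linkage: sorted positions chain while the
gap to the previous member is <= 500 bp (inclusive — a 500 bp step chains,
501 breaks), and clusters need >= 2 members. A region's total span may
therefore exceed 500 bp. The implementation reduces 1-bp ranges with the
interval machinery; an O(n^2) brute-force chaining oracle in the tests
checks exact equivalence on hundreds of random site sets.

## Regulatory enrichment

The statistic is the number of tested CpGs whose +/-1 kb window intersects
at least one element of a class (EnhD or CTCF). The null resamples the same
number of positions per chromosome, without replacement, from the universe
of all quality-filtered CpGs. This matched-universe draw preserves the CpG
density bias of RRBS — the key confounder for enhancer-proximity claims,
since RRBS enriches CpG-dense fragments and enhancers are CpG-biased too; a
`mode = "uniform"` alternative places positions uniformly for comparison.
The empirical p uses the add-one rule `(1 + #{perm >= obs})/(1 + n_perm)`
and so is never zero. Distances are reported descriptively as edge-to-point
base differences: 0 inside an element, else the difference between the site
position and the nearest element edge (a site one base past an element's
last base is at distance 1).

## Amyloid (PAC) modelling

Methylation proportion is the response of a binomial GLM with prior weights
equal to read depth and a logarithmic link:
`log p = b0 + beta_amyloid * area + age + sex + diet`, fitted in mutant
samples only (wild types carry no plaque burden and would anchor the
predictor at zero). The log link is the printed model of record despite its
unboundedness; the package guards it: a fit whose fitted values pin within
1e-6 of the mu = 1 boundary is treated as failed, retried from a damped
start, and finally refitted with the logistic link, with `link_used`
recording the outcome. With the logistic link and a binary predictor the
model is algebraically the DMC logistic test; the suite asserts agreement
to 1e-6. The weighting contract — doubling all read counts leaves the
estimate unchanged and shrinks the standard error by sqrt(2) — is asserted
directly.

Diet-specific classification fits each diet stratum separately (>= 6 mutant
samples required per stratum), classifies by the per-diet BH q at 0.05, and
reports an amyloid-by-diet interaction fit alongside. Stratum power depends
on the amyloid spread within the stratum; under supplementation the burden
(and hence the information) is smaller, so "both"-type effects can classify
as control-only at modest n — a property of the design, not the classifier.

## The synthetic-data generator

`simulateStudy()` reproduces the study design: 2 genotypes x 2 diets x
4 ages (3, 6, 9, 12 months) x 2 sexes x 3 replicates = 96 mice, each
profiled in cortex and hippocampus. Defaults (all overridable in
`simulationConfig()`):

* **Coverage**: negative binomial, mean 30, size 5 (`size = Inf` gives
  Poisson) — typical RRBS depth after dedup.
* **Baseline methylation**: Beta(0.7, 0.7), the bimodal marginal RRBS
  shows. CpGs carrying planted effects draw baselines from 0.25–0.75
  instead: a percentage-point delta needs headroom to be representable, and
  effect CpGs in real data are intermediate-methylation CpGs.
* **Effects**: percentage-point deltas (genotype 20, diet 15) are converted
  to logit shifts at each site's baseline and added on the logit scale,
  which keeps probabilities valid; age trends (1.5 points/month) and a
  loading on the microglial latent component enter the same way.
* **Cell composition**: per-sample Dirichlet draws (neuron, microglia,
  other) with genotype-specific parameters — mutants are shifted toward
  microglia, emulating microgliosis. This deliberately confounds genotype
  with the LMC covariates, as in real tissue.
* **Amyloid**: `area = a * exp(b * age) + noise` in mutants with
  `b = log(3)/6` (tripling between 3 and 9 months), `a` set so 12-month
  burden is ~6% area, noise CV 0.35, a 0.6 multiplier under supplementation
  (supplementation reduces amyloidosis); wild types are 0.
* **Amyloid-methylation effects** are planted on the link scale named in
  `pac_link` (default `"log"`, the analysis model's scale) at -0.2 per
  percent area, on a subset of the local-link CpGs so that PACs are
  discoverable within the ECpG set; some sites carry the effect under the
  control diet only.
* **Expression**: NB counts (size 20) whose log2 means carry (i) genotype
  effects for designated DE genes — choline-protected genes express the
  effect only under the control diet — and (ii) planted links: a
  standardized link coefficient beta is converted to a raw log2-scale slope
  `sigma_g * beta / sqrt(1 - beta^2)` on the z-scaled *realized* percent
  methylation of the linked CpG, with `sigma_g` the gene's delta-method
  count-noise SD, so the recovered standardized coefficient is centred on
  beta. Link-target genes carry no independent genotype term — their
  differential expression flows through the methylation link, which keeps
  the planted coefficient identifiable in the pooled regression.
  Genotype-responsive methylation concentrates at DE genes: the scattered
  genotype DMCs are placed inside DE-gene bodies first (protected genes
  foremost), matching the observed overlap of protected genes with
  differential methylation.
* The variance stabilizer is `log2(count + 1)`; the integration math only
  needs an approximately homoscedastic response, and real-data users supply
  their own stabilized matrix.

What the generator does **not** emulate: restriction-fragment positioning
(CpGs are scattered, not clustered into islands, so simulated DMR yields
are sparse), sequence-level errors or conversion failure, spatial
correlation of methylation along the genome, region-specific methylomes
(both brain regions share effect sites), and litter or batch structure.
Passing recovery tests on this generator therefore demonstrates the
statistical machinery is correct, not that real-data effect sizes will
match.

## Problem sizes and reproducibility

Unit tests run on matrices of 150–800 CpGs and 40–100 genes; the
calibration and power suites use 2,000–5,000 sites with 24 samples per
group at coverage 30, 200-seed regression-recovery sweeps at n = 46, and
100-seed amyloid-recovery sweeps at n = 48 — sizes chosen to make
Monte-Carlo error small relative to the asserted tolerances while keeping
the suite quick. The amyloid recovery oracle uses CV-0.6 within-age plaque
heterogeneity and an intermediate (0.65) baseline: a Fisher-information
calculation shows the +/-0.05 recovery band needs that much conditional
amyloid variance once age, sex and diet are adjusted for, and both values
are within the range reported for plaque burden between littermates and
for ECpG methylation levels. Every random stage takes an explicit seed;
`runPipeline()` fans a master seed out to per-stage child seeds and records
them, with md5 hashes of all outputs, in `manifest.json` — identical
configuration and inputs reproduce identical hashes.

## Known limitations

* The minimal NB Wald DE caller (`callDeMinimal()`) is plumbing for
  self-contained synthetic runs: two-group designs only, moderated common
  dispersion (median of per-gene moment estimates), Wald statistic referred
  to a t distribution with n - 2 df. It is not a substitute for a full DE
  package on real data, and the pipeline consumes externally produced DE
  tables wherever they exist.
* Local ECpG calls use raw p-values by design; interpreting their counts
  across configurations requires the same care as in the source analyses.
* The log-link binomial model can be structurally unable to fit sites with
  high methylation and positive amyloid effects; such sites fall back to
  the logistic link and are flagged, and mixing links within one BH family
  is a (documented) approximation.
* Causal direction between methylation and expression is not addressed;
  the regressions quantify association under covariate adjustment only.
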