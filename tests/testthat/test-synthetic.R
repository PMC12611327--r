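# A configuration with no planted effects, for marginal/null checks.
null_cfg <- function(seed = 1, n_cpgs = 400, n_per_cell = 1,
                     regions = "cortex", ...) {
  simulationConfig(seed = seed, n_cpgs = n_cpgs, n_genes = 50,
                   n_per_cell = n_per_cell, regions = regions,
                   n_dmc_genotype = 0, n_dmc_diet = 0, n_age_sites = 0,
                   n_links_local = 0, n_links_distal = 0, n_lmc_sites = 0,
                   n_de_genes = 0, n_protected = 0, n_pac = 0,
                   n_pac_diet_specific = 0, lmc_gamma = 0, ...)
}

test_that("the design reproduces the study layout", {
  d3 <- simulateDesign(simulationConfig(n_per_cell = 3))
  for (r in c("cortex", "hippocampus")) {
    dr <- d3[d3$region == r, ]
    expect_equal(nrow(dr), 96L)
    cells <- table(dr$genotype, dr$diet, dr$age_months, dr$sex)
    expect_true(all(cells == 3L))
  }
  expect_equal(length(unique(d3$mouse_id)), 96L)
  d1 <- simulateDesign(simulationConfig(n_per_cell = 1, regions = "cortex"))
  expect_equal(nrow(d1), 32L)
  da <- simulateDesign(simulationConfig(n_per_cell = 3, ages = 3,
                                        regions = "cortex"))
  expect_equal(nrow(da), 24L)
})

test_that("amyloid burden is zero in WT and grows with age in mutants", {
  d <- simulateDesign(simulationConfig(seed = 5))
  expect_true(all(d$amyloid_pct_area[d$genotype == "WT"] == 0))
  app <- d[d$genotype == "AppNLGF" & d$diet == "control", ]
  m <- tapply(app$amyloid_pct_area, app$age_months, mean)
  expect_true(all(diff(m) > 0))
  # the configured mean time course triples every six months
  cfg <- simulationConfig()
  expect_equal(exp(cfg$amyloid_rate * 6), 3)
  mu_expect <- cfg$amyloid_base * exp(cfg$amyloid_rate * sort(unique(app$age_months)))
  expect_equal(as.numeric(m), mu_expect,
               tolerance = 4 * cfg$amyloid_cv / sqrt(6))
  sup <- d[d$genotype == "AppNLGF" & d$diet == "supplemented", ]
  expect_lt(mean(sup$amyloid_pct_area), mean(app$amyloid_pct_area))
})

test_that("same seed reproduces the study bit-identically; seeds differ", {
  cfg <- simulationConfig(seed = 8, n_cpgs = 200, n_genes = 60,
                          n_dmc_genotype = 10, n_dmc_diet = 10,
                          n_links_local = 30, n_links_distal = 5,
                          n_de_genes = 20, n_protected = 5,
                          n_lmc_sites = 5, n_age_sites = 5,
                          regions = "cortex")
  a <- suppressWarnings(simulateStudy(cfg))
  b <- suppressWarnings(simulateStudy(cfg))
  expect_identical(methReads(a$mm), methReads(b$mm))
  expect_identical(a$expr$counts, b$expr$counts)
  expect_identical(a$samples, b$samples)
  cfg2 <- cfg; cfg2$seed <- 9L
  c2 <- suppressWarnings(simulateStudy(cfg2))
  expect_false(identical(methReads(a$mm), methReads(c2$mm)))
})

test_that("read-depth marginals match the configured distribution", {
  cfg <- null_cfg(seed = 2, n_cpgs = 10000)
  sim <- suppressWarnings(simulateMethylation(cfg, simulateDesign(cfg)))
  expect_equal(mean(totalReads(sim$mm)), cfg$coverage_mean, tolerance = 0.02)
  # Poisson depth limit: fraction of cells below the depth-10 filter matches
  # the closed-form Poisson CDF
  cfgp <- null_cfg(seed = 3, n_cpgs = 5000, coverage_size = Inf,
                   coverage_mean = 10)
  simp <- suppressWarnings(simulateMethylation(cfgp, simulateDesign(cfgp)))
  expect_equal(mean(totalReads(simp$mm) < 10), ppois(9, 10),
               tolerance = 0.02)
})

test_that("baseline methylation follows the Beta prior (calibrated over seeds)", {
  pass <- vapply(1:10, function(s) {
    cfg <- null_cfg(seed = 100 + s, n_cpgs = 300)
    sim <- suppressWarnings(simulateMethylation(cfg, simulateDesign(cfg)))
    ks <- suppressWarnings(
      ks.test(sim$truth$plan$baseline,
              pbeta, cfg$baseline_alpha, cfg$baseline_beta))
    ks$p.value > 0.01
  }, logical(1))
  expect_gte(sum(pass), 8)
})

test_that("null simulation shows no genotype effect; planted deltas realize", {
  cfg <- null_cfg(seed = 4, n_cpgs = 300, n_per_cell = 3)
  sim <- suppressWarnings(simulateMethylation(cfg, simulateDesign(cfg)))
  cd <- as.data.frame(SummarizedExperiment::colData(sim$mm))
  pct <- methPct(sim$mm)
  app <- cd$genotype == "AppNLGF"
  dbar <- rowMeans(pct[, app], na.rm = TRUE) -
    rowMeans(pct[, !app], na.rm = TRUE)
  # binomial s.e. of a group-mean difference at this depth and n
  se <- sqrt(2 * 2500 / (cfg$coverage_mean * 48))
  expect_lt(mean(abs(dbar) > 3 * se), 0.02)

  cfg2 <- simulationConfig(seed = 6, n_cpgs = 300, n_genes = 70,
                           n_dmc_genotype = 50, genotype_delta = 20,
                           n_dmc_diet = 0, n_links_local = 30,
                           n_links_distal = 5, n_de_genes = 30,
                           n_protected = 10, n_lmc_sites = 0,
                           n_age_sites = 0, n_pac = 0,
                           n_pac_diet_specific = 0, regions = "cortex")
  sim2 <- suppressWarnings(
    simulateMethylation(cfg2, simulateDesign(cfg2)))
  tr <- sim2$truth$dmcs
  tr <- tr[tr$contrast == "genotype" & tr$delta == 20, ]
  pct2 <- methPct(sim2$mm)
  cd2 <- as.data.frame(SummarizedExperiment::colData(sim2$mm))
  lab <- siteLabels(sim2$mm)
  rows <- match(paste0(tr$chrom, ":", tr$pos), lab)
  app2 <- cd2$genotype == "AppNLGF"
  dhat <- rowMeans(pct2[rows, app2], na.rm = TRUE) -
    rowMeans(pct2[rows, !app2], na.rm = TRUE)
  expect_equal(mean(dhat), 20, tolerance = 0.15)
})

test_that("truth tables record every planted effect exactly once", {
  cfg <- simulationConfig(seed = 12, n_cpgs = 250, n_genes = 70,
                          n_dmc_genotype = 15, n_dmc_diet = 12,
                          n_links_local = 30, n_links_distal = 8,
                          n_de_genes = 25, n_protected = 9,
                          n_lmc_sites = 5, n_age_sites = 5,
                          n_pac = 10, n_pac_diet_specific = 4,
                          regions = "cortex")
  st <- suppressWarnings(simulateStudy(cfg))
  tr <- st$truth
  expect_equal(sum(tr$dmcs$contrast == "genotype"), 15 + 30 + 8)
  expect_equal(sum(tr$dmcs$contrast == "diet"), 12)
  expect_equal(nrow(tr$links), 38)
  expect_equal(sum(tr$links$scope == "distal"), 8)
  expect_equal(nrow(tr$pacs), 14)
  expect_equal(length(tr$protected), 9)
  expect_false(anyDuplicated(paste(tr$dmcs$chrom, tr$dmcs$pos,
                                   tr$dmcs$contrast)) > 0)
  # planted link sites lie within (local) or well outside (distal) the
  # target gene's cis window
  gm <- st$genes
  for (k in seq_len(nrow(tr$links))) {
    g <- gm[gm$gene_id == tr$links$gene_id[k], ]
    inside <- tr$links$pos[k] >= g$start && tr$links$pos[k] <= g$end
    if (tr$links$scope[k] == "local") expect_true(inside)
    else expect_true(!inside &&
                       abs(tr$links$pos[k] - g$tss) > 5000)
  }
})

test_that("written study directories can be read back", {
  cfg <- simulationConfig(seed = 13, n_cpgs = 150, n_genes = 60,
                          n_dmc_genotype = 5, n_dmc_diet = 5,
                          n_links_local = 28, n_links_distal = 4,
                          n_de_genes = 15, n_protected = 5,
                          n_lmc_sites = 4, n_age_sites = 4,
                          regions = "cortex")
  d <- tempfile()
  st <- suppressWarnings(simulateStudy(cfg, dir = d))
  expect_true(file.exists(file.path(d, "samples.tsv")))
  back <- readMethylationBedGraph(
    list.files(file.path(d, "bedgraph"), full.names = TRUE))
  # bedGraphs drop zero-coverage cells; counts agree on shared sites
  idx <- match(siteLabels(back), siteLabels(st$mm))
  expect_identical(totalReads(back)[, colnames(st$mm)[1]],
                   totalReads(st$mm)[idx, 1])
  tr <- readRegulatoryTrack(file.path(d, "ccre.bed"))
  expect_true(all(S4Vectors::mcols(tr)$label %in% c("EnhD", "CTCF")))
})
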