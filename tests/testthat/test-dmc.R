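test_that("depth filter retains exactly the sites the three rules allow", {
  set.seed(3)
  # 12 sites x 6 samples with engineered depths: low-coverage cells,
  # a PCR-bias-like spike, and boundary sites covered in exactly half the
  # samples
  total <- matrix(sample(c(0L, 5L, 12L, 30L), 72, replace = TRUE,
                         prob = c(0.15, 0.2, 0.35, 0.3)), 12, 6)
  total[1, ] <- c(12L, 15L, 20L, 5L, 0L, 9L)    # 3 of 6 usable -> retained
  total[2, ] <- c(12L, 15L, 0L, 5L, 0L, 9L)     # 2 of 6 -> dropped
  total[3, ] <- 30L                              # always retained
  total[4, ] <- c(2L, 3L, 4L, 5L, 6L, 7L)        # never usable
  meth <- matrix(0L, 12, 6)
  mm <- toy_mm(meth, total)
  f <- filterSites(mm, min_depth = 10, max_depth_quantile = 0.999,
                   min_sample_frac = 0.5)
  want <- filter_oracle(total, 10, 0.999, 0.5)
  expect_equal(match(siteLabels(f), siteLabels(mm)), want)
  expect_true(1 %in% want)
  expect_false(2 %in% want)
})

test_that("extreme-depth cells are masked by the per-sample 99.9th percentile", {
  n <- 1001L
  total <- matrix(10L, n, 2)
  total[1, 1] <- 1000000L
  meth <- matrix(2L, n, 2)
  mm <- toy_mm(meth, total, pos = seq_len(n) * 10L)
  f <- filterSites(mm, min_depth = 10, max_depth_quantile = 0.999,
                   min_sample_frac = 0.5)
  # spiked cell masked, site survives through the other sample at frac 0.5
  expect_equal(unname(totalReads(f)[1, 1]), 0L)
  expect_equal(nrow(f), n)
})

test_that("filter is idempotent given the first-pass depth caps", {
  set.seed(9)
  total <- matrix(rnbinom(600, mu = 25, size = 3), 100, 6)
  meth <- matrix(rbinom(600, as.vector(total), 0.5), 100, 6)
  mm <- toy_mm(meth, total)
  f1 <- filterSites(mm)
  caps <- S4Vectors::metadata(f1)$depth_caps
  f2 <- filterSites(f1, depth_caps = caps)
  expect_identical(totalReads(f2), totalReads(f1))
  expect_identical(siteLabels(f2), siteLabels(f1))
})

test_that("identical groups give zero delta and p near 1; label swap negates", {
  set.seed(11)
  half <- matrix(rnbinom(80, mu = 30, size = 5) + 10L, 10, 8)
  mhalf <- matrix(rbinom(80, as.vector(half), 0.4), 10, 8)
  total <- cbind(half, half)
  meth <- cbind(mhalf, mhalf)
  colnames(total) <- colnames(meth) <- sprintf("s%02d", 1:16)
  sd <- data.frame(group = rep(c("A", "B"), each = 8),
                   sex = rep(c("M", "F"), 8))
  mm <- toy_mm(meth, total, sampleData = sd)
  res <- testDmc(mm, contrast = "group", covariates = "sex",
                 include_age = FALSE)
  expect_equal(res$delta_pct, rep(0, 10))
  expect_true(all(res$p_value > 0.99))

  mm2 <- two_group_mm(20, 10, delta_pct = 15, seed = 5)
  a <- testDmc(mm2, contrast = "group", covariates = "sex",
               include_age = FALSE, levels = c("A", "B"))
  b <- testDmc(mm2, contrast = "group", covariates = "sex",
               include_age = FALSE, levels = c("B", "A"))
  expect_equal(a$delta_pct, -b$delta_pct)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-10)
})

test_that("Wald p agrees with the likelihood-ratio test within an order of magnitude", {
  mm <- two_group_mm(15, 12, delta_pct = 10, seed = 21)
  res <- testDmc(mm, contrast = "group", covariates = "sex",
                 include_age = FALSE)
  meth <- methReads(mm); total <- totalReads(mm)
  grp <- rep(0:1, each = 12)
  sexM <- as.integer(rep(c("M", "F"), 12) == "M")
  for (i in seq_len(nrow(mm))) {
    g1 <- glm(cbind(meth[i, ], total[i, ] - meth[i, ]) ~ grp + sexM,
              family = binomial)
    g0 <- glm(cbind(meth[i, ], total[i, ] - meth[i, ]) ~ sexM,
              family = binomial)
    p_lrt <- pchisq(deviance(g0) - deviance(g1), 1, lower.tail = FALSE)
    if (res$p_value[i] > 1e-12 && p_lrt > 1e-12)
      expect_lt(abs(log10(res$p_value[i]) - log10(p_lrt)), 1)
  }
})

test_that("nominal type-I error is near 5 percent on null data", {
  mm <- two_group_mm(1500, 24, delta_pct = 0, seed = 31)
  res <- testDmc(mm, contrast = "group", covariates = "sex",
                 include_age = FALSE)
  frac <- mean(res$p_value < 0.05, na.rm = TRUE)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
  expect_equal(sum(res$is_dmc, na.rm = TRUE), 0)
})

test_that("study contrasts subset samples as designed", {
  cfg <- simulationConfig(seed = 3, n_cpgs = 210, n_genes = 65,
                          n_dmc_genotype = 10, n_dmc_diet = 10,
                          n_links_local = 30, n_links_distal = 5,
                          n_de_genes = 20, n_protected = 10,
                          n_lmc_sites = 5, n_age_sites = 5,
                          regions = "cortex")
  st <- suppressWarnings(simulateStudy(cfg))
  f <- filterSites(st$mm)
  res <- testDmc(f, "genotype")
  # genotype contrast uses control-diet samples only: 48 of 96
  expect_true(all(res$n_used <= 48))
  resd <- testDmc(f, "diet")
  expect_true(all(resd$n_used <= 48))
  # mixing regions is refused
  cfg2 <- simulationConfig(seed = 3, n_cpgs = 210, n_genes = 65,
                           n_dmc_genotype = 10, n_dmc_diet = 10,
                           n_links_local = 30, n_links_distal = 5,
                          n_de_genes = 20, n_protected = 10,
                           n_lmc_sites = 5, n_age_sites = 5)
  st2 <- suppressWarnings(simulateStudy(cfg2))
  expect_error(testDmc(st2$mm, "genotype"), "regions separately")
})

test_that("gene-level summary averages DMC changes and counts once per gene", {
  dmcs <- data.frame(chrom = "chr1", pos = c(100, 200, 300, 400),
                     contrast = "genotype",
                     delta_pct = c(10, -4, 7, -2),
                     p_value = c(0.001, 0.001, 0.5, 0.001),
                     q_value = c(0.01, 0.01, 0.8, 0.01),
                     direction = c("hyper", "hypo", "hyper", "hypo"),
                     is_dmc = c(TRUE, TRUE, FALSE, TRUE),
                     n_used = 10L,
                     gene_id = c("gA", "gA", "gA", NA))
  out <- summarizeDmgs(dmcs)
  expect_equal(nrow(out), 1L)          # non-DMC and unannotated rows ignored
  expect_equal(out$n_dmcs, 2L)
  expect_equal(out$mean_delta_pct, 3)  # (+10 - 4) / 2
  expect_equal(out$direction, "mixed")
})
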