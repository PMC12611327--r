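mk_dmcs <- function(pos, delta, contrast = "genotype", gene = "gA",
                    chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, contrast = contrast,
             delta_pct = delta, p_value = 0.001, q_value = 0.01,
             direction = ifelse(delta > 0, "hyper", "hypo"), is_dmc = TRUE,
             n_used = 40L, gene_id = gene, stringsAsFactors = FALSE)
}
mk_degs <- function(gene, lfc, fdr, contrast = "genotype") {
  data.frame(gene_id = gene, contrast = contrast, log2fc = lfc,
             p_value = fdr / 2, fdr = fdr, stringsAsFactors = FALSE)
}

test_that("local pairing applies strict delta, fold-change and FDR gates", {
  degs <- mk_degs(c("gA", "gB", "gC"), c(-0.2, 0.05, 0.5),
                  c(0.01, 0.01, 0.2))
  dmcs <- mk_dmcs(c(100, 200, 300, 400), c(3.0, 2.5, 6, 6),
                  gene = c("gA", "gA", "gB", "gC"))
  got <- pairLocal(dmcs, degs)
  expect_equal(got$pos, 100)          # all gates pass
  # pos 200: delta exactly 2.5 excluded; gB lfc 0.05 below 0.1; gC fdr 0.2
  # diet contrast relaxes the FDR rule to < 0.1
  dmcs_d <- mk_dmcs(500, 4, contrast = "diet", gene = "gD")
  degs_d <- mk_degs("gD", 0.3, 0.07, contrast = "diet")
  expect_equal(nrow(pairLocal(dmcs_d, degs_d)), 1L)
  expect_equal(nrow(pairLocal(mk_dmcs(500, 4, gene = "gD"), degs_d)), 0L)
})

test_that("distal pairing excludes cis windows and off-chromosome genes", {
  genes <- geneModel(data.frame(
    gene_id = c("g1", "g2"), chrom = c("chr1", "chr2"), strand = "+",
    tss = c(50000, 50000), start = c(50000, 50000), end = c(60000, 60000)))
  degs <- mk_degs(c("g1", "g2"), c(1, 1), c(0.001, 0.001))
  dmcs <- mk_dmcs(c(46000, 44000, 55000, 100000), c(7, 7, 7, 7),
                  gene = NA)
  got <- pairDistal(dmcs, degs, genes)
  # 46000 is 4 kb upstream of the TSS -> cis, excluded; 55000 in body;
  # 44000 (6 kb) and 100000 pair with g1 only (g2 is on chr2)
  expect_setequal(got$pos, c(44000, 100000))
  expect_true(all(got$gene_id == "g1"))
  # the 5 % delta gate is strict
  expect_equal(nrow(pairDistal(mk_dmcs(44000, 5, gene = NA), degs, genes)),
               0L)
  # genotype contrast keeps only the top-N genes by FDR
  degs_many <- mk_degs(c("g1", "g2"), c(1, 1), c(0.04, 0.001))
  got2 <- pairDistal(mk_dmcs(100000, 7, gene = NA), degs_many, genes,
                     top_n_degs = 1L)
  expect_equal(nrow(got2), 0L)  # g1 ranked 2nd, dropped; g2 other chrom
})

test_that("regression is scale-equivariant and satisfies the t/partial-r identity", {
  set.seed(17)
  n <- 46
  cov_df <- data.frame(age_c = rnorm(n), sexM = rbinom(n, 1, 0.5),
                       lmc = runif(n))
  x <- 100 * rbeta(n, 2, 2)
  y <- -0.6 * as.numeric(scale(x)) + rnorm(n, 0, 0.8)
  a <- regressPair(y, x, cov_df)
  b <- regressPair(5 * y, x, cov_df)
  expect_equal(a$beta_methylation, b$beta_methylation, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_equal(a$partial_r, b$partial_r, tolerance = 1e-12)
  # t^2 = r^2 * df / (1 - r^2) with df = n - (covariates + 2)
  df <- a$n_used - 2 - ncol(cov_df)
  t2 <- a$partial_r^2 * df / (1 - a$partial_r^2)
  p_from_t <- 2 * pt(-sqrt(t2), df)
  expect_equal(p_from_t, a$p_value, tolerance = 1e-8)
})

test_that("degenerate inputs give NA records with reason codes", {
  n <- 20
  cov_df <- data.frame(age_c = rnorm(n))
  expect_equal(regressPair(rnorm(n), rep(50, n), cov_df)$reason,
               "rank_deficient")
  expect_equal(regressPair(rnorm(5), runif(5), NULL)$reason, "too_few_obs")
  meth <- c(runif(n - 4), rep(NA, 4))
  expect_equal(regressPair(rnorm(n), meth, cov_df)$n_used, n - 4)
})

test_that("the Cook's/residual outlier rule matches the hat-matrix oracle", {
  set.seed(23)
  agree <- 0L
  for (rep in 1:40) {
    n <- 30
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    contaminate <- rep %% 2 == 0
    if (contaminate) y[n] <- y[n] + 10    # gross response outlier
    rec <- regressPair(y, x, NULL)
    # closed-form diagnostics on the same z-scaled simple regression
    zy <- as.numeric(scale(y)); zx <- as.numeric(scale(x))
    X <- cbind(1, zx)
    H <- X %*% solve(crossprod(X)) %*% t(X)
    e <- zy - H %*% zy
    p <- 2L
    s2 <- sum(e^2) / (n - p)
    rstd <- e / sqrt(s2 * (1 - diag(H)))
    cook <- e^2 * diag(H) / (p * s2 * (1 - diag(H))^2)
    flagged <- which(cook > 4 / n & abs(rstd) > 3)
    expect_equal(rec$outliers_removed, length(flagged))
    if (contaminate && length(flagged) == 1 && flagged == n) {
      agree <- agree + 1L
      clean <- regressPair(y[-n], x[-n], NULL)
      se_clean <- sqrt((1 - clean$partial_r^2) / (n - 3))
      expect_lt(abs(rec$beta_methylation - clean$beta_methylation),
                1.5 * se_clean)
    }
  }
  expect_gt(agree, 10)  # the planted contaminant is usually caught
})

test_that("the outlier pass removes at most a quarter of the points", {
  set.seed(31)
  n <- 24
  x <- rnorm(n)
  y <- rnorm(n)
  y[1:12] <- y[1:12] + 12   # half the points grossly shifted
  rec <- regressPair(y, x, NULL)
  expect_lte(rec$outliers_removed, floor(n / 4))
})

test_that("planted links are recovered with correct sign and magnitude", {
  cfg <- simulationConfig(seed = 19, n_cpgs = 300, n_genes = 80,
                          n_dmc_genotype = 10, n_dmc_diet = 0,
                          n_links_local = 36, n_links_distal = 6,
                          n_de_genes = 20, n_protected = 5,
                          n_lmc_sites = 5, n_age_sites = 5,
                          n_pac = 0, n_pac_diet_specific = 0,
                          regions = "cortex")
  st <- suppressWarnings(simulateStudy(cfg))
  f <- filterSites(st$mm)
  dmc <- testDmc(f, "genotype", genes = geneModel(st$genes))
  loc <- runIntegration("local", dmc, st$expr$de$cortex$genotype,
                        st$expr$vst, f)
  tl <- st$truth$links[st$truth$links$scope == "local", ]
  m <- merge(loc, tl, by = c("chrom", "pos"))
  expect_gt(nrow(m), 15)
  expect_gte(mean(sign(m$beta_methylation) == sign(m$beta)), 0.95)
  expect_lt(mean(abs(m$beta_methylation - m$beta)), 0.25)
  # strong links are called ECpGs
  strong <- m[abs(m$beta) >= 0.6, ]
  expect_gte(mean(strong$is_ecpg), 0.8)
})

test_that("empty candidate sets return empty records without error", {
  degs <- mk_degs("gZ", 0.05, 0.5)
  dmcs <- mk_dmcs(100, 1.0)
  mm <- two_group_mm(5, 4)
  out <- runIntegration("local", dmcs, degs, matrix(0, 1, 8,
                        dimnames = list("gZ", colnames(mm))), mm)
  expect_equal(nrow(out), 0L)
})

test_that("distal q-values are BH within family and null pairs stay quiet", {
  set.seed(41)
  # methylation and expression independent: expected discoveries at q<0.05
  # stay near the BH null rate
  n <- 40
  total <- matrix(30L, 60, n)
  meth <- matrix(rbinom(60 * n, 30, 0.5), 60, n)
  colnames(meth) <- colnames(total) <- sprintf("s%02d", 1:n)
  mm <- toy_mm(meth, total, chrom = "chr1", pos = seq_len(60) * 20000L)
  vst <- matrix(rnorm(30 * n), 30, n,
                dimnames = list(sprintf("g%02d", 1:30), colnames(meth)))
  genes <- geneModel(data.frame(
    gene_id = rownames(vst), chrom = "chr2", strand = "+",
    tss = seq_len(30) * 50000, start = seq_len(30) * 50000,
    end = seq_len(30) * 50000 + 9999))
  # put genes on chr2 but sites on chr1 -> no pairs at all
  dmcs <- mk_dmcs(seq_len(60) * 20000L, 8, gene = NA)
  degs <- mk_degs(rownames(vst), 1, 0.001)
  out <- runIntegration("distal", dmcs, degs, vst, mm, genes = genes)
  expect_equal(nrow(out), 0L)
  # same chromosome: pairs exist, BH q monotone in p
  genes2 <- geneModel(data.frame(
    gene_id = rownames(vst), chrom = "chr1", strand = "+",
    tss = 5e6 + seq_len(30) * 50000, start = 5e6 + seq_len(30) * 50000,
    end = 5e6 + seq_len(30) * 50000 + 9999))
  out2 <- runIntegration("distal", dmcs, degs, vst, mm, genes = genes2)
  expect_gt(nrow(out2), 100)
  ok <- !is.na(out2$q_value)
  o <- order(out2$p_value[ok])
  expect_true(all(diff(out2$q_value[ok][o]) >= -1e-12))
  expect_lte(mean(out2$is_ecpg), 0.05)
})
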