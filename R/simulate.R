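#' Configuration for the synthetic study generator
#'
#' Encodes the study design the generator reproduces: 2 genotypes (WT,
#' AppNLGF) x 2 diets (control, choline-supplemented) x 4 ages x 2 sexes x
#' \code{n_per_cell} replicates, profiled in two brain regions, with planted
#' methylation effects (genotype/diet/age/cell-composition), planted
#' CpG-to-gene expression links (local and distal), an exponential amyloid
#' time course in mutants, and plaque-associated methylation effects.
#'
#' Effect-carrying CpGs draw their baselines from the central range
#' (0.25-0.75) so percentage-point shifts stay representable; null CpGs draw
#' from the bimodal Beta prior.
#'
#' @param seed integer seed fanned out to each generation stage.
#' @param n_per_cell replicates per genotype x diet x age x sex cell.
#' @param ages ages at sacrifice, months.
#' @param regions brain regions profiled per mouse.
#' @param n_cpgs,n_genes matrix dimensions.
#' @param coverage_mean,coverage_size negative-binomial read depth
#'   (\code{coverage_size = Inf} gives Poisson depth).
#' @param baseline_alpha,baseline_beta Beta prior on per-CpG baseline
#'   methylation.
#' @param n_dmc_genotype,genotype_delta count and size (percentage points) of
#'   planted genotype differential-methylation effects.
#' @param n_dmc_diet,diet_delta as above for the supplemented-diet effect.
#' @param n_age_sites,age_slope sites with an age trend, pct points / month.
#' @param n_links_local,n_links_distal planted CpG-gene expression links.
#' @param link_betas standardized link coefficients cycled over link sites.
#' @param n_de_genes,de_lfc additional differentially expressed genes
#'   (log2 fold change) beyond link targets; \code{n_protected} of them carry
#'   the genotype effect only under the control diet (choline-protected).
#' @param expr_log2_range,expr_size baseline expression (log2 mean range) and
#'   NB size of counts.
#' @param amyloid_base,amyloid_rate,amyloid_cv amyloid percent area in
#'   mutants follows \code{base * exp(rate * age)} (default triples every 6
#'   months) with lognormal-like noise of the given CV; wild types are 0.
#' @param amyloid_diet_factor multiplier on amyloid burden under the
#'   supplemented diet (supplementation reduces amyloidosis).
#' @param n_pac,pac_beta,pac_link planted amyloid-methylation effects, on the
#'   named link scale per unit percent area, assigned to the first local-link
#'   CpGs so plaque-associated CpGs are discoverable among ECpGs.
#' @param n_pac_diet_specific sites whose amyloid effect acts under the
#'   control diet only.
#' @param lmc_alpha_wt,lmc_alpha_app Dirichlet parameters of the latent
#'   cell-proportion components per genotype (neuron, microglia, other).
#' @param n_lmc_sites,lmc_gamma CpGs loaded on the microglial proportion and
#'   the logit-scale loading.
#' @return A validated \code{SimulationConfig} (list).
#' @export
simulationConfig <- function(seed = 1L,
                             n_per_cell = 3L,
                             ages = c(3, 6, 9, 12),
                             regions = c("cortex", "hippocampus"),
                             n_cpgs = 2000L,
                             n_genes = 300L,
                             coverage_mean = 30,
                             coverage_size = 5,
                             baseline_alpha = 0.7,
                             baseline_beta = 0.7,
                             n_dmc_genotype = 40L,
                             genotype_delta = 20,
                             n_dmc_diet = 40L,
                             diet_delta = 15,
                             n_age_sites = 20L,
                             age_slope = 1.5,
                             n_links_local = 40L,
                             n_links_distal = 20L,
                             link_betas = c(-0.85, -0.6, -0.4, 0.4, 0.6, 0.85),
                             n_de_genes = 40L,
                             de_lfc = 1,
                             n_protected = 20L,
                             expr_log2_range = c(5, 9),
                             expr_size = 20,
                             amyloid_base = 6 / 3^2,
                             amyloid_rate = log(3) / 6,
                             amyloid_cv = 0.35,
                             amyloid_diet_factor = 0.6,
                             n_pac = 20L,
                             pac_beta = -0.2,
                             pac_link = c("log", "logit"),
                             n_pac_diet_specific = 8L,
                             lmc_alpha_wt = c(neuron = 10, microglia = 2, other = 4),
                             lmc_alpha_app = c(neuron = 8, microglia = 4, other = 4),
                             n_lmc_sites = 40L,
                             lmc_gamma = 1.0) {
  cfg <- list(seed = as.integer(seed), n_per_cell = as.integer(n_per_cell),
              ages = ages, regions = regions, n_cpgs = as.integer(n_cpgs),
              n_genes = as.integer(n_genes), coverage_mean = coverage_mean,
              coverage_size = coverage_size, baseline_alpha = baseline_alpha,
              baseline_beta = baseline_beta,
              n_dmc_genotype = n_dmc_genotype, genotype_delta = genotype_delta,
              n_dmc_diet = n_dmc_diet, diet_delta = diet_delta,
              n_age_sites = n_age_sites, age_slope = age_slope,
              n_links_local = n_links_local, n_links_distal = n_links_distal,
              link_betas = link_betas, n_de_genes = n_de_genes,
              de_lfc = de_lfc, n_protected = n_protected,
              expr_log2_range = expr_log2_range, expr_size = expr_size,
              amyloid_base = amyloid_base, amyloid_rate = amyloid_rate,
              amyloid_cv = amyloid_cv,
              amyloid_diet_factor = amyloid_diet_factor,
              n_pac = n_pac, pac_beta = pac_beta,
              pac_link = match.arg(pac_link),
              n_pac_diet_specific = n_pac_diet_specific,
              lmc_alpha_wt = lmc_alpha_wt, lmc_alpha_app = lmc_alpha_app,
              n_lmc_sites = n_lmc_sites, lmc_gamma = lmc_gamma)
  stopifnot(cfg$n_per_cell >= 1, length(cfg$ages) >= 1,
            cfg$coverage_mean > 0, cfg$n_cpgs >= 1, cfg$n_genes >= 1,
            cfg$baseline_alpha > 0, cfg$baseline_beta > 0)
  n_effect <- cfg$n_links_local + cfg$n_links_distal + cfg$n_dmc_genotype +
    cfg$n_dmc_diet + cfg$n_lmc_sites + cfg$n_age_sites
  if (n_effect > cfg$n_cpgs)
    stop("n_cpgs too small for the planted-effect sites (need >= ", n_effect, ")")
  if (cfg$n_links_local + cfg$n_links_distal + cfg$n_de_genes > cfg$n_genes)
    stop("n_genes too small for link targets plus DE genes")
  if (cfg$n_protected > cfg$n_de_genes) stop("n_protected exceeds n_de_genes")
  if (cfg$n_pac + cfg$n_pac_diet_specific > cfg$n_links_local)
    stop("PAC sites are drawn from local-link sites; increase n_links_local")
  class(cfg) <- "SimulationConfig"
  cfg
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat("SimulationConfig:", 2 * 2 * length(x$ages) * 2 * x$n_per_cell,
      "mice x", length(x$regions), "regions;",
      x$n_cpgs, "CpGs,", x$n_genes, "genes\n")
  invisible(x)
}

#' Generate the sample design table
#'
#' One row per mouse x region. Amyloid percent area is zero in wild types
#' and grows exponentially with age in mutants, damped under the supplemented
#' diet; latent cell-proportion covariates (\code{lmc_neuron},
#' \code{lmc_microglia}) are Dirichlet draws with genotype-specific
#' parameters (microgliosis in mutants).
#'
#' @param cfg a [simulationConfig()].
#' @return data.frame with columns \code{sample_id, mouse_id, genotype, diet,
#'   age_months, sex, region, lmc_neuron, lmc_microglia, amyloid_pct_area}.
#' @export
simulateDesign <- function(cfg) {
  set.seed(cfg$seed + 101L)
  mice <- expand.grid(rep = seq_len(cfg$n_per_cell), sex = c("M", "F"),
                      age_months = cfg$ages, diet = c("control", "supplemented"),
                      genotype = c("WT", "AppNLGF"),
                      stringsAsFactors = FALSE)
  mice$mouse_id <- sprintf("m%03d", seq_len(nrow(mice)))
  d <- do.call(rbind, lapply(cfg$regions, function(r)
    cbind(mice, region = r, stringsAsFactors = FALSE)))
  d$sample_id <- paste(d$mouse_id, substr(d$region, 1, 3), sep = "_")
  app <- d$genotype == "AppNLGF"
  alpha <- matrix(rep(cfg$lmc_alpha_wt, nrow(d)), nrow = nrow(d), byrow = TRUE)
  alpha[app, ] <- matrix(rep(cfg$lmc_alpha_app, sum(app)), ncol = 3,
                         byrow = TRUE)
  g <- matrix(stats::rgamma(nrow(d) * 3, shape = alpha), nrow = nrow(d))
  lmc <- g / rowSums(g)
  d$lmc_neuron <- lmc[, 1]
  d$lmc_microglia <- lmc[, 2]
  mu <- cfg$amyloid_base * exp(cfg$amyloid_rate * d$age_months) *
    ifelse(d$diet == "supplemented", cfg$amyloid_diet_factor, 1)
  noise <- stats::rnorm(nrow(d), 0, cfg$amyloid_cv * mu)
  d$amyloid_pct_area <- ifelse(app, pmax(0.01, mu + noise), 0)
  d[, c("sample_id", "mouse_id", "genotype", "diet", "age_months", "sex",
        "region", "lmc_neuron", "lmc_microglia", "amyloid_pct_area")]
}

#' Generate the gene model
#'
#' Genes laid out on four chromosomes, 50 kb apart, 10 kb bodies,
#' alternating strands.
#'
#' @param cfg a [simulationConfig()].
#' @return data.frame acceptable to [geneModel()].
#' @export
simulateGeneModel <- function(cfg) {
  n <- cfg$n_genes
  chrom <- paste0("chr", ((seq_len(n) - 1L) %% 4L) + 1L)
  idx <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  start <- 20000L + (idx - 1L) * 50000L
  end <- start + 9999L
  strand <- ifelse(seq_len(n) %% 2L == 0L, "-", "+")
  data.frame(gene_id = sprintf("gene%04d", seq_len(n)), chrom,
             strand, tss = ifelse(strand == "+", start, end),
             start = start, end = end, stringsAsFactors = FALSE)
}

# Site plan: positions, baselines and every planted per-site effect.
# Local-link sites sit inside their target gene's body; distal-link sites sit
# on the same chromosome ~20 kb downstream of the body (outside the 5 kb cis
# window); remaining effect sites and null sites are scattered, some in genes.
.site_plan <- function(cfg, genes) {
  set.seed(cfg$seed + 202L)
  n <- cfg$n_cpgs
  plan <- data.frame(chrom = character(n), pos = NA_integer_,
                     baseline = NA_real_, d_geno = 0, d_diet = 0,
                     age_slope = 0, lmc_gamma = 0, pac_beta = 0,
                     pac_diet_specific = FALSE,
                     link_gene = NA_character_, link_beta = NA_real_,
                     link_scope = NA_character_, role = "null",
                     stringsAsFactors = FALSE)
  k <- 0L
  take <- function(m) { i <- k + seq_len(m); k <<- k + m; i }
  betas <- rep_len(cfg$link_betas, cfg$n_links_local + cfg$n_links_distal)
  sgn <- function(m) sample(c(-1, 1), m, replace = TRUE)

  i <- take(cfg$n_links_local)
  g <- genes[seq_len(cfg$n_links_local), ]
  plan$chrom[i] <- g$chrom
  plan$pos[i] <- g$start + sample(1000:9000, length(i), replace = TRUE)
  plan$d_geno[i] <- cfg$genotype_delta * sgn(length(i))
  plan$link_gene[i] <- g$gene_id
  plan$link_beta[i] <- betas[seq_len(cfg$n_links_local)]
  plan$link_scope[i] <- "local"
  plan$role[i] <- "link_local"
  if (cfg$n_pac > 0) {
    j <- i[seq_len(cfg$n_pac)]
    plan$pac_beta[j] <- cfg$pac_beta
    plan$role[j] <- "link_local_pac"
  }
  if (cfg$n_pac_diet_specific > 0) {
    j <- i[cfg$n_pac + seq_len(cfg$n_pac_diet_specific)]
    plan$pac_beta[j] <- cfg$pac_beta
    plan$pac_diet_specific[j] <- TRUE
    plan$role[j] <- "link_local_pac_diet"
  }

  if (cfg$n_links_distal > 0) {
    i <- take(cfg$n_links_distal)
    g <- genes[cfg$n_links_local + seq_len(cfg$n_links_distal), ]
    plan$chrom[i] <- g$chrom
    plan$pos[i] <- g$end + 20000L + sample(0:5000, length(i), replace = TRUE)
    plan$d_geno[i] <- cfg$genotype_delta * sgn(length(i))
    plan$link_gene[i] <- g$gene_id
    plan$link_beta[i] <- betas[cfg$n_links_local + seq_len(cfg$n_links_distal)]
    plan$link_scope[i] <- "distal"
    plan$role[i] <- "link_distal"
  }

  scatter <- function(m) {
    chrom <- paste0("chr", sample(1:4, m, replace = TRUE))
    span <- max(genes$end) + 60000L
    data.frame(chrom = chrom, pos = sample(span, m))
  }
  if (cfg$n_dmc_genotype > 0) {
    # genotype-responsive methylation concentrates at the DE genes: the
    # first DMC sites sit inside the bodies of the extra DE genes
    # (choline-protected genes first), the rest are intergenic
    i <- take(cfg$n_dmc_genotype)
    k_in <- min(length(i), cfg$n_de_genes)
    if (k_in > 0) {
      g <- genes[cfg$n_links_local + cfg$n_links_distal + seq_len(k_in), ]
      plan$chrom[i[seq_len(k_in)]] <- g$chrom
      plan$pos[i[seq_len(k_in)]] <- g$start +
        sample(1000:9000, k_in, replace = TRUE)
    }
    if (length(i) > k_in) {
      s <- scatter(length(i) - k_in)
      plan$chrom[i[-seq_len(k_in)]] <- s$chrom
      plan$pos[i[-seq_len(k_in)]] <- s$pos
    }
    plan$d_geno[i] <- cfg$genotype_delta * sgn(length(i))
    plan$role[i] <- "dmc_genotype"
  }
  if (cfg$n_dmc_diet > 0) {
    i <- take(cfg$n_dmc_diet); s <- scatter(length(i))
    plan$chrom[i] <- s$chrom; plan$pos[i] <- s$pos
    plan$d_diet[i] <- cfg$diet_delta * sgn(length(i))
    plan$role[i] <- "dmc_diet"
  }
  if (cfg$n_lmc_sites > 0) {
    i <- take(cfg$n_lmc_sites); s <- scatter(length(i))
    plan$chrom[i] <- s$chrom; plan$pos[i] <- s$pos
    plan$lmc_gamma[i] <- cfg$lmc_gamma * sgn(length(i))
    plan$role[i] <- "lmc"
  }
  if (cfg$n_age_sites > 0) {
    i <- take(cfg$n_age_sites); s <- scatter(length(i))
    plan$chrom[i] <- s$chrom; plan$pos[i] <- s$pos
    plan$age_slope[i] <- cfg$age_slope * sgn(length(i))
    plan$role[i] <- "age"
  }
  i <- take(n - k)
  s <- scatter(length(i))
  plan$chrom[i] <- s$chrom; plan$pos[i] <- s$pos

  effect <- plan$role != "null"
  plan$baseline[effect] <- stats::runif(sum(effect), 0.25, 0.75)
  plan$baseline[!effect] <- stats::rbeta(sum(!effect), cfg$baseline_alpha,
                                         cfg$baseline_beta)
  # unique positions within chromosome
  dup <- duplicated(paste(plan$chrom, plan$pos))
  while (any(dup)) {
    plan$pos[dup] <- plan$pos[dup] + sample(1:97, sum(dup), replace = TRUE)
    dup <- duplicated(paste(plan$chrom, plan$pos))
  }
  plan
}

# percentage-point delta -> logit shift at a site's baseline
.pct_shift <- function(baseline, delta_pct) {
  p1 <- pmin(0.999, pmax(0.001, baseline + delta_pct / 100))
  stats::qlogis(p1) - stats::qlogis(baseline)
}

#' Simulate the methylation count matrix with planted effects
#'
#' Read depth is negative-binomial per cell; the per-sample methylation
#' probability is assembled additively on the logit scale from the site
#' baseline, genotype/diet percentage-point shifts (converted to logit shifts
#' at the baseline), an age trend, and a loading on the microglial latent
#' component; amyloid effects are applied on the configured link scale.
#' Methylated reads are binomial.
#'
#' @param cfg a [simulationConfig()].
#' @param samples design from [simulateDesign()].
#' @param genes gene model data.frame from [simulateGeneModel()] (used to
#'   position planted link sites); generated if missing.
#' @return list with \code{mm} (a \linkS4class{MethylMatrix} whose colData is
#'   the sample table), \code{truth} (truth tables: \code{dmcs},
#'   \code{links}, \code{pacs}, and per-site \code{plan}).
#' @export
simulateMethylation <- function(cfg, samples, genes = simulateGeneModel(cfg)) {
  plan <- .site_plan(cfg, genes)
  set.seed(cfg$seed + 303L)
  n <- nrow(plan); ns <- nrow(samples)
  total <- if (is.finite(cfg$coverage_size)) {
    matrix(stats::rnbinom(n * ns, mu = cfg$coverage_mean,
                          size = cfg$coverage_size), n, ns)
  } else {
    matrix(stats::rpois(n * ns, cfg$coverage_mean), n, ns)
  }
  app <- samples$genotype == "AppNLGF"
  sup <- samples$diet == "supplemented"
  agec <- samples$age_months - mean(cfg$ages)
  zmic <- as.numeric(scale(samples$lmc_microglia))
  amy <- samples$amyloid_pct_area

  eta <- matrix(stats::qlogis(plan$baseline), n, ns)
  eta <- eta + .pct_shift(plan$baseline, plan$d_geno) %o% as.numeric(app)
  eta <- eta + .pct_shift(plan$baseline, plan$d_diet) %o% as.numeric(sup)
  # age trend: per-site logit shift at the site baseline per centered month
  slope_shift <- .pct_shift(plan$baseline, plan$age_slope) # shift per +1 month
  eta <- eta + slope_shift %o% agec
  eta <- eta + plan$lmc_gamma %o% zmic
  p <- stats::plogis(eta)
  pac_mask <- t(vapply(seq_len(n), function(i) {
    if (plan$pac_beta[i] == 0) return(rep(0, ns))
    m <- as.numeric(app)
    if (plan$pac_diet_specific[i]) m <- m * as.numeric(!sup)
    plan$pac_beta[i] * amy * m
  }, numeric(ns)))
  if (cfg$pac_link == "log") p <- p * exp(pac_mask) else
    p <- stats::plogis(stats::qlogis(p) + pac_mask)
  clipped <- p <= 1e-4 | p >= 1 - 1e-4
  if (any(clipped))
    warning(sum(clipped), " methylation probabilities clipped to (0,1)")
  p <- pmin(1 - 1e-4, pmax(1e-4, p))
  meth <- matrix(stats::rbinom(n * ns, as.vector(total), as.vector(p)), n, ns)
  colnames(meth) <- colnames(total) <- samples$sample_id
  mm <- MethylMatrix(meth, total,
                     data.frame(chrom = plan$chrom, pos = plan$pos),
                     sampleData = samples)
  truth <- list(
    dmcs = rbind(
      data.frame(chrom = plan$chrom, pos = plan$pos, contrast = "genotype",
                 delta = plan$d_geno)[plan$d_geno != 0, ],
      data.frame(chrom = plan$chrom, pos = plan$pos, contrast = "diet",
                 delta = plan$d_diet)[plan$d_diet != 0, ]),
    links = data.frame(chrom = plan$chrom, pos = plan$pos,
                       gene_id = plan$link_gene, beta = plan$link_beta,
                       scope = plan$link_scope)[!is.na(plan$link_gene), ],
    pacs = data.frame(chrom = plan$chrom, pos = plan$pos,
                      beta_amyloid = plan$pac_beta,
                      diet_specific = plan$pac_diet_specific)[plan$pac_beta != 0, ],
    plan = plan)
  list(mm = mm, truth = truth)
}

#' Simulate expression counts, stabilized matrix and DE tables
#'
#' Gene-level NB counts whose log2 means carry planted genotype effects
#' (choline-protected genes express the genotype effect only under the
#' control diet) and planted links to the realized percent methylation of
#' linked CpGs. A planted standardized link coefficient \code{beta} is
#' converted to a raw log2-scale slope \code{sigma_g * beta / sqrt(1-beta^2)}
#' using the gene's delta-method count-noise SD \code{sigma_g}, so the
#' standardized coefficient recovered by regression matches \code{beta}.
#' The variance-stabilizing transform is \code{log2(count + 1)}.
#'
#' @param cfg a [simulationConfig()].
#' @param samples design table.
#' @param mm MethylMatrix from [simulateMethylation()].
#' @param truth matching truth list.
#' @return list: \code{counts}, \code{vst} (genes x samples), \code{de}
#'   (per region: \code{genotype}, \code{genotype_supplemented}, \code{diet}
#'   tables from [callDeMinimal()]), \code{truth_protected} (gene ids).
#' @export
simulateExpression <- function(cfg, samples, mm, truth) {
  set.seed(cfg$seed + 404L)
  plan <- truth$plan
  ng <- cfg$n_genes; ns <- nrow(samples)
  gene_id <- sprintf("gene%04d", seq_len(ng))
  mu0 <- stats::runif(ng, cfg$expr_log2_range[1], cfg$expr_log2_range[2])
  # per-gene log2-scale noise sd by delta method on log2(C+1), C ~ NB
  m <- 2^mu0
  sigma_g <- sqrt((1 / log(2)^2) * (1 / m + 1 / cfg$expr_size))

  # link-target genes carry no independent genotype term: their differential
  # expression arises through the methylation link itself (the linked CpG
  # shifts with genotype, expression follows via beta)
  lfc <- numeric(ng); protected <- logical(ng)
  n_link <- cfg$n_links_local + cfg$n_links_distal
  de_extra <- n_link + seq_len(cfg$n_de_genes)
  lfc[de_extra] <- cfg$de_lfc * sample(c(-1, 1), cfg$n_de_genes, replace = TRUE)
  protected[de_extra[seq_len(cfg$n_protected)]] <- TRUE

  app <- samples$genotype == "AppNLGF"
  ctrl <- samples$diet == "control"
  eff <- matrix(0, ng, ns)
  geno_on <- ifelse(protected, 1, 0) %o% as.numeric(app & ctrl) +
    ifelse(protected, 0, 1) %o% as.numeric(app)
  eff <- eff + lfc * geno_on

  pct <- methPct(mm)
  lab <- siteLabels(mm)
  li <- which(!is.na(plan$link_gene))
  for (i in li) {
    gi <- match(plan$link_gene[i], gene_id)
    row <- match(paste0(plan$chrom[i], ":", plan$pos[i]), lab)
    x <- pct[row, ]
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    z <- as.numeric(scale(x))
    b <- plan$link_beta[i]
    eff[gi, ] <- eff[gi, ] + sigma_g[gi] * b / sqrt(1 - b^2) * z
  }
  mu <- 2^(mu0 + eff)
  counts <- matrix(stats::rnbinom(ng * ns, mu = as.vector(mu),
                                  size = cfg$expr_size), ng, ns,
                   dimnames = list(gene_id, samples$sample_id))
  vst <- log2(counts + 1)
  de <- lapply(stats::setNames(cfg$regions, cfg$regions), function(r) {
    s <- samples$region == r
    list(
      genotype = callDeMinimal(counts[, s & ctrl, drop = FALSE],
                               samples[s & ctrl, ], contrast = "genotype",
                               levels = c("WT", "AppNLGF")),
      genotype_supplemented = callDeMinimal(
        counts[, s & !ctrl, drop = FALSE], samples[s & !ctrl, ],
        contrast = "genotype", levels = c("WT", "AppNLGF")),
      diet = callDeMinimal(counts[, s & app, drop = FALSE],
                           samples[s & app, ], contrast = "diet",
                           levels = c("control", "supplemented")))
  })
  list(counts = counts, vst = vst, de = de,
       truth_protected = gene_id[protected])
}

#' Simulate a cCRE-style regulatory track
#'
#' Distal-enhancer (EnhD) elements are planted within 800 bp of each distal
#' link CpG (so enrichment is recoverable), plus random background EnhD and
#' CTCF elements across the simulated genome.
#'
#' @param cfg a [simulationConfig()].
#' @param truth truth list from [simulateMethylation()].
#' @param n_background random background elements per label.
#' @return GRanges with mcols \code{label}.
#' @export
simulateRegulatoryTrack <- function(cfg, truth, n_background = 50L) {
  set.seed(cfg$seed + 505L)
  plan <- truth$plan
  distal <- plan[!is.na(plan$link_scope) & plan$link_scope == "distal", ]
  span <- max(plan$pos) + 10000L
  planted <- if (nrow(distal)) {
    off <- sample(-800:800, nrow(distal), replace = TRUE)
    data.frame(chrom = distal$chrom, start = pmax(1L, distal$pos + off - 100L),
               label = "EnhD")
  } else NULL
  bg <- data.frame(chrom = paste0("chr", sample(1:4, 2 * n_background, TRUE)),
                   start = sample(span, 2 * n_background),
                   label = rep(c("EnhD", "CTCF"), each = n_background))
  d <- rbind(planted, bg)
  gr <- GenomicRanges::GRanges(d$chrom,
                               IRanges::IRanges(d$start, width = 200L))
  S4Vectors::mcols(gr)$label <- d$label
  sort(gr)
}

#' Run the whole generator and optionally write study files
#'
#' @param cfg a [simulationConfig()].
#' @param dir if given, writes per-sample bedGraphs plus \code{samples.tsv},
#'   \code{genes.tsv}, \code{ccre.bed}, \code{counts.tsv}, \code{vst.tsv},
#'   per-region DE tables and truth tables under \code{dir}.
#' @return list: \code{samples}, \code{mm}, \code{genes} (data.frame),
#'   \code{expr} (list from [simulateExpression()]), \code{track},
#'   \code{truth}.
#' @export
simulateStudy <- function(cfg, dir = NULL) {
  samples <- simulateDesign(cfg)
  genes <- simulateGeneModel(cfg)
  sim <- simulateMethylation(cfg, samples, genes)
  expr <- simulateExpression(cfg, samples, sim$mm, sim$truth)
  track <- simulateRegulatoryTrack(cfg, sim$truth)
  out <- list(samples = samples, mm = sim$mm, genes = genes, expr = expr,
              track = track, truth = c(sim$truth,
                                       list(protected = expr$truth_protected)))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeMethylationBedGraph(sim$mm, file.path(dir, "bedgraph"))
    writeResultsTable(samples, file.path(dir, "samples.tsv"))
    writeResultsTable(genes, file.path(dir, "genes.tsv"))
    track_df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(track)),
      start0 = BiocGenerics::start(track) - 1L,
      end0 = BiocGenerics::end(track),
      label = S4Vectors::mcols(track)$label)
    utils::write.table(track_df, file.path(dir, "ccre.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    writeResultsTable(data.frame(gene_id = rownames(expr$counts),
                                 expr$counts, check.names = FALSE),
                      file.path(dir, "counts.tsv"))
    writeResultsTable(data.frame(gene_id = rownames(expr$vst), expr$vst,
                                 check.names = FALSE),
                      file.path(dir, "vst.tsv"))
    for (r in names(expr$de))
      for (ct in names(expr$de[[r]]))
        writeResultsTable(expr$de[[r]][[ct]],
                          file.path(dir, paste0("de_", r, "_", ct, ".tsv")))
    for (nm in c("dmcs", "links", "pacs"))
      writeResultsTable(sim$truth[[nm]],
                        file.path(dir, paste0("truth_", nm, ".tsv")))
    writeResultsTable(data.frame(gene_id = expr$truth_protected),
                      file.path(dir, "truth_protected.tsv"))
  }
  out
}
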