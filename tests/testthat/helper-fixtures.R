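# Shared fixture builders. Everything is generated in code; no stored data.

# Small MethylMatrix from explicit count matrices.
toy_mm <- function(meth, total, chrom = "chr1",
                   pos = seq_len(nrow(as.matrix(meth))) * 100L,
                   sampleData = NULL) {
  meth <- as.matrix(meth); total <- as.matrix(total)
  if (is.null(colnames(meth)))
    colnames(meth) <- colnames(total) <- paste0("s", seq_len(ncol(meth)))
  MethylMatrix(meth, total,
               data.frame(chrom = rep(chrom, length.out = nrow(meth)),
                          pos = pos),
               sampleData = sampleData)
}

# Two-group binomial methylation data with balanced covariate-free design:
# n_per_group samples per level, constant coverage distribution, a fixed
# percentage-point shift at every site. Used to isolate test power from the
# covariate structure of the full generator.
two_group_mm <- function(n_sites, n_per_group, coverage = 30,
                         baseline = 0.4, delta_pct = 0, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  total <- matrix(rnbinom(n_sites * n, mu = coverage, size = 5) + 1L,
                  n_sites, n)
  p <- matrix(baseline, n_sites, n)
  p[, seq_len(n_per_group) + n_per_group] <- baseline + delta_pct / 100
  meth <- matrix(rbinom(n_sites * n, as.vector(total), as.vector(p)),
                 n_sites, n)
  colnames(meth) <- colnames(total) <- sprintf("s%03d", seq_len(n))
  sd <- data.frame(
    group = rep(c("A", "B"), each = n_per_group),
    sex = rep(c("M", "F"), n / 2))
  toy_mm(meth, total, pos = seq_len(n_sites) * 50L, sampleData = sd)
}

# Simple gene model data.frame for annotation tests.
toy_genes <- function(...) {
  g <- list(...)
  do.call(rbind, lapply(seq_along(g), function(i) {
    x <- g[[i]]
    data.frame(gene_id = x$id, chrom = x$chrom %||% "chr1",
               strand = x$strand %||% "+",
               tss = if ((x$strand %||% "+") == "+") x$start else x$end,
               start = x$start, end = x$end, stringsAsFactors = FALSE)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force CpG -> gene annotation oracle: scan every gene, window
# arithmetic done independently of the package's interval machinery.
annotate_oracle <- function(chrom, pos, genes) {
  best <- NULL
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$chrom != chrom) next
    feature <- NULL
    if (pos >= g$start && pos <= g$end) feature <- "gene_body"
    else if (g$strand == "+" && pos >= g$tss - 1000 && pos <= g$tss - 1)
      feature <- "promoter_1kb"
    else if (g$strand == "-" && pos >= g$tss + 1 && pos <= g$tss + 1000)
      feature <- "promoter_1kb"
    else if (g$strand == "+" && pos >= g$tss - 5000 && pos <= g$tss - 1001)
      feature <- "upstream_1to5kb"
    else if (g$strand == "-" && pos >= g$tss + 1001 && pos <= g$tss + 5000)
      feature <- "upstream_1to5kb"
    if (is.null(feature)) next
    cand <- list(gene_id = g$gene_id, feature = feature,
                 dist = abs(pos - g$tss))
    if (is.null(best) || cand$dist < best$dist ||
        (cand$dist == best$dist && cand$gene_id < best$gene_id))
      best <- cand
  }
  best
}

# O(n^2) single-linkage chaining oracle for DMR construction.
dmr_oracle <- function(pos, max_gap = 500, min_cpgs = 2) {
  pos <- sort(unique(pos))
  if (!length(pos)) return(list())
  clusters <- list(pos[1])
  for (p in pos[-1]) {
    last <- clusters[[length(clusters)]]
    if (p - max(last) <= max_gap)
      clusters[[length(clusters)]] <- c(last, p)
    else clusters[[length(clusters) + 1]] <- p
  }
  Filter(function(cl) length(cl) >= min_cpgs, clusters)
}

# Random DE-table pair for protection-set property tests; plants exact-0.05
# boundary rows.
random_de_pair <- function(n_genes = 60, seed = 1) {
  set.seed(seed)
  ids <- sprintf("g%03d", seq_len(n_genes))
  mk <- function() {
    fdr <- runif(n_genes)
    fdr[sample(n_genes, 3)] <- 0.05  # exact boundary
    data.frame(gene_id = sample(ids), contrast = "genotype",
               log2fc = rnorm(n_genes), p_value = runif(n_genes),
               fdr = fdr, stringsAsFactors = FALSE)
  }
  list(control = mk(), supplemented = mk())
}

# Hand-enumerated oracle for the three depth-filter rules on a small matrix.
filter_oracle <- function(total, min_depth, q, frac) {
  caps <- apply(total, 2, function(col) {
    cov <- col[col > 0]
    if (!length(cov)) Inf else quantile(cov, q, type = 7, names = FALSE)
  })
  unmasked <- matrix(FALSE, nrow(total), ncol(total))
  for (i in seq_len(nrow(total)))
    for (j in seq_len(ncol(total)))
      unmasked[i, j] <- total[i, j] >= min_depth && total[i, j] <= caps[j]
  which(rowMeans(unmasked) >= frac)
}

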