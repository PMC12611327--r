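#' Minimal negative-binomial Wald differential expression caller
#'
#' Plumbing so synthetic runs are self-contained; deliberately simpler than
#' (and not equivalent to) full DE packages, which real-data users should
#' supply tables from. For a two-level contrast the NB GLM with log link is
#' saturated, so the MLE fold change is the log2 ratio of normalized group
#' means and the Wald standard error follows from the observed information
#' with a moderated common dispersion (median of per-gene method-of-moments
#' estimates). A gene with identical normalized counts in the two groups
#' therefore has log2fc exactly 0; all-zero genes give an NA record.
#'
#' @param counts integer matrix, genes x samples.
#' @param samples data.frame with one row per column of \code{counts}.
#' @param contrast name of the two-level column in \code{samples}.
#' @param levels level order, reference first; defaults to sorted unique.
#' @param size_factors per-sample normalization factors; \code{NULL}
#'   estimates median-of-ratios factors (total-count fallback when no gene
#'   is expressed everywhere).
#' @return data.frame: \code{gene_id, contrast, log2fc, p_value, fdr}.
#' @export
callDeMinimal <- function(counts, samples, contrast, levels = NULL,
                          size_factors = NULL) {
  counts <- as.matrix(counts)
  v <- as.character(samples[[contrast]])
  if (is.null(levels)) levels <- sort(unique(v))
  stopifnot(length(levels) == 2)
  grp <- factor(v, levels = levels)
  if (any(is.na(grp))) stop("samples outside contrast levels")
  if (min(table(grp)) < 2) stop("need >= 2 samples per level")
  if (is.null(size_factors)) size_factors <- .size_factors(counts)
  norm <- sweep(counts, 2, size_factors, "/")
  i1 <- grp == levels[1]; i2 <- grp == levels[2]
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- rowMeans(norm[, i1, drop = FALSE])
  m2 <- rowMeans(norm[, i2, drop = FALSE])
  v1 <- apply(norm[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(norm[, i2, drop = FALSE], 1, stats::var)
  # method-of-moments NB dispersion alpha: var = m + alpha m^2, pooled
  mbar <- (m1 * n1 + m2 * n2) / (n1 + n2)
  vbar <- (v1 * (n1 - 1) + v2 * (n2 - 1)) / (n1 + n2 - 2)
  alpha_g <- (vbar - mbar) / mbar^2
  alpha <- stats::median(alpha_g[is.finite(alpha_g) & mbar > 0], na.rm = TRUE)
  alpha <- max(1e-8, alpha, na.rm = TRUE)
  zero_one_side <- (m1 == 0) != (m2 == 0)
  m1a <- ifelse(zero_one_side, m1 + 0.5, m1)
  m2a <- ifelse(zero_one_side, m2 + 0.5, m2)
  log2fc <- log2(m2a / m1a)
  se <- sqrt((1 / m1a + alpha) / n1 + (1 / m2a + alpha) / n2) / log(2)
  z <- log2fc / se
  # refer the Wald statistic to a t distribution to account for dispersion
  # estimation at small n
  p <- 2 * stats::pt(-abs(z), df = n1 + n2 - 2)
  allzero <- m1 == 0 & m2 == 0
  log2fc[allzero] <- NA; p[allzero] <- NA
  fdr <- rep(NA_real_, length(p))
  fdr[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], "BH")
  data.frame(gene_id = rownames(counts), contrast = contrast,
             log2fc = log2fc, p_value = p, fdr = fdr,
             stringsAsFactors = FALSE, row.names = NULL)
}

.size_factors <- function(counts) {
  logs <- log(counts)
  fin <- rowSums(is.finite(logs)) == ncol(counts)
  if (!any(fin)) {
    sf <- colSums(counts); return(sf / exp(mean(log(sf))))
  }
  ref <- rowMeans(logs[fin, , drop = FALSE])
  sf <- apply(logs[fin, , drop = FALSE], 2,
              function(l) exp(stats::median(l - ref)))
  sf / exp(mean(log(sf)))
}

#' Choline-protected gene sets
#'
#' Genes differentially expressed between mutant and wild type under the
#' control diet (FDR < 0.05, strict) but no longer so under the supplemented
#' diet (FDR > 0.05, strict): supplementation prevented the expression
#' change. Genes at exactly 0.05 fall in neither class. The set is ranked
#' ascending by control-contrast FDR and truncated to \code{top_n}.
#'
#' @param de_control DE table (mutant vs WT, control diet).
#' @param de_supplemented DE table (mutant vs WT, supplemented diet).
#' @param top_n truncation after ranking.
#' @return data.frame: \code{gene_id, fdr_control, fdr_supplemented,
#'   delta_log2fc} (supplemented minus control log2fc), \code{rank}.
#' @export
protectedGenes <- function(de_control, de_supplemented, top_n = 2000L) {
  j <- merge(de_control[, c("gene_id", "log2fc", "fdr")],
             de_supplemented[, c("gene_id", "log2fc", "fdr")],
             by = "gene_id", suffixes = c("_control", "_supplemented"))
  n_dropped <- nrow(de_control) + nrow(de_supplemented) - 2 * nrow(j)
  keep <- !is.na(j$fdr_control) & !is.na(j$fdr_supplemented) &
    j$fdr_control < 0.05 & j$fdr_supplemented > 0.05
  out <- j[keep, , drop = FALSE]
  out <- out[order(out$fdr_control, out$gene_id), , drop = FALSE]
  out <- utils::head(out, top_n)
  res <- data.frame(gene_id = out$gene_id,
                    fdr_control = out$fdr_control,
                    fdr_supplemented = out$fdr_supplemented,
                    delta_log2fc = out$log2fc_supplemented - out$log2fc_control,
                    rank = seq_len(nrow(out)), stringsAsFactors = FALSE)
  attr(res, "n_unmatched_genes") <- n_dropped
  res
}

#' Overlap of protected genes with differentially methylated genes
#'
#' @param protected table from [protectedGenes()].
#' @param dmgs per-gene table from [summarizeDmgs()].
#' @return list: \code{n_protected}, \code{n_overlap}, \code{fraction}
#'   (NA with a warning for an empty protected set) and the joined
#'   \code{table}.
#' @export
joinProtectionMethylation <- function(protected, dmgs) {
  if (!nrow(protected)) {
    warning("empty protected gene set; overlap fraction undefined")
    return(list(n_protected = 0L, n_overlap = 0L, fraction = NA_real_,
                table = protected))
  }
  tab <- merge(protected, dmgs, by = "gene_id", all.x = TRUE)
  tab$is_dmg <- !is.na(tab$n_dmcs)
  list(n_protected = nrow(protected),
       n_overlap = sum(tab$is_dmg),
       fraction = mean(tab$is_dmg),
       table = tab[order(tab$rank), ])
}
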