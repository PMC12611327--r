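#' Candidate local CpG-gene pairs
#'
#' A DMC is paired with the gene it maps to when the methylation change
#' exceeds 2.5 percentage points (strict), the gene is differentially
#' expressed under the contrast's FDR rule (genotype < 0.05, diet < 0.1) and
#' its |log2 fold change| exceeds 0.1 (strict; filters shrinkage artefacts
#' at low counts).
#'
#' @param dmcs annotated DMC records from [testDmc()] (with \code{gene_id}).
#' @param degs DE table with \code{gene_id, log2fc, fdr}.
#' @param min_delta minimum |delta_pct|, strict.
#' @param min_lfc minimum |log2fc|, strict.
#' @param fdr_cutoff DE significance rule; default follows the contrast
#'   recorded in \code{dmcs} (0.05 for genotype, 0.1 for diet).
#' @return data.frame of pairs: \code{chrom, pos, gene_id, delta_pct,
#'   log2fc}.
#' @export
pairLocal <- function(dmcs, degs, min_delta = 2.5, min_lfc = 0.1,
                      fdr_cutoff = NULL) {
  if (is.null(fdr_cutoff))
    fdr_cutoff <- if (identical(unique(dmcs$contrast), "diet")) 0.1 else 0.05
  d <- dmcs[!is.na(dmcs$gene_id) & !is.na(dmcs$delta_pct) &
              abs(dmcs$delta_pct) > min_delta, , drop = FALSE]
  g <- degs[!is.na(degs$fdr) & degs$fdr < fdr_cutoff &
              abs(degs$log2fc) > min_lfc, , drop = FALSE]
  d <- d[d$gene_id %in% g$gene_id, , drop = FALSE]
  data.frame(chrom = d$chrom, pos = d$pos, gene_id = d$gene_id,
             delta_pct = d$delta_pct,
             log2fc = g$log2fc[match(d$gene_id, g$gene_id)],
             stringsAsFactors = FALSE)
}

#' Candidate distal CpG-gene pairs
#'
#' All same-chromosome pairs of a DMC with |delta| above the stricter distal
#' cutoff and a gene from the distal-eligible DE list (top \code{top_n_degs}
#' by FDR for the genotype contrast; all diet DEGs at the relaxed FDR < 0.1
#' with |log2fc| > 0.1 for the diet contrast), excluding cis pairs where the
#' site lies in the gene body or within \code{cis_tss_window} of the TSS.
#'
#' @param dmcs DMC records (annotation not required).
#' @param degs DE table.
#' @param genes gene model GRanges.
#' @param min_delta minimum |delta_pct|, strict.
#' @param top_n_degs genotype-contrast DE list truncation (by FDR).
#' @param cis_tss_window half-width of the excluded TSS window, bp.
#' @param contrast \code{"genotype"} or \code{"diet"}; default from
#'   \code{dmcs}.
#' @param min_lfc |log2fc| gate on eligible genes.
#' @return data.frame of pairs as for [pairLocal()].
#' @export
pairDistal <- function(dmcs, degs, genes, min_delta = 5.0,
                       top_n_degs = 1000L, cis_tss_window = 5000L,
                       contrast = NULL, min_lfc = 0.1) {
  if (is.null(contrast)) contrast <- unique(dmcs$contrast)[1]
  d <- dmcs[!is.na(dmcs$delta_pct) & abs(dmcs$delta_pct) > min_delta, ,
            drop = FALSE]
  g <- degs[!is.na(degs$fdr) & abs(degs$log2fc) > min_lfc, , drop = FALSE]
  if (identical(contrast, "diet")) {
    g <- g[g$fdr < 0.1, , drop = FALSE]
  } else {
    g <- g[g$fdr < 0.05, , drop = FALSE]
    g <- g[order(g$fdr), , drop = FALSE]
    g <- utils::head(g, top_n_degs)
  }
  gm <- as.data.frame(genes)[, c("seqnames", "start", "end")]
  gm$gene_id <- S4Vectors::mcols(genes)$gene_id
  gm$tss <- S4Vectors::mcols(genes)$tss
  gm <- gm[gm$gene_id %in% g$gene_id, , drop = FALSE]
  if (!nrow(d) || !nrow(gm))
    return(data.frame(chrom = character(), pos = integer(),
                      gene_id = character(), delta_pct = numeric(),
                      log2fc = numeric()))
  pairs <- merge(
    data.frame(chrom = d$chrom, pos = d$pos, delta_pct = d$delta_pct),
    data.frame(chrom = as.character(gm$seqnames), gene_id = gm$gene_id,
               g_start = gm$start, g_end = gm$end, tss = gm$tss),
    by = "chrom")
  cis <- (pairs$pos >= pairs$g_start & pairs$pos <= pairs$g_end) |
    abs(pairs$pos - pairs$tss) <= cis_tss_window
  pairs <- pairs[!cis, , drop = FALSE]
  data.frame(chrom = pairs$chrom, pos = pairs$pos, gene_id = pairs$gene_id,
             delta_pct = pairs$delta_pct,
             log2fc = g$log2fc[match(pairs$gene_id, g$gene_id)],
             stringsAsFactors = FALSE)
}

#' Regress a gene's stabilized expression on a CpG's percent methylation
#'
#' Ordinary least squares of z-scaled expression on z-scaled percent
#' methylation plus covariates (age, sex, latent cell proportions), so the
#' methylation coefficient is standardized. One outlier pass drops points
#' with Cook's distance > 4/n AND |standardized residual| > 3 (conjunctive;
#' at most floor(n/4) points, worst first) and refits once. The partial
#' correlation of expression and methylation given the covariates is
#' computed from covariate-residualized vectors.
#'
#' @param expr numeric expression vector (variance-stabilized), one value
#'   per sample.
#' @param meth_pct numeric percent methylation per sample; \code{NA} where
#'   uncovered (those samples are dropped).
#' @param covariate_df data.frame of covariates aligned with \code{expr}.
#' @param min_n minimum complete observations.
#' @return one-row data.frame: \code{beta_methylation, p_value, partial_r,
#'   n_used, outliers_removed, reason} (\code{NA} record with a reason code
#'   on rank deficiency or short data).
#' @export
regressPair <- function(expr, meth_pct, covariate_df = NULL, min_n = 8L) {
  na_rec <- function(reason)
    data.frame(beta_methylation = NA_real_, p_value = NA_real_,
               partial_r = NA_real_, n_used = 0L, outliers_removed = 0L,
               reason = reason, stringsAsFactors = FALSE)
  use <- !is.na(meth_pct) & !is.na(expr)
  if (!is.null(covariate_df))
    use <- use & stats::complete.cases(covariate_df)
  if (sum(use) < min_n) return(na_rec("too_few_obs"))
  y <- expr[use]; x <- meth_pct[use]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(na_rec("rank_deficient"))
  cv <- NULL
  if (!is.null(covariate_df)) {
    cv <- covariate_df[use, , drop = FALSE]
    cv <- cv[, vapply(cv, function(v) length(unique(v)) > 1, logical(1)),
             drop = FALSE]
  }
  build <- function(keep) {
    d <- data.frame(y = as.numeric(scale(y[keep])),
                    x = as.numeric(scale(x[keep])))
    if (!is.null(cv) && ncol(cv)) d <- cbind(d, cv[keep, , drop = FALSE])
    d
  }
  keep <- rep(TRUE, length(y))
  dat <- build(keep)
  fit <- stats::lm(y ~ ., data = dat)
  if (fit$rank < ncol(stats::model.matrix(fit))) return(na_rec("rank_deficient"))
  n <- nrow(dat)
  cd <- stats::cooks.distance(fit)
  rs <- stats::rstandard(fit)
  flag <- which(cd > 4 / n & abs(rs) > 3)
  if (length(flag) > floor(n / 4))
    flag <- flag[order(cd[flag], decreasing = TRUE)][seq_len(floor(n / 4))]
  removed <- length(flag)
  if (removed) {
    keep[flag] <- FALSE
    if (stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0)
      return(na_rec("rank_deficient"))
    # re-standardize on the retained points so the reported beta is not
    # distorted by the removed outliers' variance inflation
    dat <- build(keep)
    fit <- stats::lm(y ~ ., data = dat)
    if (fit$rank < ncol(stats::model.matrix(fit)))
      return(na_rec("rank_deficient"))
  }
  sm <- summary(fit)$coefficients
  if (!"x" %in% rownames(sm)) return(na_rec("rank_deficient"))
  beta <- sm["x", "Estimate"]; p <- sm["x", "Pr(>|t|)"]
  # partial correlation via covariate residualization on the final data
  covs <- setdiff(names(dat), c("y", "x"))
  if (length(covs)) {
    fy <- stats::lm(stats::reformulate(covs, "y"), data = dat)
    fx <- stats::lm(stats::reformulate(covs, "x"), data = dat)
    pr <- stats::cor(stats::residuals(fy), stats::residuals(fx))
  } else pr <- stats::cor(dat$y, dat$x)
  data.frame(beta_methylation = beta, p_value = p, partial_r = pr,
             n_used = nrow(dat), outliers_removed = removed,
             reason = NA_character_, stringsAsFactors = FALSE)
}

#' Discover expression-linked CpGs (ECpGs)
#'
#' Applies [pairLocal()] or [pairDistal()] and then [regressPair()] to every
#' candidate pair. Local ECpGs are called at raw p < 0.05 (the published
#' asymmetry; noted in the output metadata); distal pairs are corrected by
#' Benjamini-Hochberg within the (contrast, scope) family and called at
#' q < 0.05. Output rows are ordered by chromosome, position, gene.
#'
#' @param scope \code{"local"} or \code{"distal"}.
#' @param dmcs DMC records for the contrast (annotated for local scope).
#' @param degs DE table for the matching contrast.
#' @param vst stabilized expression matrix (genes x samples).
#' @param mm \linkS4class{MethylMatrix} aligned with \code{vst} columns.
#' @param covariates colData columns adjusted for (age is added as centered
#'   months when present).
#' @param genes gene model GRanges (needed for distal scope).
#' @param p_cutoff local ECpG call threshold (raw p).
#' @param q_cutoff distal ECpG call threshold (BH q).
#' @param ... passed to the pairing function.
#' @return data.frame of records: \code{chrom, pos, gene_id, scope,
#'   beta_methylation, p_value, q_value, partial_r, n_used,
#'   outliers_removed, delta_pct, is_ecpg, reason}.
#' @export
runIntegration <- function(scope = c("local", "distal"), dmcs, degs, vst, mm,
                           covariates = c("sex", "lmc_neuron",
                                          "lmc_microglia"),
                           genes = NULL, p_cutoff = 0.05, q_cutoff = 0.05,
                           ...) {
  scope <- match.arg(scope)
  # regress within the contrast's sample set (genotype: control diet only;
  # diet: mutants only), matching the DMC contrast definition
  contrast <- unique(dmcs$contrast)[1]
  cd0 <- as.data.frame(SummarizedExperiment::colData(mm))
  keep <- rep(TRUE, ncol(mm))
  if (identical(contrast, "genotype") && "diet" %in% names(cd0))
    keep <- cd0$diet == "control"
  if (identical(contrast, "diet") && "genotype" %in% names(cd0))
    keep <- cd0$genotype == "AppNLGF"
  mm <- mm[, keep]
  vst <- vst[, colnames(mm), drop = FALSE]
  pairs <- if (scope == "local") pairLocal(dmcs, degs, ...)
           else pairDistal(dmcs, degs, genes, ...)
  empty <- data.frame(chrom = character(), pos = integer(),
                      gene_id = character(), scope = character(),
                      beta_methylation = numeric(), p_value = numeric(),
                      q_value = numeric(), partial_r = numeric(),
                      n_used = integer(), outliers_removed = integer(),
                      delta_pct = numeric(), is_ecpg = logical(),
                      reason = character(), stringsAsFactors = FALSE)
  if (!nrow(pairs)) return(empty)
  cd <- as.data.frame(SummarizedExperiment::colData(mm))
  cov_df <- cd[, intersect(covariates, names(cd)), drop = FALSE]
  if ("age_months" %in% names(cd))
    cov_df$age_c <- cd$age_months - mean(cd$age_months)
  pct <- methPct(mm)
  lab <- siteLabels(mm)
  rows <- match(paste0(pairs$chrom, ":", pairs$pos), lab)
  gidx <- match(pairs$gene_id, rownames(vst))
  recs <- lapply(seq_len(nrow(pairs)), function(k) {
    if (is.na(rows[k]) || is.na(gidx[k]))
      return(data.frame(beta_methylation = NA_real_, p_value = NA_real_,
                        partial_r = NA_real_, n_used = 0L,
                        outliers_removed = 0L, reason = "missing_input"))
    regressPair(vst[gidx[k], ], pct[rows[k], ], cov_df)
  })
  out <- cbind(pairs[, c("chrom", "pos", "gene_id")],
               scope = scope, do.call(rbind, recs),
               delta_pct = pairs$delta_pct)
  ok <- !is.na(out$p_value)
  out$q_value <- NA_real_
  if (scope == "distal") {
    out$q_value[ok] <- stats::p.adjust(out$p_value[ok], "BH")
    out$is_ecpg <- !is.na(out$q_value) & out$q_value < q_cutoff
  } else {
    out$is_ecpg <- ok & out$p_value < p_cutoff
  }
  out <- out[order(out$chrom, out$pos, out$gene_id), ]
  rownames(out) <- NULL
  attr(out, "multiple_testing") <-
    if (scope == "local") "raw p < 0.05 (local scope, by design)"
    else "BH within (contrast, scope) family"
  out
}
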