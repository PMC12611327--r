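#' Depth-filter a MethylMatrix
#'
#' Applies the three RRBS quality rules: per sample, cells with read depth
#' below \code{min_depth} or above that sample's empirical
#' \code{max_depth_quantile} (type-7, computed over the sample's covered
#' sites; high depth flags PCR bias) are masked (set to zero coverage); a
#' site is retained iff it is unmasked in at least \code{min_sample_frac}
#' of samples (inclusive). Site order is preserved.
#'
#' @param x a \linkS4class{MethylMatrix}.
#' @param min_depth minimum read depth per cell.
#' @param max_depth_quantile per-sample empirical depth quantile above which
#'   cells are masked.
#' @param min_sample_frac minimum fraction of unmasked samples per site.
#' @param depth_caps optional precomputed per-sample depth caps (named
#'   numeric); when supplied, quantiles are not recomputed, which makes the
#'   filter idempotent.
#' @return The filtered MethylMatrix; the caps used are stored in
#'   \code{metadata(x)$depth_caps}.
#' @export
filterSites <- function(x, min_depth = 10, max_depth_quantile = 0.999,
                        min_sample_frac = 0.5, depth_caps = NULL) {
  t <- totalReads(x); m <- methReads(x)
  if (is.null(depth_caps)) {
    depth_caps <- vapply(seq_len(ncol(t)), function(j) {
      cov <- t[t[, j] > 0L, j]
      if (!length(cov)) return(Inf)
      stats::quantile(cov, max_depth_quantile, type = 7, names = FALSE)
    }, numeric(1))
    names(depth_caps) <- colnames(t)
  }
  mask <- t < min_depth | sweep(t, 2, depth_caps, ">")
  m[mask] <- 0L; t[mask] <- 0L
  keep <- rowMeans(!mask) >= min_sample_frac
  if (!any(keep)) warning("no sites survive filtering")
  out <- MethylMatrix(m[keep, , drop = FALSE], t[keep, , drop = FALSE],
                      cpgSites(x)[keep],
                      SummarizedExperiment::colData(x))
  S4Vectors::metadata(out)$depth_caps <- depth_caps
  out
}

#' Covariate-adjusted per-CpG differential methylation test
#'
#' Fits, at every site, a binomial logistic regression of (methylated,
#' unmethylated) read counts on the contrast plus covariates and reports the
#' Wald p-value of the contrast term. Following the published design,
#' \code{contrast = "genotype"} compares mutant vs wild type within the
#' control diet and \code{contrast = "diet"} compares supplemented vs control
#' within mutants. \code{delta_pct} is the difference of group mean percent
#' methylation (level 2 minus level 1). q-values are Benjamini-Hochberg
#' within the tested family (this package substitutes BH for the sliding
#' linear model correction used by some callers; recorded in the output
#' metadata). Sites with a singular or separated fit get \code{NA} p and are
#' excluded from the BH family.
#'
#' @param x a filtered \linkS4class{MethylMatrix} whose colData carries the
#'   design.
#' @param contrast colData column to test; \code{"genotype"} and
#'   \code{"diet"} get the study's default subsetting and level order, any
#'   other two-level column is tested as-is.
#' @param covariates character vector of colData columns adjusted for.
#' @param include_age add centered numeric age (months) as a covariate;
#'   ignored (with the study's convention) when stratifying by age.
#' @param stratum optional named list subsetting samples, e.g.
#'   \code{list(age_months = 3)}.
#' @param levels optional length-2 level order (reference first).
#' @param overdispersion \code{"none"} (binomial, default) or
#'   \code{"mcfadden"}: scale the Wald covariance by the Pearson
#'   overdispersion when it exceeds 1.
#' @param q_cutoff DMC flag threshold on the q-value.
#' @param genes optional gene model GRanges for nearest-gene annotation.
#' @return data.frame of per-site records: \code{chrom, pos, contrast,
#'   delta_pct, p_value, q_value, direction, is_dmc, n_used, gene_id,
#'   feature}; attribute \code{fdr_method} documents the correction.
#' @export
testDmc <- function(x, contrast = c("genotype", "diet"),
                    covariates = c("sex", "lmc_neuron", "lmc_microglia"),
                    include_age = TRUE, stratum = NULL, levels = NULL,
                    overdispersion = c("none", "mcfadden"),
                    q_cutoff = 0.05, genes = NULL) {
  overdispersion <- match.arg(overdispersion)
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  contrast <- contrast[1]
  if (!contrast %in% names(cd)) stop("contrast column '", contrast,
                                     "' not in colData")
  if ("region" %in% names(cd) && length(unique(cd$region)) > 1)
    stop("colData mixes brain regions; analyze regions separately")
  keep <- rep(TRUE, nrow(cd))
  if (contrast == "genotype") {
    if (is.null(levels)) levels <- c("WT", "AppNLGF")
    if ("diet" %in% names(cd)) keep <- cd$diet == "control"
  } else if (contrast == "diet") {
    if (is.null(levels)) levels <- c("control", "supplemented")
    if ("genotype" %in% names(cd)) keep <- cd$genotype == "AppNLGF"
  }
  if (!is.null(stratum))
    for (nm in names(stratum)) keep <- keep & cd[[nm]] %in% stratum[[nm]]
  if (!is.null(stratum) && "age_months" %in% names(stratum))
    include_age <- FALSE
  cd <- cd[keep, , drop = FALSE]
  x <- x[, keep]
  if (is.null(levels)) {
    levels <- sort(unique(as.character(cd[[contrast]])))
    if (length(levels) != 2) stop("contrast must have exactly two levels")
  }
  grp <- as.integer(factor(as.character(cd[[contrast]]), levels = levels)) - 1L
  if (any(is.na(grp))) stop("samples outside the contrast levels")
  covariates <- intersect(covariates, names(cd))
  df <- data.frame(grp = grp)
  for (v in covariates) df[[v]] <- cd[[v]]
  if (include_age && "age_months" %in% names(cd))
    df$age_c <- cd$age_months - mean(cd$age_months)
  X <- stats::model.matrix(~ ., df)

  meth <- methReads(x); total <- totalReads(x)
  pct <- methPct(x)
  n_sites <- nrow(x)
  p_value <- rep(NA_real_, n_sites); delta <- rep(NA_real_, n_sites)
  n_used <- integer(n_sites)
  for (i in seq_len(n_sites)) {
    use <- total[i, ] > 0L
    n_used[i] <- sum(use)
    if (sum(use & grp == 0L) < 2L || sum(use & grp == 1L) < 2L) next
    delta[i] <- mean(pct[i, use & grp == 1L]) - mean(pct[i, use & grp == 0L])
    p_value[i] <- .binom_wald_p(X[use, , drop = FALSE],
                                meth[i, use], total[i, use], overdispersion)
  }
  q_value <- rep(NA_real_, n_sites)
  ok <- !is.na(p_value)
  q_value[ok] <- stats::p.adjust(p_value[ok], "BH")
  rr <- cpgSites(x)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                    pos = BiocGenerics::start(rr),
                    contrast = contrast, delta_pct = delta,
                    p_value = p_value, q_value = q_value,
                    direction = ifelse(delta > 0, "hyper", "hypo"),
                    is_dmc = !is.na(q_value) & q_value < q_cutoff,
                    n_used = n_used, stringsAsFactors = FALSE)
  if (!is.null(genes)) {
    ann <- annotateCpGs(rr, genes)
    out$gene_id <- ann$gene_id
    out$feature <- ann$feature
  }
  attr(out, "fdr_method") <- "Benjamini-Hochberg (substituted for SLIM)"
  attr(out, "n_failed_fits") <- sum(!ok)
  out
}

# Wald p for column 2 of X in a binomial logistic fit of (meth, total).
# Returns NA on rank deficiency, non-convergence or separation.
.binom_wald_p <- function(X, meth, total, overdispersion = "none") {
  fit <- tryCatch(suppressWarnings(
    stats::glm.fit(X, meth / total, weights = total,
                   family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged || fit$rank < ncol(X)) return(NA_real_)
  co <- fit$coefficients
  V <- .glmfit_vcov(fit, ncol(X))
  if (is.null(V)) return(NA_real_)
  se <- sqrt(diag(V))
  if (overdispersion == "mcfadden") {
    mu <- fit$fitted.values
    pearson <- sum(total * (meth / total - mu)^2 / (mu * (1 - mu)))
    phi <- pearson / max(1, nrow(X) - ncol(X))
    se <- se * sqrt(max(1, phi))
  }
  if (!is.finite(se[2]) || se[2] > 1e3 || abs(co[2]) > 50) return(NA_real_)
  2 * stats::pnorm(-abs(co[2] / se[2]))
}

#' Gene-level summary of differentially methylated CpGs
#'
#' Aggregates DMC records by their annotated gene: number of DMCs, mean
#' percent-methylation change (net gene methylation) and the dominant
#' direction. Records without a gene or not flagged as DMCs are ignored.
#'
#' @param dmcs data.frame from [testDmc()] (annotated, i.e. carrying
#'   \code{gene_id}); if \code{genes} is supplied annotation is redone here.
#' @param genes optional gene model GRanges.
#' @return data.frame: \code{gene_id, n_dmcs, mean_delta_pct, direction}.
#' @export
summarizeDmgs <- function(dmcs, genes = NULL) {
  if (!is.null(genes)) {
    gr <- GenomicRanges::GRanges(dmcs$chrom,
                                 IRanges::IRanges(dmcs$pos, width = 1L))
    dmcs$gene_id <- annotateCpGs(gr, genes)$gene_id
  }
  if (!"gene_id" %in% names(dmcs))
    stop("dmcs must carry gene_id (annotate first or pass genes=)")
  d <- dmcs[dmcs$is_dmc & !is.na(dmcs$gene_id), , drop = FALSE]
  if (!nrow(d))
    return(data.frame(gene_id = character(), n_dmcs = integer(),
                      mean_delta_pct = numeric(), direction = character()))
  sp <- split(d$delta_pct, d$gene_id)
  data.frame(gene_id = names(sp),
             n_dmcs = lengths(sp),
             mean_delta_pct = vapply(sp, mean, numeric(1)),
             direction = vapply(sp, function(v) {
               s <- sum(sign(v))
               if (s > 0) "hyper" else if (s < 0) "hypo" else "mixed"
             }, character(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
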