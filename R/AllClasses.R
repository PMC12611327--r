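#' MethylMatrix: per-CpG, per-sample bisulfite read counts
#'
#' An S4 container for RRBS-style methylation data, extending
#' \linkS4class{RangedSummarizedExperiment}. Rows are CpG sites (1-based
#' point coordinates, strand-aware, never collapsed across strands), columns
#' are samples. Two integer assays are carried: \code{meth} (methylated read
#' count) and \code{total} (total read count); percent methylation is the
#' derived quantity \code{100 * meth / total}, defined only where
#' \code{total > 0}. The sample design table (genotype, diet, age, sex,
#' region, latent cell-proportion covariates, amyloid burden) lives in
#' \code{colData}.
#'
#' @slot .Data inherited RangedSummarizedExperiment structure.
#' @aliases MethylMatrix-class
#' @exportClass MethylMatrix
setClass("MethylMatrix", contains = "RangedSummarizedExperiment")

setValidity("MethylMatrix", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("meth", "total") %in% an))
    return("assays 'meth' and 'total' are required")
  m <- SummarizedExperiment::assay(object, "meth")
  t <- SummarizedExperiment::assay(object, "total")
  if (any(m < 0, na.rm = TRUE) || any(t < 0, na.rm = TRUE))
    return("read counts must be nonnegative")
  if (any(m > t, na.rm = TRUE))
    return("meth counts exceed total counts")
  rr <- SummarizedExperiment::rowRanges(object)
  if (length(rr) && any(BiocGenerics::width(rr) != 1L))
    return("CpG sites must be 1-bp point ranges")
  key <- paste(GenomicRanges::seqnames(rr), BiocGenerics::start(rr),
               BiocGenerics::strand(rr))
  if (anyDuplicated(key))
    return("duplicate (chrom, pos, strand) CpG sites")
  TRUE
})

#' Construct a MethylMatrix
#'
#' @param meth,total integer matrices (sites x samples) of methylated and
#'   total read counts; \code{meth <= total} elementwise.
#' @param sites a \code{GRanges} of 1-bp CpG positions (1-based), or a
#'   data.frame with columns \code{chrom}, \code{pos} and optionally
#'   \code{strand}.
#' @param sampleData optional \code{DataFrame}/data.frame of per-sample
#'   covariates, one row per column of \code{meth}.
#' @return A \linkS4class{MethylMatrix}.
#' @export
MethylMatrix <- function(meth, total, sites, sampleData = NULL) {
  meth <- as.matrix(meth); total <- as.matrix(total)
  storage.mode(meth) <- "integer"; storage.mode(total) <- "integer"
  if (is.data.frame(sites)) {
    strand <- if ("strand" %in% names(sites)) sites$strand else "*"
    sites <- GenomicRanges::GRanges(
      sites$chrom, IRanges::IRanges(sites$pos, width = 1L), strand = strand)
  }
  if (is.null(sampleData))
    sampleData <- S4Vectors::DataFrame(row.names = colnames(meth))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(meth = meth, total = total),
    rowRanges = sites,
    colData = S4Vectors::DataFrame(sampleData))
  methods::new("MethylMatrix", se)
}

#' @describeIn MethylMatrix methylated read counts (sites x samples).
#' @param x a MethylMatrix.
#' @export
methReads <- function(x) SummarizedExperiment::assay(x, "meth")

#' @describeIn MethylMatrix total read counts (sites x samples).
#' @export
totalReads <- function(x) SummarizedExperiment::assay(x, "total")

#' @describeIn MethylMatrix percent methylation, \code{NA} where uncovered.
#' @export
methPct <- function(x) {
  m <- methReads(x); t <- totalReads(x)
  p <- 100 * m / t
  p[t == 0L] <- NA_real_
  p
}

#' @describeIn MethylMatrix CpG coordinates as a GRanges.
#' @export
cpgSites <- function(x) SummarizedExperiment::rowRanges(x)

#' @describeIn MethylMatrix canonical "chrom:pos" site labels.
#' @export
siteLabels <- function(x) {
  rr <- cpgSites(x)
  paste0(GenomicRanges::seqnames(rr), ":", BiocGenerics::start(rr))
}

setMethod("show", "MethylMatrix", function(object) {
  cat("MethylMatrix with", nrow(object), "CpG sites x", ncol(object),
      "samples\n")
  t <- totalReads(object)
  cov <- mean(t[t > 0])
  cat("  mean covered depth:", round(cov, 1),
      "| uncovered cells:", sum(t == 0L), "\n")
  cd <- SummarizedExperiment::colData(object)
  if (ncol(cd))
    cat("  colData:", paste(colnames(cd), collapse = ", "), "\n")
  invisible(NULL)
})
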