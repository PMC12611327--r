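#' Read per-sample methylation bedGraph files into a MethylMatrix
#'
#' Reads one file per sample in the 6-column counts dialect produced by
#' standard bisulfite extractors: \code{chrom start0 end0 percent meth unmeth}
#' with BED-style 0-based half-open coordinates. Positions are converted to
#' 1-based points at the boundary (\code{pos = end0} for a 1-bp interval).
#' The returned matrix is the union of sites seen in any sample; cells absent
#' from a sample get \code{total = 0}.
#'
#' @param paths character vector of file paths, one per sample. Names, if
#'   present, become sample ids; otherwise basenames without extension.
#' @param dialect only \code{"counts"} (6-column) is supported; the 4-column
#'   percent dialect carries no read counts and is rejected with a pointer to
#'   the counts dialect.
#' @return A \linkS4class{MethylMatrix}.
#' @export
readMethylationBedGraph <- function(paths, dialect = c("counts", "percent")) {
  dialect <- match.arg(dialect)
  if (dialect == "percent")
    stop("percent dialect carries no read counts; supply counts bedGraphs ",
         "(chrom start end pct meth unmeth)")
  ids <- names(paths)
  if (is.null(ids)) ids <- sub("\\.[^.]*$", "", basename(paths))
  per <- lapply(seq_along(paths), function(i)
    .read_counts_bedgraph(paths[[i]]))
  keys <- unique(do.call(rbind, lapply(per, function(d) d[, c("chrom", "pos")])))
  keys <- keys[order(keys$chrom, keys$pos), , drop = FALSE]
  key <- paste(keys$chrom, keys$pos)
  n <- nrow(keys)
  meth <- matrix(0L, n, length(paths), dimnames = list(NULL, ids))
  total <- matrix(0L, n, length(paths), dimnames = list(NULL, ids))
  for (i in seq_along(per)) {
    j <- match(paste(per[[i]]$chrom, per[[i]]$pos), key)
    meth[j, i] <- per[[i]]$meth
    total[j, i] <- per[[i]]$total
  }
  MethylMatrix(meth, total,
               data.frame(chrom = keys$chrom, pos = keys$pos))
}

.read_counts_bedgraph <- function(path) {
  d <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                      data.table = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e)))
  if (ncol(d) < 6)
    stop("malformed bedGraph ", path, ": expected 6 columns ",
         "(chrom start end pct meth unmeth), found ", ncol(d))
  names(d)[1:6] <- c("chrom", "start0", "end0", "pct", "meth", "unmeth")
  bad <- which(!is.finite(d$start0) | !is.finite(d$end0) |
                 !is.finite(d$meth) | !is.finite(d$unmeth))
  if (length(bad))
    stop("malformed line ", bad[1], " in ", path)
  if (any(d$end0 - d$start0 != 1))
    stop("non point interval (width != 1) at line ",
         which(d$end0 - d$start0 != 1)[1], " in ", path)
  if (any(d$meth < 0) || any(d$unmeth < 0))
    stop("negative read count at line ",
         which(d$meth < 0 | d$unmeth < 0)[1], " in ", path)
  data.frame(chrom = as.character(d$chrom),
             pos = as.integer(d$end0),      # 0-based half-open -> 1-based point
             meth = as.integer(d$meth),
             total = as.integer(d$meth + d$unmeth))
}

#' Write a MethylMatrix as one counts bedGraph per sample
#'
#' Inverse of [readMethylationBedGraph()]: cells with \code{total = 0} are
#' omitted from a sample's file, so write-then-read round-trips counts
#' exactly.
#'
#' @param x a MethylMatrix.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written file paths (named by sample).
#' @export
writeMethylationBedGraph <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rr <- cpgSites(x)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  m <- methReads(x); t <- totalReads(x)
  paths <- character(ncol(x)); names(paths) <- colnames(x)
  for (i in seq_len(ncol(x))) {
    keep <- t[, i] > 0L
    d <- data.frame(chrom = chrom[keep], start0 = pos[keep] - 1L,
                    end0 = pos[keep],
                    pct = round(100 * m[keep, i] / t[keep, i], 2),
                    meth = m[keep, i], unmeth = t[keep, i] - m[keep, i])
    paths[i] <- file.path(dir, paste0(colnames(x)[i], ".bedGraph"))
    data.table::fwrite(d, paths[i], sep = "\t", col.names = FALSE)
  }
  invisible(paths)
}

#' Read a gene model table
#'
#' TSV with columns \code{gene_id, chrom, strand, tss, start, end}
#' (1-based inclusive gene-body bounds; \code{tss = start} on the plus
#' strand, \code{tss = end} on the minus strand).
#'
#' @param path TSV path.
#' @return A GRanges over gene bodies with mcols \code{gene_id} and
#'   \code{tss}.
#' @export
readGeneModel <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  geneModel(d)
}

#' Build a gene-model GRanges from a data.frame
#'
#' @param d data.frame with \code{gene_id, chrom, strand, tss, start, end}.
#' @return GRanges as for [readGeneModel()].
#' @export
geneModel <- function(d) {
  req <- c("gene_id", "chrom", "strand", "tss", "start", "end")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("gene model missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(d$start > d$end)) stop("gene model: start > end")
  plus <- d$strand == "+"
  if (any(plus & d$tss != d$start) || any(!plus & d$tss != d$end))
    stop("gene model: tss inconsistent with strand")
  gr <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start, d$end),
                               strand = d$strand)
  S4Vectors::mcols(gr)$gene_id <- as.character(d$gene_id)
  S4Vectors::mcols(gr)$tss <- as.integer(d$tss)
  gr
}

#' Read a regulatory-element BED track (cCRE-style)
#'
#' BED4 whose name column carries the element class; only \code{EnhD}
#' (distal enhancer-like) and \code{CTCF} elements are retained.
#'
#' @param path BED file path.
#' @return GRanges (1-based, as imported) with mcols \code{label}.
#' @export
readRegulatoryTrack <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  lab <- S4Vectors::mcols(gr)$name
  keep <- lab %in% c("EnhD", "CTCF")
  gr <- gr[keep]
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(label = lab[keep])
  gr
}

#' Read the sample design table
#'
#' @param path TSV with at least \code{sample_id, genotype, diet, age_months,
#'   sex, region}; latent cell-proportion covariates in \code{lmc_*} columns;
#'   \code{amyloid_pct_area} optional (may be NA for wild types).
#' @return data.frame keyed by \code{sample_id}.
#' @export
readSampleTable <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "genotype", "diet", "age_months", "sex", "region")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("sample table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(d$sample_id)) stop("duplicate sample_id")
  d
}

#' Write any per-record result table as TSV
#'
#' Header, stable column order, \code{NA} for missing values.
#'
#' @param records data.frame of homogeneous records.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeResultsTable <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Map CpG sites to genes with promoter/upstream/body windows
#'
#' A CpG maps to a gene if it lies in the gene body (start..end), within 1 kb
#' upstream of the TSS (\code{promoter_1kb}), or 1-5 kb upstream
#' (\code{upstream_1to5kb}); otherwise it maps to no gene. When several genes
#' capture a site, the tie is broken by smallest distance to TSS, then
#' lexicographic \code{gene_id}.
#'
#' @param sites GRanges of 1-bp CpG positions (or a MethylMatrix).
#' @param genes gene-model GRanges from [geneModel()].
#' @return data.frame with one row per site: \code{gene_id}, \code{feature}
#'   (\code{promoter_1kb}, \code{upstream_1to5kb}, \code{gene_body} or NA)
#'   and \code{dist_to_tss}.
#' @export
annotateCpGs <- function(sites, genes) {
  if (methods::is(sites, "MethylMatrix")) sites <- cpgSites(sites)
  win <- .gene_windows(genes)
  pos <- BiocGenerics::start(sites)
  hits <- GenomicRanges::findOverlaps(sites, win, ignore.strand = TRUE)
  out <- data.frame(gene_id = rep(NA_character_, length(sites)),
                    feature = rep(NA_character_, length(sites)),
                    dist_to_tss = rep(NA_integer_, length(sites)))
  if (!length(hits)) return(out)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  gid <- S4Vectors::mcols(win)$gene_id[s]
  feat <- S4Vectors::mcols(win)$feature[s]
  dist <- abs(pos[q] - S4Vectors::mcols(win)$tss[s])
  o <- order(q, dist, gid)
  q <- q[o]; gid <- gid[o]; feat <- feat[o]; dist <- dist[o]
  first <- !duplicated(q)
  out$gene_id[q[first]] <- gid[first]
  out$feature[q[first]] <- feat[first]
  out$dist_to_tss[q[first]] <- dist[first]
  out
}

# Windows per gene: body [start,end]; promoter = 1 kb immediately upstream of
# the TSS; upstream_1to5kb = the next 4 kb. Upstream is strand-aware.
# Windows truncated at position 1 are dropped when empty.
.gene_windows <- function(genes) {
  tss <- S4Vectors::mcols(genes)$tss
  gid <- S4Vectors::mcols(genes)$gene_id
  chrom <- as.character(GenomicRanges::seqnames(genes))
  plus <- as.character(BiocGenerics::strand(genes)) != "-"
  w <- rbind(
    data.frame(chrom, start = BiocGenerics::start(genes),
               end = BiocGenerics::end(genes), gene_id = gid, tss,
               feature = "gene_body"),
    data.frame(chrom, start = ifelse(plus, pmax(1L, tss - 1000L), tss + 1L),
               end = ifelse(plus, tss - 1L, tss + 1000L), gene_id = gid, tss,
               feature = "promoter_1kb"),
    data.frame(chrom, start = ifelse(plus, pmax(1L, tss - 5000L), tss + 1001L),
               end = ifelse(plus, tss - 1001L, tss + 5000L), gene_id = gid, tss,
               feature = "upstream_1to5kb"))
  w <- w[w$start <= w$end, , drop = FALSE]
  win <- GenomicRanges::GRanges(w$chrom, IRanges::IRanges(w$start, w$end))
  S4Vectors::mcols(win)$gene_id <- w$gene_id
  S4Vectors::mcols(win)$tss <- w$tss
  S4Vectors::mcols(win)$feature <- w$feature
  win
}
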