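#' Chain expression-linked CpGs into differentially methylated regions
#'
#' Single-linkage chaining along each chromosome: sites are sorted and a
#' region breaks whenever the distance between consecutive CpGs exceeds
#' \code{max_gap} (inclusive: a 500 bp step still chains; 501 breaks), so a
#' region's total span may exceed \code{max_gap}. Clusters with fewer than
#' \code{min_cpgs} members are dropped. Local and distal ECpGs are pooled by
#' default; pass \code{split_scope = TRUE} to cluster scopes separately.
#' Contrasts/regions should be clustered separately (pass one table per
#' family, as the pipeline does).
#'
#' @param ecpgs data.frame with \code{chrom, pos} and optionally
#'   \code{delta_pct}, \code{gene_id}, \code{scope}, \code{is_ecpg} (when
#'   present, only called ECpGs are clustered).
#' @param max_gap maximum distance (bp) between consecutive member CpGs.
#' @param min_cpgs minimum members per region.
#' @param split_scope cluster local and distal records separately.
#' @return data.frame: \code{chrom, start, end} (1-based inclusive bounds of
#'   member CpGs), \code{n_cpgs, mean_delta_pct, linked_genes}
#'   (comma-joined), \code{member_pos} (comma-joined positions).
#' @export
buildDmrs <- function(ecpgs, max_gap = 500L, min_cpgs = 2L,
                      split_scope = FALSE) {
  if ("is_ecpg" %in% names(ecpgs))
    ecpgs <- ecpgs[ecpgs$is_ecpg, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpgs = integer(),
                      mean_delta_pct = numeric(), linked_genes = character(),
                      member_pos = character(), stringsAsFactors = FALSE)
  if (!nrow(ecpgs)) return(empty)
  groups <- if (split_scope && "scope" %in% names(ecpgs))
    split(ecpgs, ecpgs$scope) else list(ecpgs)
  out <- lapply(groups, function(e) {
    e <- unique(e[, intersect(c("chrom", "pos", "delta_pct", "gene_id"),
                              names(e)), drop = FALSE])
    # distinct sites; a site linked to several genes contributes once,
    # carrying the union of its gene links
    key <- paste(e$chrom, e$pos)
    first <- !duplicated(key)
    sites <- e[first, , drop = FALSE]
    gr <- GenomicRanges::GRanges(sites$chrom,
                                 IRanges::IRanges(sites$pos, width = 1L))
    red <- GenomicRanges::reduce(sort(gr), min.gapwidth = max_gap)
    hit <- GenomicRanges::findOverlaps(gr, red)
    cl <- rep(NA_integer_, length(gr))
    cl[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
    sp <- split(seq_along(cl), cl)
    sp <- sp[lengths(sp) >= min_cpgs]
    if (!length(sp)) return(empty)
    do.call(rbind, lapply(sp, function(ix) {
      pos <- sort(sites$pos[ix])
      genes <- if ("gene_id" %in% names(e)) {
        g <- unique(e$gene_id[paste(e$chrom, e$pos) %in%
                                paste(sites$chrom[ix], sites$pos[ix])])
        paste(sort(g[!is.na(g)]), collapse = ",")
      } else ""
      data.frame(chrom = sites$chrom[ix][1], start = min(pos),
                 end = max(pos), n_cpgs = length(ix),
                 mean_delta_pct = if ("delta_pct" %in% names(sites))
                   mean(sites$delta_pct[ix]) else NA_real_,
                 linked_genes = genes,
                 member_pos = paste(pos, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write DMRs as a BED6 browser track
#'
#' @param dmrs table from [buildDmrs()].
#' @param path output BED path.
#' @return Invisibly, \code{path}.
#' @export
writeDmrBed <- function(dmrs, path) {
  d <- data.frame(chrom = dmrs$chrom, start0 = dmrs$start - 1L,
                  end0 = dmrs$end,
                  name = paste0("DMR_", seq_len(nrow(dmrs)), "_",
                                dmrs$n_cpgs, "CpG"),
                  score = pmin(1000L, pmax(0L,
                    as.integer(round(abs(dmrs$mean_delta_pct) * 10)))),
                  strand = ".")
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
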