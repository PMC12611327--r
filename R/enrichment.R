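#' Distance from each CpG to its nearest regulatory element
#'
#' Distance is 0 when the site lies inside an element, otherwise the base
#' pair difference to the closest element edge on the same chromosome (a
#' site one base past an element's last base is at distance 1). Sites on
#' chromosomes carrying no element of the label get \code{NA}.
#'
#' @param sites GRanges of 1-bp CpG positions, or data.frame with
#'   \code{chrom, pos}.
#' @param track regulatory GRanges with mcols \code{label} (1-based
#'   coordinates as from [readRegulatoryTrack()]).
#' @param label element class, e.g. \code{"EnhD"} or \code{"CTCF"}.
#' @return list: \code{distances} (per site, bp) and \code{median} over
#'   non-NA sites.
#' @export
nearestElementDistance <- function(sites, track, label) {
  sites <- .as_sites_granges(sites)
  el <- track[S4Vectors::mcols(track)$label == label]
  if (!length(el)) stop("no elements with label ", label)
  d <- rep(NA_real_, length(sites))
  hit <- GenomicRanges::distanceToNearest(sites, el)
  q <- S4Vectors::queryHits(hit); s <- S4Vectors::subjectHits(hit)
  pos <- BiocGenerics::start(sites)[q]
  st <- BiocGenerics::start(el)[s]; en <- BiocGenerics::end(el)[s]
  d[q] <- pmax(0, st - pos, pos - en)
  list(distances = d, median = stats::median(d, na.rm = TRUE))
}

.as_sites_granges <- function(sites) {
  if (methods::is(sites, "MethylMatrix")) return(cpgSites(sites))
  if (is.data.frame(sites))
    return(GenomicRanges::GRanges(sites$chrom,
                                  IRanges::IRanges(sites$pos, width = 1L)))
  sites
}

#' Permutation test for ECpG proximity to regulatory elements
#'
#' The statistic is the number of sites whose +/- \code{window} bp interval
#' overlaps at least one element of the label. The null resamples, for each
#' of \code{n_perm} permutations, the same number of positions per
#' chromosome without replacement from the supplied site universe (all
#' quality-filtered CpGs) - a matched-universe draw that respects the CpG
#' density bias of RRBS. \code{mode = "uniform"} instead places positions
#' uniformly within each chromosome's universe span. The empirical p uses
#' the add-one rule, so it is never 0.
#'
#' @param sites tested CpGs (GRanges or \code{chrom, pos} data.frame).
#' @param universe resampling universe (same formats); must contain at
#'   least as many positions per chromosome as \code{sites}.
#' @param track,label regulatory track and element class.
#' @param window half-width (bp) of the interval around each CpG.
#' @param n_perm number of permutations.
#' @param seed optional RNG seed for reproducibility.
#' @param mode \code{"shuffle_sites"} (matched universe, default) or
#'   \code{"uniform"}.
#' @return list: \code{label, n_ecpgs, observed_overlaps, perm_mean,
#'   perm_sd, z, empirical_p, median_distance}.
#' @export
permutationOverlapTest <- function(sites, universe, track, label,
                                   window = 1000L, n_perm = 1000L,
                                   seed = NULL,
                                   mode = c("shuffle_sites", "uniform")) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  sites <- .as_sites_granges(sites)
  universe <- .as_sites_granges(universe)
  el <- track[S4Vectors::mcols(track)$label == label]
  if (!length(el)) stop("no elements with label ", label)
  schrom <- as.character(GenomicRanges::seqnames(sites))
  spos <- BiocGenerics::start(sites)
  uchrom <- as.character(GenomicRanges::seqnames(universe))
  upos <- BiocGenerics::start(universe)
  per_chrom <- table(schrom)
  for (ch in names(per_chrom))
    if (sum(uchrom == ch) < per_chrom[[ch]])
      stop("universe smaller than sites on ", ch)

  # a +/- window interval around pos overlaps an element iff pos falls in
  # the element padded by the window; pad and merge once, then count by
  # binary search per permutation
  pad <- GenomicRanges::reduce(GenomicRanges::resize(
    el, BiocGenerics::width(el) + 2L * window, fix = "center"))
  pad_by <- split(data.frame(
    s = BiocGenerics::start(pad), e = BiocGenerics::end(pad)),
    as.character(GenomicRanges::seqnames(pad)), drop = TRUE)
  count_overlaps <- function(chrom, pos) {
    tot <- 0L
    for (ch in unique(chrom)) {
      iv <- pad_by[[ch]]
      if (is.null(iv)) next
      p <- pos[chrom == ch]
      idx <- findInterval(p, iv$s)
      tot <- tot + sum(idx > 0L & p <= iv$e[pmax(1L, idx)])
    }
    tot
  }
  obs <- count_overlaps(schrom, spos)
  upos_by <- split(upos, uchrom)
  span_by <- lapply(upos_by, range)
  null <- vapply(seq_len(n_perm), function(i) {
    pos <- unlist(lapply(names(per_chrom), function(ch) {
      k <- per_chrom[[ch]]
      if (mode == "shuffle_sites") sample(upos_by[[ch]], k)
      else sample(seq(span_by[[ch]][1], span_by[[ch]][2]), k)
    }), use.names = FALSE)
    chrom <- rep(names(per_chrom), per_chrom)
    count_overlaps(chrom, pos)
  }, numeric(1))
  mu <- mean(null); sdv <- stats::sd(null)
  list(label = label,
       n_ecpgs = length(sites),
       observed_overlaps = obs,
       perm_mean = mu, perm_sd = sdv,
       z = if (sdv > 0) (obs - mu) / sdv else NA_real_,
       empirical_p = (1 + sum(null >= obs)) / (1 + n_perm),
       median_distance = nearestElementDistance(sites, track, label)$median)
}
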