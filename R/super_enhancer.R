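#' Stitch enhancer peaks into candidate enhancer regions
#'
#' ROSE-style stitching: consecutive peaks on the same chromosome whose
#' gap is at most `stitch_distance` bp are unioned into one region, so
#' clusters of constituent enhancers are scored as a single entity.
#'
#' @param peaks Data frame of intervals (`chrom`, `start`, `end`;
#'   0-based half-open), e.g. from [read_bed()]. May be unsorted and
#'   overlapping.
#' @param stitch_distance Maximum gap (bp) across which peaks are
#'   merged. Default 12500, the conventional stitching window.
#' @return Data frame of merged regions sorted by (`chrom`, `start`)
#'   with columns `chrom`, `start`, `end`, `region_id`,
#'   `constituent_count` (peaks merged into the region). Output
#'   regions are pairwise separated by more than `stitch_distance`.
#' @export
stitch_peaks <- function(peaks, stitch_distance = 12500L) {
  if (length(stitch_distance) != 1L || is.na(stitch_distance) || stitch_distance < 0)
    stop("stitch_distance must be a single non-negative number")
  if (nrow(peaks) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      region_id = character(), constituent_count = integer(),
                      stringsAsFactors = FALSE))
  }
  stopifnot(all(peaks$start < peaks$end), all(nzchar(peaks$chrom)))
  gr <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges   = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
  # In 1-based closed coordinates the gap between adjacent ranges equals
  # the half-open gap, and reduce() merges ranges with gap < min.gapwidth,
  # so min.gapwidth = stitch_distance + 1 merges gaps <= stitch_distance.
  red <- GenomicRanges::reduce(gr, min.gapwidth = stitch_distance + 1L,
                               with.revmap = TRUE)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1,
    end   = as.numeric(GenomicRanges::end(red)),
    stringsAsFactors = FALSE
  )
  out$region_id <- sprintf("%s:%d-%d", out$chrom, as.integer(out$start),
                           as.integer(out$end))
  out$constituent_count <- lengths(S4Vectors::mcols(red)$revmap)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score stitched regions by input-subtracted signal
#'
#' Signal is treatment minus control density, clamped at zero, summed
#' over the region (reads/million, input subtracted). Densities may be
#' supplied either as per-region totals (numeric vectors aligned with
#' `regions`, or named by `region_id`) or as bedGraph-style coverage
#' tables (`chrom`, `start`, `end`, `value`; per-bp density), in which
#' case density x overlapped bases is summed within each region.
#'
#' @param regions Data frame from [stitch_peaks()].
#' @param treatment,control Per-region numeric vectors, or bedGraph-like
#'   data frames of per-bp density.
#' @return `regions` with a `signal` column (`max(0, treatment -
#'   control)` aggregated per region).
#' @export
score_regions <- function(regions, treatment, control) {
  t_tot <- region_totals(regions, treatment, "treatment")
  c_tot <- region_totals(regions, control, "control")
  regions$signal <- pmax(0, t_tot - c_tot)
  regions
}

region_totals <- function(regions, density, what) {
  if (is.numeric(density)) {
    if (!is.null(names(density))) {
      density <- density[regions$region_id]
    } else if (length(density) != nrow(regions)) {
      stop("Per-region ", what, " vector length (", length(density),
           ") does not match region count (", nrow(regions), ")")
    }
    if (anyNA(density)) {
      miss <- regions$region_id[which(is.na(density))[1L]]
      stop("Missing ", what, " value for region ", miss)
    }
    return(as.numeric(density))
  }
  stopifnot(is.data.frame(density))
  gr_reg <- GenomicRanges::GRanges(regions$chrom,
    IRanges::IRanges(regions$start + 1L, regions$end))
  gr_cov <- GenomicRanges::GRanges(density$chrom,
    IRanges::IRanges(density$start + 1L, density$end))
  hits <- GenomicRanges::findOverlaps(gr_reg, gr_cov)
  ov <- GenomicRanges::pintersect(gr_reg[S4Vectors::queryHits(hits)],
                                  gr_cov[S4Vectors::subjectHits(hits)])
  contrib <- GenomicRanges::width(ov) * density$value[S4Vectors::subjectHits(hits)]
  tot <- numeric(nrow(regions))
  agg <- tapply(contrib, S4Vectors::queryHits(hits), sum)
  tot[as.integer(names(agg))] <- agg
  tot
}

#' Rank scored regions and call super-enhancers by the tangent cutoff
#'
#' Regions are sorted ascending by signal; rank index and signal are
#' each rescaled to \[0, 1\], giving the hockey-stick curve whose
#' inflection separates typical enhancers from super-enhancers. The
#' cutoff is the signal at the first point (scanning from the low-signal
#' end) where the discrete forward slope of the rescaled curve exceeds
#' 1 -- the discrete analogue of the tangent-slope-1 rule. Every region
#' with signal strictly above the cutoff is a super-enhancer.
#'
#' @param regions Data frame from [score_regions()] (needs `signal`).
#' @return `regions` with `rank` (1 = highest signal; ties broken by
#'   `chrom` then `start`) and logical `is_super`, sorted by rank. If
#'   all signals are equal the geometry is degenerate: a warning is
#'   issued and no region is called super.
#' @export
rank_and_cut <- function(regions) {
  n <- nrow(regions)
  if (n == 0L) {
    regions$rank <- integer(); regions$is_super <- logical()
    return(regions)
  }
  s <- regions$signal
  stopifnot(is.numeric(s), all(s >= 0))
  ord <- order(-s, regions$chrom, regions$start)  # stable, deterministic
  regions <- regions[ord, , drop = FALSE]
  regions$rank <- seq_len(n)
  if (n < 3L || length(unique(s)) == 1L) {
    if (length(unique(s)) == 1L)
      warning("Degenerate ranking geometry (all signals equal); no super-enhancers called")
    regions$is_super <- FALSE
    rownames(regions) <- NULL
    return(regions)
  }
  cutoff <- tangent_cutoff(s)
  regions$is_super <- regions$signal > cutoff
  rownames(regions) <- NULL
  regions
}

# Signal cutoff from the rescaled rank/signal curve: first point whose
# forward slope exceeds 1. Returns max(signal) (=> empty super set) if
# no slope exceeds 1.
tangent_cutoff <- function(signal) {
  s <- sort(signal)
  n <- length(s)
  y <- (s - s[1L]) / (s[n] - s[1L])
  slope <- diff(y) * (n - 1)          # forward slope at points 1..n-1
  idx <- which(slope > 1)
  if (length(idx) == 0L) return(s[n])
  s[idx[1L]]
}

#' Associate a locus with its nearest super-enhancer
#'
#' Finds the super-enhancer on the locus chromosome minimizing the gap
#' distance (0 if overlapping); equidistant candidates resolve to the
#' higher-ranked (lower rank number) one. `relative_position` is
#' reported with respect to the locus strand: upstream means the
#' super-enhancer lies toward the 5' side of the locus, so for a
#' minus-strand locus upstream is at higher coordinates.
#'
#' @param locus One-row data frame (or list) with `chrom`, `start`,
#'   `end`, `name`, `strand` (0-based half-open; unstranded loci are
#'   treated as plus strand).
#' @param ranking Data frame from [rank_and_cut()].
#' @return One-row data frame: `locus`, `super_id`, `rank`,
#'   `distance_bp`, `relative_position` (upstream / downstream /
#'   overlapping).
#' @export
associate_locus <- function(locus, ranking) {
  sup <- ranking[ranking$is_super, , drop = FALSE]
  if (nrow(sup) == 0L) stop("No super-enhancers in ranking; cannot associate locus")
  sup <- sup[sup$chrom == locus$chrom, , drop = FALSE]
  if (nrow(sup) == 0L)
    stop("No super-enhancer on chromosome ", locus$chrom,
         " (cross-chromosome associations are never made)")
  gap <- pmax(0, pmax(sup$start - locus$end, locus$start - sup$end))
  best <- which(gap == min(gap))
  if (length(best) > 1L) best <- best[which.min(sup$rank[best])]
  hit <- sup[best, , drop = FALSE]
  d <- gap[best]
  strand <- if (!is.null(locus$strand) && locus$strand %in% c("+", "-"))
    locus$strand else "+"
  pos <- if (d == 0) "overlapping"
    else if (hit$end <= locus$start) { if (strand == "+") "upstream" else "downstream" }
    else { if (strand == "+") "downstream" else "upstream" }
  data.frame(
    locus = if (!is.null(locus$name)) locus$name else NA_character_,
    super_id = hit$region_id,
    rank = hit$rank,
    distance_bp = d,
    relative_position = pos,
    stringsAsFactors = FALSE
  )
}

#' Run the full super-enhancer stage
#'
#' Convenience wrapper: stitch, score, rank/cut, then associate each
#' query locus.
#'
#' @param peaks Peak intervals (data frame).
#' @param treatment,control Densities as in [score_regions()].
#' @param loci Optional data frame of query loci (`chrom`, `start`,
#'   `end`, `name`, `strand`).
#' @param stitch_distance Stitching window (bp).
#' @return List with `ranking` (ranked regions) and `associations`
#'   (one row per locus, `NULL` if no loci given).
#' @export
call_super_enhancers <- function(peaks, treatment, control, loci = NULL,
                                 stitch_distance = 12500L) {
  regions <- stitch_peaks(peaks, stitch_distance)
  scored <- score_regions(regions, treatment, control)
  ranking <- rank_and_cut(scored)
  assoc <- NULL
  if (!is.null(loci) && nrow(loci) > 0L) {
    assoc <- do.call(rbind, lapply(seq_len(nrow(loci)), function(i)
      associate_locus(loci[i, , drop = FALSE], ranking)))
  }
  list(ranking = ranking, associations = assoc)
}
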