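#' Stitch peaks and rank stitched regions by signal (super-enhancer call)
#'
#' Peaks within `stitch_distance` of each other are merged into stitched
#' regions whose signal is the sum of member peak signals. Regions are
#' ranked ascending by signal; with both rank and signal axes scaled to
#' \[0, 1\], the elbow is the point where a line of slope 1 is tangent to
#' the rank-signal curve, i.e. the (last) rank minimising `scaled_signal -
#' scaled_rank`. Regions strictly above the tangent point are flagged
#' super-enhancers; on the degenerate curve y = x no region is super.
#'
#' @param peaks `GRanges` with a finite `signal` metadata column.
#' @param stitch_distance merge peaks separated by at most this many bp.
#' @return Object of class `ranked_enhancers`: `regions` (`GRanges` in
#'   ascending rank order with `signal`, `rank`, `super`), `elbow_index`,
#'   `cutoff_signal`, `stitch_distance`.
#' @export
stitch_and_rank <- function(peaks, stitch_distance = 15000L) {
  sig <- mcols(peaks)$signal
  if (is.null(sig) || any(!is.finite(sig))) {
    stop("peaks must carry a finite 'signal' metadata column")
  }
  regions <- reduce(granges(peaks), min.gapwidth = stitch_distance + 1L,
                    ignore.strand = TRUE)
  hits <- findOverlaps(regions, peaks, ignore.strand = TRUE)
  rsig <- rep(0, length(regions))
  agg <- tapply(sig[subjectHits(hits)], queryHits(hits), sum)
  rsig[as.integer(names(agg))] <- agg
  n <- length(regions)
  if (n < 3L) stop("fewer than 3 stitched regions: elbow undefined")
  if (length(unique(rsig)) == 1L) {
    stop("all stitched regions have identical signal: elbow undefined")
  }
  o <- order(rsig)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (rsig[o] - min(rsig)) / (max(rsig) - min(rsig))
  d <- y - x
  elbow <- max(which(d == min(d)))
  regions <- regions[o]
  mcols(regions)$signal <- rsig[o]
  mcols(regions)$rank <- seq_len(n)
  mcols(regions)$super <- seq_len(n) > elbow
  structure(list(regions = regions, elbow_index = elbow,
                 cutoff_signal = rsig[o][elbow],
                 stitch_distance = stitch_distance),
            class = "ranked_enhancers")
}

#' @export
print.ranked_enhancers <- function(x, ...) {
  cat(sprintf(
    "ranked_enhancers: %d stitched regions (stitch %d bp), %d super above elbow rank %d (cutoff signal %.3g)\n",
    length(x$regions), x$stitch_distance, sum(mcols(x$regions)$super),
    x$elbow_index, x$cutoff_signal))
  invisible(x)
}

#' Extract the super-enhancer regions from a ranked list
#' @param ranked a `ranked_enhancers` object.
#' @return `GRanges` of the regions above the elbow.
#' @export
super_enhancers <- function(ranked) {
  ranked$regions[mcols(ranked$regions)$super]
}

.cluster_spans <- function(clusters) {
  if (inherits(clusters, "cluster_set")) clusters$spans else clusters
}

#' Overlap statistics between super-enhancers and density clusters
#'
#' @param super `GRanges` of super-enhancer regions (e.g.
#'   [super_enhancers()] output).
#' @param clusters a `cluster_set` or a `GRanges` of cluster spans.
#' @param window regions within this many bp (edge-to-edge) of a cluster
#'   count as "within window"; direct overlaps are included.
#' @return list with `n_super`, `n_direct`, `n_within_window`,
#'   `frac_direct`, `frac_within_window`.
#' @export
cluster_overlap_stats <- function(super, clusters, window = 100000L) {
  spans <- .cluster_spans(clusters)
  n <- length(super)
  if (n == 0L || length(spans) == 0L) {
    return(list(n_super = n, n_direct = 0L, n_within_window = 0L,
                frac_direct = 0, frac_within_window = 0))
  }
  direct <- countOverlaps(super, spans, ignore.strand = TRUE) > 0L
  dist <- rep(Inf, n)
  dtn <- distanceToNearest(super, spans, ignore.strand = TRUE)
  dist[queryHits(dtn)] <- mcols(dtn)$distance
  within <- dist <= window
  list(n_super = n, n_direct = sum(direct),
       n_within_window = sum(within),
       frac_direct = mean(direct), frac_within_window = mean(within))
}

#' TAD containment of super-enhancer regions
#'
#' A region is "within a TAD" when fully contained in at least one TAD
#' interval; with overlapping TAD definitions the smallest containing TAD
#' is recorded (and each region counted once). A TAD "has" a region when it
#' overlaps one by any amount; mean TAD lengths are reported for the two
#' TAD groups.
#'
#' @param ldec `GRanges` of regions (super-enhancers / LDECs).
#' @param tads `GRanges` of TAD intervals (may overlap each other).
#' @return list with `fraction_within`, `n_within`, `assigned_tad`
#'   (index into `tads` or `NA` per region), `tad_has_ldec` (logical per
#'   TAD), `mean_len_with`, `mean_len_without`.
#' @export
tad_containment <- function(ldec, tads) {
  stopifnot(length(tads) > 0L)
  hits <- findOverlaps(ldec, tads, type = "within", ignore.strand = TRUE)
  assigned <- rep(NA_integer_, length(ldec))
  if (length(hits)) {
    hdf <- data.frame(q = queryHits(hits), s = subjectHits(hits),
                      w = width(tads)[subjectHits(hits)])
    hdf <- hdf[order(hdf$q, hdf$w), ]
    first <- !duplicated(hdf$q)
    assigned[hdf$q[first]] <- hdf$s[first]
  }
  has <- countOverlaps(tads, ldec, ignore.strand = TRUE) > 0L
  wl <- width(tads)
  list(fraction_within = mean(!is.na(assigned)),
       n_within = sum(!is.na(assigned)),
       assigned_tad = assigned,
       tad_has_ldec = has,
       mean_len_with = if (any(has)) mean(wl[has]) else NA_real_,
       mean_len_without = if (any(!has)) mean(wl[!has]) else NA_real_)
}
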