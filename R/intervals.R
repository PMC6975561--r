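#' Partition one peak set by overlap with another
#'
#' Splits `a` into the peaks that overlap at least one peak of `b` by at
#' least `min_overlap_bp` bases (`common`) and the remainder (`only`). The
#' partition is exhaustive and disjoint.
#'
#' @param a,b `GRanges` peak sets.
#' @param min_overlap_bp minimum overlap in bp (>= 1).
#' @return `list(common = , only = )`, both subsets of `a` in `a`'s order.
#' @export
intersect_sets <- function(a, b, min_overlap_bp = 1L) {
  if (min_overlap_bp < 1L) stop("min_overlap_bp must be >= 1")
  hit <- countOverlaps(a, b, minoverlap = min_overlap_bp,
                       ignore.strand = TRUE) > 0L
  list(common = a[hit], only = a[!hit])
}

#' k nearest gene features for each query interval
#'
#' Distance is measured from the query midpoint to the feature TSS (the
#' promoter-window convention used for nascent-transcription counting).
#' Ties are broken by (feature start, feature name).
#'
#' @param query `GRanges` of query intervals.
#' @param features gene models from [gene_models()] (must carry `tss` and
#'   `name` metadata columns).
#' @param k number of nearest features per query (>= 1).
#' @return data.frame with columns `query` (index into `query`), `feature`,
#'   `tss`, `distance`, `rank`. Queries on chromosomes with fewer than `k`
#'   features return fewer rows (with a single warning).
#' @export
nearest_features <- function(query, features, k = 4L) {
  stopifnot(k >= 1L, length(features) > 0L)
  tss <- mcols(features)$tss
  fname <- mcols(features)$name
  if (is.null(tss)) stop("features must carry a 'tss' metadata column")
  qmid <- floor((start(query) + end(query)) / 2)
  fchrom <- as.character(seqnames(features))
  qchrom <- as.character(seqnames(query))
  fs <- start(features)
  short <- FALSE
  out <- vector("list", length(query))
  for (i in seq_along(query)) {
    sel <- which(fchrom == qchrom[i])
    if (length(sel) == 0L) {
      short <- TRUE
      next
    }
    d <- abs(tss[sel] - qmid[i])
    o <- sel[order(d, fs[sel], fname[sel])]
    kk <- min(k, length(o))
    if (kk < k) short <- TRUE
    o <- o[seq_len(kk)]
    out[[i]] <- data.frame(query = i, feature = fname[o], tss = tss[o],
                           distance = abs(tss[o] - qmid[i]),
                           rank = seq_len(kk), stringsAsFactors = FALSE)
  }
  if (short) warning("fewer than k features available for some queries")
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(query = integer(0), feature = character(0),
                      tss = numeric(0), distance = numeric(0),
                      rank = integer(0))
  }
  res
}

# interval midpoints (integer, floor of the center)
.midpoints <- function(gr) floor((start(gr) + end(gr)) / 2)
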