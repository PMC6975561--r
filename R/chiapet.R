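# Anchor GRanges for one replicate's pair table.
.anchor_granges <- function(df, which) {
  GRanges(df[[paste0("chrom", which)]],
          IRanges(df[[paste0("start", which)]], df[[paste0("end", which)]]))
}

# Canonicalize anchor order so anchor1 <= anchor2 by (chrom, start).
.canonical_pairs <- function(df) {
  swap <- df$chrom2 < df$chrom1 |
    (df$chrom2 == df$chrom1 & df$start2 < df$start1)
  if (any(swap)) {
    tmp <- df[swap, c("chrom1", "start1", "end1")]
    df[swap, c("chrom1", "start1", "end1")] <-
      df[swap, c("chrom2", "start2", "end2")]
    df[swap, c("chrom2", "start2", "end2")] <- tmp
  }
  df
}

# Matches between pairs of two replicates: both anchors overlap, in either
# anchor order. Returns a 2-column matrix of (row in a, row in b).
.pair_matches <- function(a1, a2, b1, b2, min_overlap_bp) {
  .hits_df <- function(x, y) {
    h <- findOverlaps(x, y, minoverlap = min_overlap_bp,
                      ignore.strand = TRUE)
    cbind(queryHits(h), subjectHits(h))
  }
  .both <- function(h_first, h_second) {
    if (nrow(h_first) == 0L || nrow(h_second) == 0L) {
      return(matrix(integer(0), ncol = 2L))
    }
    k1 <- paste(h_first[, 1L], h_first[, 2L])
    k2 <- paste(h_second[, 1L], h_second[, 2L])
    h_first[k1 %in% k2, , drop = FALSE]
  }
  straight <- .both(.hits_df(a1, b1), .hits_df(a2, b2))
  crossed <- .both(.hits_df(a1, b2), .hits_df(a2, b1))
  unique(rbind(straight, crossed))
}

#' Merge ChIA-PET replicates into a both-end consensus
#'
#' A pair is retained when every replicate contains a pair whose two
#' anchors both overlap the candidate's anchors (in either anchor order),
#' the behaviour of bedtools `pairtopair`. Supported pairs from all
#' replicates are clustered by both-end overlap and each cluster is
#' reported once, with the coordinates of its earliest-replicate member
#' and `support` equal to the cluster size, making the consensus
#' independent of replicate order (up to both-end-overlap identity) and
#' idempotent on its own output.
#'
#' @param reps list of >= 2 pair data.frames (`chrom1,start1,end1,chrom2,
#'   start2,end2`, 1-based closed; see [read_bedpe()]).
#' @param min_overlap_bp minimum per-anchor overlap in bp.
#' @return consensus data.frame with the six anchor columns plus `support`.
#' @export
merge_chiapet_replicates <- function(reps, min_overlap_bp = 1L) {
  if (length(reps) < 2L) stop("need at least 2 replicates")
  reps <- lapply(reps, .canonical_pairs)
  ns <- vapply(reps, nrow, 0L)
  if (any(ns == 0L)) {
    out <- reps[[1L]][0L, c("chrom1", "start1", "end1",
                            "chrom2", "start2", "end2")]
    out$support <- integer(0)
    return(out)
  }
  a1 <- lapply(reps, .anchor_granges, 1L)
  a2 <- lapply(reps, .anchor_granges, 2L)
  R <- length(reps)
  offsets <- cumsum(c(0L, ns))[seq_len(R)]
  # matches[[i]][[j]]: matrix of (row_i, row_j)
  supported <- vector("list", R)
  edges <- list()
  for (i in seq_len(R)) supported[[i]] <- rep(TRUE, ns[i])
  for (i in seq_len(R)) {
    for (j in seq_len(R)) {
      if (i == j) next
      m <- .pair_matches(a1[[i]], a2[[i]], a1[[j]], a2[[j]], min_overlap_bp)
      supported[[i]] <- supported[[i]] &
        tabulate(m[, 1L], nbins = ns[i]) > 0L
      if (i < j && nrow(m)) {
        edges[[length(edges) + 1L]] <-
          cbind(m[, 1L] + offsets[i], m[, 2L] + offsets[j])
      }
    }
  }
  total <- sum(ns)
  keep <- unlist(supported)
  # union-find over supported pairs linked by cross-replicate matches
  parent <- seq_len(total)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in edges) {
    for (r in seq_len(nrow(e))) {
      p <- e[r, 1L]; q <- e[r, 2L]
      if (!keep[p] || !keep[q]) next
      rp <- find(p); rq <- find(q)
      if (rp != rq) parent[rq] <- rp
    }
  }
  ids <- which(keep)
  if (length(ids) == 0L) {
    out <- reps[[1L]][0L, c("chrom1", "start1", "end1",
                            "chrom2", "start2", "end2")]
    out$support <- integer(0)
    return(out)
  }
  roots <- vapply(ids, find, 0L)
  comp <- split(ids, roots)
  all_df <- do.call(rbind, lapply(reps, function(d)
    d[, c("chrom1", "start1", "end1", "chrom2", "start2", "end2")]))
  rep_of <- rep(seq_len(R), ns)
  rows <- lapply(comp, function(members) {
    lead <- members[order(rep_of[members], members)][1L]
    cbind(all_df[lead, , drop = FALSE], support = length(members))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$chrom1, out$start1, out$chrom2, out$start2), , drop = FALSE]
}

#' Interaction degree of classified sites
#'
#' The degree of a site is the number of distinct interaction pairs with
#' at least one anchor overlapping the site.
#'
#' @param pairs consensus pair data.frame (six anchor columns).
#' @param sites classified `GRanges` (with a `site_class` metadata column).
#' @return data.frame with `site` (index), `name`, `site_class`, `degree`.
#' @export
interaction_degree <- function(pairs, sites) {
  cls <- mcols(sites)$site_class
  if (is.null(cls)) stop("sites must carry a 'site_class' metadata column")
  nm <- mcols(sites)$name
  if (is.null(nm)) nm <- sprintf("site_%d", seq_along(sites))
  deg <- rep(0L, length(sites))
  if (nrow(pairs)) {
    a1 <- .anchor_granges(pairs, 1L)
    a2 <- .anchor_granges(pairs, 2L)
    h1 <- findOverlaps(sites, a1, ignore.strand = TRUE)
    h2 <- findOverlaps(sites, a2, ignore.strand = TRUE)
    sp <- unique(rbind(
      cbind(queryHits(h1), subjectHits(h1)),
      cbind(queryHits(h2), subjectHits(h2))))
    if (nrow(sp)) deg <- tabulate(sp[, 1L], nbins = length(sites))
  }
  data.frame(site = seq_along(sites), name = nm, site_class = cls,
             degree = deg, stringsAsFactors = FALSE)
}
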