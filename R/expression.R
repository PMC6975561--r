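#' Count signal-track coverage in fixed windows around genes or peaks
#'
#' `gene_body` mode counts coverage from 1 kb past the promoter-proximal
#' end to 13 kb into the gene body, oriented by strand (the window is
#' mirrored for `-` strand genes); `erna` mode sums coverage from both
#' strands in a symmetric window about the peak center, the convention for
#' enhancer-RNA quantification from nascent transcription.
#'
#' @param track `GRanges` coverage track with a `value` metadata column
#'   (per-bp rate); intervals within a chromosome must not overlap (per
#'   strand for stranded tracks). Counts are
#'   `sum(value * overlap_width)` and are exactly linear in the track.
#' @param targets gene models (with `tss` and strand) for `gene_body`, or
#'   peaks for `erna`.
#' @param mode `"gene_body"` or `"erna"`.
#' @param flank promoter offset (bp) for `gene_body` (default 1000).
#' @param body_end downstream extent (bp) for `gene_body` (default 13000).
#' @param erna_halfwidth half-width (bp) of the window about the peak
#'   center for `erna` (default 1000).
#' @param norm_factor library-size normalization factor applied to counts.
#' @return numeric vector of counts, one per target, named by the targets'
#'   `name` column when present. Windows extending past position 1 are
#'   truncated with a warning.
#' @export
quantify_window_counts <- function(track, targets,
                                   mode = c("gene_body", "erna"),
                                   flank = 1000L, body_end = 13000L,
                                   erna_halfwidth = 1000L,
                                   norm_factor = 1) {
  mode <- match.arg(mode)
  val <- mcols(track)$value
  if (is.null(val)) val <- mcols(track)$score
  if (is.null(val) || any(val < 0)) {
    stop("track must carry a non-negative 'value' metadata column")
  }
  if (mode == "gene_body") {
    tss <- mcols(targets)$tss
    str <- as.character(strand(targets))
    if (is.null(tss) || any(!str %in% c("+", "-"))) {
      stop("gene_body mode needs gene models with 'tss' and +/- strand")
    }
    ws <- ifelse(str == "+", tss + flank, tss - body_end + 1L)
    we <- ifelse(str == "+", tss + body_end - 1L, tss - flank)
  } else {
    ctr <- .midpoints(targets)
    ws <- ctr - erna_halfwidth
    we <- ctr + erna_halfwidth - 1L
  }
  if (any(ws < 1L)) {
    warning("window truncated at chromosome start for ",
            sum(ws < 1L), " target(s)")
    ws <- pmax(ws, 1L)
  }
  windows <- GRanges(seqnames(targets), IRanges(ws, we))
  hits <- findOverlaps(windows, track, ignore.strand = TRUE)
  counts <- rep(0, length(targets))
  if (length(hits)) {
    ov_w <- pmin(we[queryHits(hits)], end(track)[subjectHits(hits)]) -
      pmax(ws[queryHits(hits)], start(track)[subjectHits(hits)]) + 1L
    contrib <- val[subjectHits(hits)] * ov_w
    agg <- tapply(contrib, queryHits(hits), sum)
    counts[as.integer(names(agg))] <- agg
  }
  counts <- counts * norm_factor
  nm <- mcols(targets)$name
  if (!is.null(nm)) names(counts) <- nm
  counts
}

#' Compare expression (or any numeric) distributions between groups
#'
#' Wilcoxon rank-sum for unpaired comparisons, Wilcoxon signed-rank for
#' paired ones, applied pairwise over the supplied groups.
#'
#' @param values named list of numeric vectors (>= 2 groups, each of
#'   size >= 2; paired comparisons need equal lengths).
#' @param paired logical.
#' @return data.frame with one row per group pair: `group1`, `group2`,
#'   `n1`, `n2`, `median1`, `median2`, `statistic`, `p_value`.
#' @export
compare_groups <- function(values, paired = FALSE) {
  if (!is.list(values) || length(values) < 2L) {
    stop("values must be a list of >= 2 groups")
  }
  if (is.null(names(values))) {
    names(values) <- sprintf("group%d", seq_along(values))
  }
  if (any(lengths(values) < 2L)) stop("every group needs >= 2 values")
  idx <- combn(length(values), 2L)
  rows <- lapply(seq_len(ncol(idx)), function(j) {
    i1 <- idx[1L, j]; i2 <- idx[2L, j]
    x <- values[[i1]]; y <- values[[i2]]
    if (paired && length(x) != length(y)) {
      stop("paired comparison needs equal group lengths")
    }
    wt <- suppressWarnings(wilcox.test(x, y, paired = paired))
    data.frame(group1 = names(values)[i1], group2 = names(values)[i2],
               n1 = length(x), n2 = length(y),
               median1 = median(x), median2 = median(y),
               statistic = unname(wt$statistic), p_value = wt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
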