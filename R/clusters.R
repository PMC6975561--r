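#' Call genomic clusters of peaks by single-linkage chaining
#'
#' Walks each chromosome in positional order and chains a peak onto the
#' current cluster when its distance to the previous peak is at most
#' `max_gap`; chains with at least `min_sites` members are emitted. Distance
#' is center-to-center by default (peaks are ~200 bp so the choice is
#' second-order); `distance_mode = "edge"` measures end-to-start instead.
#' The result is invariant to input order (sort-then-chain).
#'
#' @param peaks `GRanges`; `signal` and `site_class` metadata columns are
#'   summarised per cluster when present.
#' @param max_gap maximum distance (bp) between consecutive member peaks.
#' @param min_sites minimum peaks per cluster (>= 2).
#' @param distance_mode `"center"` or `"edge"`.
#' @return Object of class `cluster_set`: list with `spans` (`GRanges` with
#'   `n_sites`, `total_signal`, `n_persistent`, `has_persistent`), `members`
#'   (list of integer indices into `peaks`, in positional order), `params`,
#'   `n_peaks`.
#' @export
call_clusters <- function(peaks, max_gap = 20000L, min_sites = 3L,
                          distance_mode = c("center", "edge")) {
  distance_mode <- match.arg(distance_mode)
  stopifnot(max_gap > 0L, min_sites >= 2L)
  n <- length(peaks)
  o <- order(as.character(seqnames(peaks)), start(peaks), end(peaks))
  chrom <- as.character(seqnames(peaks))[o]
  s <- start(peaks)[o]
  e <- end(peaks)[o]
  pos <- floor((s + e) / 2)
  if (n == 0L) {
    spans <- GRanges()
    mcols(spans)$n_sites <- integer(0)
    mcols(spans)$total_signal <- numeric(0)
    mcols(spans)$n_persistent <- integer(0)
    mcols(spans)$has_persistent <- logical(0)
    return(structure(list(spans = spans, members = list(),
                          params = list(max_gap = max_gap,
                                        min_sites = min_sites,
                                        distance_mode = distance_mode),
                          n_peaks = 0L), class = "cluster_set"))
  }
  gap <- if (distance_mode == "center") c(Inf, diff(pos))
         else c(Inf, s[-1L] - e[-n])
  new_chain <- gap > max_gap | c(TRUE, chrom[-1L] != chrom[-n])
  chain <- cumsum(new_chain)
  keep <- which(tabulate(chain) >= min_sites)
  members <- split(seq_len(n), chain)[as.character(keep)]
  members <- unname(lapply(members, function(i) o[i]))
  sig <- mcols(peaks)$signal
  cls <- mcols(peaks)$site_class
  span_chrom <- vapply(members, function(m)
    as.character(seqnames(peaks))[m[1L]], "")
  span_start <- vapply(members, function(m) min(start(peaks)[m]), 0)
  span_end <- vapply(members, function(m) max(end(peaks)[m]), 0)
  if (length(members)) {
    spans <- GRanges(span_chrom, IRanges(span_start, span_end))
  } else spans <- GRanges()
  mcols(spans)$n_sites <- vapply(members, length, 0L)
  mcols(spans)$total_signal <- if (is.null(sig)) rep(NA_real_, length(members))
    else vapply(members, function(m) sum(sig[m]), 0)
  np <- if (is.null(cls)) rep(0L, length(members))
    else vapply(members, function(m) sum(cls[m] == "persistent"), 0L)
  mcols(spans)$n_persistent <- np
  mcols(spans)$has_persistent <- np >= 1L
  structure(list(spans = spans, members = members,
                 params = list(max_gap = max_gap, min_sites = min_sites,
                               distance_mode = distance_mode),
                 n_peaks = n, peaks_checksum = .peaks_checksum(peaks)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf(
    "cluster_set: %d clusters (max_gap %d bp, min_sites %d, %s distance)\n",
    length(x$members), x$params$max_gap, x$params$min_sites,
    x$params$distance_mode))
  cat(sprintf("  %d of %d peaks clustered (%.1f%%)\n",
              length(unlist(x$members)), x$n_peaks,
              100 * length(unlist(x$members)) / max(1L, x$n_peaks)))
  invisible(x)
}

#' Fraction of peaks that fall inside any called cluster
#'
#' @param clusters a `cluster_set` called from `all_peaks`.
#' @param all_peaks the peak set the clusters were called from.
#' @return fraction in \[0, 1\].
#' @export
clustering_fraction <- function(clusters, all_peaks) {
  if (length(all_peaks) == 0L) stop("all_peaks is empty")
  if (clusters$n_peaks != length(all_peaks) ||
      !identical(clusters$peaks_checksum, .peaks_checksum(all_peaks))) {
    stop("clusters were not called from this peak set")
  }
  length(unique(unlist(clusters$members))) / length(all_peaks)
}

#' Randomized-background null for the clustering statistic
#'
#' Repeatedly draws `n_draw` sites uniformly without replacement from a
#' background site list (e.g. genome-wide ERE motif matches or DHS), calls
#' clusters with the same parameters as the observed analysis, and records
#' the cluster count and clustered-site fraction per iteration. The
#' empirical p-value for an observed fraction uses the add-one correction
#' `(1 + #{null >= observed}) / (n_iter + 1)` so it can never be zero.
#'
#' @param background `GRanges` of background sites.
#' @param n_draw number of sites per draw (the observed peak count).
#' @param n_iter number of iterations.
#' @param max_gap,min_sites,distance_mode passed to [call_clusters()].
#' @param seed RNG seed (recorded in the result; mandatory for
#'   reproducibility).
#' @param observed_fraction optional observed clustered fraction to compare
#'   against the null.
#' @return Object of class `null_clustering`: per-iteration `counts` and
#'   `fractions`, their means/sds, `p_value` (if `observed_fraction` given),
#'   `n_draw`, `seed`.
#' @export
null_clustering <- function(background, n_draw, n_iter = 100L,
                            max_gap = 20000L, min_sites = 3L,
                            distance_mode = "center", seed = 1L,
                            observed_fraction = NULL) {
  nb <- length(background)
  if (nb < n_draw) {
    stop(sprintf("background (%d) smaller than draw size (%d)", nb, n_draw))
  }
  stopifnot(n_iter >= 1L)
  counts <- integer(n_iter)
  fracs <- numeric(n_iter)
  .with_seed(seed, {
    for (i in seq_len(n_iter)) {
      idx <- if (n_draw == nb) seq_len(nb) else sample.int(nb, n_draw)
      cc <- call_clusters(background[idx], max_gap = max_gap,
                          min_sites = min_sites,
                          distance_mode = distance_mode)
      counts[i] <- length(cc$members)
      fracs[i] <- length(unlist(cc$members)) / n_draw
    }
  })
  p <- if (is.null(observed_fraction)) NA_real_ else
    (1 + sum(fracs >= observed_fraction)) / (n_iter + 1)
  structure(list(counts = counts, fractions = fracs,
                 mean_count = mean(counts), sd_count = sd(counts),
                 mean_fraction = mean(fracs), sd_fraction = sd(fracs),
                 p_value = p, n_draw = n_draw, n_iter = n_iter, seed = seed),
            class = "null_clustering")
}

#' @export
print.null_clustering <- function(x, ...) {
  cat(sprintf(
    "null_clustering: %d draws of %d sites -> %.1f clusters (sd %.1f), %.1f%% clustered\n",
    x$n_iter, x$n_draw, x$mean_count, x$sd_count, 100 * x$mean_fraction))
  if (!is.na(x$p_value)) cat(sprintf("  empirical p = %.4g\n", x$p_value))
  invisible(x)
}

#' Signal decay around persistent sites within clusters
#'
#' For every cluster containing a persistent site, members are ranked by
#' ordinal distance from the anchor (the strongest persistent member when
#' there are several) and grouped into bins of two consecutive sites per
#' direction: bin 0 is the anchor itself, bin 1 the first and second
#' neighbours on either side, bin 2 the third and fourth, and so on. The
#' mean signal per bin across clusters traces the sphere of influence of
#' the persistent site.
#'
#' @param clusters a `cluster_set`.
#' @param peaks the peak set the clusters were called from; must carry
#'   `signal` and `site_class` metadata columns.
#' @return data.frame with `bin`, `mean_signal`, `n_sites`; clusters
#'   without a persistent member are skipped (count in attribute
#'   `n_skipped`).
#' @export
decay_profile <- function(clusters, peaks) {
  sig <- mcols(peaks)$signal
  cls <- mcols(peaks)$site_class
  if (is.null(sig) || is.null(cls)) {
    stop("peaks must carry 'signal' and 'site_class' metadata columns")
  }
  sums <- numeric(0)
  cnts <- integer(0)
  skipped <- 0L
  for (m in clusters$members) {
    pers <- which(cls[m] == "persistent")
    if (length(pers) == 0L) {
      skipped <- skipped + 1L
      next
    }
    a <- pers[which.max(sig[m][pers])]
    bin <- ceiling(abs(seq_along(m) - a) / 2)
    for (b in unique(bin)) {
      j <- b + 1L
      if (j > length(sums)) {
        sums <- c(sums, numeric(j - length(sums)))
        cnts <- c(cnts, integer(j - length(cnts)))
      }
      sums[j] <- sums[j] + sum(sig[m][bin == b])
      cnts[j] <- cnts[j] + sum(bin == b)
    }
  }
  res <- data.frame(bin = seq_along(sums) - 1L,
                    mean_signal = ifelse(cnts > 0, sums / pmax(cnts, 1L), NA),
                    n_sites = cnts)
  attr(res, "n_skipped") <- skipped
  res
}
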