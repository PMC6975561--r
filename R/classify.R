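#' Classify two-condition ERa peaks into persistent / transient / -E2-unique
#'
#' Peaks called in the unliganded (-E2) condition that overlap a +E2 peak
#' are *persistent* sites (reported with their -E2 coordinates, as the
#' pre-existing side); the remaining -E2 peaks are *-E2-unique*; +E2 peaks
#' overlapping no -E2 peak are *transient*. A -E2 peak overlapping several
#' +E2 peaks is persistent once and all its +E2 partners are marked
#' non-transient (`plus_persistent`), so nothing is double counted.
#'
#' @param minus,plus `GRanges` peak sets for the -E2 and +E2 conditions.
#' @param min_overlap_bp minimum overlap (bp) for two peaks to be "common".
#' @return An object of class `site_classification`: list with `GRanges`
#'   elements `persistent`, `minus_unique`, `transient`, `plus_persistent`
#'   (each with `site_class` set), a `counts` list, and the overlap rule.
#' @export
classify_sites <- function(minus, plus, min_overlap_bp = 1L) {
  if (length(minus) == 0L || length(plus) == 0L) {
    warning("empty input peak set; classification is degenerate")
  }
  minus <- sort_peaks(minus)
  plus <- sort_peaks(plus)
  part_minus <- intersect_sets(minus, plus, min_overlap_bp)
  part_plus <- intersect_sets(plus, minus, min_overlap_bp)
  persistent <- part_minus$common
  minus_unique <- part_minus$only
  plus_persistent <- part_plus$common
  transient <- part_plus$only
  .set_class <- function(gr, lab) {
    if (length(gr)) mcols(gr)$site_class <- lab
    else mcols(gr)$site_class <- character(0)
    gr
  }
  persistent <- .set_class(persistent, "persistent")
  minus_unique <- .set_class(minus_unique, "minus_unique")
  transient <- .set_class(transient, "transient")
  plus_persistent <- .set_class(plus_persistent, "persistent")
  structure(list(
    persistent = persistent,
    minus_unique = minus_unique,
    transient = transient,
    plus_persistent = plus_persistent,
    counts = list(n_minus = length(minus), n_plus = length(plus),
                  n_persistent = length(persistent),
                  n_minus_unique = length(minus_unique),
                  n_transient = length(transient),
                  n_plus_persistent = length(plus_persistent)),
    min_overlap_bp = min_overlap_bp
  ), class = "site_classification")
}

#' @export
print.site_classification <- function(x, ...) {
  cat("Site classification (overlap >=", x$min_overlap_bp, "bp)\n")
  cat(sprintf("  -E2 peaks: %d  (+E2 peaks: %d)\n",
              x$counts$n_minus, x$counts$n_plus))
  cat(sprintf("  persistent: %d   -E2-unique: %d   transient: %d\n",
              x$counts$n_persistent, x$counts$n_minus_unique,
              x$counts$n_transient))
  invisible(x)
}

#' Label +E2 peaks with their site class
#'
#' Applies a [classify_sites()] result to the +E2 peak set: persistent
#' partners get `"persistent"`, the rest `"transient"`.
#' @param plus the +E2 `GRanges` used for classification (any order).
#' @param classification a `site_classification`.
#' @return `plus` with a `site_class` metadata column.
#' @export
label_plus_peaks <- function(plus, classification) {
  hit <- countOverlaps(plus, classification$persistent,
                       minoverlap = classification$min_overlap_bp,
                       ignore.strand = TRUE) > 0L
  mcols(plus)$site_class <- ifelse(hit, "persistent", "transient")
  plus
}

#' Bin persistent sites into signal quantiles
#'
#' Sites are ranked by signal; the quartile boundaries sit at the empirical
#' 25/50/75 percentiles and the bottom two quartiles are merged, giving
#' three quantile groups Q1 (bottom half), Q2 (50-75\%) and Q3 (top
#' quarter). Ties are resolved by a stable sort on (signal, chrom, start)
#' with boundary sites going to the lower quantile, so the assignment is
#' deterministic.
#'
#' @param persistent `GRanges` of persistent sites.
#' @param signal per-site signal; defaults to the `signal` metadata column.
#' @return list with `labels` (factor Q1/Q2/Q3 in input order), `sizes`,
#'   and `boundaries` (signal values at the two cut ranks).
#' @export
assign_quantiles <- function(persistent, signal = NULL) {
  if (is.null(signal)) signal <- mcols(persistent)$signal
  if (is.null(signal) || any(!is.finite(signal))) {
    stop("every persistent peak needs a finite signal value")
  }
  n <- length(signal)
  if (n < 4L) stop("need at least 4 sites to form quantiles")
  if (length(unique(signal)) == 1L) {
    stop("all signals identical: quantile assignment is degenerate")
  }
  o <- order(signal, as.character(seqnames(persistent)), start(persistent))
  rk <- integer(n)
  rk[o] <- seq_len(n)
  c1 <- floor(n * 0.5)
  c2 <- floor(n * 0.75)
  labels <- factor(ifelse(rk <= c1, "Q1", ifelse(rk <= c2, "Q2", "Q3")),
                   levels = c("Q1", "Q2", "Q3"))
  list(labels = labels,
       sizes = table(labels),
       boundaries = c(q50 = signal[o][c1], q75 = signal[o][c2]))
}
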