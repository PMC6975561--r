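#' Compare chromatin-entropy distributions between bin groups
#'
#' Entropy values per 100 kb genomic bin are supplied externally (this
#' module does not compute entropy). Bins are partitioned into those
#' containing an LDEC, those containing an ERa peak but no LDEC, and the
#' rest; distributions are compared per condition by Wilcoxon rank-sum
#' tests, and the -E2 to +E2 entropy drop is summarised per group.
#'
#' @param bins data.frame with columns `entropy_minus`, `entropy_plus`
#'   (finite; bins with missing values are excluded and counted), logical
#'   `has_ldec` and `has_peak`.
#' @return list with `summary` (per group x condition: n, median),
#'   `tests` (pairwise rank-sum p-values per condition and for the drop),
#'   `drop` (per-group median entropy drop), `n_excluded`.
#' @export
entropy_group_compare <- function(bins) {
  need <- c("entropy_minus", "entropy_plus", "has_ldec", "has_peak")
  miss <- setdiff(need, names(bins))
  if (length(miss)) stop("bins lacks columns: ", paste(miss, collapse = ", "))
  ok <- is.finite(bins$entropy_minus) & is.finite(bins$entropy_plus)
  n_excluded <- sum(!ok)
  bins <- bins[ok, , drop = FALSE]
  group <- ifelse(bins$has_ldec, "LDEC",
                  ifelse(bins$has_peak, "peak_no_LDEC", "other"))
  groups <- split(seq_len(nrow(bins)), group)
  summ <- do.call(rbind, lapply(names(groups), function(g) {
    i <- groups[[g]]
    data.frame(group = g, n = length(i),
               median_minus = median(bins$entropy_minus[i]),
               median_plus = median(bins$entropy_plus[i]),
               median_drop = median(bins$entropy_minus[i] -
                                      bins$entropy_plus[i]),
               stringsAsFactors = FALSE)
  }))
  tests <- NULL
  gn <- names(groups)
  if (length(gn) >= 2L) {
    cmb <- combn(gn, 2L)
    tests <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
      g1 <- cmb[1L, j]; g2 <- cmb[2L, j]
      i1 <- groups[[g1]]; i2 <- groups[[g2]]
      if (length(i1) < 2L || length(i2) < 2L) return(NULL)
      pm <- suppressWarnings(wilcox.test(bins$entropy_minus[i1],
                                         bins$entropy_minus[i2]))$p.value
      pp <- suppressWarnings(wilcox.test(bins$entropy_plus[i1],
                                         bins$entropy_plus[i2]))$p.value
      pd <- suppressWarnings(wilcox.test(
        bins$entropy_minus[i1] - bins$entropy_plus[i1],
        bins$entropy_minus[i2] - bins$entropy_plus[i2]))$p.value
      data.frame(group1 = g1, group2 = g2, p_minusE2 = pm, p_plusE2 = pp,
                 p_drop = pd, stringsAsFactors = FALSE)
    }))
  }
  list(summary = summ, tests = tests,
       drop = setNames(summ$median_drop, summ$group),
       n_excluded = n_excluded)
}
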