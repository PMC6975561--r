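#' Recompute the headline cluster/LDEC/TAD statistics from deposited lists
#'
#' Runs the full association chain on a directory of peak/region lists
#' extracted from the study's deposited supplementary tables (exported as
#' BED): calls genomic clusters (20 kb gap, >= 3 sites) on the complete
#' +E2 ERa peak list, computes the clustered fraction and the share of
#' clusters containing a persistent site, overlaps the deposited
#' super-enhancer (LDEC) list with the clusters directly and within a
#' 100 kb window, and measures LDEC containment in the deposited TADs
#' with the mean TAD lengths by group.
#'
#' @param dir directory containing `all_peaks.bed` (every +E2 ERa peak),
#'   `persistent_peaks.bed`, `transient_peaks.bed`, `ldec.bed`,
#'   `tads.bed`. See `inst/extdata/deposited/README.md` for provenance.
#' @param max_gap,min_sites cluster-calling parameters.
#' @param window LDEC-to-cluster proximity window in bp.
#' @return list of the recomputed statistics.
#' @export
reproduce_deposited_stats <- function(dir, max_gap = 20000L,
                                      min_sites = 3L, window = 100000L) {
  files <- c(all_peaks = "all_peaks.bed",
             persistent = "persistent_peaks.bed",
             transient = "transient_peaks.bed",
             ldec = "ldec.bed", tads = "tads.bed")
  paths <- file.path(dir, files)
  names(paths) <- names(files)
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("deposited data not found; expected files in ", dir, ": ",
         paste(files[missing], collapse = ", "))
  }
  all_peaks <- read_peaks(paths["all_peaks"])
  persistent <- read_peaks(paths["persistent"])
  transient <- read_peaks(paths["transient"])
  ldec <- read_peaks(paths["ldec"])
  tads <- read_peaks(paths["tads"])
  mcols(all_peaks)$site_class <-
    ifelse(countOverlaps(all_peaks, persistent, ignore.strand = TRUE) > 0L,
           "persistent", "transient")
  clusters <- call_clusters(all_peaks, max_gap = max_gap,
                            min_sites = min_sites)
  ov <- cluster_overlap_stats(ldec, clusters, window = window)
  tc <- tad_containment(ldec, tads)
  list(n_all_peaks = length(all_peaks),
       n_persistent = length(persistent),
       n_transient = length(transient),
       n_clusters = length(clusters$members),
       clustered_fraction = clustering_fraction(clusters, all_peaks),
       frac_clusters_with_persistent =
         mean(mcols(clusters$spans)$has_persistent),
       n_ldec = length(ldec),
       n_ldec_direct = ov$n_direct,
       n_ldec_within_window = ov$n_within_window,
       tad_fraction_within = tc$fraction_within,
       mean_tad_len_with_ldec = tc$mean_len_with,
       mean_tad_len_without_ldec = tc$mean_len_without)
}
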