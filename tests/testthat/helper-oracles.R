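# Independent brute-force oracles and shared fixtures for the test suite.
# Oracles are deliberately naive (all-pairs loops, exhaustive enumeration)
# and never share code with the implementation they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

# all-pairs overlap length of two 1-based closed interval sets
oracle_overlap_any <- function(a, b, min_overlap_bp = 1L) {
  hit <- logical(length(a))
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      if (as.character(seqnames(a))[i] != as.character(seqnames(b))[j]) next
      ov <- min(end(a)[i], end(b)[j]) - max(start(a)[i], start(b)[j]) + 1L
      if (ov >= min_overlap_bp) {
        hit[i] <- TRUE
        break
      }
    }
  }
  hit
}

# naive chaining: sorted positions on one chromosome, chains of peaks with
# consecutive distance <= max_gap, emitted when >= min_sites
oracle_chain <- function(pos, max_gap, min_sites) {
  o <- order(pos)
  pos <- pos[o]
  chains <- list()
  cur <- o[1L]
  for (i in seq_along(pos)[-1L]) {
    if (pos[i] - pos[i - 1L] <= max_gap) {
      cur <- c(cur, o[i])
    } else {
      if (length(cur) >= min_sites) chains[[length(chains) + 1L]] <- cur
      cur <- o[i]
    }
  }
  if (length(cur) >= min_sites) chains[[length(chains) + 1L]] <- cur
  chains
}

# clustered-site count for a subset of positions (used by the exhaustive
# null enumeration)
oracle_clustered_count <- function(pos, max_gap, min_sites) {
  if (length(pos) == 0L) return(0L)
  length(unlist(oracle_chain(pos, max_gap, min_sites)))
}

# random peak set on a toy genome
random_peaks <- function(n, chroms = "chrT", L = 1e6, width = 50L,
                         signal = NULL) {
  chrom <- sample(chroms, n, replace = TRUE)
  s <- round(runif(n, 1, L - width))
  if (is.null(signal)) signal <- runif(n, 1, 100)
  peak_set(chrom, s, s + width - 1L, signal = signal)
}

# small generator configuration used across the suite (same structure as
# the defaults, scaled down for speed)
small_config <- function(...) {
  sim_config(n_chrom = 4L, chrom_length = 40e6,
             n_seed_clusters = 60L, n_transient_clusters = 60L,
             n_isolated_persistent = 200L, n_background_transient = 600L,
             n_minus_unique = 200L, n_genes = 300L,
             n_ere = 8000L, n_dhs = 6000L, n_background_tads = 300L,
             n_chiapet_pairs = 800L, n_cells = 100L, n_frap_traces = 4L,
             ...)
}

# memoized full-scale default peakscape (shared by the tests that probe
# the study-scale behaviour, generated once per run)
.fixture_env <- new.env(parent = emptyenv())
default_peakscape <- function() {
  if (is.null(.fixture_env$ps)) {
    .fixture_env$ps <- simulate_peakscape(sim_config(), seed = 7L)
  }
  .fixture_env$ps
}

# Toy 5C builder: nf/nr non-desert + nd desert primers per axis.
toy_fivec <- function(counts, nd = 2L) {
  nf <- nrow(counts) - nd
  nr <- ncol(counts) - nd
  fwd <- data.frame(id = sprintf("F%02d", seq_len(nf + nd)),
                    chrom = c(rep("chr21", nf), rep("chr16", nd)),
                    start = seq_len(nf + nd) * 10000,
                    end = seq_len(nf + nd) * 10000 + 119,
                    desert = c(rep(FALSE, nf), rep(TRUE, nd)))
  rev <- data.frame(id = sprintf("R%02d", seq_len(nr + nd)),
                    chrom = c(rep("chr21", nr), rep("chr16", nd)),
                    start = seq_len(nr + nd) * 10000 + 5000,
                    end = seq_len(nr + nd) * 10000 + 5119,
                    desert = c(rep(FALSE, nr), rep(TRUE, nd)))
  fivec_matrix(counts, fwd, rev)
}

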