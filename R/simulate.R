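#' Synthetic-data generator configuration
#'
#' Defaults reproduce the statistical structure and scale of the MCF-7
#' ERa two-condition experiment the pipeline targets: 6659 unliganded
#' (-E2) peaks of which 3779 persist after estradiol and 2880 are
#' -E2-unique; 18,055 ligand-dependent transient peaks; 1514 planted
#' genomic clusters (757 seeded by a persistent site, 757 transient-only)
#' holding about 30\% of all +E2 peaks; transient signal decaying
#' geometrically (factor 0.7) per two-site ordinal bin away from the seed;
#' TADs drawn so ~70\% of clusters are contained in one; induced genes
#' peaking at 40 min and dropping by 160 min; 5C matrices with per-primer
#' efficiency biases, a distance-decay baseline and an intra-cluster
#' contact boost in +E2; ChIA-PET pairs preferring persistent anchors;
#' and imaging tables with 2x ERa enrichment on cluster loci in +E2 and a
#' 60\% FRAP mobile fraction.
#'
#' @param ... named overrides of any default listed above (see the
#'   function definition for the full set).
#' @return A named list of generator parameters (class `sim_config`).
#' @export
sim_config <- function(...) {
  cfg <- list(
    # genome
    n_chrom = 20L, chrom_length = 150e6, peak_width = 200L,
    # planted site counts (incidental chains among the uniform background
    # add ~130 called clusters on top of the planted 1400)
    n_seed_clusters = 700L, n_transient_clusters = 700L,
    n_isolated_persistent = 3079L, n_background_transient = 12735L,
    n_minus_unique = 2880L,
    # cluster geometry
    transient_per_seed_mean = 3.3,      # 2 + geometric extras
    transient_cluster_size_mean = 4.3,  # 3 + geometric extras
    max_gap = 20000L, gap_min = 1000, gap_max = 18000,
    cluster_min_separation = 250000,
    # signal model
    decay_factor = 0.7, signal_noise_sd = 0.2, plus_gain = 1.5,
    persistent_signal_meanlog = log(50), persistent_signal_sdlog = 0.4,
    isolated_persistent_signal_meanlog = log(28),
    isolated_persistent_signal_sdlog = 0.5,
    transient_cluster_signal_meanlog = log(15),
    transient_cluster_signal_sdlog = 0.5,
    background_signal_meanlog = log(8), background_signal_sdlog = 0.6,
    # genes and expression
    n_genes = 2000L, gene_near_window = 40000,
    frac_genes_near_seeded = 0.2, frac_genes_near_transient_cluster = 0.1,
    induction_fold_seeded = c(t0 = 1, t10 = 2.5, t40 = 6, t160 = 1.5),
    induction_fold_transient = c(t0 = 1, t10 = 1.5, t40 = 2, t160 = 1.2),
    gene_base_expr_meanlog = log(5), gene_expr_noise_sd = 0.15,
    gene_length_meanlog = log(30000), gene_length_sdlog = 0.5,
    # TADs (planted rate sits above the emergent ~0.7 containment of
    # called super-enhancers because incidental background regions
    # without a planted TAD dilute the called set)
    tad_containment_rate = 0.85,
    tad_margin_min = 2000, tad_margin_max = 15000,
    tad_len_meanlog = log(58000), tad_len_sdlog = 0.35,
    n_background_tads = 3000L,
    # null backgrounds (ERE motif matches, DHS)
    n_ere = 200000L, ere_clustered_fraction = 0.35, ere_clump_mean = 3,
    n_dhs = 150000L, dhs_clustered_fraction = 0.55, dhs_clump_mean = 4,
    # 5C
    n_5c_clusters = 6L, n_desert = 8L,
    primer_efficiency_sdlog = 0.3, contact_base = 300,
    contact_d0 = 20000, contact_decay_floor = 0.05,
    ldec_boost = 2, trans_level = 0.1,
    # ChIA-PET
    n_chiapet_pairs = 4000L, persistent_anchor_weight = 6,
    q3_anchor_weight = 12, chiapet_rep_keep = 0.85,
    chiapet_noise_frac = 0.1, anchor_width = 2000L, anchor_jitter = 200L,
    # imaging
    n_cells = 100L, fish_enrichment_e2 = 2.0, fish_enrichment_ici = 1.0,
    fish_ratio_sdlog = 0.25, nucleus_mean = 1000, nucleus_sd = 100,
    n_nucleus_images = 12L, nucleus_pixel_cv = 0.08,
    n_frap_traces = 10L, frap_mobile_fraction = 0.6, frap_tau = 15,
    frap_noise_sd = 0.02, frap_bleach_depth = 0.05, frap_n_frames = 76L,
    frap_dt = 2, frap_bleach_frame = 6L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "sim_config")
}

# n positions on [1, L] pairwise separated by >= min_sep: pick distinct
# slots of width 2*min_sep and jitter inside the first half of each.
.separated_positions <- function(n, L, min_sep) {
  n_slots <- floor(L / (2 * min_sep))
  if (n > n_slots) stop("chromosome too short for requested separation")
  slots <- sample.int(n_slots, n)
  (slots - 1) * 2 * min_sep + 1 + runif(n, 0, min_sep)
}

# geometric counts with given minimum and mean
.geom_counts <- function(n, minimum, mean_total) {
  extra_mean <- max(mean_total - minimum, 1e-9)
  minimum + rgeom(n, prob = 1 / (1 + extra_mean))
}

# clumped background point process: a fraction of sites sit in short
# chains (consecutive gaps < 15 kb), the rest are uniform
.clumped_sites <- function(n, frac_clumped, clump_mean, n_chrom, L, width,
                           prefix) {
  n_cl <- round(n * frac_clumped)
  n_clumps <- max(1L, round(n_cl / clump_mean))
  sizes <- .geom_counts(n_clumps, 2L, clump_mean)
  sizes <- sizes[cumsum(sizes) <= n_cl]
  n_single <- n - sum(sizes)
  chrom_cl <- sample.int(n_chrom, length(sizes), replace = TRUE)
  centers <- runif(length(sizes), 1, L - 1e6)
  pos <- numeric(0)
  chr <- integer(0)
  for (i in seq_along(sizes)) {
    gaps <- runif(sizes[i] - 1L, 500, 15000)
    p <- centers[i] + c(0, cumsum(gaps))
    pos <- c(pos, p)
    chr <- c(chr, rep(chrom_cl[i], sizes[i]))
  }
  pos <- c(pos, runif(n_single, 1, L - 1e6))
  chr <- c(chr, sample.int(n_chrom, n_single, replace = TRUE))
  s <- pmax(1, round(pos - width / 2))
  gr <- GRanges(paste0("chr", chr), IRanges(s, s + width - 1L))
  mcols(gr)$name <- sprintf("%s_%d", prefix, seq_along(gr))
  mcols(gr)$signal <- NA_real_
  sort_peaks(gr)
}

#' Generate the synthetic two-condition peak landscape
#'
#' Emits -E2 and +E2 peak sets with planted persistent / transient /
#' -E2-unique classes, seeded and transient-only genomic clusters, signal
#' tracks and per-gene expression over the E2 time course, TADs, and the
#' ERE/DHS background site lists used by the clustering null — together
#' with a ground-truth record. Deterministic under `seed`; planted
#' background peaks colliding with peaks of another class are re-placed
#' (count recorded in `truth$n_rejittered`).
#'
#' @param config a [sim_config()].
#' @param seed master seed; per-output child seeds are derived
#'   deterministically.
#' @return list with `minus`, `plus` (peak `GRanges` with truth
#'   `site_class`), `genes`, `expression`, `tracks` (per time point),
#'   `tads`, `ere`, `dhs`, `truth`.
#' @export
simulate_peakscape <- function(config = sim_config(), seed = 1L) {
  cfg <- config
  .with_seed(child_seed(seed, "peakscape"), {
    n_chrom <- cfg$n_chrom
    L <- cfg$chrom_length
    w <- cfg$peak_width
    n_clusters <- cfg$n_seed_clusters + cfg$n_transient_clusters
    chrom_of <- sample.int(n_chrom, n_clusters, replace = TRUE)
    origins <- numeric(n_clusters)
    for (ch in unique(chrom_of)) {
      i <- which(chrom_of == ch)
      origins[i] <- .separated_positions(length(i), L - 1e6,
                                         cfg$cluster_min_separation)
    }
    seeded <- c(rep(TRUE, cfg$n_seed_clusters),
                rep(FALSE, cfg$n_transient_clusters))
    sizes <- integer(n_clusters)
    sizes[seeded] <- .geom_counts(sum(seeded), 3L,
                                  cfg$transient_per_seed_mean + 1)
    sizes[!seeded] <- .geom_counts(sum(!seeded), 3L,
                                   cfg$transient_cluster_size_mean)
    # member peaks per cluster
    rec <- vector("list", n_clusters)
    for (i in seq_len(n_clusters)) {
      s <- sizes[i]
      gaps <- runif(s - 1L, cfg$gap_min, cfg$gap_max)
      centers <- origins[i] + c(0, cumsum(gaps))
      if (seeded[i]) {
        seed_idx <- sample.int(s, 1L)
        b <- rlnorm(1, cfg$persistent_signal_meanlog,
                    cfg$persistent_signal_sdlog)
        bin <- ceiling(abs(seq_len(s) - seed_idx) / 2)
        sig_plus <- b * cfg$plus_gain * cfg$decay_factor^bin *
          exp(rnorm(s, 0, cfg$signal_noise_sd))
        sig_plus[seed_idx] <- b * cfg$plus_gain
        cls <- rep("transient", s)
        cls[seed_idx] <- "persistent"
        sig_minus <- rep(NA_real_, s)
        sig_minus[seed_idx] <- b
      } else {
        sig_plus <- rlnorm(s, cfg$transient_cluster_signal_meanlog,
                           cfg$transient_cluster_signal_sdlog)
        cls <- rep("transient", s)
        sig_minus <- rep(NA_real_, s)
      }
      rec[[i]] <- data.frame(
        chrom = paste0("chr", chrom_of[i]), center = centers,
        signal_plus = sig_plus, signal_minus = sig_minus, class = cls,
        cluster = i, stringsAsFactors = FALSE)
    }
    members <- do.call(rbind, rec)
    .uniform_df <- function(n, class, meanlog, sdlog, gain = 1) {
      if (n == 0L) {
        return(data.frame(chrom = character(0), center = numeric(0),
                          signal_plus = numeric(0),
                          signal_minus = numeric(0), class = character(0),
                          cluster = integer(0), stringsAsFactors = FALSE))
      }
      b <- rlnorm(n, meanlog, sdlog)
      data.frame(chrom = paste0("chr", sample.int(n_chrom, n, replace = TRUE)),
                 center = runif(n, 1, L - 1e6),
                 signal_plus = b * gain * exp(rnorm(n, 0, cfg$signal_noise_sd)),
                 signal_minus = b, class = class, cluster = NA_integer_,
                 stringsAsFactors = FALSE)
    }
    iso <- .uniform_df(cfg$n_isolated_persistent, "persistent",
                       cfg$isolated_persistent_signal_meanlog,
                       cfg$isolated_persistent_signal_sdlog,
                       gain = cfg$plus_gain)
    bgt <- .uniform_df(cfg$n_background_transient, "transient",
                       cfg$background_signal_meanlog,
                       cfg$background_signal_sdlog)
    bgt$signal_minus <- rep(NA_real_, nrow(bgt))
    mnu <- .uniform_df(cfg$n_minus_unique, "minus_unique",
                       cfg$background_signal_meanlog,
                       cfg$background_signal_sdlog)
    mnu$signal_plus <- rep(NA_real_, nrow(mnu))
    all_sites <- rbind(members, iso, bgt, mnu)
    all_sites$start <- pmax(1, round(all_sites$center - w / 2))
    all_sites$end <- all_sites$start + w - 1L
    # resolve collisions between classes that must not overlap: movable
    # uniform sites are re-placed until clean
    movable <- is.na(all_sites$cluster)
    n_rejittered <- 0L
    for (round in 1:50) {
      gr_all <- GRanges(all_sites$chrom,
                        IRanges(all_sites$start, all_sites$end))
      in_minus <- all_sites$class %in% c("persistent", "minus_unique")
      in_plus <- all_sites$class %in% c("persistent", "transient")
      h <- findOverlaps(gr_all, gr_all, ignore.strand = TRUE)
      qh <- queryHits(h); sh <- subjectHits(h)
      off <- qh != sh &
        ((in_minus[qh] & in_plus[sh]) | (in_plus[qh] & in_minus[sh])) &
        all_sites$class[qh] != all_sites$class[sh]
      bad <- unique(qh[off])
      bad <- bad[movable[bad]]
      if (length(bad) == 0L) break
      n_rejittered <- n_rejittered + length(bad)
      all_sites$center[bad] <- runif(length(bad), 1, L - 1e6)
      all_sites$chrom[bad] <-
        paste0("chr", sample.int(n_chrom, length(bad), replace = TRUE))
      all_sites$start[bad] <- pmax(1, round(all_sites$center[bad] - w / 2))
      all_sites$end[bad] <- all_sites$start[bad] + w - 1L
    }
    all_sites$name <- sprintf("site_%05d", seq_len(nrow(all_sites)))
    .build <- function(rows, signal_col) {
      gr <- GRanges(all_sites$chrom[rows],
                    IRanges(all_sites$start[rows], all_sites$end[rows]))
      mcols(gr)$name <- all_sites$name[rows]
      mcols(gr)$signal <- all_sites[[signal_col]][rows]
      mcols(gr)$site_class <- all_sites$class[rows]
      sort_peaks(gr)
    }
    minus <- .build(which(all_sites$class %in%
                            c("persistent", "minus_unique")), "signal_minus")
    plus <- .build(which(all_sites$class %in%
                           c("persistent", "transient")), "signal_plus")
    # planted cluster spans
    span_df <- do.call(rbind, lapply(seq_len(n_clusters), function(i) {
      r <- all_sites[!is.na(all_sites$cluster) & all_sites$cluster == i, ]
      data.frame(chrom = r$chrom[1L], start = min(r$start),
                 end = max(r$end), stringsAsFactors = FALSE)
    }))
    cluster_spans <- GRanges(span_df$chrom,
                             IRanges(span_df$start, span_df$end))
    mcols(cluster_spans)$seeded <- seeded
    mcols(cluster_spans)$n_sites <- sizes
    # genes: a fraction placed near planted clusters, the rest uniform
    ng <- cfg$n_genes
    n_near_s <- if (any(seeded)) round(ng * cfg$frac_genes_near_seeded)
                else 0L
    n_near_t <- if (any(!seeded))
      round(ng * cfg$frac_genes_near_transient_cluster) else 0L
    n_far <- ng - n_near_s - n_near_t
    pick_s <- sample(which(seeded), n_near_s, replace = TRUE)
    pick_t <- sample(which(!seeded), n_near_t, replace = TRUE)
    near_tss <- function(pick) {
      span_df$start[pick] + runif(length(pick), -cfg$gene_near_window,
                                  cfg$gene_near_window)
    }
    tss <- c(near_tss(pick_s), near_tss(pick_t),
             runif(n_far, 2e5, L - 2e5))
    gchrom <- c(span_df$chrom[pick_s], span_df$chrom[pick_t],
                paste0("chr", sample.int(n_chrom, n_far, replace = TRUE)))
    gclass <- c(rep("near_seeded", n_near_s),
                rep("near_transient_cluster", n_near_t),
                rep("background", n_far))
    gstrand <- sample(c("+", "-"), ng, replace = TRUE)
    glen <- pmax(2000, round(rlnorm(ng, cfg$gene_length_meanlog,
                                    cfg$gene_length_sdlog)))
    tss <- pmax(tss, glen + 1)
    gs <- ifelse(gstrand == "+", round(tss), round(tss) - glen + 1L)
    ge <- gs + glen - 1L
    genes <- gene_models(gchrom, gs, ge, gstrand,
                         sprintf("gene_%04d", seq_len(ng)))
    mcols(genes)$gene_class <- gclass
    # expression over the E2 time course
    base <- rlnorm(ng, cfg$gene_base_expr_meanlog, 0.6)
    tp <- c("t0", "t10", "t40", "t160")
    fold <- rbind(cfg$induction_fold_seeded, cfg$induction_fold_transient,
                  c(1, 1, 1, 1))
    rownames(fold) <- c("near_seeded", "near_transient_cluster", "background")
    expr <- sapply(seq_along(tp), function(j) {
      base * fold[gclass, j] * exp(rnorm(ng, 0, cfg$gene_expr_noise_sd))
    })
    colnames(expr) <- tp
    expression <- data.frame(gene = mcols(genes)$name,
                             gene_class = gclass, expr,
                             stringsAsFactors = FALSE)
    # per-time-point coverage tracks: gene-body windows plus eRNA blocks
    gb_tss <- mcols(genes)$tss
    gb_s <- ifelse(gstrand == "+", gb_tss + 1000L, gb_tss - 13000L + 1L)
    gb_e <- ifelse(gstrand == "+", gb_tss + 13000L - 1L, gb_tss - 1000L)
    gb_s <- pmax(gb_s, 1L)
    in_cluster <- !is.na(all_sites$cluster) &
      all_sites$class %in% c("persistent", "transient")
    er_center <- round(all_sites$center[in_cluster])
    er_chrom <- all_sites$chrom[in_cluster]
    er_sig <- all_sites$signal_plus[in_cluster]
    tracks <- lapply(seq_along(tp), function(j) {
      gr <- suppressWarnings(
        c(GRanges(gchrom, IRanges(gb_s, gb_e)),
          GRanges(er_chrom, IRanges(pmax(er_center - 1000L, 1L),
                                    er_center + 999L))))
      mcols(gr)$value <- c(expr[, j] / 12000,
                           er_sig * fold["near_seeded", j] / 2000 / 50)
      sort(gr, ignore.strand = TRUE)
    })
    names(tracks) <- tp
    # TADs: most planted clusters get a containing TAD, the rest an
    # overlapping-but-not-containing one; background TADs elsewhere
    contains <- runif(n_clusters) < cfg$tad_containment_rate
    m1 <- runif(n_clusters, cfg$tad_margin_min, cfg$tad_margin_max)
    m2 <- runif(n_clusters, cfg$tad_margin_min, cfg$tad_margin_max)
    t_s <- ifelse(contains, span_df$start - m1,
                  span_df$start + pmax(200, 0.3 * (span_df$end -
                                                     span_df$start)))
    t_len <- rlnorm(n_clusters, cfg$tad_len_meanlog, cfg$tad_len_sdlog)
    t_e <- ifelse(contains, span_df$end + m2, t_s + t_len)
    bg_s <- runif(cfg$n_background_tads, 1, L - 5e5)
    bg_chr <- paste0("chr", sample.int(n_chrom, cfg$n_background_tads,
                                       replace = TRUE))
    bg_len <- rlnorm(cfg$n_background_tads, cfg$tad_len_meanlog,
                     cfg$tad_len_sdlog)
    tads <- GRanges(c(span_df$chrom, bg_chr),
                    IRanges(pmax(1, round(c(t_s, bg_s))),
                            round(c(t_e, bg_s + bg_len))))
    mcols(tads)$name <- sprintf("tad_%05d", seq_along(tads))
    ere <- .clumped_sites(cfg$n_ere, cfg$ere_clustered_fraction,
                          cfg$ere_clump_mean, n_chrom, L, 20L, "ere")
    dhs <- .clumped_sites(cfg$n_dhs, cfg$dhs_clustered_fraction,
                          cfg$dhs_clump_mean, n_chrom, L, 150L, "dhs")
    truth <- list(sites = all_sites, cluster_spans = cluster_spans,
                  n_rejittered = n_rejittered, config = cfg, seed = seed)
    list(minus = minus, plus = plus, genes = genes,
         expression = expression, tracks = tracks, tads = tads,
         ere = ere, dhs = dhs, truth = truth)
  })
}

#' Generate synthetic 5C libraries and ChIA-PET replicates
#'
#' 5C: alternating forward/reverse primers are placed on the member peaks
#' of a handful of seeded clusters on one chromosome, plus gene-desert
#' control primers on a separate control chromosome. Raw counts are
#' Poisson with per-primer efficiency biases, a distance-decay baseline,
#' and an intra-cluster contact boost applied only in the +E2 condition;
#' two replicate libraries (independent efficiencies) are emitted per
#' condition. ChIA-PET: interaction pairs are sampled with anchors
#' preferring persistent sites (strongest-quartile persistent sites most),
#' then jittered and subsampled into three replicates with added noise
#' pairs.
#'
#' @param peakscape a [simulate_peakscape()] result.
#' @param config the same [sim_config()].
#' @param seed master seed.
#' @return list with `fivec` (`$ici`, `$e2`: two [fivec_matrix()] each),
#'   `regions` (the clusters the primers cover), `chiapet` (three pair
#'   data.frames), `sites` (classified +E2 peaks used for anchors), and
#'   `truth` (primer cluster ids, true means, true pair list).
#' @export
simulate_contacts <- function(peakscape, config = sim_config(), seed = 1L) {
  cfg <- config
  .with_seed(child_seed(seed, "contacts"), {
    spans <- peakscape$truth$cluster_spans
    seeded_spans <- spans[mcols(spans)$seeded]
    tab <- table(as.character(seqnames(seeded_spans)))
    chr <- names(tab)[which.max(tab)]
    on_chr <- seeded_spans[as.character(seqnames(seeded_spans)) == chr]
    on_chr <- on_chr[order(start(on_chr))]
    regions <- head(on_chr, cfg$n_5c_clusters)
    mcols(regions)$name <- sprintf("ldec_%d", seq_along(regions))
    plus <- peakscape$plus
    hit <- findOverlaps(plus, regions, select = "first",
                        ignore.strand = TRUE)
    sel <- which(!is.na(hit))
    sel <- sel[order(start(plus)[sel])]
    cluster_id <- hit[sel]
    orient <- rep(c("F", "R"), length.out = length(sel))
    man <- data.frame(id = sprintf("p_%s_%03d", orient, seq_along(sel)),
                      chrom = as.character(seqnames(plus))[sel],
                      start = start(plus)[sel], end = end(plus)[sel],
                      orientation = orient, desert = FALSE,
                      cluster = cluster_id, stringsAsFactors = FALSE)
    des_pos <- seq(1e6, by = 5000, length.out = 2 * cfg$n_desert)
    des <- data.frame(id = sprintf("d_%s_%03d",
                                   rep(c("F", "R"), cfg$n_desert),
                                   seq_len(2 * cfg$n_desert)),
                      chrom = "chr16_desert", start = round(des_pos),
                      end = round(des_pos) + 119L,
                      orientation = rep(c("F", "R"), cfg$n_desert),
                      desert = TRUE, cluster = NA_integer_,
                      stringsAsFactors = FALSE)
    man <- rbind(man, des)
    fwd <- man[man$orientation == "F", , drop = FALSE]
    rev <- man[man$orientation == "R", , drop = FALSE]
    ctr <- function(m) (m$start + m$end) / 2
    cF <- ctr(fwd); cR <- ctr(rev)
    base_mu <- function(is_e2) {
      mu <- matrix(cfg$contact_base * cfg$trans_level,
                   nrow(fwd), nrow(rev))
      cis <- outer(!fwd$desert, !rev$desert, `&`)
      d <- abs(outer(cF, cR, `-`))
      decay <- pmin(pmax(cfg$contact_d0 / pmax(d, 1),
                         cfg$contact_decay_floor), 1)
      same <- outer(fwd$cluster, rev$cluster,
                    function(a, b) !is.na(a) & !is.na(b) & a == b)
      boost <- 1 + cfg$ldec_boost * same * as.numeric(is_e2)
      mu[cis] <- (cfg$contact_base * decay * boost)[cis]
      mu
    }
    make_lib <- function(is_e2) {
      eF <- rlnorm(nrow(fwd), 0, cfg$primer_efficiency_sdlog)
      eR <- rlnorm(nrow(rev), 0, cfg$primer_efficiency_sdlog)
      mu <- base_mu(is_e2) * outer(eF, eR)
      counts <- matrix(rpois(length(mu), mu), nrow(fwd), nrow(rev))
      fivec_matrix(counts, fwd[, names(fwd) != "cluster"],
                   rev[, names(rev) != "cluster"])
    }
    fivec <- list(ici = list(make_lib(FALSE), make_lib(FALSE)),
                  e2 = list(make_lib(TRUE), make_lib(TRUE)))
    # ChIA-PET anchors with persistent-site preference
    sites <- plus
    cls <- mcols(sites)$site_class
    sig <- mcols(sites)$signal
    weight <- rep(1, length(sites))
    pers <- which(cls == "persistent")
    weight[pers] <- cfg$persistent_anchor_weight
    q3 <- pers[sig[pers] >= quantile(sig[pers], 0.75)]
    weight[q3] <- cfg$q3_anchor_weight
    np <- cfg$n_chiapet_pairs
    i1 <- sample.int(length(sites), np, replace = TRUE, prob = weight)
    i2 <- sample.int(length(sites), np, replace = TRUE, prob = weight)
    ok <- i1 != i2
    i1 <- i1[ok]; i2 <- i2[ok]
    mid <- .midpoints(sites)
    half <- cfg$anchor_width %/% 2L
    true_pairs <- data.frame(
      chrom1 = as.character(seqnames(sites))[i1],
      start1 = mid[i1] - half, end1 = mid[i1] + half - 1L,
      chrom2 = as.character(seqnames(sites))[i2],
      start2 = mid[i2] - half, end2 = mid[i2] + half - 1L,
      stringsAsFactors = FALSE)
    jitter_pairs <- function(df) {
      for (col in c("start1", "end1")) {
        j <- round(runif(nrow(df), -cfg$anchor_jitter, cfg$anchor_jitter))
        df[[col]] <- df[[col]] + j
      }
      for (col in c("start2", "end2")) {
        j <- round(runif(nrow(df), -cfg$anchor_jitter, cfg$anchor_jitter))
        df[[col]] <- df[[col]] + j
      }
      df
    }
    chiapet <- lapply(1:3, function(r) {
      keep <- runif(nrow(true_pairs)) < cfg$chiapet_rep_keep
      df <- true_pairs[keep, , drop = FALSE]
      n_noise <- round(cfg$chiapet_noise_frac * nrow(df))
      ni1 <- sample.int(length(sites), n_noise, replace = TRUE)
      ni2 <- sample.int(length(sites), n_noise, replace = TRUE)
      noise <- data.frame(
        chrom1 = as.character(seqnames(sites))[ni1],
        start1 = mid[ni1] - half, end1 = mid[ni1] + half - 1L,
        chrom2 = as.character(seqnames(sites))[ni2],
        start2 = mid[ni2] - half, end2 = mid[ni2] + half - 1L,
        stringsAsFactors = FALSE)
      out <- jitter_pairs(rbind(df, noise))
      rownames(out) <- NULL
      out
    })
    list(fivec = fivec, regions = regions, chiapet = chiapet,
         sites = sites,
         truth = list(forward_cluster = fwd$cluster,
                      reverse_cluster = rev$cluster,
                      mu_ici = base_mu(FALSE), mu_e2 = base_mu(TRUE),
                      true_pairs = true_pairs, weights = weight))
  })
}

#' Generate synthetic imaging tables (immunoFISH spots, nuclei, FRAP)
#'
#' Spot tables carry a planted ERa enrichment on cluster (LDEC) loci in
#' the +E2 condition and none in the unliganded control or on random
#' loci; nucleus images are near-homogeneous intensity matrices for the
#' random-ROI null; FRAP traces are single-exponential recoveries with a
#' configured mobile fraction and noise.
#'
#' @param config a [sim_config()].
#' @param seed master seed.
#' @return list with `spots` (data.frame), `nuclei` (list of matrices),
#'   `frap` (list of `list(trace, bleach_frame, true_mobile_fraction)`).
#' @export
simulate_imaging <- function(config = sim_config(), seed = 1L) {
  cfg <- config
  .with_seed(child_seed(seed, "imaging"), {
    conds <- c(ICI = cfg$fish_enrichment_ici, E2 = cfg$fish_enrichment_e2)
    rows <- list()
    for (cd in names(conds)) {
      for (locus in c("LDEC", "random")) {
        nuc <- rnorm(cfg$n_cells, cfg$nucleus_mean, cfg$nucleus_sd)
        nuc <- pmax(nuc, 1)
        eff <- if (locus == "LDEC") conds[[cd]] else 1.0
        ratio <- rlnorm(cfg$n_cells, log(eff), cfg$fish_ratio_sdlog)
        rows[[length(rows) + 1L]] <- data.frame(
          cell = seq_len(cfg$n_cells), spot = 1L, condition = cd,
          locus = locus, nucleus_mean = nuc, spot_mean = nuc * ratio,
          spot_diameter = 1.0, stringsAsFactors = FALSE)
      }
    }
    spots <- do.call(rbind, rows)
    rownames(spots) <- NULL
    nuclei <- lapply(seq_len(cfg$n_nucleus_images), function(i) {
      M <- matrix(NA_real_, 60, 60)
      cy <- 30.5; cx <- 30.5; r <- 26
      idx <- which(outer((1:60 - cy)^2, (1:60 - cx)^2, `+`) <= r^2)
      M[idx] <- cfg$nucleus_mean *
        exp(rnorm(length(idx), 0, cfg$nucleus_pixel_cv))
      M
    })
    frap <- lapply(seq_len(cfg$n_frap_traces), function(i) {
      nfr <- cfg$frap_n_frames
      tb <- cfg$frap_bleach_frame
      t <- seq(0, by = cfg$frap_dt, length.out = nfr)
      true <- rep(1, nfr)
      post <- tb:nfr
      true[post] <- cfg$frap_bleach_depth +
        (cfg$frap_mobile_fraction - cfg$frap_bleach_depth) *
        (1 - exp(-(t[post] - t[tb]) / cfg$frap_tau))
      obs <- true + rnorm(nfr, 0, cfg$frap_noise_sd)
      whole <- 1000
      bg <- 50
      trace <- data.frame(time = t,
                          roi = bg + whole * 0.9 * obs,
                          background = rep(bg, nfr),
                          whole_cell = rep(whole, nfr),
                          unbleached = bg + whole * 0.9 *
                            (1 + rnorm(nfr, 0, cfg$frap_noise_sd)))
      list(trace = trace, bleach_frame = tb,
           true_mobile_fraction = cfg$frap_mobile_fraction)
    })
    list(spots = spots, nuclei = nuclei, frap = frap)
  })
}
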