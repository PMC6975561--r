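test_that("stitching handles isolated peaks and degenerate geometry", {
  pk <- peak_set("chr1", c(1e6, 3e6, 5e6), c(1e6, 3e6, 5e6) + 199,
                 signal = c(1, 5, 9))
  se <- stitch_and_rank(pk)
  expect_length(se$regions, 3L)
  expect_equal(width(se$regions), rep(200L, 3))
  expect_equal(mcols(se$regions)$signal, c(1, 5, 9))

  # two peaks within the stitch distance merge and sum their signal
  pk2 <- peak_set("chr1", c(1e6, 1e6 + 10000, 3e6, 5e6),
                  c(1e6, 1e6 + 10000, 3e6, 5e6) + 199,
                  signal = c(1, 2, 5, 9))
  se2 <- stitch_and_rank(pk2, stitch_distance = 15000)
  expect_length(se2$regions, 3L)
  expect_true(3 %in% mcols(se2$regions)$signal)

  expect_error(stitch_and_rank(pk[1:2]), "fewer than 3")
  flat <- peak_set("chr1", c(1e6, 3e6, 5e6), c(1e6, 3e6, 5e6) + 199,
                   signal = c(2, 2, 2))
  expect_error(stitch_and_rank(flat), "identical")
})

test_that("elbow sits within 2 ranks of the dense tangent-scan oracle", {
  set.seed(101)
  n <- 200
  # convex curve with a sharp knee at rank fraction ~0.9
  sig <- c(seq(0.5, 20, length.out = 180),
           20 * exp(seq(0.5, 4, length.out = 20)))
  sig <- sig * runif(n, 0.98, 1.02)
  pos <- seq(1e5, by = 1e6, length.out = n)
  pk <- peak_set("chr1", pos, pos + 199, signal = sig)
  se <- stitch_and_rank(pk)
  # independent dense scan on the returned rank-ordered signals
  s <- mcols(se$regions)$signal
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - min(s)) / (max(s) - min(s))
  oracle_elbow <- which.min(y - x)
  expect_lte(abs(se$elbow_index - oracle_elbow), 2)
  expect_true(all(mcols(se$regions)$super == (seq_len(n) > se$elbow_index)))
  expect_true(all(mcols(se$regions)$signal[mcols(se$regions)$super] >
                    se$cutoff_signal - 1e-9))
})

test_that("cluster overlap statistics match the all-pairs distance oracle", {
  set.seed(111)
  super <- random_peaks(50, chroms = c("chr1", "chr2"), L = 5e6,
                        width = 20000)
  spans <- granges(random_peaks(20, chroms = c("chr1", "chr2"), L = 5e6,
                                width = 50000))
  ov <- cluster_overlap_stats(super, spans, window = 100000)
  direct <- oracle_overlap_any(super, spans)
  within <- logical(length(super))
  for (i in seq_along(super)) {
    for (j in seq_along(spans)) {
      if (as.character(seqnames(super))[i] !=
          as.character(seqnames(spans))[j]) next
      gap <- max(start(spans)[j] - end(super)[i],
                 start(super)[i] - end(spans)[j], 0)
      if (gap <= 100000) within[i] <- TRUE
    }
  }
  expect_equal(ov$n_direct, sum(direct))
  expect_equal(ov$n_within_window, sum(within))
  expect_true(ov$n_direct <= ov$n_within_window)
  expect_true(ov$n_within_window <= ov$n_super)

  none <- cluster_overlap_stats(super, spans[0])
  expect_equal(none$n_direct, 0L)
  expect_equal(none$n_within_window, 0L)
})

test_that("TAD containment matches brute force and preserves the length identity", {
  set.seed(121)
  tads <- granges(random_peaks(30, chroms = "chr1", L = 3e6,
                               width = 60000))
  ldec <- random_peaks(40, chroms = "chr1", L = 3e6, width = 30000)
  tc <- tad_containment(ldec, tads)
  contained <- logical(length(ldec))
  for (i in seq_along(ldec)) {
    for (j in seq_along(tads)) {
      if (start(ldec)[i] >= start(tads)[j] &&
          end(ldec)[i] <= end(tads)[j]) contained[i] <- TRUE
    }
  }
  expect_equal(tc$fraction_within, mean(contained))
  # weighted mean of the two group means equals the overall mean length
  w <- sum(tc$tad_has_ldec)
  total <- w * tc$mean_len_with + (length(tads) - w) * tc$mean_len_without
  expect_equal(total / length(tads), mean(width(tads)))

  inside <- peak_set("chr1", start(tads)[1:5] + 1000,
                     start(tads)[1:5] + 2000)
  expect_equal(tad_containment(inside, tads)$fraction_within, 1.0)
  # smallest containing TAD is selected under overlapping definitions
  big <- GRanges("chr9", IRanges(c(1, 100), c(10000, 500)))
  one <- peak_set("chr9", 150, 300)
  expect_equal(tad_containment(one, big)$assigned_tad, 2L)
})

test_that("window counting is exact, strand-mirrored, and linear in the track", {
  genes <- gene_models(c("chr1", "chr1"), c(50000, 50000),
                       c(80000, 80000), c("+", "-"), c("gplus", "gminus"))
  # gminus TSS is at 80000; mirror the +strand window block
  track <- GRanges("chr1", IRanges(c(51000, 67001), c(62999, 79000)))
  mcols(track)$value <- c(1, 1)
  counts <- quantify_window_counts(track, genes, mode = "gene_body")
  expect_equal(unname(counts["gplus"]), 12000)
  expect_equal(unname(counts["gminus"]), unname(counts["gplus"]))

  # per-base oracle on an arbitrary stepped track
  set.seed(131)
  steps <- GRanges("chr1", IRanges(seq(40000, 99000, by = 1000),
                                   seq(40999, 99999, by = 1000)))
  mcols(steps)$value <- runif(length(steps), 0, 3)
  got <- quantify_window_counts(steps, genes, mode = "gene_body")
  base_val <- rep(0, 2e5)
  for (i in seq_along(steps)) {
    base_val[start(steps)[i]:end(steps)[i]] <- mcols(steps)$value[i]
  }
  expect_equal(unname(got["gplus"]), sum(base_val[51000:62999]))
  expect_equal(unname(got["gminus"]), sum(base_val[67001:79000]))

  doubled <- steps
  mcols(doubled)$value <- mcols(steps)$value * 2
  expect_equal(quantify_window_counts(doubled, genes, mode = "gene_body"),
               got * 2)

  # eRNA mode: symmetric window about the peak center
  pk <- peak_set("chr1", 59901, 60100)  # center 60000
  er <- quantify_window_counts(steps, pk, mode = "erna")
  expect_equal(unname(er), sum(base_val[59000:60999]))
})

test_that("group comparison wraps the exact rank tests", {
  set.seed(141)
  x <- rnorm(50)
  same <- compare_groups(list(a = x, b = x))
  expect_gt(same$p_value, 0.99)
  shifted <- compare_groups(list(a = x, b = x + 10))
  expect_lt(shifted$p_value, 0.001)
  expect_error(compare_groups(list(a = 1, b = 1:5)), ">= 2 values")
  expect_error(compare_groups(list(a = 1:3)), ">= 2 groups")
  expect_error(compare_groups(list(a = 1:3, b = 1:4), paired = TRUE),
               "equal group lengths")

  # exact two-sided p at n = 5 against full enumeration of rank splits
  g1 <- c(1.2, 3.4, 2.2, 5.1, 0.3)
  g2 <- c(2.9, 6.3, 4.4, 7.0, 5.9)
  res <- compare_groups(list(a = g1, b = g2))
  ranks <- rank(c(g1, g2))
  w_obs <- sum(ranks[1:5]) - 5 * 6 / 2
  wnull <- apply(combn(10, 5), 2, function(i) sum(seq_len(10)[i]) - 15)
  p_enum <- min(1, 2 * min(mean(wnull <= w_obs), mean(wnull >= w_obs)))
  expect_equal(res$p_value, p_enum)
})
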