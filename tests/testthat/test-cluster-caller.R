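test_that("chaining matches hand-computable cases and the brute-force oracle", {
  centers <- c(0, 10000, 20000) + 5000
  pk <- peak_set("chr1", centers - 100, centers + 99)
  cc <- call_clusters(pk, max_gap = 20000, min_sites = 3)
  expect_length(cc$members, 1L)
  expect_equal(mcols(cc$spans)$n_sites, 3L)

  far <- c(0, 25000, 50000) + 5000
  pk2 <- peak_set("chr1", far - 100, far + 99)
  expect_length(call_clusters(pk2, 20000, 3)$members, 0L)

  set.seed(61)
  for (rep in 1:100) {
    n <- sample(20:80, 1)
    max_gap <- sample(c(5000, 10000, 20000), 1)
    min_sites <- sample(2:3, 1)
    pk <- random_peaks(n, L = 10e6, width = 200)
    cc <- call_clusters(pk, max_gap, min_sites)
    truth <- oracle_chain(floor((start(pk) + end(pk)) / 2),
                          max_gap, min_sites)
    got <- lapply(cc$members, sort)
    want <- lapply(truth, sort)
    expect_equal(got[order(vapply(got, min, 0))],
                 want[order(vapply(want, min, 0))])
  }
})

test_that("cluster calling is order-invariant and monotone in its parameters", {
  set.seed(71)
  pk <- random_peaks(500, L = 10e6)
  shuf <- pk[sample(length(pk))]
  a <- call_clusters(pk, 20000, 3)
  b <- call_clusters(shuf, 20000, 3)
  expect_equal(granges(a$spans), granges(b$spans))

  sizes <- vapply(c(5000, 10000, 20000), function(g)
    length(unlist(call_clusters(pk, g, 3)$members)), 0L)
  expect_true(all(diff(sizes) >= 0))  # membership grows with max_gap
  counts <- vapply(2:5, function(m)
    length(call_clusters(pk, 20000, m)$members), 0L)
  expect_true(all(diff(counts) <= 0))  # clusters shrink with min_sites
  expect_true(sum(mcols(a$spans)$n_sites) <= length(pk))
})

test_that("clustering_fraction handles the boundary cases", {
  tight <- peak_set("chr1", c(1000, 3000, 5000), c(1200, 3200, 5200))
  cc <- call_clusters(tight, 20000, 3)
  expect_equal(clustering_fraction(cc, tight), 1.0)
  sparse <- peak_set("chr1", c(1e6, 2e6, 3e6), c(1e6, 2e6, 3e6) + 200)
  expect_equal(clustering_fraction(call_clusters(sparse, 20000, 3), sparse),
               0.0)
  expect_error(clustering_fraction(cc, tight[0]), "empty")
  expect_error(clustering_fraction(cc, sparse), "not called from")
})

test_that("null clustering is seeded, degenerate-exact, and matches enumeration", {
  set.seed(81)
  bg <- random_peaks(200, L = 5e6)
  obs <- call_clusters(bg, 20000, 3)
  # degenerate draw of the full background reproduces the observed count
  null_full <- null_clustering(bg, length(bg), n_iter = 5, seed = 3)
  expect_true(all(null_full$counts == length(obs$members)))
  # determinism under the seed
  n1 <- null_clustering(bg, 100, n_iter = 20, seed = 9)
  n2 <- null_clustering(bg, 100, n_iter = 20, seed = 9)
  expect_identical(n1$counts, n2$counts)
  expect_identical(n1$fractions, n2$fractions)
  expect_error(null_clustering(bg, 1000, seed = 1), "smaller than")

  # exhaustive C(20,5) enumeration on a toy chromosome vs Monte Carlo
  pos <- sort(round(runif(20, 1, 3e5)))
  toy <- peak_set("chrT", pos - 25, pos + 24)
  combs <- combn(20, 5)
  exact <- apply(combs, 2, function(i)
    oracle_clustered_count(pos[i], 20000, 3) / 5)
  mc <- null_clustering(toy, 5, n_iter = 400, max_gap = 20000,
                        min_sites = 3, seed = 17)
  se <- sd(mc$fractions) / sqrt(mc$n_iter)
  expect_lt(abs(mc$mean_fraction - mean(exact)), 3 * max(se, 1e-6))

  # add-one empirical p-value can never be zero
  p <- null_clustering(toy, 5, n_iter = 50, seed = 2,
                       observed_fraction = 1.01)$p_value
  expect_equal(p, 1 / 51)
})

test_that("decay profile is flat for constant signal and strictly ordered for planted decay", {
  centers <- seq(1000, by = 5000, length.out = 7)
  pk <- peak_set("chr1", centers - 100, centers + 99,
                 signal = rep(4, 7),
                 site_class = c(rep("transient", 3), "persistent",
                                rep("transient", 3)))
  cc <- call_clusters(pk, 20000, 3)
  dp <- decay_profile(cc, pk)
  expect_true(all(abs(dp$mean_signal - 4) < 1e-12))

  dec <- peak_set("chr1", centers - 100, centers + 99,
                  signal = c(20, 35, 60, 100, 60, 35, 20),
                  site_class = c(rep("transient", 3), "persistent",
                                 rep("transient", 3)))
  dpd <- decay_profile(call_clusters(dec, 20000, 3), dec)
  expect_true(all(diff(dpd$mean_signal) < 0))

  # cluster without a persistent member is skipped
  nop <- peak_set("chr1", centers - 100, centers + 99,
                  signal = 1:7, site_class = rep("transient", 7))
  dpn <- decay_profile(call_clusters(nop, 20000, 3), nop)
  expect_equal(attr(dpn, "n_skipped"), 1L)
  expect_equal(nrow(dpn), 0L)
})

test_that("decay profile recovers a planted factor 0.7 within 0.05 at 200 clusters", {
  set.seed(91)
  rows <- list()
  for (i in 1:200) {
    origin <- 1e5 + (i - 1) * 2e5
    centers <- origin + seq(0, by = 5000, length.out = 9)
    b <- rlnorm(1, log(50), 0.5)
    bin <- ceiling(abs(seq_len(9) - 5) / 2)
    sig <- b * 0.7^bin * exp(rnorm(9, 0, 0.1))
    rows[[i]] <- data.frame(center = centers, signal = sig,
                            class = ifelse(seq_len(9) == 5, "persistent",
                                           "transient"))
  }
  df <- do.call(rbind, rows)
  pk <- peak_set("chr1", df$center - 100, df$center + 99,
                 signal = df$signal, site_class = df$class)
  cc <- call_clusters(pk, 20000, 3)
  dp <- decay_profile(cc, pk)
  ratios <- exp(diff(log(dp$mean_signal[dp$bin <= 2])))
  est <- exp(mean(log(ratios)))
  expect_lt(abs(est - 0.7), 0.05)
})
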