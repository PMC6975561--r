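test_that("desert normalization reduces to raw/c for constant desert rows", {
  set.seed(151)
  counts <- matrix(rpois(36, 100), 6, 6)
  counts[, 5:6] <- 40  # every desert interaction equals c = 40
  counts[5:6, ] <- 40
  fm <- toy_fivec(counts, nd = 2L)
  nc <- normalize_5c(fm)
  expect_equal(nc$values[1:4, 1:4], counts[1:4, 1:4] / 40,
               ignore_attr = TRUE)
  # desert-desert cells are excluded from the output
  expect_true(all(is.na(nc$values[5:6, 5:6])))
  # scale equivariance: k * raw leaves cell ratios unchanged
  nck <- normalize_5c(toy_fivec(counts * 7, nd = 2L))
  r1 <- nc$values[1, 1] / nc$values[2, 3]
  r2 <- nck$values[1, 1] / nck$values[2, 3]
  expect_equal(r1, r2)
  # primer with zero desert coverage is dropped with a warning
  bad <- counts
  bad[3, 5:6] <- 0
  expect_warning(ncb <- normalize_5c(toy_fivec(bad, nd = 2L)),
                 "zero desert coverage")
  expect_false("F03" %in% rownames(ncb$values))
})

test_that("normalization removes planted per-primer biases within 5% at mean 200", {
  set.seed(161)
  nf <- 40L; nr <- 40L; nd <- 10L
  eF <- rlnorm(nf + nd, 0, 0.3)
  eR <- rlnorm(nr + nd, 0, 0.3)
  truth <- 200
  mu <- truth * outer(eF, eR)
  counts <- matrix(rpois(length(mu), mu), nf + nd, nr + nd)
  fm <- toy_fivec(counts, nd = nd)
  nc <- normalize_5c(fm)
  vals <- nc$values[1:nf, 1:nr]
  # systematic per-primer residual bias (Poisson shot noise averaged out
  # over the 40 partners) is under 5% for every primer
  row_bias <- rowMeans(vals) / median(rowMeans(vals))
  col_bias <- colMeans(vals) / median(colMeans(vals))
  expect_lt(mean(abs(row_bias - 1)), 0.05)
  expect_lt(mean(abs(col_bias - 1)), 0.05)
  expect_lt(max(abs(row_bias - 1)), 0.10)
  expect_lt(max(abs(col_bias - 1)), 0.10)
  # per-cell error is bounded by shot noise at mean 200 (~5% median)
  expect_lt(median(abs(vals / median(vals) - 1)), 0.075)
  # per-primer efficiency factors recovered proportionally
  fhat <- nc$factor_forward[1:nf]
  expect_gt(cor(fhat, eF[1:nf]), 0.95)
  # without normalization the planted biases are far larger
  raw_bias <- rowMeans(counts[1:nf, 1:nr]) /
    median(rowMeans(counts[1:nf, 1:nr]))
  expect_gt(max(abs(raw_bias - 1)), 0.3)
})

test_that("replicate libraries with different efficiencies correlate > 0.95 after normalization", {
  ps <- simulate_peakscape(small_config(), seed = 7L)
  ct <- simulate_contacts(ps, small_config(), seed = 7L)
  for (cond in c("ici", "e2")) {
    n1 <- normalize_5c(ct$fivec[[cond]][[1]])
    n2 <- normalize_5c(ct$fivec[[cond]][[2]])
    v1 <- n1$values[!is.na(n1$values)]
    v2 <- n2$values[!is.na(n2$values)]
    expect_gt(cor(v1, v2, method = "pearson"), 0.95)
  }
})

test_that("contact binning is additive, mass-conserving, and matches brute force", {
  set.seed(171)
  counts <- matrix(rpois(22 * 22, 150), 22, 22)
  fm <- toy_fivec(counts, nd = 2L)
  nc <- normalize_5c(fm)
  # 4 disjoint regions covering primers 1..20 on chr21
  regions <- GRanges("chr21", IRanges(c(1, 60001, 120001, 180001),
                                      c(60000, 120000, 180000, 240000)))
  mcols(regions)$name <- paste0("r", 1:4)
  bc <- bin_contacts(nc, regions)
  # brute-force double loop
  fgr <- GRanges(nc$forward$chrom, IRanges(nc$forward$start,
                                           nc$forward$end))
  rgr <- GRanges(nc$reverse$chrom, IRanges(nc$reverse$start,
                                           nc$reverse$end))
  fa <- findOverlaps(fgr, regions, select = "first")
  ra <- findOverlaps(rgr, regions, select = "first")
  brute <- matrix(0, 4, 4)
  for (i in seq_along(fa)) {
    for (j in seq_along(ra)) {
      if (is.na(fa[i]) || is.na(ra[j])) next
      brute[fa[i], ra[j]] <- brute[fa[i], ra[j]] + nc$values[i, j]
    }
  }
  expect_equal(unname(bc$matrix), brute)
  # mass conservation over assigned primers
  assigned <- sum(nc$values[!is.na(fa), !is.na(ra)], na.rm = TRUE)
  expect_equal(sum(bc$matrix), assigned)
  # desert primers on chr16 fall in no region
  expect_true(all(grepl("F2[12]", bc$leftover_forward)))
  # merging two regions adds their binned values
  merged <- GRanges("chr21", IRanges(c(1, 120001), c(120000, 240000)))
  mcols(merged)$name <- c("m1", "m2")
  bm <- bin_contacts(nc, merged)
  expect_equal(bm$matrix["m1", "m1"],
               sum(bc$matrix[1:2, 1:2]))
  expect_error(bin_contacts(nc, c(regions, regions[1])), "non-overlapping")
})

test_that("planted intra-cluster contact boost is detected and absent when zero", {
  ps <- simulate_peakscape(small_config(), seed = 11L)
  for (boost in c(0, 2)) {
    ct <- simulate_contacts(ps, small_config(ldec_boost = boost),
                            seed = 11L)
    vals <- list()
    for (cond in c("ici", "e2")) {
      nc <- normalize_5c(ct$fivec[[cond]][[1]])
      bc <- bin_contacts(nc, ct$regions)
      vals[[cond]] <- diag(bc$matrix)  # intra-cluster contacts
    }
    p <- compare_groups(list(ici = vals$ici, e2 = vals$e2),
                        paired = TRUE)$p_value
    if (boost == 0) expect_gt(p, 0.05) else expect_lt(p, 0.05)
    if (boost > 0) expect_gt(median(vals$e2 / vals$ici), 1.5)
  }
})

test_that("replicate merge matches the brute-force both-end overlap rule", {
  mk <- function(s1, s2, chrom = "chr1", w = 1000L) {
    data.frame(chrom1 = chrom, start1 = s1, end1 = s1 + w - 1L,
               chrom2 = chrom, start2 = s2, end2 = s2 + w - 1L,
               stringsAsFactors = FALSE)
  }
  r1 <- mk(c(1000, 50000, 90000), c(200000, 260000, 320000))
  identical_merge <- merge_chiapet_replicates(list(r1, r1, r1))
  expect_equal(nrow(identical_merge), 3L)
  expect_true(all(identical_merge$support == 3L))
  empty <- r1[0, ]
  expect_equal(nrow(merge_chiapet_replicates(list(r1, empty, r1))), 0L)

  set.seed(181)
  base <- mk(seq(10000, by = 40000, length.out = 12) +
               round(runif(12, -2000, 2000)),
             seq(600000, by = 40000, length.out = 12) +
               round(runif(12, -2000, 2000)))
  jit <- function(df) {
    for (col in c("start1", "end1")) df[[col]] <- df[[col]] +
        round(runif(nrow(df), -400, 400))
    for (col in c("start2", "end2")) df[[col]] <- df[[col]] +
        round(runif(nrow(df), -400, 400))
    df
  }
  reps <- list(jit(base[1:10, ]), jit(base[3:12, ]), jit(base[c(1:6, 9:12), ]))
  cons <- merge_chiapet_replicates(reps)
  # brute force: a rep-1 pair is supported iff both ends overlap some pair
  # in every other replicate (either anchor order)
  ov <- function(s1, e1, s2, e2) min(e1, e2) - max(s1, s2) + 1L >= 1L
  supported <- vapply(seq_len(nrow(reps[[1]])), function(i) {
    all(vapply(2:3, function(r) {
      any(vapply(seq_len(nrow(reps[[r]])), function(j) {
        a <- reps[[1]][i, ]; b <- reps[[r]][j, ]
        straight <- ov(a$start1, a$end1, b$start1, b$end1) &&
          ov(a$start2, a$end2, b$start2, b$end2)
        crossed <- ov(a$start1, a$end1, b$start2, b$end2) &&
          ov(a$start2, a$end2, b$start1, b$end1)
        straight || crossed
      }, NA))
    }, NA))
  }, NA)
  # every supported rep-1 pair has a consensus entry overlapping both ends
  for (i in which(supported)) {
    a <- reps[[1]][i, ]
    hit <- any(vapply(seq_len(nrow(cons)), function(k) {
      b <- cons[k, ]
      ov(a$start1, a$end1, b$start1, b$end1) &&
        ov(a$start2, a$end2, b$start2, b$end2)
    }, NA))
    expect_true(hit)
  }
  expect_equal(nrow(cons), sum(supported))

  # idempotence and replicate-order symmetry (up to both-end overlap)
  again <- merge_chiapet_replicates(list(cons, cons))
  expect_equal(again[, 1:6], cons[, 1:6], ignore_attr = TRUE)
  perm <- merge_chiapet_replicates(reps[c(2, 3, 1)])
  expect_equal(nrow(perm), nrow(cons))
})

test_that("interaction degree counts distinct pairs per site and orders classes", {
  sites <- peak_set("chr1", c(1000, 5e5), c(2000, 5e5 + 1000),
                    name = c("hub", "lone"),
                    site_class = c("persistent", "transient"))
  star <- data.frame(chrom1 = "chr1", start1 = 1200, end1 = 1800,
                     chrom2 = "chr1", start2 = seq(1e5, 5e4 * 6, by = 5e4),
                     end2 = seq(1e5, 5e4 * 6, by = 5e4) + 999)
  deg <- interaction_degree(star, sites)
  expect_equal(deg$degree[deg$name == "hub"], 5L)
  expect_equal(deg$degree[deg$name == "lone"], 0L)

  ps <- simulate_peakscape(small_config(), seed = 13L)
  ct <- simulate_contacts(ps, small_config(), seed = 13L)
  cons <- merge_chiapet_replicates(ct$chiapet)
  dt <- interaction_degree(cons, ct$sites)
  med <- tapply(dt$degree, dt$site_class, median)
  expect_gt(med["persistent"], med["transient"])
  p <- compare_groups(split(dt$degree, dt$site_class))$p_value
  expect_lt(p, 0.01)
})

test_that("entropy group comparison detects planted drops and nothing else", {
  flat <- data.frame(entropy_minus = rep(5, 60), entropy_plus = rep(5, 60),
                     has_ldec = rep(c(TRUE, FALSE), 30),
                     has_peak = TRUE)
  ef <- entropy_group_compare(flat)
  expect_true(all(ef$drop == 0))
  expect_false(any(ef$tests$p_minusE2 < 0.05, na.rm = TRUE))

  set.seed(191)
  n <- 200
  has_ldec <- rep(c(TRUE, FALSE), each = n / 2)
  bins <- data.frame(
    entropy_minus = rnorm(n, 6, 0.3),
    entropy_plus = rnorm(n, 6, 0.3) - ifelse(has_ldec, 0.8, 0.1),
    has_ldec = has_ldec, has_peak = TRUE)
  eg <- entropy_group_compare(bins)
  row <- eg$tests[eg$tests$group1 == "LDEC" | eg$tests$group2 == "LDEC", ]
  expect_lt(row$p_plusE2, 0.01)
  expect_lt(row$p_drop, 0.01)
  # permuting the labels abolishes the effect
  perm <- bins
  perm$has_ldec <- sample(perm$has_ldec)
  ep <- entropy_group_compare(perm)
  expect_gt(min(ep$tests$p_drop), 0.05)
  # bins with missing entropy are excluded and counted
  bins$entropy_plus[1:3] <- NA
  expect_equal(entropy_group_compare(bins)$n_excluded, 3L)
})
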