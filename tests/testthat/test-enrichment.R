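gr_iv <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand)
}

test_that("percent overlap counts covered bases once per class", {
  clusters <- gr_iv("chr1", 1, 1000)
  feats <- c(gr_iv("chr1", 1, 400), gr_iv("chr1", 301, 500),
             gr_iv("chr1", 2001, 3000))
  feats$feature_class <- c("TE", "TE", "TE")
  # union of the first two features covers 1..500 = 50%; the third is
  # outside the cluster and the overlap region must not double-count
  expect_equal(unname(percent_overlap(clusters, feats)), 50)
  # two classes computed independently
  feats2 <- c(gr_iv("chr1", 1, 400), gr_iv("chr1", 1, 400))
  feats2$feature_class <- c("TE", "gene")
  po <- percent_overlap(clusters, feats2)
  expect_equal(unname(po[c("TE", "gene")]), c(40, 40))
  expect_error(percent_overlap(gr_iv("chr1", 1, 0)[0], feats), "zero")
})

test_that("percent overlap matches a per-base bitmap oracle", {
  set.seed(23)
  cl_len <- 30000
  s <- sample.int(cl_len - 900, 12)
  clusters <- GenomicRanges::reduce(gr_iv("chr1", s, s + 700))
  fs <- sample.int(cl_len - 300, 40)
  feats <- gr_iv("chr1", fs, fs + sample.int(250, 40))
  feats$feature_class <- sample(c("x", "y"), 40, TRUE)
  po <- percent_overlap(clusters, feats)
  for (cls in c("x", "y")) {
    bitmap <- logical(cl_len)
    f <- feats[feats$feature_class == cls]
    for (i in seq_along(f))
      bitmap[GenomicRanges::start(f)[i]:GenomicRanges::end(f)[i]] <- TRUE
    covered <- 0L
    for (i in seq_along(clusters))
      covered <- covered + sum(bitmap[GenomicRanges::start(clusters)[i]:
                                        GenomicRanges::end(clusters)[i]])
    expect_equal(unname(po[[cls]]),
                 100 * covered / sum(IRanges::width(clusters)))
  }
})

test_that("overlap is invariant under splitting a feature into adjacent pieces", {
  clusters <- gr_iv("chr1", 101, 2100)
  whole <- gr_iv("chr1", 501, 1500)
  whole$feature_class <- "TE"
  parts <- c(gr_iv("chr1", 501, 900), gr_iv("chr1", 901, 1200),
             gr_iv("chr1", 1201, 1500))
  parts$feature_class <- "TE"
  expect_equal(percent_overlap(clusters, whole),
               percent_overlap(clusters, parts))
})

test_that("max_shift = 0 yields a flagged degenerate null", {
  clusters <- gr_iv("chr1", 1001, 2000)
  feats <- gr_iv("chr1", 1501, 2500)
  feats$feature_class <- "TE"
  res <- shuffle_null_test(clusters, feats, c(chr1 = 10000),
                           max_shift = 0, n_shuffles = 20, seed = 1)
  expect_equal(res$null_mean, res$observed_pct)
  expect_equal(res$null_sd, 0)
  expect_true(res$degenerate)
  expect_true(is.na(res$z))
})

test_that("shuffles preserve cluster length and respect chromosome bounds", {
  set.seed(3)
  s <- sample.int(30000, 8)
  clusters <- gr_iv("chr1", s, s + 999)
  for (i in 1:20) {
    sh <- pirnascape:::.shuffle_clusters(clusters, c(chr1 = 40000), 18000)
    expect_equal(IRanges::width(sh), IRanges::width(clusters))
    expect_true(all(GenomicRanges::start(sh) >= 1))
    expect_true(all(GenomicRanges::end(sh) <= 40000))
    expect_true(all(abs(GenomicRanges::start(sh) -
                          GenomicRanges::start(clusters)) <= 18000))
  }
  expect_error(
    pirnascape:::.shuffle_clusters(gr_iv("chr1", 1, 5000),
                                   c(chr1 = 3000), 100),
    "longer")
})

test_that("features planted inside clusters score z above 3", {
  g <- simulate_genome(c(chr1 = 300000, chr2 = 200000), seed = 51)
  set.seed(52)
  s <- sort(sample.int(250000, 12))
  clusters <- GenomicRanges::reduce(gr_iv("chr1", s, s + 4000))
  feats <- simulate_features(g, "planted", n_per_class = 30,
                             feature_length = 400, inside = clusters,
                             seed = 53)
  res <- shuffle_null_test(clusters, feats, g$chrom_lengths, seed = 54)
  expect_gt(res$z, 3)
})

test_that("independent placement keeps z near zero (calibration)", {
  g <- simulate_genome(c(chr1 = 300000, chr2 = 200000), seed = 61)
  zs <- numeric(0)
  for (seed in 1:8) {
    set.seed(1000 + seed)
    s <- sort(sample.int(250000, 10))
    clusters <- GenomicRanges::reduce(gr_iv("chr1", s, s + 3000))
    feats <- simulate_features(g, c("a", "b"), n_per_class = 25,
                               feature_length = 500, seed = 2000 + seed)
    res <- shuffle_null_test(clusters, feats, g$chrom_lengths,
                             seed = 3000 + seed)
    zs <- c(zs, res$z[!is.na(res$z)])
  }
  expect_gte(mean(abs(zs) < 3), 0.9)
})

test_that("bootstrap CI is zero-width when replicates cannot vary", {
  # identical clusters: every omission subset has the same overlap
  clusters <- rep(gr_iv("chr1", 1001, 2000), 6)
  feats <- gr_iv("chr1", 1501, 2500)
  feats$feature_class <- "TE"
  ci <- bootstrap_ci(clusters, feats, seed = 1)
  expect_equal(ci$ci_low, ci$observed_pct)
  expect_equal(ci$ci_high, ci$observed_pct)
  # omit_fraction 0: all replicates equal the observed value
  het <- gr_iv("chr1", seq(1, by = 3000, length.out = 6),
               seq(1, by = 3000, length.out = 6) + c(500, 900, 1300,
                                                     1700, 2100, 2500))
  ci0 <- bootstrap_ci(het, feats, omit_fraction = 0, seed = 3)
  expect_equal(ci0$ci_low, ci0$observed_pct)
  expect_equal(ci0$ci_high, ci0$observed_pct)
  expect_error(bootstrap_ci(clusters[1:3], feats), "at least 5")
})

test_that("bootstrap CI covers the full-set observed value for heterogeneous clusters", {
  set.seed(9)
  covered <- 0L
  feats <- gr_iv("chr1", seq(1, 90000, by = 3000),
                 seq(1, 90000, by = 3000) + 800)
  feats$feature_class <- "TE"
  for (seed in 1:40) {
    set.seed(seed)
    s <- sample.int(90000, 10)
    clusters <- GenomicRanges::reduce(gr_iv("chr1", s, s + 1500))
    ci <- bootstrap_ci(clusters, feats, seed = 500 + seed)
    if (ci$ci_low <= ci$observed_pct && ci$observed_pct <= ci$ci_high)
      covered <- covered + 1L
  }
  expect_gte(covered / 40, 0.95)
})

test_that("enrichment_test merges CI and null columns, with optional BH", {
  g <- simulate_genome(c(chr1 = 100000), seed = 71)
  set.seed(72)
  s <- sample.int(80000, 8)
  clusters <- GenomicRanges::reduce(gr_iv("chr1", s, s + 2000))
  feats <- simulate_features(g, c("a", "b"), n_per_class = 15,
                             feature_length = 400, seed = 73)
  res <- enrichment_test(clusters, feats, g$chrom_lengths, seed = 74,
                         adjust = TRUE)
  expect_setequal(res$feature_class, c("a", "b"))
  expect_true(all(c("ci_low", "ci_high", "null_mean", "z", "p",
                    "p_adj") %in% names(res)))
  expect_true(all(res$p_adj >= res$p | is.na(res$p)))
})

test_that("per-gene scores use only fully enclosed windows", {
  genes <- gr_iv("chr1", 1, 1000)
  genes$gene_id <- "g1"
  windows <- c(gr_iv("chr1", 1, 100), gr_iv("chr1", 951, 1050))
  windows$score <- c(0.5, 9)
  out <- per_gene_score(windows, genes)
  expect_equal(out$mu_median, 0.5)
  expect_equal(out$n_windows, 1L)
  # median over {1,2,3}
  g2 <- gr_iv("chr1", 1, 1000); g2$gene_id <- "g"
  w2 <- gr_iv("chr1", c(1, 301, 601), c(100, 400, 700))
  w2$score <- c(1, 2, 3)
  expect_equal(per_gene_score(w2, g2)$mu_median, 2)
})

test_that("per-gene percentiles match a brute-force rank", {
  set.seed(13)
  n <- 100
  starts <- seq(1, by = 2000, length.out = n)
  genes <- gr_iv("chr1", starts, starts + 1500)
  genes$gene_id <- sprintf("g%03d", 1:n)
  # one enclosed window per gene with a known planted score
  planted <- runif(n)
  windows <- gr_iv("chr1", starts + 100, starts + 400)
  windows$score <- planted
  out <- per_gene_score(windows, genes)
  expect_equal(length(attr(out, "unscored")), 0L)
  expect_equal(out$gene_id[which.max(out$percentile)],
               genes$gene_id[which.max(planted)])
  expect_equal(max(out$percentile), 100)
  expect_equal(out$percentile,
               100 * rank(planted, ties.method = "average") / n)
  # a gene with no enclosed window is reported unscored
  g_extra <- gr_iv("chr1", 500001, 500100)
  g_extra$gene_id <- "lonely"
  out2 <- per_gene_score(windows, c(genes, g_extra))
  expect_equal(attr(out2, "unscored"), "lonely")
})
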