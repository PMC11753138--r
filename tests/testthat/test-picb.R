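gr_aln <- function(chrom, start, end, strand = "+",
                   category = "unique") {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                              strand = strand)
  g$read_id <- sprintf("r%05d", seq_along(g))
  g$category <- category
  g$n_hits <- ifelse(category == "unique", 1L, 2L)
  g
}

test_that("sliding windows tile, step and clip as specified", {
  w <- sliding_windows(1000, 350, 35)
  expect_equal(length(w), 29L)
  expect_equal(c(IRanges::start(w)[1], IRanges::end(w)[1]), c(1, 350))
  expect_equal(c(IRanges::start(w)[2], IRanges::end(w)[2]), c(36, 385))
  expect_true(all(IRanges::end(w) <= 1000))
  # short chromosome: all windows clipped
  w2 <- sliding_windows(100, 350, 35)
  expect_equal(as.data.frame(w2)[, 1:2],
               data.frame(start = c(1, 36, 71), end = c(100, 100, 100)))
  # degenerate tiling
  w3 <- sliding_windows(350, 350, 350)
  expect_equal(length(w3), 1L)
  expect_equal(IRanges::width(w3), 350L)
  expect_error(sliding_windows(0, 350, 35), "positive")
})

test_that("window FPKM follows reads/kb/million", {
  expect_equal(window_fpkm(7, 350, 1e6), 20)
  expect_equal(window_fpkm(0, 350, 1e6), 0)
  expect_equal(window_fpkm(1, 1000, 5e6), 0.2)
  expect_error(window_fpkm(1, 1000, 0), "library_size")
})

test_that("anchors with no passing window survive a stage unchanged", {
  cl <- c(chr1 = 10000)
  anchors <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000),
                                    strand = "+")
  p <- stage_params(350, 35, 4, strict = TRUE, anchor_required = TRUE)
  out <- call_stage(GenomicRanges::GRanges(), anchors, p, cl, 1000)
  expect_equal(GenomicRanges::start(out), 1L)
  expect_equal(GenomicRanges::end(out), 1000L)
  # and with no anchors at all, a seed stage returns nothing
  p0 <- stage_params(350, 35, 2, min_length = 800)
  out0 <- call_stage(GenomicRanges::GRanges(), GenomicRanges::GRanges(),
                     p0, cl, 1000)
  expect_equal(length(out0), 0L)
})

test_that("a dense read run produces the seed the naive recount predicts", {
  # 30 reads of 28 nt tiling positions 1001..2027 (0-based 1000..2027)
  starts <- seq(1001, by = 35, length.out = 30)
  aln <- gr_aln("chr1", starts, starts + 27)
  cl <- c(chr1 = 10000)
  p <- stage_params(350, 35, 2, min_length = 800)
  out <- call_stage(aln, GenomicRanges::GRanges(), p, cl, 1e6)
  oracle <- naive_stage(
    data.frame(chrom = "chr1", start = starts, end = starts + 27),
    data.frame(chrom = character(0), start = integer(0),
               end = integer(0)),
    cl, 350, 35, 2, FALSE, 800, FALSE, 1e6, "+")
  expect_same_intervals(out, oracle)
  expect_equal(length(out), 1L)
})

test_that("a library of only unique reads can still yield a cluster", {
  # one dense 2 kb region of uniquely mapping reads, no multimappers
  starts <- seq(5001, by = 20, length.out = 100)
  aln <- gr_aln("chr1", starts, starts + 27)
  lib <- pirna_library(aln, c(chr1 = 20000))
  cs <- run_picb(lib)
  expect_equal(length(cs$clusters), 1L)
  expect_equal(length(cs$seeds), 1L)
  # the cluster contains its seed
  expect_true(IRanges::start(cs$clusters) <= IRanges::start(cs$seeds))
  expect_true(IRanges::end(cs$clusters) >= IRanges::end(cs$seeds))
})

test_that("run_picb equals the naive full-scan oracle on random libraries", {
  for (seed in 1:4) {
    sim <- small_sim(seed, n_reads = 600,
                     chrom_lengths = c(chr1 = 30000, chr2 = 15000))
    cs <- run_picb(sim$library)
    oracle <- naive_picb(sim$library)
    expect_same_intervals(cs$seeds, oracle$seeds)
    expect_same_intervals(cs$cores, oracle$cores)
    expect_same_intervals(cs$clusters, oracle$clusters)
  }
})

test_that("tiers nest: seed bases <= core bases <= cluster bases", {
  for (seed in 5:8) {
    sim <- small_sim(seed, n_reads = 700)
    cs <- run_picb(sim$library)
    sb <- sum(IRanges::width(cs$seeds))
    cb <- sum(IRanges::width(cs$cores))
    kb <- sum(IRanges::width(cs$clusters))
    expect_lte(sb, cb)
    expect_lte(cb, kb)
  }
})

test_that("strands are called independently", {
  sim <- small_sim(21)
  lib <- sim$library
  plus_before <- run_picb(lib)$clusters
  plus_before <- plus_before[GenomicRanges::strand(plus_before) == "+"]
  # permute minus-strand reads: reverse their order of start positions
  aln <- lib$alignments
  neg <- which(as.character(GenomicRanges::strand(aln)) == "-")
  set.seed(99)
  drop <- sample(neg, length(neg) %/% 2)
  lib2 <- lib
  lib2$alignments <- aln[-drop]
  lib2$library_size <- lib$library_size  # keep normalisation fixed
  plus_after <- run_picb(lib2)$clusters
  plus_after <- plus_after[GenomicRanges::strand(plus_after) == "+"]
  expect_equal(as.data.frame(plus_after)[, 1:5],
               as.data.frame(plus_before)[, 1:5])
})

test_that("raising any threshold never adds clusters or bases", {
  # count monotonicity is asserted for the FPKM knobs; raising the
  # minimum seed length can split a merged cluster by deleting a short
  # bridging seed, so there only base monotonicity and refinement
  # (containment in a looser cluster) are guaranteed
  for (seed in 9:12) {
    sim <- small_sim(seed, n_reads = 700)
    base <- run_picb(sim$library)
    n0 <- length(base$clusters)
    b0 <- sum(IRanges::width(base$clusters))
    variants <- list(picb_params(seed_fpkm = 4),
                     picb_params(core_fpkm = 8),
                     picb_params(cluster_fpkm = 0.4))
    for (p in variants) {
      cs <- run_picb(sim$library, p)
      expect_lte(length(cs$clusters), n0)
      expect_lte(sum(IRanges::width(cs$clusters)), b0)
    }
    cs <- run_picb(sim$library, picb_params(min_seed_length = 1600))
    expect_lte(sum(IRanges::width(cs$clusters)), b0)
    expect_true(all(GenomicRanges::countOverlaps(cs$clusters,
                                                 base$clusters,
                                                 type = "within") >= 1))
  }
})

test_that("identical input produces byte-identical BED output", {
  sim <- small_sim(31)
  f1 <- tempfile(fileext = ".bed"); f2 <- tempfile(fileext = ".bed")
  write_bed(run_picb(sim$library)$clusters, f1)
  write_bed(run_picb(sim$library)$clusters, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("cluster intersection is strand-aware and symmetric", {
  a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000), "+")
  b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(501, 1500), "+")
  r <- combine_cluster_sets(a, b)
  expect_equal(GenomicRanges::start(r$shared), 501L)
  expect_equal(GenomicRanges::end(r$shared), 1000L)
  expect_equal(length(r$only_a), 0L)
  expect_equal(length(r$only_b), 0L)
  # opposite strands never share
  b2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000), "-")
  r2 <- combine_cluster_sets(a, b2)
  expect_equal(length(r2$shared), 0L)
  expect_equal(length(r2$only_a), 1L)
  expect_equal(length(r2$only_b), 1L)
  # disjoint chromosome namespaces error
  c2 <- GenomicRanges::GRanges("scaffold_9", IRanges::IRanges(1, 100), "+")
  expect_error(combine_cluster_sets(a, c2), "scaffold_9")
})

test_that("multi-set intersections match a brute-force pairwise sweep", {
  set.seed(7)
  mk <- function(n) {
    s <- sort(sample.int(50000, n))
    GenomicRanges::GRanges("chr1", IRanges::IRanges(s, s + 800),
                           sample(c("+", "-"), n, TRUE))
  }
  a <- GenomicRanges::reduce(mk(20)); b <- GenomicRanges::reduce(mk(20))
  r <- combine_cluster_sets(a, b)
  # brute force: overlap of every (a, b) pair on the same strand
  brute_shared <- 0L
  for (i in seq_along(a)) for (j in seq_along(b)) {
    if (as.character(GenomicRanges::strand(a))[i] !=
        as.character(GenomicRanges::strand(b))[j]) next
    lo <- max(GenomicRanges::start(a)[i], GenomicRanges::start(b)[j])
    hi <- min(GenomicRanges::end(a)[i], GenomicRanges::end(b)[j])
    if (hi >= lo) brute_shared <- brute_shared + (hi - lo + 1L)
  }
  expect_equal(sum(IRanges::width(r$shared)), brute_shared)
  brute_only_a <- sum(vapply(seq_along(a), function(i) {
    !any(vapply(seq_along(b), function(j)
      as.character(GenomicRanges::strand(a))[i] ==
        as.character(GenomicRanges::strand(b))[j] &&
        GenomicRanges::start(a)[i] <= GenomicRanges::end(b)[j] &&
        GenomicRanges::end(a)[i] >= GenomicRanges::start(b)[j],
      logical(1)))
  }, logical(1)))
  expect_equal(length(r$only_a), brute_only_a)
})

test_that("cluster statistics follow the pseudocount and assignment rules", {
  clusters <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000), "+")
  aln <- gr_aln("chr1", seq(10, by = 50, length.out = 10),
                seq(10, by = 50, length.out = 10) + 27)
  lib <- pirna_library(aln, c(chr1 = 2000))
  st <- cluster_statistics(clusters, lib)
  pc <- st$per_cluster
  expect_equal(pc$read_count, 10L)
  expect_equal(pc$sense_antisense_ratio, (10 + 1) / (0 + 1))
  expect_true(pc$dual_strand)          # 11 < 100-fold
  expect_false(cluster_statistics(clusters, lib,
                                  fold_threshold = 10)$per_cluster$dual_strand)
  # every read inside clusters -> explained fraction 1
  expect_equal(st$summary$explained_fraction, 1)
  expect_equal(pc$productivity, 1)
})

test_that("explained fraction recovers the planted in-cluster share", {
  g <- simulate_genome(c(chr1 = 200000), seed = 41)
  cl <- data.frame(chrom = "chr1",
                   start = c(10001, 60001, 120001),
                   end = c(14000, 64000, 124000),
                   strand = c("+", "+", "-"),
                   n_reads = c(500, 400, 500))
  sim <- simulate_pirna_library(g, cl, background_rate = 3, seed = 42)
  lib <- sim$library
  planted <- GenomicRanges::GRanges(cl$chrom,
                                    IRanges::IRanges(cl$start, cl$end),
                                    cl$strand)
  st <- cluster_statistics(planted, lib)
  in_cluster <- sum(sim$truth$clusters$reads_planted)
  expected <- in_cluster / lib$library_size
  # binomial-scale slack around the planted proportion
  expect_lt(abs(st$summary$explained_fraction - expected), 0.03)
})
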