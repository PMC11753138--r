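# Independent naive reference implementations used as test oracles.
# Deliberately written in plain base R over data.frames, materialising
# every window and recounting by full scan, so they share no code path
# with the package functions they check.

# intervals as data.frame(chrom, start, end, strand), 1-based closed

.gr_to_df <- function(gr) {
  if (length(gr) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)))
  df[order(df$chrom, df$start, df$end, df$strand), , drop = FALSE]
}

# merge overlapping or book-ended intervals of one chromosome by scan
naive_merge <- function(starts, ends) {
  if (length(starts) == 0) return(list(start = integer(0), end = integer(0)))
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me + 1) {       # overlap or book-ended
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

# one stage on one chromosome and strand
naive_stage_chrom <- function(aln_s, aln_e, anc_s, anc_e, chrom_len,
                              size, step, thr, strict, min_len,
                              anchor_required, library_size) {
  win_s <- seq(1, chrom_len, by = step)
  win_e <- pmin(win_s + size - 1, chrom_len)
  called_s <- integer(0); called_e <- integer(0)
  for (w in seq_along(win_s)) {
    cnt <- 0
    for (a in seq_along(aln_s))
      if (aln_s[a] <= win_e[w] && aln_e[a] >= win_s[w]) cnt <- cnt + 1
    fpkm <- cnt * 1e9 / ((win_e[w] - win_s[w] + 1) * library_size)
    pass <- if (strict) fpkm > thr else fpkm >= thr
    if (pass) { called_s <- c(called_s, win_s[w])
                called_e <- c(called_e, win_e[w]) }
  }
  m <- naive_merge(c(called_s, anc_s), c(called_e, anc_e))
  keep <- rep(TRUE, length(m$start))
  if (anchor_required) {
    for (i in seq_along(m$start)) {
      has <- FALSE
      for (j in seq_along(anc_s))
        if (anc_s[j] <= m$end[i] && anc_e[j] >= m$start[i]) has <- TRUE
      keep[i] <- has
    }
  }
  if (!is.null(min_len))
    keep <- keep & (m$end - m$start + 1 >= min_len)
  list(start = m$start[keep], end = m$end[keep])
}

naive_stage <- function(aln, anchors, chrom_lengths, size, step, thr,
                        strict, min_len, anchor_required, library_size,
                        strand) {
  out <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), strand = character(0))
  chroms <- sort(union(unique(aln$chrom), unique(anchors$chrom)))
  for (chr in chroms) {
    a <- aln[aln$chrom == chr, ]
    an <- anchors[anchors$chrom == chr, ]
    r <- naive_stage_chrom(a$start, a$end, an$start, an$end,
                           chrom_lengths[[chr]], size, step, thr, strict,
                           min_len, anchor_required, library_size)
    if (length(r$start))
      out <- rbind(out, data.frame(chrom = chr, start = r$start,
                                   end = r$end, strand = strand))
  }
  out
}

# full three-stage pipeline against a pirna_library
naive_picb <- function(library, params = picb_params()) {
  gr <- library$alignments
  aln <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    category = gr$category)
  cl <- library$chrom_lengths
  ls <- library$library_size
  tiers <- list(seeds = NULL, cores = NULL, clusters = NULL)
  for (tier in names(tiers)) tiers[[tier]] <-
    data.frame(chrom = character(0), start = integer(0),
               end = integer(0), strand = character(0))
  for (s in c("+", "-")) {
    a <- aln[aln$strand == s, ]
    p <- params$seed
    seeds <- naive_stage(a[a$category == "unique", ],
                         a[0, ], cl, p$window_size, p$window_step,
                         p$fpkm_threshold, p$strict, p$min_length,
                         p$anchor_required, ls, s)
    p <- params$core
    cores <- naive_stage(a[a$category == "primary_multi", ], seeds, cl,
                         p$window_size, p$window_step, p$fpkm_threshold,
                         p$strict, p$min_length, p$anchor_required, ls, s)
    p <- params$cluster
    clusters <- naive_stage(a[a$category == "secondary_multi", ], cores,
                            cl, p$window_size, p$window_step,
                            p$fpkm_threshold, p$strict, p$min_length,
                            p$anchor_required, ls, s)
    tiers$seeds <- rbind(tiers$seeds, seeds)
    tiers$cores <- rbind(tiers$cores, cores)
    tiers$clusters <- rbind(tiers$clusters, clusters)
  }
  lapply(tiers, function(d) {
    d <- d[order(d$chrom, d$start, d$end, d$strand), , drop = FALSE]
    rownames(d) <- NULL
    d
  })
}

expect_same_intervals <- function(gr, df) {
  got <- .gr_to_df(gr)
  rownames(got) <- NULL
  rownames(df) <- NULL
  expect_equal(got, df)
}
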