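#' Small-RNA length spectrum
#'
#' Tallies read counts per length over the 18-36 nt profile range, either
#' for all reads (uncollapsed) or counting each distinct sequence once
#' (collapsed, which removes abundance bias), together with the
#' 5'-nucleotide composition at each length.
#'
#' @param sequences character vector of read sequences (5'->3'), one entry
#'   per read (repeat entries for read multiplicity).
#' @param collapse count each distinct sequence once.
#' @param range lengths to profile; default `18:36`.
#' @return data.frame with columns `length`, `count` and per-base
#'   5'-nucleotide counts `A`, `C`, `G`, `U`.
#' @export
length_spectrum <- function(sequences, collapse = FALSE, range = 18:36) {
  sequences <- toupper(sequences)
  if (collapse) sequences <- unique(sequences)
  len <- nchar(sequences)
  keep <- len %in% range
  sequences <- sequences[keep]; len <- len[keep]
  first <- substr(sequences, 1, 1)
  first[first == "T"] <- "U"
  out <- data.frame(length = range, count = 0L,
                    A = 0L, C = 0L, G = 0L, U = 0L)
  if (length(sequences)) {
    tab <- table(factor(len, levels = range))
    out$count <- as.integer(tab)
    for (b in c("A", "C", "G", "U")) {
      tb <- table(factor(len[first == b], levels = range))
      out[[b]] <- as.integer(tb)
    }
  }
  out
}

#' Positional base-frequency matrix from 3'-trimmed reads
#'
#' Each (collapsed, unique) sequence is trimmed from the 3' end to
#' `trim_len` nucleotides, keeping the 5' end, and per-position base
#' frequencies are computed over the four ribonucleotides (T reported as
#' U). This is the matrix behind piRNA sequence logos, where the 1U bias
#' appears at position 1 and the ping-pong 10A signature at position 10.
#'
#' @param sequences character vector of unique sequences.
#' @param trim_len target length after 3' trimming; default 20.
#' @return 4 x `trim_len` numeric matrix (rows `A`, `C`, `G`, `U`); the
#'   number of too-short sequences excluded is attached as attribute
#'   `n_excluded`.
#' @export
base_frequency_matrix <- function(sequences, trim_len = 20) {
  sequences <- toupper(sequences)
  short <- nchar(sequences) < trim_len
  if (any(short))
    warning(sum(short), " sequence(s) shorter than ", trim_len,
            " nt excluded")
  sequences <- substr(sequences[!short], 1, trim_len)
  bases <- c("A", "C", "G", "U")
  m <- matrix(0, nrow = 4, ncol = trim_len,
              dimnames = list(bases, seq_len(trim_len)))
  if (length(sequences)) {
    chars <- matrix(unlist(strsplit(sequences, "")), ncol = trim_len,
                    byrow = TRUE)
    chars[chars == "T"] <- "U"
    for (j in seq_len(trim_len)) {
      tab <- table(factor(chars[, j], levels = bases))
      m[, j] <- as.numeric(tab) / length(sequences)
    }
  }
  attr(m, "n_excluded") <- sum(short)
  m
}

#' Ping-pong overlap signature
#'
#' For every plus-strand alignment with 5' end at p and minus-strand
#' alignment with 5' end at m on the same chromosome, the 5'-overlap is
#' `o = m - p + 1` nucleotides (in 0-based genomic coordinates; the
#' formula is evaluated equivalently on the 1-based closed intervals
#' used in memory). Pairs with `min_o <= o <= max_o` are counted per
#' offset, and `z10` summarises the excess at the characteristic 10 nt
#' ping-pong overlap as a z-score of the offset-10 count against the
#' offset-1..26 counts (sample sd).
#'
#' @param alignments stranded `GRanges` of alignment intervals.
#' @param min_o,max_o offset range; defaults 1 and 26.
#' @param exclude_self exclude offset 10 itself from the background mean
#'   and sd (the default background includes it, which is conservative).
#' @param collapse count unique (chrom, plus-5', minus-5') coordinate
#'   pairs rather than all alignment pairs.
#' @return list with `counts` (named vector over offsets) and `z10`
#'   (`NA` when the background sd is zero, with attribute `degenerate`).
#' @export
pingpong_signature <- function(alignments, min_o = 1, max_o = 26,
                               exclude_self = FALSE, collapse = FALSE) {
  offsets <- min_o:max_o
  counts <- setNames(numeric(length(offsets)), offsets)
  plus <- alignments[strand(alignments) == "+"]
  minus <- alignments[strand(alignments) == "-"]
  chroms <- intersect(unique(as.character(seqnames(plus))),
                      unique(as.character(seqnames(minus))))
  for (chr in chroms) {
    p5 <- start(plus[seqnames(plus) == chr])     # plus-strand 5' ends
    m5 <- end(minus[seqnames(minus) == chr])     # minus-strand 5' ends
    if (collapse) { p5 <- unique(p5); m5 <- unique(m5) }
    tp <- table(p5); tm <- table(m5)
    pos_p <- as.integer(names(tp))
    for (k in seq_along(offsets)) {
      o <- offsets[k]
      # pair (p, m) overlaps by o <=> m = p + o - 1
      target <- as.character(pos_p + o - 1L)
      hit <- target %in% names(tm)
      if (any(hit))
        counts[k] <- counts[k] +
          sum(as.numeric(tp[hit]) * as.numeric(tm[target[hit]]))
    }
  }
  bg <- if (exclude_self) counts[offsets != 10] else counts
  s <- sd(bg)
  z10 <- if (!("10" %in% names(counts))) NA_real_
  else if (is.na(s) || s == 0) {
    z <- NA_real_; attr(z, "degenerate") <- TRUE; z
  } else (counts[["10"]] - mean(bg)) / s
  list(counts = counts, z10 = z10)
}

#' Phasing distance histogram
#'
#' For each alignment, the nearest downstream alignment on the same
#' chromosome and strand whose 5' end lies at or beyond this alignment's
#' 3' end is identified (a follow, non-overlap semantics: downstream
#' reads starting before the upstream 3' end are skipped), and the
#' 3'-to-5' gap `d` is recorded; `d = 0` marks directly adjacent,
#' head-to-tail pairs, the hallmark of phased piRNA biogenesis.
#' Directions are mirrored on the minus strand.
#'
#' @param alignments stranded `GRanges`.
#' @param max_d largest gap tallied; default 100.
#' @return data.frame with columns `distance` (0..`max_d`) and `count`.
#' @export
phasing_histogram <- function(alignments, max_d = 100) {
  counts <- integer(max_d + 1)
  for (chr in unique(as.character(seqnames(alignments)))) {
    gr <- alignments[seqnames(alignments) == chr]
    # plus strand: upstream 3' = end; nearest downstream 5' = smallest
    # start >= end + 1; gap d = start - end - 1
    p <- gr[strand(gr) == "+"]
    if (length(p) > 1) {
      ss <- sort(unique(start(p)))
      idx <- findInterval(end(p), ss) + 1L     # first start > end
      ok <- idx <= length(ss)
      d <- ss[idx[ok]] - end(p)[ok] - 1L
      counts <- counts + tabulate(d[d <= max_d] + 1L, nbins = max_d + 1)
    }
    # minus strand: upstream 3' = start; nearest downstream 5' = largest
    # end <= start - 1; gap d = start - end - 1
    m <- gr[strand(gr) == "-"]
    if (length(m) > 1) {
      ee <- sort(unique(end(m)))
      idx <- findInterval(start(m) - 1L, ee)   # last end <= start - 1
      ok <- idx >= 1L
      d <- start(m)[ok] - ee[idx[ok]] - 1L
      counts <- counts + tabulate(d[d <= max_d] + 1L, nbins = max_d + 1)
    }
  }
  data.frame(distance = 0:max_d, count = counts)
}

#' Restrict a library to reads overlapping given regions
#'
#' Used to compute signatures on reads inside clusters or TE annotations;
#' `orientation` selects reads mapping sense or antisense relative to the
#' (stranded) regions, as used for TE-sense/antisense logo matrices.
#'
#' @param library a [pirna_library].
#' @param regions `GRanges`.
#' @param orientation `"any"`, `"sense"` or `"antisense"` relative to the
#'   region strand.
#' @return a [pirna_library] containing the overlapping records.
#' @export
subset_library <- function(library, regions,
                           orientation = c("any", "sense", "antisense")) {
  orientation <- match.arg(orientation)
  aln <- library$alignments
  hits <- findOverlaps(aln, regions, ignore.strand = TRUE)
  keep <- switch(orientation,
    any = unique(queryHits(hits)),
    sense = unique(queryHits(hits)[
      as.character(strand(aln)[queryHits(hits)]) ==
        as.character(strand(regions)[subjectHits(hits)])]),
    antisense = unique(queryHits(hits)[
      as.character(strand(aln)[queryHits(hits)]) !=
        as.character(strand(regions)[subjectHits(hits)])]))
  out <- library
  out$alignments <- aln[sort(keep)]
  out
}
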