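#' Simulate a genome with duplicated segments
#'
#' Random sequence at a stated GC fraction. Duplicated segments
#' (`repeats`) are copied verbatim to non-overlapping positions, creating
#' exact multi-mapping targets: a read falling entirely inside one copy
#' aligns equally well to every copy, which is how multimapping arises
#' structurally rather than by fabricating alignment records.
#'
#' @param chrom_lengths named vector of chromosome lengths (> 0).
#' @param gc GC fraction; default 0.41.
#' @param repeats `NULL` or data.frame with columns `length` and `copies`
#'   (one row per repeat unit).
#' @param seed optional RNG seed.
#' @return list of class `sim_genome`: `sequences` (`DNAStringSet`),
#'   `chrom_lengths`, `repeats` (`GRanges` of all copies with metadata
#'   `unit` and `copy`).
#' @export
simulate_genome <- function(chrom_lengths, gc = 0.41, repeats = NULL,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(chrom_lengths > 0), !is.null(names(chrom_lengths)))
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- lapply(chrom_lengths, function(n)
    sample(names(probs), n, replace = TRUE, prob = probs))
  rep_gr <- .empty_gr(chrom_lengths)
  if (!is.null(repeats) && nrow(repeats) > 0) {
    occupied <- .empty_gr(chrom_lengths)
    for (u in seq_len(nrow(repeats))) {
      len <- repeats$length[u]; k <- repeats$copies[u]
      if (all(chrom_lengths < len))
        stop("repeat segment longer than every chromosome")
      placed <- .empty_gr(chrom_lengths)
      guard <- 0
      while (length(placed) < k) {
        guard <- guard + 1
        if (guard > 10000) stop("cannot place repeat copies; genome too full")
        chr <- sample(names(chrom_lengths)[chrom_lengths >= len], 1)
        s <- sample.int(chrom_lengths[[chr]] - len + 1, 1)
        cand <- .with_levels(GRanges(chr, IRanges(s, s + len - 1)),
                             chrom_lengths)
        if (length(findOverlaps(cand, c(occupied, placed))) == 0)
          placed <- c(placed, cand)
      }
      placed <- sort(placed)
      # copy the first placement's bases into all other copies
      src_chr <- as.character(seqnames(placed))[1]
      src <- seqs[[src_chr]][start(placed)[1]:end(placed)[1]]
      for (i in seq_len(k)) {
        chr_i <- as.character(seqnames(placed))[i]
        seqs[[chr_i]][start(placed)[i]:end(placed)[i]] <- src
      }
      placed$unit <- u
      placed$copy <- seq_len(k)
      occupied <- c(occupied, placed)
      rep_gr <- c(rep_gr, placed)
    }
  }
  dna <- DNAStringSet(vapply(seqs, paste, character(1), collapse = ""))
  names(dna) <- names(chrom_lengths)
  structure(list(sequences = dna, chrom_lengths = chrom_lengths,
                 repeats = rep_gr),
            class = "sim_genome")
}

#' Write a simulated genome to FASTA and a chrom-sizes TSV
#' @param genome a `sim_genome`.
#' @param fasta_path,sizes_path output paths.
#' @export
write_sim_genome <- function(genome, fasta_path, sizes_path = NULL) {
  Biostrings::writeXStringSet(genome$sequences, fasta_path)
  if (!is.null(sizes_path))
    write.table(data.frame(names(genome$chrom_lengths),
                           genome$chrom_lengths),
                sizes_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(fasta_path)
}

# triangular length distribution over len_range peaked at mode
.draw_lengths <- function(n, mode, len_range = 24:35) {
  spread <- max(mode - min(len_range), max(len_range) - mode) + 1
  w <- spread + 1 - abs(len_range - mode)
  sample(len_range, n, replace = TRUE, prob = w / sum(w))
}

# fetch read sequence in read orientation and apply 1U/10A overrides
.read_sequences <- function(genome, gr, u1, a10) {
  sq <- character(length(gr))
  for (chr in unique(as.character(seqnames(gr)))) {
    idx <- which(as.character(seqnames(gr)) == chr)
    views <- substring(as.character(genome$sequences[[chr]]),
                       start(gr)[idx], end(gr)[idx])
    neg <- as.character(strand(gr)[idx]) == "-"
    if (any(neg))
      views[neg] <- as.character(
        reverseComplement(DNAStringSet(views[neg])))
    sq[idx] <- views
  }
  n <- length(sq)
  # override base 1 to U(T) with probability u1, else uniform non-T, so
  # the planted probability is exact at any n
  set1 <- runif(n) < u1
  substr(sq, 1, 1) <- ifelse(set1, "T", sample(c("A", "C", "G"), n,
                                               replace = TRUE))
  long <- nchar(sq) >= 10
  set10 <- runif(n) < a10 & long
  alt10 <- sample(c("C", "G", "T"), n, replace = TRUE)
  substr(sq, 10, 10) <- ifelse(set10, "A",
                               ifelse(long, alt10, substr(sq, 10, 10)))
  sq
}

# expand read intervals into alignment records, realising multimapping
# through the genome's duplicated segments
.make_records <- function(genome, gr, read_prefix = "r") {
  n <- length(gr)
  read_id <- sprintf("%s%06d", read_prefix, seq_len(n))
  reps <- genome$repeats
  recs <- gr
  mcols(recs) <- DataFrame(read_id = read_id, category = "unique",
                           n_hits = 1L,
                           sequence = if (!is.null(gr$sequence))
                             gr$sequence else NA_character_)
  if (length(reps) == 0) return(recs)
  within <- findOverlaps(gr, reps, type = "within")
  if (length(within) == 0) return(recs)
  qh <- queryHits(within); sh <- subjectHits(within)
  extra <- list()
  for (i in unique(qh)) {
    unit <- reps$unit[sh[qh == i][1]]
    copies <- reps[reps$unit == unit]
    home <- sh[qh == i][1]
    off <- start(gr)[i] - start(reps)[home]
    k <- length(copies)
    # homologous interval in every copy; one primary chosen uniformly
    locs <- GRanges(seqnames(copies),
                    IRanges(start(copies) + off,
                            start(copies) + off + width(gr)[i] - 1L),
                    strand = strand(gr)[i])
    prim <- sample.int(k, 1)
    cat_v <- rep("secondary_multi", k)
    cat_v[prim] <- "primary_multi"
    mcols(locs) <- DataFrame(read_id = read_id[i], category = cat_v,
                             n_hits = k,
                             sequence = mcols(recs)$sequence[i])
    extra[[length(extra) + 1]] <- .with_levels(locs,
                                               genome$chrom_lengths)
  }
  keep <- recs[-unique(qh)]
  out <- c(keep, do.call(c, extra))
  seqlevels(out) <- names(genome$chrom_lengths)
  sort(out)
}

#' Simulate a piRNA library with planted clusters and ground truth
#'
#' Plants strand-specific clusters of reads with configurable length
#' distributions (triangular, peaked at a 24-35 nt mode), 1U/10A base
#' biases (applied by overriding the first/tenth base, so the planted
#' probabilities are exact at any depth), optional exact-10-nt ping-pong
#' partners on the opposite strand, and optional phased head-to-tail read
#' trails. Reads falling inside duplicated genome segments become genuine
#' multimappers (one uniformly chosen primary alignment, the rest
#' secondary); background reads are scattered uniformly at a stated rate.
#'
#' @param genome a [simulate_genome] result.
#' @param clusters data.frame with columns `chrom`, `start`, `end`
#'   (1-based closed), `strand`, `n_reads`, and optionally `len_mode`
#'   (default 27), `u1` (default 0.25), `a10` (default 0.25),
#'   `pingpong_fraction` (default 0), `phased` (default `FALSE`).
#' @param background_rate background reads per kb of genome; default 0.
#' @param len_range allowed read lengths; default `24:35`.
#' @param with_sequence attach read sequences; default `TRUE`.
#' @param seed optional RNG seed.
#' @return list with `library` (a [pirna_library]) and `truth` (planted
#'   cluster table with realised read tallies, per-read cluster
#'   assignment, ping-pong pair count and the genome's repeat copies).
#' @export
simulate_pirna_library <- function(genome, clusters,
                                   background_rate = 0,
                                   len_range = 24:35,
                                   with_sequence = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(genome, "sim_genome"))
  def <- list(len_mode = 27, u1 = 0.25, a10 = 0.25,
              pingpong_fraction = 0, phased = FALSE)
  for (nm in names(def))
    if (is.null(clusters[[nm]])) clusters[[nm]] <- def[[nm]]
  bad <- clusters$end > genome$chrom_lengths[clusters$chrom] |
    clusters$start < 1
  if (any(bad)) stop("planted cluster outside the genome: row(s) ",
                     paste(which(bad), collapse = ", "))
  all_gr <- .empty_gr(genome$chrom_lengths)
  assignment <- integer(0)
  n_pp <- integer(nrow(clusters))
  max_len <- max(len_range)
  for (ci in seq_len(nrow(clusters))) {
    cl <- clusters[ci, ]
    n <- cl$n_reads
    if (n == 0) next
    lens <- .draw_lengths(n, cl$len_mode, len_range)
    if (isTRUE(cl$phased)) {
      # head-to-tail trails: each read's 5' end directly follows the
      # previous read's 3' end (gap 0)
      starts <- integer(n)
      cur <- NA_integer_
      for (i in seq_len(n)) {
        if (is.na(cur) || cur + lens[i] - 1 > cl$end) {
          lo <- cl$start
          hi <- max(lo, cl$end - 40 * mean(len_range))
          cur <- lo + sample.int(max(1, hi - lo + 1), 1) - 1
        }
        starts[i] <- cur
        cur <- cur + lens[i]
      }
      if (cl$strand == "+") {
        gr <- GRanges(cl$chrom, IRanges(starts, starts + lens - 1), "+")
      } else {
        # mirrored: trails run towards smaller coordinates
        ends <- cl$end - (starts - cl$start)
        gr <- GRanges(cl$chrom, IRanges(ends - lens + 1, ends), "-")
      }
    } else {
      if (cl$strand == "+") {
        hi <- max(cl$start, cl$end - max_len + 1)
        p5 <- cl$start + sample.int(hi - cl$start + 1, n, replace = TRUE) - 1
        gr <- GRanges(cl$chrom, IRanges(p5, p5 + lens - 1), "+")
      } else {
        lo <- min(cl$end, cl$start + max_len - 1)
        p5 <- lo + sample.int(cl$end - lo + 1, n, replace = TRUE) - 1
        gr <- GRanges(cl$chrom, IRanges(p5 - lens + 1, p5), "-")
      }
    }
    # clip reads protruding past the chromosome (rare at cluster edges)
    gr <- .clip_reads(gr, genome$chrom_lengths, min(len_range))
    k_pp <- round(cl$pingpong_fraction * length(gr))
    if (k_pp > 0) {
      pick <- sample.int(length(gr), k_pp)
      partners <- .pingpong_partners(gr[pick], len_range,
                                     genome$chrom_lengths)
      gr <- c(gr, partners)
      n_pp[ci] <- length(partners)
    }
    all_gr <- c(all_gr, gr)
    assignment <- c(assignment, rep(ci, length(gr)))
  }
  genome_kb <- sum(genome$chrom_lengths) / 1000
  n_bg <- if (background_rate > 0) rpois(1, background_rate * genome_kb)
  else 0L
  if (n_bg > 0) {
    chr_b <- sample(names(genome$chrom_lengths), n_bg, replace = TRUE,
                    prob = genome$chrom_lengths / sum(genome$chrom_lengths))
    lens <- .draw_lengths(n_bg, 27, len_range)
    s <- vapply(seq_len(n_bg), function(i)
      sample.int(genome$chrom_lengths[[chr_b[i]]] - lens[i] + 1, 1),
      integer(1))
    bg <- .with_levels(GRanges(chr_b, IRanges(s, s + lens - 1),
                               sample(c("+", "-"), n_bg, replace = TRUE)),
                       genome$chrom_lengths)
    all_gr <- c(all_gr, bg)
    assignment <- c(assignment, rep(0L, n_bg))
  }
  seqlevels(all_gr) <- names(genome$chrom_lengths)
  if (with_sequence && length(all_gr)) {
    u1v <- c(clusters$u1, 0.25)[ifelse(assignment == 0,
                                       nrow(clusters) + 1, assignment)]
    a10v <- c(clusters$a10, 0.25)[ifelse(assignment == 0,
                                         nrow(clusters) + 1, assignment)]
    # per-read override probabilities differ per cluster
    sq <- character(length(all_gr))
    for (p in unique(paste(u1v, a10v))) {
      idx <- which(paste(u1v, a10v) == p)
      sq[idx] <- .read_sequences(genome, all_gr[idx], u1v[idx][1],
                                 a10v[idx][1])
    }
    all_gr$sequence <- sq
  }
  ord <- order(as.integer(seqnames(all_gr)), start(all_gr))
  all_gr <- all_gr[ord]
  assignment <- assignment[ord]
  recs <- .make_records(genome, all_gr)
  lib <- pirna_library(recs, genome$chrom_lengths)
  per_cluster <- as.integer(tabulate(assignment, nbins = nrow(clusters)))
  truth <- list(clusters = cbind(clusters, reads_planted = per_cluster),
                assignment = assignment,
                n_pingpong_pairs = n_pp,
                n_background = n_bg,
                repeats = genome$repeats)
  list(library = lib, truth = truth)
}

.clip_reads <- function(gr, chrom_lengths, min_len) {
  lim <- chrom_lengths[as.character(seqnames(gr))]
  s <- pmax(start(gr), 1L)
  e <- pmin(end(gr), as.integer(lim))
  keep <- e - s + 1 >= min_len
  .with_levels(GRanges(as.character(seqnames(gr))[keep],
                       IRanges(s[keep], e[keep]),
                       strand(gr)[keep]),
               chrom_lengths)
}

.pingpong_partners <- function(gr, len_range, chrom_lengths) {
  n <- length(gr)
  lens <- .draw_lengths(n, 27, len_range)
  pos <- as.character(strand(gr)) == "+"
  # plus read 5' p -> minus partner 5' at p + 9; minus read 5' m ->
  # plus partner 5' at m - 9 (exact 10 nt 5' overlap both ways)
  p5 <- ifelse(pos, start(gr), end(gr))
  m5 <- ifelse(pos, p5 + 9L, p5 - 9L)
  s <- ifelse(pos, m5 - lens + 1L, m5)
  e <- ifelse(pos, m5, m5 + lens - 1L)
  out <- GRanges(as.character(seqnames(gr)), IRanges(pmax(s, 1L), e),
                 ifelse(pos, "-", "+"))
  .clip_reads(out, chrom_lengths, min(len_range))
}

#' Simulate a uniform random library (no planted structure)
#'
#' Reads placed uniformly over the genome on random strands, with
#' multimapping realised through the genome's duplicated segments. Used
#' for calibration and oracle-equivalence checks.
#'
#' @param genome a [simulate_genome] result.
#' @param n_reads number of reads.
#' @param len_range read lengths; default `24:35`.
#' @param seed optional RNG seed.
#' @return a [pirna_library].
#' @export
simulate_random_library <- function(genome, n_reads, len_range = 24:35,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chr <- sample(names(genome$chrom_lengths), n_reads, replace = TRUE,
                prob = genome$chrom_lengths / sum(genome$chrom_lengths))
  lens <- .draw_lengths(n_reads, 27, len_range)
  s <- vapply(seq_len(n_reads), function(i)
    sample.int(genome$chrom_lengths[[chr[i]]] - lens[i] + 1, 1),
    integer(1))
  gr <- GRanges(chr, IRanges(s, s + lens - 1),
                sample(c("+", "-"), n_reads, replace = TRUE))
  seqlevels(gr) <- names(genome$chrom_lengths)
  gr <- sort(gr)
  recs <- .make_records(genome, gr)
  pirna_library(recs, genome$chrom_lengths)
}

#' Simulate two-population biallelic TE-insertion genotypes
#'
#' Active families carry many recent insertions segregating at low
#' frequency within one population and absent from the other (high
#' within-population diversity relative to between-population
#' divergence, hence a high pi/D_xy ratio); inactive families carry
#' fewer, older insertions differentiated between the populations (low
#' ratio). Populations alternate as the host of activity.
#'
#' @param n_active,n_inactive numbers of families of each kind.
#' @param sites_active,sites_inactive polymorphic sites per family.
#' @param L genome length used as the diversity denominator.
#' @param seed optional RNG seed.
#' @return list with `sites` (data.frame as in [read_te_sites]) and
#'   `truth` (data.frame `family`, `active`).
#' @export
simulate_te_genotypes <- function(n_active = 3, n_inactive = 7,
                                  sites_active = 80, sites_inactive = 25,
                                  L = 1e6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list(); truth <- list()
  fam_id <- 0
  for (i in seq_len(n_active)) {
    fam_id <- fam_id + 1
    fam <- sprintf("ActiveFam-%d", i)
    q_host <- runif(sites_active, 0.05, 0.25)
    host_is_1 <- i %% 2 == 1
    rows[[fam_id]] <- data.frame(
      family = fam,
      site_id = sprintf("%s_s%03d", fam, seq_len(sites_active)),
      p_pop1 = if (host_is_1) 1 - q_host else rep(1, sites_active),
      p_pop2 = if (host_is_1) rep(1, sites_active) else 1 - q_host)
    truth[[fam_id]] <- data.frame(family = fam, active = TRUE)
  }
  for (i in seq_len(n_inactive)) {
    fam_id <- fam_id + 1
    fam <- sprintf("InactiveFam-%d", i)
    q1 <- runif(sites_inactive, 0.85, 1)
    q2 <- runif(sites_inactive, 0, 0.10)
    rows[[fam_id]] <- data.frame(
      family = fam,
      site_id = sprintf("%s_s%03d", fam, seq_len(sites_inactive)),
      p_pop1 = 1 - q1, p_pop2 = 1 - q2)
    truth[[fam_id]] <- data.frame(family = fam, active = FALSE)
  }
  list(sites = do.call(rbind, rows), truth = do.call(rbind, truth))
}

#' Plant annotation features, independent of or inside given regions
#'
#' @param genome a [simulate_genome] result.
#' @param classes character vector of feature class labels.
#' @param n_per_class features per class.
#' @param feature_length feature length in nt.
#' @param inside optional `GRanges`; when given, features are placed
#'   inside these regions (enriched placement) instead of uniformly.
#' @param seed optional RNG seed.
#' @return `GRanges` with `feature_class` and `name` metadata.
#' @export
simulate_features <- function(genome, classes, n_per_class = 20,
                              feature_length = 500, inside = NULL,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- .empty_gr(genome$chrom_lengths)
  for (cl in classes) {
    if (is.null(inside)) {
      chr <- sample(names(genome$chrom_lengths), n_per_class,
                    replace = TRUE,
                    prob = genome$chrom_lengths / sum(genome$chrom_lengths))
      s <- vapply(chr, function(ch)
        sample.int(max(1, genome$chrom_lengths[[ch]] - feature_length), 1),
        integer(1))
      g <- GRanges(chr, IRanges(s, s + feature_length - 1))
    } else {
      pick <- sample.int(length(inside), n_per_class, replace = TRUE)
      host <- inside[pick]
      room <- pmax(1L, width(host) - feature_length)
      off <- vapply(room, function(r) sample.int(r, 1), integer(1))
      s <- start(host) + off - 1L
      g <- GRanges(seqnames(host),
                   IRanges(s, pmin(s + feature_length - 1L, end(host))))
    }
    g$feature_class <- cl
    g$name <- sprintf("%s_%03d", cl, seq_len(n_per_class))
    out <- c(out, .with_levels(g, genome$chrom_lengths))
  }
  seqlevels(out) <- names(genome$chrom_lengths)
  out
}
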