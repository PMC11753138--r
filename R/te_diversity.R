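#' Within-population TE insertion diversity
#'
#' Nucleotide-diversity analogue over biallelic TE insertion sites:
#' `pi_TE = sum_i 2 p_i q_i / L`, where `p_i` is the reference-allele
#' frequency at site i, `q_i = 1 - p_i` the insertion-allele frequency,
#' and `L` the genome length. Fixed sites (p in {0, 1}) contribute
#' nothing; the statistic is invariant under swapping which allele is
#' called reference.
#'
#' @param p numeric vector of reference-allele frequencies in `[0, 1]`.
#' @param L genome length in nt (> 0).
#' @return numeric scalar.
#' @export
pi_te <- function(p, L) {
  if (L <= 0) stop("genome length L must be positive")
  if (any(p < 0 | p > 1)) stop("allele frequencies must lie in [0, 1]")
  sum(2 * p * (1 - p)) / L
}

#' Between-population TE insertion diversity
#'
#' `D_xyTE = sum_i (p_1i q_2i + p_2i q_1i) / L` over index-matched sites
#' of two populations. Symmetric in the two populations; equals the
#' within-population form only when the frequencies coincide.
#'
#' @param p1,p2 reference-allele frequencies per population, matched by
#'   position (and by name when named).
#' @param L genome length in nt (> 0).
#' @return numeric scalar.
#' @export
dxy_te <- function(p1, p2, L) {
  if (L <= 0) stop("genome length L must be positive")
  if (length(p1) != length(p2))
    stop("site lists differ in length (", length(p1), " vs ", length(p2), ")")
  if (!is.null(names(p1)) && !is.null(names(p2))) {
    mism <- names(p1) != names(p2)
    if (any(mism))
      stop("unmatched site(s) between populations: ",
           paste(head(names(p1)[mism]), collapse = ", "))
  }
  if (any(c(p1, p2) < 0 | c(p1, p2) > 1))
    stop("allele frequencies must lie in [0, 1]")
  sum(p1 * (1 - p2) + p2 * (1 - p1)) / L
}

#' Per-family TE diversity table
#'
#' Computes `pi_TE` per population, `D_xyTE` between the two populations
#' and the activity ratio `pi_TE / D_xyTE` for every TE family in a site
#' table, along with the number of polymorphic sites used and the mean
#' insertion-allele frequency per population (reported for transparency;
#' no frequency cutoff is applied).
#'
#' @param sites data.frame with columns `family`, `site_id`, `p_pop1`,
#'   `p_pop2` (reference-allele frequencies; see [read_te_sites]).
#' @param L genome length in nt.
#' @return data.frame with one row per family: `family`, `S`, `L`, `pi1`,
#'   `pi2`, `dxy`, `ratio1`, `ratio2`, `mean_q1`, `mean_q2`.
#' @export
te_diversity <- function(sites, L) {
  stopifnot(all(c("family", "site_id", "p_pop1", "p_pop2") %in%
                  names(sites)))
  fams <- unique(sites$family)
  rows <- lapply(fams, function(f) {
    s <- sites[sites$family == f, ]
    pi1 <- pi_te(s$p_pop1, L)
    pi2 <- pi_te(s$p_pop2, L)
    dxy <- dxy_te(s$p_pop1, s$p_pop2, L)
    data.frame(family = f, S = nrow(s), L = L,
               pi1 = pi1, pi2 = pi2, dxy = dxy,
               ratio1 = if (dxy > 0) pi1 / dxy else NA_real_,
               ratio2 = if (dxy > 0) pi2 / dxy else NA_real_,
               mean_q1 = mean(1 - s$p_pop1),
               mean_q2 = mean(1 - s$p_pop2))
  })
  do.call(rbind, rows)
}

#' Rank TE families by transpositional-activity signal
#'
#' Families are ranked by the `pi_TE / D_xyTE` ratio, descending; high
#' ratios (abundant low-frequency polymorphism within a population
#' relative to between-population divergence) indicate recent
#' transpositional activity. By default the maximum of the two
#' populations' ratios is used, selecting families active in either
#' population; per-population rankings are available via `population`.
#' Families with `D_xy = 0` have an undefined ratio and are excluded
#' from the ranking but reported in the `excluded` attribute.
#'
#' @param results data.frame from [te_diversity].
#' @param k number of top families to return; default 10.
#' @param population `"either"` (max of the two ratios), `"pop1"` or
#'   `"pop2"`.
#' @return data.frame of the top `k` families with their ranking ratio;
#'   attribute `excluded` lists families with undefined ratios.
#' @export
rank_active_families <- function(results, k = 10,
                                 population = c("either", "pop1", "pop2")) {
  population <- match.arg(population)
  ratio <- switch(population,
                  either = pmax(results$ratio1, results$ratio2),
                  pop1 = results$ratio1,
                  pop2 = results$ratio2)
  ok <- is.finite(ratio)
  out <- results[ok, , drop = FALSE]
  out$rank_ratio <- ratio[ok]
  out <- out[order(out$rank_ratio, decreasing = TRUE), , drop = FALSE]
  out <- head(out, k)
  rownames(out) <- NULL
  attr(out, "excluded") <- results$family[!ok]
  out
}

#' Mean genomic spacing of a TE family
#'
#' Expected distance between consecutive copies of a family placed over a
#' genome: genome size divided by copy number (e.g. 315 high-quality
#' copies over a > 880 Mb genome give one copy every ~2.8 Mb).
#'
#' @param genome_size genome length in nt.
#' @param n_copies number of copies (> 0).
#' @return mean spacing in nt.
#' @export
mean_insertion_spacing <- function(genome_size, n_copies) {
  stopifnot(genome_size > 0, n_copies > 0)
  genome_size / n_copies
}

#' Scan a sequence for a motif allowing mismatches
#'
#' Reports every offset where the Hamming distance between the sequence
#' window and the motif is at most `max_mismatch`, with the mismatch
#' count; overlapping hits are allowed and ambiguous bases (N) count as
#' mismatches. With `both_strands = TRUE` the reverse complement of the
#' motif is also scanned and hits reported on the minus strand at their
#' forward-sequence positions.
#'
#' @param sequence a character string or `DNAString`.
#' @param motif motif string, shorter than the sequence.
#' @param max_mismatch maximum Hamming distance; default 0.
#' @param both_strands also scan the reverse complement.
#' @return data.frame with columns `position` (1-based start on the
#'   forward sequence), `strand`, `mismatches`.
#' @export
motif_scan <- function(sequence, motif, max_mismatch = 0,
                       both_strands = FALSE) {
  sequence <- toupper(as.character(sequence))
  motif <- toupper(as.character(motif))
  m <- nchar(motif); n <- nchar(sequence)
  if (m == 0) stop("motif must be non-empty")
  if (m > n) stop("motif longer than sequence")
  scan_one <- function(mot, strand_label) {
    mot_chars <- strsplit(mot, "")[[1]]
    nw <- n - m + 1L
    seq_chars <- strsplit(sequence, "")[[1]]
    mism <- integer(nw)
    for (j in seq_len(m))
      mism <- mism + (seq_chars[j:(j + nw - 1L)] != mot_chars[j])
    hit <- which(mism <= max_mismatch)
    if (!length(hit)) return(NULL)
    data.frame(position = hit, strand = strand_label,
               mismatches = mism[hit])
  }
  out <- scan_one(motif, "+")
  if (both_strands) {
    rc <- as.character(reverseComplement(DNAStringSet(motif))[[1]])
    if (rc != motif) out <- rbind(out, scan_one(rc, "-"))
    else {
      rc_hits <- scan_one(rc, "-")
      out <- rbind(out, rc_hits)
    }
  }
  if (is.null(out))
    return(data.frame(position = integer(0), strand = character(0),
                      mismatches = integer(0)))
  out[order(out$position), , drop = FALSE]
}

#' Motif density per sequence
#'
#' Motif count normalised by sequence length, the unit compared between
#' gene groups (e.g. TTAA density of piwi genes versus all other genes).
#'
#' @param counts motif hit counts per sequence.
#' @param lengths sequence lengths in nt.
#' @return numeric vector of densities.
#' @export
motif_density <- function(counts, lengths) {
  stopifnot(length(counts) == length(lengths), all(lengths > 0))
  counts / lengths
}

#' Welch's t-test between two groups of motif densities
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value from the t distribution.
#'
#' @param group_a,group_b numeric vectors, each with at least 2 values.
#' @return list with elements `t`, `df`, `p`.
#' @export
motif_density_test <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 values")
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (!is.finite(va) || !is.finite(vb))
    stop("non-finite variance in a group")
  if (va == 0 && vb == 0) {
    if (mean(group_a) == mean(group_b))
      return(list(t = 0, df = length(group_a) + length(group_b) - 2, p = 1))
    stop("both groups have zero variance; Welch degrees of freedom ",
         "degenerate")
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}
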