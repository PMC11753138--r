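#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   countOverlaps findOverlaps reduce pintersect resize shift mcols mcols<-
#' @importFrom IRanges IRanges subsetByOverlaps
#' @importFrom S4Vectors queryHits subjectHits DataFrame
#' @importFrom GenomeInfoDb seqlevels seqlengths seqlevels<- seqlengths<-
#'   keepSeqlevels
#' @importFrom Biostrings readDNAStringSet DNAStringSet reverseComplement
#' @importFrom stats median pnorm qnorm quantile rbinom rpois runif sd setNames
#' @importFrom utils read.delim write.table head
#' @importFrom methods is
#' @importFrom tools file_ext
NULL

ALIGNMENT_CATEGORIES <- c("unique", "primary_multi", "secondary_multi")

# pin a GRanges to the full chromosome namespace so concatenation across
# chromosomes is silent and coordinates are validated against lengths
.with_levels <- function(gr, chrom_lengths) {
  seqlevels(gr) <- names(chrom_lengths)
  seqlengths(gr) <- unname(chrom_lengths)
  gr
}

.empty_gr <- function(chrom_lengths = NULL) {
  g <- GRanges()
  if (!is.null(chrom_lengths)) g <- .with_levels(g, chrom_lengths)
  g
}

#' Small-RNA alignment library
#'
#' Container for one small-RNA library after ingestion: a `GRanges` of
#' alignment records (metadata columns `read_id`, `category`, `n_hits` and
#' optionally `sequence`), the library size used as the FPKM denominator,
#' and the chromosome lengths of the reference.
#'
#' The library size is the number of distinct reads with at least one
#' reported alignment (each multimapping read counts once, through its
#' primary alignment), so that per-read normalisation is not inflated by
#' multimapping.
#'
#' @param alignments `GRanges` with metadata columns `read_id` (character),
#'   `category` (one of `"unique"`, `"primary_multi"`, `"secondary_multi"`),
#'   `n_hits` (integer >= 1) and optionally `sequence` (read bases, 5'->3').
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param metadata optional list of sample labels.
#' @return An object of class `pirna_library`.
#' @export
pirna_library <- function(alignments, chrom_lengths, metadata = list()) {
  stopifnot(is(alignments, "GRanges"))
  req <- c("read_id", "category", "n_hits")
  missing_cols <- setdiff(req, names(mcols(alignments)))
  if (length(missing_cols))
    stop("alignments lack metadata column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- !(alignments$category %in% ALIGNMENT_CATEGORIES)
  if (any(bad))
    stop("unknown alignment category: ",
         paste(unique(alignments$category[bad]), collapse = ", "))
  # unique <=> n_hits == 1
  if (any(alignments$category == "unique" & alignments$n_hits != 1))
    stop("alignments categorised 'unique' must have n_hits == 1")
  if (any(alignments$category != "unique" & alignments$n_hits < 2))
    stop("multimapping alignments must have n_hits >= 2")
  chroms <- unique(as.character(seqnames(alignments)))
  absent <- setdiff(chroms, names(chrom_lengths))
  if (length(absent))
    stop("chromosome(s) missing from chrom_lengths: ",
         paste(absent, collapse = ", "))
  lib_size <- length(unique(
    alignments$read_id[alignments$category != "secondary_multi"]))
  structure(
    list(alignments = alignments,
         library_size = lib_size,
         chrom_lengths = chrom_lengths,
         metadata = metadata),
    class = "pirna_library")
}

#' @export
print.pirna_library <- function(x, ...) {
  cat("pirna_library:", length(x$alignments), "alignment records,",
      x$library_size, "reads,",
      length(x$chrom_lengths), "chromosome(s)\n")
  tab <- table(factor(x$alignments$category, ALIGNMENT_CATEGORIES))
  cat("  categories:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Read a small-RNA alignment file
#'
#' Ingests alignments from a BAM/SAM file or from a plain TSV dialect
#' (columns `read_id`, `chrom`, `start`, `end`, `strand`, `category`,
#' `n_hits`, `sequence`; coordinates 0-based half-open as in BED), keeping
#' only reads whose reference span lies in the piRNA size range, and
#' categorising every record as uniquely mapping, primary multimapping or
#' secondary multimapping.
#'
#' Categorisation uses the secondary-alignment flag and the `NH` hit-count
#' tag. Records flagged secondary but lacking `NH` are inferred
#' multimappers (n_hits counted from the file); a non-secondary record
#' without `NH` is rejected with an error naming the read.
#'
#' @param path path to a `.bam`, `.sam` or `.tsv` file.
#' @param min_len,max_len inclusive bounds on the aligned length (reference
#'   span). Defaults 24 and 35, the piRNA size range.
#' @param chrom_lengths named vector of chromosome lengths; taken from the
#'   BAM header when `NULL` (required for the TSV dialect).
#' @param keep_sequence keep read sequences (needed for logo statistics).
#' @return A [pirna_library].
#' @export
read_alignments <- function(path, min_len = 24, max_len = 35,
                            chrom_lengths = NULL, keep_sequence = TRUE) {
  if (!file.exists(path)) stop("cannot read alignment file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("bam", "sam")) {
    .read_alignments_bam(path, min_len, max_len, chrom_lengths, keep_sequence)
  } else {
    .read_alignments_tsv(path, min_len, max_len, chrom_lengths, keep_sequence)
  }
}

.read_alignments_bam <- function(path, min_len, max_len, chrom_lengths,
                                 keep_sequence) {
  if (tolower(tools::file_ext(path)) == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  } else bam <- path
  what <- c("qname", "flag")
  if (keep_sequence) what <- c(what, "seq")
  param <- Rsamtools::ScanBamParam(
    what = what, tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  gr <- GRanges(GenomicAlignments::seqnames(ga),
                IRanges(GenomicAlignments::start(ga),
                        GenomicAlignments::end(ga)),
                strand = GenomicAlignments::strand(ga))
  md <- mcols(ga)
  secondary <- bitwAnd(md$flag, 256L) > 0L
  nh <- md$NH
  if (is.null(nh)) nh <- rep(NA_integer_, length(ga))
  # infer hit counts for reads lacking NH but flagged secondary
  if (anyNA(nh)) {
    per_read <- table(md$qname)
    inferable <- is.na(nh) &
      (secondary | md$qname %in% md$qname[secondary])
    nh[inferable] <- as.integer(per_read[md$qname[inferable]])
    if (anyNA(nh))
      stop("alignment record missing multimapper count (NH tag) for read: ",
           md$qname[which(is.na(nh))[1]])
  }
  category <- ifelse(nh == 1L, "unique",
                     ifelse(secondary, "secondary_multi", "primary_multi"))
  mcols(gr) <- DataFrame(read_id = md$qname,
                         category = category,
                         n_hits = as.integer(nh))
  if (keep_sequence) {
    sq <- as.character(md$seq)
    # BAM stores reverse-strand reads reverse-complemented; restore read
    # orientation (5'->3')
    neg <- as.logical(strand(gr) == "-")
    sq[neg] <- as.character(reverseComplement(DNAStringSet(sq[neg])))
    gr$sequence <- sq
  }
  if (is.null(chrom_lengths)) {
    sl <- seqlengths(ga)
    if (anyNA(sl)) stop("BAM header lacks chromosome lengths; supply ",
                        "chrom_lengths explicitly")
    chrom_lengths <- sl
  }
  .finalise_library(gr, min_len, max_len, chrom_lengths)
}

.read_alignments_tsv <- function(path, min_len, max_len, chrom_lengths,
                                 keep_sequence) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("read_id", "chrom", "start", "end", "strand", "category", "n_hits")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("alignment TSV lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyNA(df$n_hits))
    stop("alignment record missing multimapper count for read: ",
         df$read_id[which(is.na(df$n_hits))[1]])
  # file dialect is 0-based half-open; convert at the boundary
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end),
                strand = df$strand)
  mcols(gr) <- DataFrame(read_id = as.character(df$read_id),
                         category = df$category,
                         n_hits = as.integer(df$n_hits))
  if (keep_sequence && "sequence" %in% names(df)) {
    sq <- as.character(df$sequence)
    sq[!is.na(sq) & sq == ""] <- NA_character_
    gr$sequence <- sq
  }
  if (is.null(chrom_lengths)) {
    warning("no chrom_lengths supplied; inferring from maximal end positions")
    mx <- tapply(df$end, df$chrom, max)
    chrom_lengths <- setNames(as.numeric(mx), names(mx))
  }
  .finalise_library(gr, min_len, max_len, chrom_lengths)
}

.finalise_library <- function(gr, min_len, max_len, chrom_lengths) {
  keep <- width(gr) >= min_len & width(gr) <= max_len
  gr <- gr[keep]
  seqlevels(gr) <- names(chrom_lengths)
  seqlengths(gr) <- unname(chrom_lengths)
  pirna_library(gr, chrom_lengths)
}

#' Write a library to the alignment TSV dialect
#'
#' Coordinates are written 0-based half-open (as in BED); [read_alignments]
#' re-ingests the file losslessly.
#'
#' @param library a [pirna_library].
#' @param path output path.
#' @export
write_alignments_tsv <- function(library, path) {
  gr <- library$alignments
  df <- data.frame(read_id = gr$read_id,
                   chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L,
                   end = end(gr),
                   strand = as.character(strand(gr)),
                   category = gr$category,
                   n_hits = gr$n_hits,
                   sequence = if (!is.null(gr$sequence))
                     ifelse(is.na(gr$sequence), "", gr$sequence) else "")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genomic feature annotations
#'
#' Reads BED (3/6 column) or GFF3 annotations into a `GRanges` with
#' metadata columns `feature_class` and `name`. BED coordinates (0-based
#' half-open) and GFF3 coordinates (1-based closed) are both converted to
#' the in-memory 1-based closed convention of `GRanges`; strand is
#' preserved. Records whose interval is empty after conversion are dropped
#' with a warning.
#'
#' @param path path to a `.bed`, `.gff`, `.gff3` or `.gtf` file.
#' @param feature_class class label to assign when the file does not carry
#'   one (BED `name` column is used as `name`; GFF3 `type` as
#'   `feature_class`).
#' @return `GRanges` with `feature_class` and `name` metadata columns.
#' @export
read_features <- function(path, feature_class = NULL) {
  if (!file.exists(path)) stop("cannot read annotation file: ", path)
  ext <- tolower(tools::file_ext(path))
  gr <- rtracklayer::import(path)
  if (ext == "bed") {
    cls <- if (!is.null(feature_class)) feature_class else "feature"
    nm <- if (!is.null(gr$name)) gr$name else
      paste0("feature_", seq_along(gr))
    mcols(gr) <- DataFrame(feature_class = cls, name = nm)
  } else {
    cls <- if (!is.null(feature_class)) feature_class else
      as.character(gr$type)
    nm <- if (!is.null(gr$ID)) as.character(gr$ID) else
      if (!is.null(gr$Name)) as.character(gr$Name) else
        paste0("feature_", seq_along(gr))
    mcols(gr) <- DataFrame(feature_class = cls, name = nm)
  }
  bad <- width(gr) <= 0
  if (any(bad)) {
    warning(sum(bad), " annotation record(s) with empty interval dropped")
    gr <- gr[!bad]
  }
  gr
}

#' Write intervals to BED6
#'
#' @param gr `GRanges`; an optional numeric `score` metadata column is
#'   written to the BED score field.
#' @param path output path.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L,
                   end = end(gr),
                   name = if (!is.null(gr$name)) gr$name else
                     paste0("iv_", seq_along(gr)),
                   score = if (!is.null(gr$score)) round(gr$score) else 0L,
                   strand = as.character(strand(gr)))
  df$strand[df$strand == "*"] <- "."
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a chromosome-length table (TSV: chrom, length)
#' @param path two-column TSV, no header required.
#' @return named numeric vector.
#' @export
read_chrom_lengths <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (is.character(df[[1]]) && identical(tolower(df[[1]][1]), "chrom"))
    df <- df[-1, , drop = FALSE]
  setNames(as.numeric(df[[2]]), df[[1]])
}

#' Read a genome FASTA
#' @param path FASTA path.
#' @return `DNAStringSet`.
#' @export
read_genome <- function(path) readDNAStringSet(path)

#' Read a biallelic TE-insertion allele-frequency table
#'
#' TSV with columns `family`, `site_id`, `p_pop1`, `p_pop2` where `p_*` is
#' the reference-allele frequency in each population (the insertion allele
#' frequency is `q = 1 - p`).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_te_sites <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("family", "site_id", "p_pop1", "p_pop2")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("site table lacks column(s): ", paste(missing_cols, collapse = ", "))
  bad <- df$p_pop1 < 0 | df$p_pop1 > 1 | df$p_pop2 < 0 | df$p_pop2 > 1
  if (any(bad)) stop("allele frequencies outside [0, 1] at site(s): ",
                     paste(head(df$site_id[bad]), collapse = ", "))
  df
}
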