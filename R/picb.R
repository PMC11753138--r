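#' Sliding windows over one chromosome
#'
#' Windows start at 0, `step`, 2*`step`, ... (0-based genomic positions;
#' returned as 1-based closed `IRanges`), with the last window starting at
#' the largest multiple of `step` strictly below the chromosome length.
#' Windows are clipped at the chromosome end, so no window is empty and
#' short chromosomes yield progressively shorter trailing windows.
#'
#' @param chrom_length chromosome length in nt (> 0).
#' @param size window size in nt (>= 1).
#' @param step distance between window starts, 1 <= step <= size.
#' @return `IRanges` of windows in genomic order.
#' @export
sliding_windows <- function(chrom_length, size, step) {
  if (chrom_length <= 0) stop("chrom_length must be positive")
  stopifnot(size >= 1, step >= 1, step <= size)
  starts <- seq.int(1L, chrom_length, by = step)
  IRanges(starts, pmin(starts + size - 1L, as.integer(chrom_length)))
}

#' Window density in FPKM
#'
#' Reads per kilobase of window per million library reads:
#' `count * 1e9 / (window_length * library_size)`. Clipped windows use
#' their clipped length, so density is not deflated at chromosome ends.
#'
#' @param count number of alignments overlapping the window.
#' @param window_length window length in nt (> 0).
#' @param library_size total reads in the library (> 0).
#' @return numeric FPKM value(s); vectorised.
#' @export
window_fpkm <- function(count, window_length, library_size) {
  if (any(library_size <= 0))
    stop("library_size must be positive (FPKM undefined)")
  if (any(window_length <= 0)) stop("window_length must be positive")
  count * 1e9 / (window_length * library_size)
}

#' Parameters for one cluster-calling stage
#'
#' @param window_size,window_step sliding-window geometry in nt.
#' @param fpkm_threshold window-calling density threshold.
#' @param strict compare strictly (`fpkm > threshold`) rather than
#'   inclusively (`fpkm >= threshold`).
#' @param min_length discard merged intervals shorter than this (nt), or
#'   `NULL` for no length filter.
#' @param anchor_required keep only merged intervals containing at least
#'   one anchor interval from the previous stage.
#' @return list of class `stage_params`.
#' @export
stage_params <- function(window_size, window_step, fpkm_threshold,
                         strict = FALSE, min_length = NULL,
                         anchor_required = FALSE) {
  stopifnot(window_step <= window_size, fpkm_threshold >= 0)
  structure(list(window_size = window_size, window_step = window_step,
                 fpkm_threshold = fpkm_threshold, strict = strict,
                 min_length = min_length, anchor_required = anchor_required),
            class = "stage_params")
}

#' Default three-stage parameter set
#'
#' Seeds are called from uniquely mapping alignments in 350 nt windows
#' stepped every 35 nt at >= 2 FPKM, and seeds shorter than 800 nt are
#' discarded to suppress degradation fragments of abundant structural
#' RNAs. Cores add primary multimapping alignments (350/35 nt windows,
#' strictly > 4 FPKM) and must contain a seed. Clusters add secondary
#' multimapping alignments (1000/100 nt windows, >= 0.2 FPKM) and must
#' contain a core.
#'
#' @param seed_fpkm,core_fpkm,cluster_fpkm FPKM thresholds per stage.
#' @param min_seed_length minimal seed length in nt.
#' @return named list with elements `seed`, `core`, `cluster`.
#' @export
picb_params <- function(seed_fpkm = 2, core_fpkm = 4, cluster_fpkm = 0.2,
                        min_seed_length = 800) {
  list(
    seed = stage_params(350, 35, seed_fpkm, strict = FALSE,
                        min_length = min_seed_length,
                        anchor_required = FALSE),
    core = stage_params(350, 35, core_fpkm, strict = TRUE,
                        anchor_required = TRUE),
    cluster = stage_params(1000, 100, cluster_fpkm, strict = FALSE,
                           anchor_required = TRUE))
}

#' Run one calling stage on one strand
#'
#' Counts alignments overlapping each sliding window by at least 1 bp,
#' calls windows whose FPKM passes the stage threshold, merges called
#' windows together with the anchor intervals of the previous stage
#' (overlapping or book-ended intervals merge), optionally keeps only
#' merged intervals containing an anchor, and applies the minimum-length
#' filter. Anchors with no passing window survive unchanged, so a locus
#' covered exclusively by the previous stage's alignments can still be
#' carried forward.
#'
#' @param alignments `GRanges` of alignment intervals, all on one strand.
#' @param anchors `GRanges` of anchor intervals from the previous stage
#'   (may be empty when `params$anchor_required` is `FALSE`).
#' @param params a [stage_params] object.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param library_size FPKM denominator.
#' @return `GRanges` of merged stranded intervals.
#' @export
call_stage <- function(alignments, anchors, params, chrom_lengths,
                       library_size) {
  stopifnot(inherits(params, "stage_params"))
  strands <- unique(as.character(strand(alignments)))
  if (length(strands) > 1)
    stop("call_stage expects alignments on a single strand")
  this_strand <- if (length(strands)) strands else
    if (length(anchors)) as.character(strand(anchors))[1] else "*"
  if (params$anchor_required && length(anchors) == 0 &&
      length(alignments) == 0)
    return(.empty_gr(chrom_lengths))
  chroms <- union(unique(as.character(seqnames(alignments))),
                  unique(as.character(seqnames(anchors))))
  out <- lapply(chroms, function(chr) {
    aln <- alignments[seqnames(alignments) == chr]
    anc <- anchors[seqnames(anchors) == chr]
    win <- sliding_windows(chrom_lengths[[chr]],
                           params$window_size, params$window_step)
    cnt <- countOverlaps(win, ranges(aln))
    fpkm <- window_fpkm(cnt, width(win), library_size)
    pass <- if (params$strict) fpkm > params$fpkm_threshold else
      fpkm >= params$fpkm_threshold
    called <- win[pass]
    merged <- reduce(c(called, ranges(anc)))
    if (params$anchor_required)
      merged <- merged[countOverlaps(merged, ranges(anc)) > 0]
    if (!is.null(params$min_length))
      merged <- merged[width(merged) >= params$min_length]
    if (length(merged) == 0) return(NULL)
    .with_levels(GRanges(chr, merged, strand = this_strand),
                 chrom_lengths)
  })
  out <- Filter(Negate(is.null), out)
  res <- if (length(out)) do.call(c, out) else .empty_gr(chrom_lengths)
  sort(res)
}

#' @importFrom GenomicRanges ranges
#' @importFrom IRanges ranges
NULL

#' Three-stage piRNA cluster calling
#'
#' Per chromosome and strand: seeds are called from uniquely mapping
#' alignments; cores from primary multimapping alignments anchored on
#' seeds; clusters from secondary multimapping alignments anchored on
#' cores. Each stage merges its called windows with the previous tier, so
#' total covered bases can only grow from seeds to cores to clusters.
#'
#' @param library a [pirna_library].
#' @param params three-stage parameter list from [picb_params].
#' @return object of class `cluster_set` with elements `seeds`, `cores`,
#'   `clusters` (stranded `GRanges`), `library_size` and `params`.
#' @export
run_picb <- function(library, params = picb_params()) {
  stopifnot(inherits(library, "pirna_library"))
  aln <- library$alignments
  if (length(aln) == 0) {
    warning("empty library: returning empty cluster set")
    empty <- GRanges()
    return(structure(list(seeds = empty, cores = empty, clusters = empty,
                          library_size = library$library_size,
                          params = params),
                     class = "cluster_set"))
  }
  cl <- library$chrom_lengths
  ls <- library$library_size
  per_strand <- lapply(c("+", "-"), function(s) {
    a <- aln[strand(aln) == s]
    seeds <- call_stage(a[a$category == "unique"], GRanges(),
                        params$seed, cl, ls)
    cores <- call_stage(a[a$category == "primary_multi"], seeds,
                        params$core, cl, ls)
    clusters <- call_stage(a[a$category == "secondary_multi"], cores,
                           params$cluster, cl, ls)
    list(seeds = seeds, cores = cores, clusters = clusters)
  })
  comb <- function(f) sort(c(per_strand[[1]][[f]], per_strand[[2]][[f]]))
  structure(list(seeds = comb("seeds"), cores = comb("cores"),
                 clusters = comb("clusters"),
                 library_size = ls, params = params),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", length(x$seeds), "seeds,", length(x$cores), "cores,",
      length(x$clusters), "clusters (library_size ",
      x$library_size, ")\n", sep = " ")
  invisible(x)
}

.clusters_of <- function(x) {
  if (inherits(x, "cluster_set")) x$clusters
  else if (is(x, "GRanges")) x
  else stop("expected a cluster_set or GRanges")
}

#' Strand-aware intersection of two cluster sets
#'
#' `shared` is the strand-aware interval intersection of the two cluster
#' sets; `only_a` / `only_b` are clusters of one set with zero same-strand
#' overlap in the other (divergent clusters). Chaining `shared` through
#' further sets supports multi-sample intersections.
#'
#' @param a,b `cluster_set` objects or `GRanges` of clusters.
#' @return list with elements `shared`, `only_a`, `only_b`.
#' @export
combine_cluster_sets <- function(a, b) {
  ca <- .clusters_of(a); cb <- .clusters_of(b)
  if (length(ca) && length(cb)) {
    common <- intersect(unique(as.character(seqnames(ca))),
                        unique(as.character(seqnames(cb))))
    if (length(common) == 0)
      stop("cluster sets share no chromosomes; namespaces: [",
           paste(unique(as.character(seqnames(ca))), collapse = ","),
           "] vs [",
           paste(unique(as.character(seqnames(cb))), collapse = ","), "]")
  }
  # align seqlevels so set operations do not error on disjoint levels
  lv <- union(seqlevels(ca), seqlevels(cb))
  seqlevels(ca) <- lv; seqlevels(cb) <- lv
  shared <- GenomicRanges::intersect(ca, cb, ignore.strand = FALSE)
  only_a <- ca[countOverlaps(ca, cb, ignore.strand = FALSE) == 0]
  only_b <- cb[countOverlaps(cb, ca, ignore.strand = FALSE) == 0]
  list(shared = shared, only_a = only_a, only_b = only_b)
}

#' Per-cluster read statistics
#'
#' Assigns each read at most once, through its unique or primary
#' alignment, to the cluster it overlaps (first cluster in genomic order
#' on ties), and reports per-cluster read counts, productivity
#' (read_count / library_size), length and sense/antisense ratios. The
#' raw ratio uses a +1 pseudocount on both strands; the
#' productivity-normalised variant divides each strand's count by the
#' cluster read count before applying a small pseudocount, shrinking the
#' ratio of sparse clusters toward 1. A cluster is flagged dual-strand
#' when piRNA production differs less than `fold_threshold`-fold between
#' strands.
#'
#' @param set `cluster_set` (or `GRanges` of non-overlapping clusters).
#' @param library the [pirna_library] the clusters were called from.
#' @param fold_threshold dual-strand band: `max(ratio, 1/ratio)` below
#'   this flags the cluster dual-strand. Default 100.
#' @param pseudocount added to each strand's raw count. Default 1.
#' @return list with `per_cluster` (data.frame) and `summary` (list with
#'   `explained_fraction`, `n_clusters`, `top50` row indices of the 50%
#'   most productive clusters, `dual_strand_fraction`).
#' @export
cluster_statistics <- function(set, library, fold_threshold = 100,
                               pseudocount = 1) {
  clusters <- sort(.clusters_of(set))
  aln <- library$alignments
  reads <- aln[aln$category %in% c("unique", "primary_multi")]
  n <- length(clusters)
  if (n == 0)
    return(list(per_cluster = data.frame(), summary = list(
      explained_fraction = 0, n_clusters = 0L, top50 = integer(0),
      dual_strand_fraction = NA_real_)))
  hits <- findOverlaps(reads, clusters, ignore.strand = TRUE)
  # one cluster per read: keep the first hit in genomic cluster order
  first <- !duplicated(queryHits(hits))
  qh <- queryHits(hits)[first]; sh <- subjectHits(hits)[first]
  same <- as.character(strand(reads)[qh]) ==
    as.character(strand(clusters)[sh])
  cnt <- tabulate(sh, nbins = n)
  sense <- tabulate(sh[same], nbins = n)
  anti <- cnt - sense
  ratio <- (sense + pseudocount) / (anti + pseudocount)
  ratio_norm <- ifelse(cnt > 0,
                       (sense / pmax(cnt, 1) + 0.01) /
                         (anti / pmax(cnt, 1) + 0.01), 1)
  dual <- pmax(ratio, 1 / ratio) < fold_threshold
  per_cluster <- data.frame(
    chrom = as.character(seqnames(clusters)),
    start = start(clusters), end = end(clusters),
    strand = as.character(strand(clusters)),
    length = width(clusters),
    read_count = cnt,
    productivity = cnt / library$library_size,
    sense_count = sense, antisense_count = anti,
    sense_antisense_ratio = ratio,
    sense_antisense_ratio_norm = ratio_norm,
    dual_strand = dual)
  ord <- order(per_cluster$productivity, decreasing = TRUE)
  top50 <- ord[seq_len(ceiling(n / 2))]
  list(per_cluster = per_cluster,
       summary = list(
         explained_fraction = length(qh) / library$library_size,
         n_clusters = n,
         top50 = top50,
         dual_strand_fraction = mean(dual)))
}
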