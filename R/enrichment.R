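#' Base-level overlap of clusters with annotation classes
#'
#' For each feature class, the percentage of cluster bases covered by at
#' least one feature of that class: `100 * covered / total cluster
#' bases`. Feature bases are deduplicated within a class, and strand is
#' ignored for the intersection (overlap is positional). Classes are
#' computed independently, so percentages across classes can sum above
#' 100.
#'
#' @param clusters `GRanges` of clusters (non-overlapping per strand).
#' @param features `GRanges` with a `feature_class` metadata column, or
#'   plain `GRanges` when `by_class = FALSE`.
#' @param by_class split by `feature_class`; otherwise one overall value.
#' @return named numeric vector of observed percentages per class.
#' @export
percent_overlap <- function(clusters, features, by_class = TRUE) {
  total <- sum(width(clusters))
  if (total == 0) stop("zero total cluster bases")
  classes <- if (by_class) {
    if (is.null(features$feature_class))
      stop("features lack a feature_class column")
    unique(features$feature_class)
  } else "all"
  vapply(classes, function(cl) {
    f <- if (by_class) features[features$feature_class == cl] else features
    fr <- reduce(f, ignore.strand = TRUE)
    hits <- findOverlaps(clusters, fr, ignore.strand = TRUE)
    if (length(hits) == 0) return(0)
    # fr is disjoint after reduce, so per-cluster pieces never double-count
    ov <- pintersect(clusters[queryHits(hits)], fr[subjectHits(hits)],
                     ignore.strand = TRUE)
    100 * sum(width(ov)) / total
  }, numeric(1))
}

.shuffle_clusters <- function(clusters, chrom_lengths, max_shift) {
  n <- length(clusters)
  shift_v <- integer(n)
  chr <- as.character(seqnames(clusters))
  lo <- 1L - start(clusters)                       # smallest legal shift
  hi <- as.integer(chrom_lengths[chr]) - end(clusters)  # largest legal
  if (any(hi < lo)) stop("cluster longer than its chromosome")
  pending <- rep(TRUE, n)
  for (it in 1:10000) {
    if (!any(pending)) break
    draw <- as.integer(floor(runif(sum(pending), -max_shift,
                                   max_shift + 1)))
    ok <- draw >= lo[pending] & draw <= hi[pending]
    idx <- which(pending)
    shift_v[idx[ok]] <- draw[ok]
    pending[idx[ok]] <- FALSE
  }
  if (any(pending)) {
    warning("clamping shifts for ", sum(pending),
            " cluster(s) near chromosome ends")
    shift_v[pending] <- pmin(pmax(0L, lo[pending]), hi[pending])
  }
  shift(clusters, shift_v)
}

#' Shuffle-null enrichment test
#'
#' Builds a positional null by independently shifting every cluster by a
#' uniform integer in `[-max_shift, +max_shift]` (length and strand
#' preserved; shifts that would cross a chromosome boundary are redrawn),
#' recomputes the per-class base overlap for each shuffle, and reports a
#' Z-test of the observed overlap against the shuffle-null moments.
#'
#' @param clusters,features as in [percent_overlap].
#' @param chrom_lengths named vector of chromosome lengths.
#' @param max_shift maximal absolute shift in nt; default 18000.
#' @param n_shuffles number of shuffles; default 100.
#' @param seed optional RNG seed.
#' @return data.frame per class: `feature_class`, `observed_pct`,
#'   `null_mean`, `null_sd`, `z`, `p` (two-sided normal), `degenerate`
#'   (`TRUE` when the null sd is zero and z is undefined).
#' @export
shuffle_null_test <- function(clusters, features, chrom_lengths,
                              max_shift = 18000, n_shuffles = 100,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  obs <- percent_overlap(clusters, features)
  null_mat <- vapply(seq_len(n_shuffles), function(i) {
    percent_overlap(.shuffle_clusters(clusters, chrom_lengths, max_shift),
                    features)
  }, numeric(length(obs)))
  null_mat <- matrix(null_mat, nrow = length(obs))
  mu <- rowMeans(null_mat)
  sdv <- apply(null_mat, 1, sd)
  z <- ifelse(sdv > 0, (obs - mu) / sdv, NA_real_)
  data.frame(feature_class = names(obs), observed_pct = unname(obs),
             null_mean = mu, null_sd = sdv, z = z,
             p = ifelse(is.na(z), NA_real_, 2 * pnorm(-abs(z))),
             degenerate = sdv == 0, row.names = NULL)
}

#' Bootstrap confidence interval for the observed overlap
#'
#' Replicates omit a fraction of clusters uniformly without replacement
#' and recompute the per-class overlap; the 95% CI is the normal
#' approximation `mean +/- 1.96 sd` over replicates (empirical 2.5/97.5%
#' quantiles are reported alongside, though they are coarse at the
#' default 10 replicates).
#'
#' @param clusters,features as in [percent_overlap].
#' @param omit_fraction fraction of clusters omitted per replicate;
#'   default 0.2.
#' @param n_boot number of replicates; default 10.
#' @param seed optional RNG seed.
#' @return data.frame per class: `feature_class`, `observed_pct`,
#'   `ci_low`, `ci_high`, `q_low`, `q_high`.
#' @export
bootstrap_ci <- function(clusters, features, omit_fraction = 0.2,
                         n_boot = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(clusters)
  if (n < 5) stop("need at least 5 clusters for the omission bootstrap")
  n_omit <- floor(omit_fraction * n)
  if (n - n_omit < 1) stop("omission would leave no clusters")
  obs <- percent_overlap(clusters, features)
  reps <- vapply(seq_len(n_boot), function(i) {
    keep <- if (n_omit > 0) -sample.int(n, n_omit) else seq_len(n)
    percent_overlap(clusters[keep], features)
  }, numeric(length(obs)))
  reps <- matrix(reps, nrow = length(obs))
  mu <- rowMeans(reps)
  sdv <- apply(reps, 1, sd)
  data.frame(feature_class = names(obs), observed_pct = unname(obs),
             ci_low = mu - 1.96 * sdv, ci_high = mu + 1.96 * sdv,
             q_low = apply(reps, 1, quantile, 0.025),
             q_high = apply(reps, 1, quantile, 0.975),
             row.names = NULL)
}

#' Full per-class enrichment summary
#'
#' Combines [percent_overlap], [bootstrap_ci] and [shuffle_null_test]
#' into one table, optionally with Benjamini-Hochberg adjusted p-values
#' across classes.
#'
#' @inheritParams shuffle_null_test
#' @inheritParams bootstrap_ci
#' @param adjust apply Benjamini-Hochberg correction across classes.
#' @return data.frame, one row per feature class.
#' @export
enrichment_test <- function(clusters, features, chrom_lengths,
                            max_shift = 18000, n_shuffles = 100,
                            omit_fraction = 0.2, n_boot = 10,
                            seed = NULL, adjust = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  ci <- bootstrap_ci(clusters, features, omit_fraction, n_boot)
  nul <- shuffle_null_test(clusters, features, chrom_lengths,
                           max_shift, n_shuffles)
  out <- merge(ci, nul[, setdiff(names(nul), "observed_pct")],
               by = "feature_class", sort = FALSE)
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Per-gene aggregation of window scores
#'
#' Aggregates a genomic window statistic (e.g. a composite selective
#' sweep score computed in sliding windows) to genes: for each gene, the
#' median over windows fully enclosed by the gene interval (window start
#' at or after the gene start and window end at or before the gene end),
#' and the percentile rank of that median among all scored genes
#' (`100 * rank / n`, mean rank on ties). Genes with no enclosed window
#' receive no score and are listed in the `unscored` attribute.
#'
#' @param windows `GRanges` with a numeric `score` metadata column.
#' @param genes `GRanges` of largest-transcript gene spans with a
#'   `gene_id` metadata column.
#' @return data.frame per scored gene: `gene_id`, `mu_median`,
#'   `n_windows`, `percentile`; attribute `unscored` holds the ids of
#'   genes with zero enclosed windows.
#' @export
per_gene_score <- function(windows, genes) {
  if (is.null(windows$score)) stop("windows lack a score column")
  if (is.null(genes$gene_id)) stop("genes lack a gene_id column")
  hits <- findOverlaps(windows, genes, type = "within",
                       ignore.strand = TRUE)
  med <- tapply(windows$score[queryHits(hits)], subjectHits(hits), median)
  nw <- table(subjectHits(hits))
  idx <- as.integer(names(med))
  out <- data.frame(gene_id = genes$gene_id[idx],
                    mu_median = as.numeric(med),
                    n_windows = as.integer(nw))
  out$percentile <- 100 * rank(out$mu_median, ties.method = "average") /
    nrow(out)
  attr(out, "unscored") <- setdiff(genes$gene_id, out$gene_id)
  out
}
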