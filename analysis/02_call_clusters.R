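#!/usr/bin/env Rscript

# Calls piRNA clusters on the simulated library with the three-stage
# seed/core/cluster procedure, compares them against the planted truth,
# and writes the cluster BED plus per-cluster statistics.

suppressPackageStartupMessages({
  library(pirnascape)
  library(GenomicRanges)
})

out_dir <- "results"
chrom_lengths <- read_chrom_lengths(file.path(out_dir, "genome.sizes.tsv"))
lib <- read_alignments(file.path(out_dir, "library.tsv"),
                       chrom_lengths = chrom_lengths)
print(lib)

cs <- run_picb(lib)
cat(sprintf("seeds %d, cores %d, clusters %d\n",
            length(cs$seeds), length(cs$cores), length(cs$clusters)))

write_bed(cs$clusters, file.path(out_dir, "clusters.bed"))
write_bed(cs$seeds, file.path(out_dir, "seeds.bed"))

st <- cluster_statistics(cs$clusters, lib)
write.table(st$per_cluster, file.path(out_dir, "cluster_stats.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("explained fraction: %.3f, dual-strand fraction: %.3f\n",
            st$summary$explained_fraction,
            st$summary$dual_strand_fraction))

truth <- read.delim(file.path(out_dir, "planted_clusters.tsv"))
planted <- GRanges(truth$chrom, IRanges::IRanges(truth$start, truth$end),
                   truth$strand)
cat(sprintf("planted %d, recovered %d, spurious %d\n",
            length(planted),
            sum(countOverlaps(planted, cs$clusters) >= 1),
            sum(countOverlaps(cs$clusters, planted) == 0)))
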