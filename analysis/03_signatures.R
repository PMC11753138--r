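#!/usr/bin/env Rscript

# Computes the piRNA sequence and pairing signatures of the simulated
# library: length spectrum, positional base frequencies (1U/10A),
# ping-pong overlap z-score per cluster, and the phasing histogram.

suppressPackageStartupMessages({
  library(pirnascape)
  library(GenomicRanges)
})

out_dir <- "results"
chrom_lengths <- read_chrom_lengths(file.path(out_dir, "genome.sizes.tsv"))
lib <- read_alignments(file.path(out_dir, "library.tsv"),
                       chrom_lengths = chrom_lengths)

spectrum <- length_spectrum(lib$alignments$sequence)
write.table(spectrum, file.path(out_dir, "length_spectrum.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

m <- base_frequency_matrix(lib$alignments$sequence, trim_len = 20)
write.table(round(m, 4), file.path(out_dir, "base_frequencies.tsv"),
            sep = "\t", quote = FALSE)
cat(sprintf("U at position 1: %.3f, A at position 10: %.3f\n",
            m["U", 1], m["A", 10]))

clusters <- read_features(file.path(out_dir, "clusters.bed"),
                          feature_class = "cluster")
rows <- lapply(seq_along(clusters), function(i) {
  sub <- subset_library(lib, clusters[i])
  pp <- pingpong_signature(sub$alignments)
  data.frame(cluster = i,
             chrom = as.character(seqnames(clusters))[i],
             start = start(clusters)[i], end = end(clusters)[i],
             reads = length(sub$alignments),
             z10 = if (is.na(pp$z10)) NA else unname(pp$z10))
})
pp_tab <- do.call(rbind, rows)
write.table(pp_tab, file.path(out_dir, "pingpong_per_cluster.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(pp_tab)

h <- phasing_histogram(lib$alignments)
write.table(h, file.path(out_dir, "phasing_histogram.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("phasing d=0 count: %d (max other bin %d)\n",
            h$count[h$distance == 0], max(h$count[h$distance != 0])))
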