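#!/usr/bin/env Rscript

# Generates the shared simulated dataset used by the downstream drivers:
# a two-chromosome genome with duplicated segments, a piRNA library with
# planted clusters carrying 1U/10A biases, ping-pong pairs and a phased
# cluster, TE genotype tables for two populations, and annotation
# features both independent of and enriched in the planted clusters.

suppressPackageStartupMessages({
  library(pirnascape)
  library(GenomicRanges)
})

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)
seed <- 20250101

genome <- simulate_genome(
  c(chr1 = 600000, chr2 = 400000),
  repeats = data.frame(length = c(800, 500), copies = c(3, 4)),
  seed = seed)
write_sim_genome(genome, file.path(out_dir, "genome.fa"),
                 file.path(out_dir, "genome.sizes.tsv"))

clusters <- data.frame(
  chrom  = c("chr1", "chr1", "chr1", "chr2", "chr2"),
  start  = c(20001, 150001, 320001, 30001, 200001),
  end    = c(26000, 158000, 340000, 36000, 280000),
  strand = c("+", "-", "+", "-", "+"),
  n_reads = c(800, 600, 900, 700, 600),
  u1     = c(0.8, 0.8, 0.8, 0.8, 0.8),
  a10    = c(0.6, 0.25, 0.6, 0.25, 0.25),
  pingpong_fraction = c(0.3, 0, 0.3, 0, 0),
  phased = c(FALSE, FALSE, FALSE, FALSE, TRUE))

# note: at desk scale the FPKM thresholds are permissive (a library of a
# few thousand reads makes even a single read exceed 2 FPKM in a 350 nt
# window), so the background is kept sparse enough that isolated reads
# cannot chain into 800 nt seed regions
sim <- simulate_pirna_library(genome, clusters, background_rate = 0.1,
                              seed = seed + 1)
write_alignments_tsv(sim$library, file.path(out_dir, "library.tsv"))
write.table(sim$truth$clusters,
            file.path(out_dir, "planted_clusters.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

geno <- simulate_te_genotypes(seed = seed + 2)
write.table(geno$sites, file.path(out_dir, "te_sites.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(geno$truth, file.path(out_dir, "te_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

planted_gr <- GRanges(clusters$chrom,
                      IRanges::IRanges(clusters$start, clusters$end),
                      clusters$strand)
feat_indep <- simulate_features(genome, c("DNA_TE", "LTR_TE"),
                                n_per_class = 40, feature_length = 600,
                                seed = seed + 3)
feat_in <- simulate_features(genome, "cluster_TE", n_per_class = 30,
                             feature_length = 500, inside = planted_gr,
                             seed = seed + 4)
write_bed(c(feat_indep, feat_in), file.path(out_dir, "features.bed"))

cat("simulated dataset written to", out_dir, "\n")
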