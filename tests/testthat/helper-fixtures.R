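# in-code fixtures: everything is generated at test time, no binary files

make_sam_fixture <- function(path, records,
                             chrom_lengths = c(chr1 = 10000, chr2 = 5000)) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   chrom_lengths))
  writeLines(c(hdr, records), path)
  path
}

# one SAM alignment line; pos is 1-based, seq length defines the span
sam_line <- function(qname, flag, chrom, pos, seq, nh = NULL) {
  tag <- if (!is.null(nh)) sprintf("\tNH:i:%d", nh) else ""
  sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*%s",
          qname, flag, chrom, pos, nchar(seq), seq, tag)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# deterministic small genome + library for reuse across tests
small_sim <- function(seed, n_reads = 800, chrom_lengths =
                        c(chr1 = 40000, chr2 = 20000),
                      repeats = data.frame(length = 400, copies = 3)) {
  g <- simulate_genome(chrom_lengths, repeats = repeats, seed = seed)
  lib <- simulate_random_library(g, n_reads, seed = seed + 1000)
  list(genome = g, library = lib)
}
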