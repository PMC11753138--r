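---
title: "Methods: piRNA cluster calling, sequence signatures, and TE activity statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: piRNA cluster calling, sequence signatures, and TE activity statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(pirnascape)
library(GenomicRanges)
```

This vignette documents the statistical model behind each module, the
default parameters and why they were chosen, what the synthetic-data
generators emulate, and the numerical and coordinate conventions used
throughout.

## Scientific setting

PIWI-interacting RNAs (piRNAs) are 24–35 nt germline small RNAs that
silence transposable elements (TEs). They are produced from genomic
*piRNA clusters*, carry characteristic sequence signatures — a uridine
bias at position 1 (1U), and, for reads produced by the "ping-pong"
amplification loop, an adenine at position 10 (10A) together with an
exact 10 nt 5′ overlap between sense and antisense partners — and can be
produced in *phased* head-to-tail trails. On the TE side, a family's
recent transpositional activity leaves a population-genetic fingerprint:
many insertion alleles segregating at low frequency within a population,
against little divergence between populations.

## Coordinates

All in-memory intervals are `GRanges` objects, i.e. **1-based closed**
coordinates, the native Bioconductor convention; every overlap, merge
and width computation is then performed by `IRanges` semantics that the
rest of the ecosystem shares. File dialects keep their own conventions:
BED and the library TSV are 0-based half-open on disk and converted at
the boundary by `read_features`/`read_alignments`/`write_bed`. The
ping-pong overlap of a plus-strand 5′ end $p$ and minus-strand 5′ end
$m$ is $o = m - p + 1$ in these coordinates, which is identical to the
$o = m - p$ formula in 0-based coordinates.

## Cluster calling (`run_picb`)

Clusters are called in three stages, each a sliding-window scan followed
by merging, anchored on the previous stage:

1. **Seeds** — uniquely mapping reads only; 350 nt windows every 35 nt;
   a window is called at ≥ 2 FPKM (inclusive); called windows are merged
   (book-ended windows merge) and merged regions shorter than 800 nt are
   discarded.
2. **Cores** — primary alignments of multimapping reads; same 350/35
   windows at > 4 FPKM (strict); called windows are merged together with
   the seeds, and every merged region must contain a seed.
3. **Clusters** — secondary alignments; 1000 nt windows every 100 nt at
   ≥ 0.2 FPKM; merged together with the cores, and every region must
   contain a core.

Anchors pass through unchanged, so a seed can become a core and a
cluster without any multimapping support. FPKM is
$c \cdot 10^9 / (w \cdot N)$ for window count $c$, window length $w$ and
library size $N$; $N$ counts **distinct reads** (unique plus primary
records), not alignment records, so multimapping does not inflate the
denominator. Strands are called independently throughout.

```{r picb-example}
genome <- simulate_genome(c(chr1 = 60000), seed = 7)
cl <- data.frame(chrom = "chr1", start = 20001, end = 24000,
                 strand = "+", n_reads = 400)
lib <- simulate_pirna_library(genome, cl, seed = 8)$library
run_picb(lib)$clusters
```

Two consequences of this construction are worth knowing. First, total
covered bases are monotone in every threshold (a stricter stage's window
union is a pointwise subset of a looser one's), but the cluster *count*
is not monotone in the minimum seed length: deleting a short seed that
bridged two window runs can split one merged cluster into two smaller
ones. The test suite asserts exactly the guaranteed forms. Second, at
small library sizes the FPKM thresholds are permissive — with a few
thousand reads a single read already exceeds 2 FPKM in a 350 nt window —
so only the 800 nt minimum seed length separates clusters from sparse
background; simulated backgrounds should stay below roughly one read
per 2 kb if clean recovery is wanted.

Per-cluster read statistics (`cluster_statistics`) assign each read once
(first overlapping cluster), and report a sense/antisense ratio with a
pseudocount of 1 on both strands, plus a normalised variant
$(s/n + 0.01)/(a/n + 0.01)$ that is comparable across read depths.
Clusters within a 100-fold ratio of balance are flagged dual-strand.

## Sequence signatures

* `length_spectrum` tallies reads per length over 18–36 nt with the 5′
  base composition per length; `collapse = TRUE` counts each distinct
  sequence once, removing abundance bias.
* `base_frequency_matrix` trims sequences from the 3′ end to a common
  20 nt and reports the 4 × 20 positional frequency matrix (T reported
  as U). The 1U bias appears in row U, column 1, the ping-pong 10A in
  row A, column 10.
* `pingpong_signature` counts, for every offset $o \in 1..26$, the
  plus/minus 5′-end pairs overlapping by $o$ nt, and summarises the
  ping-pong excess as $z_{10} = (c_{10} - \bar c)/s_c$, the z-score of
  the offset-10 count against all 26 offsets (sample standard
  deviation). The background includes offset 10 itself by default, which
  is conservative; `exclude_self = TRUE` removes it. A zero background
  standard deviation yields `NA` flagged `degenerate`, never a division
  by zero.
* `phasing_histogram` finds, per read, the nearest same-strand
  downstream read whose 5′ end lies at or past this read's 3′ end and
  records the 3′-to-5′ gap; `d = 0` is the head-to-tail hallmark of
  phased biogenesis. Overlapping downstream reads are not partners.

```{r signature-example}
cl <- data.frame(chrom = "chr1", start = 5001, end = 55000,
                 strand = "+", n_reads = 300, u1 = 0.8, a10 = 0.6,
                 pingpong_fraction = 0.3)
lib <- simulate_pirna_library(genome, cl, seed = 9)$library
m <- base_frequency_matrix(lib$alignments$sequence)
round(m[, c(1, 10)], 3)
pingpong_signature(lib$alignments)$z10
```

## TE activity statistics

For biallelic TE insertion sites with reference-allele frequency $p_i$
($q_i = 1 - p_i$) and genome length $L$:

$$\pi_{TE} = \frac{1}{L}\sum_i 2 p_i q_i, \qquad
  D_{xy,TE} = \frac{1}{L}\sum_i (p_{1i} q_{2i} + p_{2i} q_{1i}).$$

A high $\pi_{TE}/D_{xy,TE}$ ratio — abundant low-frequency polymorphism
within a population against little between-population divergence — marks
recent transpositional activity. `rank_active_families` ranks families
by this ratio, by default by the maximum over the two populations so a
family active in either is found; families with $D_{xy} = 0$ have an
undefined ratio and are excluded (reported via the `excluded`
attribute), not ranked as infinite.

`motif_scan` is a Hamming-distance scan (overlapping hits allowed,
ambiguous bases count as mismatches) used for target-site motifs such as
TTAA, and `motif_density_test` is Welch's unequal-variance t-test on
per-sequence motif densities.

## Interval enrichment

`percent_overlap` reports, per annotation class, the percentage of
cluster bases covered by at least one feature of that class (features
deduplicated within the class; strand ignored; classes independent, so
percentages may sum above 100). The null model
(`shuffle_null_test`) shifts every cluster independently by a uniform
integer in ±18,000 nt — length and strand preserved, boundary-crossing
shifts redrawn — and reports a Z-test of the observed overlap against
the shuffle moments, with a zero null standard deviation flagged
`degenerate` rather than producing an infinite z. `bootstrap_ci` omits
20% of clusters per replicate (10 replicates) and reports the normal
approximation mean ± 1.96 sd alongside the coarse empirical quantiles.
`per_gene_score` aggregates window statistics to genes using only
windows fully enclosed by the gene span, reporting the median and its
percentile rank.

## What the generators emulate — and what they do not

`simulate_genome` draws i.i.d. bases at a stated GC fraction (default
0.41) and copies *duplicated segments* verbatim to non-overlapping
positions. Multimapping is therefore structural: a read inside one copy
genuinely aligns to all copies (`n_hits` = copy number, one uniformly
chosen primary), rather than being fabricated in the alignment records.

`simulate_pirna_library` plants clusters with: read lengths from a
discretised triangular distribution peaked at a configurable mode
(default 27 nt) over 24–35 nt; 1U/10A achieved by *overriding* the
first/tenth base with the stated probability (the alternative base is
drawn uniformly from the remaining three), which makes planted
probabilities exact at any depth instead of approximate via rejection;
ping-pong partners placed at an exact 10 nt 5′ overlap on the opposite
strand; phased clusters as head-to-tail trails; and Poisson background
at a stated rate per kb. The ground truth records every planted
quantity.

Not modelled: sequencing error, quality scores, real TE sequence
evolution, and empirical length-distribution shapes. Problem sizes in
the tests and drivers (genomes of tens of kb to 1 Mb, libraries of
hundreds to ten thousand reads) are the package's own choices for fast,
deterministic validation; they are far below the scale of real
germline sRNA-seq data, which is why validation is property-based
(oracle equivalence, planted-truth recovery, calibration) rather than a
reproduction of any particular dataset's headline numbers.

## Numerical conventions

* Sample (n−1) standard deviations everywhere a z-score is formed.
* Degenerate denominators (zero sd, zero $D_{xy}$) yield flagged `NA`s.
* All randomised operations accept an explicit seed; identical inputs
  produce byte-identical outputs.
* Two-sided p-values: normal for shuffle z-scores, t for Welch's test.
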