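---
title: "Methods: isoform discovery, polyadenylation and modification profiling for direct RNA sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isoform discovery, polyadenylation and modification profiling for direct RNA sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanotx)
```

# Scope and data model

`nanotx` analyses spliced long-read alignments from native (direct) RNA
sequencing, where each read is a full-length or 5'-degraded copy of one mRNA
molecule anchored at its poly(A) tail. The package starts downstream of
basecalling and alignment: its inputs are BED12 read alignments, a GFF3
reference annotation, and optional per-read poly(A)-length and per-site
modification-fraction tables produced by signal-level tools.

Everything is built on one coordinate object, the **exon chain**: an ordered
list of non-overlapping exonic intervals on a chromosome and strand, stored
0-based half-open. Reads, isoform clusters and annotated transcripts are all
exon chains; the gaps between consecutive exons are splice junctions. GFF3's
1-based closed coordinates are converted at the I/O boundary and nowhere
else, which removes the usual class of off-by-one errors.

Two biological facts shape all downstream decisions:

* **3' ends are trustworthy, 5' ends are not.** Sequencing proceeds from the
  poly(A) end; the 5' terminus of a read reflects how far the molecule
  survived, and the final stretch of the 5' end (about a dozen nucleotides)
  is often lost. So 3' termini carry signal (polyadenylation sites), while
  5' starts within a shared junction chain are treated as technical.
* **Splice junctions are reproducible but jittery.** Aligner wobble shifts
  individual donor/acceptor coordinates by a few nucleotides, so junction
  identity is always assessed under a small coordinate tolerance.

# Read clustering

`cluster_reads()` merges reads into isoforms per chromosome/strand
partition:

1. Junctions are *snapped*: unique (donor, acceptor) pairs are visited in
   order of decreasing read support, and every pair within the tolerance
   (both ends) of the visited pair adopts its coordinates. The
   highest-support coordinate wins, which is deterministic and recovers the
   true junction under moderate jitter.
2. Reads grouped by identical snapped junction chains form provisional
   isoforms. Zero-junction (mono-exon) reads have no junction chain to key
   on, so they are grouped by single-linkage genomic overlap instead — the
   one place the grouping rule needs a spatial criterion.
3. **Truncation absorption:** a group whose junction chain is a strand-aware
   3'-terminal suffix of a larger group's chain, whose 3' end lies within
   `end_window` (default 50 nt) of the larger group's modal 3' end, and
   whose 5' end does not bridge any unshared junction of the larger chain,
   is merged into it. This folds 5'-degraded reads into their full-length
   isoform while keeping genuinely distinct isoforms (e.g. a mono-exon read
   spanning an intron, which is intron retention, not truncation) separate.
4. The representative chain takes the parent's junction chain, the 5'-most
   member start and the modal member 3' end; clusters with fewer than
   `min_support` reads (default 5) are discarded.

Because groups are canonically sorted before merging, the output is
invariant under permutation of the input reads, and raising `min_support`
can only reduce the number of clusters.

A consequence of treating 5' starts as technical: alternative transcription
initiation is only reported as a separate isoform when it is accompanied by
a distinguishing junction or survives as a separate suffix-incompatible
chain — a deliberate trade-off against calling every degraded read a novel
5' variant.

# Isoform classification

`classify_isoform()` assigns each cluster `"known"` or one of eleven novel
categories relative to the best-matching reference transcript at its locus
(most matched junctions, ties by exonic Jaccard, then lexicographic id).
The decision cascade, first match wins:

1. **fusion** — the cluster's exons overlap two or more same-strand loci by
   at least `min_overlap` (20 nt) each, or two or more loci in antisense;
2. **intron retention** — a reference intron lies entirely inside one
   cluster exon, all cluster junctions matching;
3. **extra exon** — a cluster exon sits inside a reference intron, bounded
   by two junctions absent from the reference;
4. **missing exon** — an internal reference exon has no overlapping cluster
   exon and is spanned by a single cluster junction whose ends match the
   flanking reference boundaries;
5. **5'/3' extra** — one or more exons lie strictly outside the reference
   span, joined through novel junctions (strand decides which end);
6. **5'/3' missing** — the cluster's junctions form a proper contiguous run
   of the reference's junctions, missing one or more at one end;
7. **new junction** — a cluster junction matches no annotated junction of
   any isoform at the locus;
8. **extra/missing UTR** — junction chains identical, but a terminal exon
   extends beyond or stops short of the reference terminal boundary by more
   than `utr_tol` (20 nt);
9. otherwise **known**.

Ordering structural changes (2–7) before end-length changes (8) means a
chain showing both gets the more informative label; the categories are
disjoint by construction. A genuinely open boundary case — a terminal
extension that itself contains a novel junction — is resolved by junction
presence (it becomes an extra-exon/extra-end call, not a UTR call).
Single-locus antisense clusters are labelled `antisense` and clusters
overlapping no gene `intergenic`; neither is counted among the eleven
categories.

`utr_tol = 20` nt was chosen to sit above both junction jitter and the
~13-nt 5'-end loss characteristic of the platform, so UTR calls are not
triggered by ordinary read degradation.

Fusion/readthrough clusters are typed into six structural classes
(`classify_fusion()`), checked in this order: (ii) mono-exon read spanning
two or more loci; (v) antisense with the inter-locus region spliced out;
(iii) more than two loci with splicing; (iv) all junctions annotated and
the intergenic region retained as exon; (i) partners spliced as annotated
plus a novel junction inside the intergenic region; (vi) any partner-internal
deviation. The order puts the most constrained patterns first so each read
matches exactly one type.

# Polyadenylation

`call_sites()` collapses read 3' termini at exact positions, absorbs
positions within 5 nt into their higher-support neighbour (ties toward the
smaller coordinate), and retains sites with support **strictly greater
than** 5 reads. The isoform threshold (at least 5) and the site threshold
(more than 5) are intentionally separate configuration keys. Whether to
collapse nearby ends before the support filter is not dictated by the site
definition itself; the 5-nt absorption radius mirrors the 5-nt
cross-dataset identity shift used by `match_site_sets()`, and is recorded in
the output metadata.

`hexamer_enrichment()` scans the 50-nt window upstream of each site for all
4096 hexamers. Ranking motifs by raw frequency in 3'UTR sequence returns
poly-U/poly-T trivially, so "over-represented" is defined against a
**dinucleotide-preserving shuffle** of the same windows (Altschul–Erickson
Eulerian-path shuffling, 20 rounds, seeded): `enrichment =
(observed + 0.5) / (expected + 0.5)` where observed/expected count windows
containing the motif at least once. Both the enrichment rank and the raw
frequency rank are reported. `positional_occurrence()` then counts sites
whose motif copy starts 14–24 nt upstream — the canonical placement of the
plant polyadenylation signal.

`summarize_polya()` only summarizes per-read length tables (median, mean,
fraction below 100 nt per sample); signal-level length estimation is out of
scope.

# Differential expression

Two views, deliberately kept distinct:

* **DEI** (`call_dei()`): an isoform's relative abundance is its share of
  its locus's reads; an isoform is differentially expressed when that share
  changes by more than 10 **percentage points** between tissues. The
  wording "relative abundance (percentage of read count) … greater than
  10%" admits a relative-change reading too; the percentage-point reading
  is the default and a `relative = TRUE` flag provides the other. There is
  no significance test in the rule; an auxiliary two-proportion z-test
  column is emitted for reference only. Isoforms below the support floor
  are excluded from numerator *and* denominator, so retained shares still
  sum to one per locus.
* **DEG** (`call_deg()`): counts per million with a 0.5 pseudocount give
  the tissue fold change; the test is an exact two-sided binomial test of
  the pooled tissue counts against the library-size ratio (the conditional
  test of equal relative abundance under Poisson sampling), with
  Benjamini–Hochberg FDR across loci. A gene is called at |log2FC| > 1 and
  FDR < 0.05. Replicates are pooled for the test — the package targets the
  2 + 2 library design — and a fold-change sign-consistency flag across
  replicate pairs is emitted as QC. This is a fully specified, dependency-
  free test with known conditional behaviour; a negative-binomial GLM is
  out of scope, and the test suite cross-checks the ranking against an
  established exact-test implementation on simulated counts.

# Modification profiles

Per-site modification fractions arrive in spliced transcript coordinates.
The metagene machinery uses the **w0 convention**: positions without a
reported site contribute zero, so a bin's value is the summed site fraction
divided by the bin width (5 nt by default) — a coverage-normalized level,
not a mean over reported sites. This is the only reading under which a
sparse site table yields well-defined binned profiles; the per-site mean is
also emitted alongside for the other reading of plotted levels.

Only isoforms with both UTRs longer than 50 nt qualify. Each region
(5'UTR, body, 3'UTR) is binned and linearly rescaled to fixed lengths
(20/60/20 bins by default; the counts are parameters, chosen to keep the
body at roughly its typical share of transcript length).

`compare_sets()` contrasts a gene set against all qualifying isoforms: the
statistic is the difference in mean per-isoform w0 level per region, with a
relabeling null (1000 random same-size subsets) and two-sided permutation
p-values. `stopcodon_meta()` averages the w0 signal at each offset from the
stop codon (offset 0 = first 3'UTR base) to localize positional peaks such
as the adenine-modification maximum near the stop codon.

# The synthetic-data generator

`sim_config()` + `simulate_dataset()` generate a genome, annotation, reads
and auxiliary tables with full ground truth, deterministic under a seed
(each stage reseeds from `seed` plus a fixed offset, so stages are
individually reproducible). The defaults encode the study conditions the
analysis targets:

* multi-exon genes (4–6 exons of 100–250 nt, introns 80–200 nt) on both
  strands with at least 300 nt between genes, one reference isoform each,
  UTRs of 60–120 nt;
* planted events, each hosted by a dedicated gene (or run of adjacent
  same-strand genes for fusions), constructed to satisfy exactly their
  category's defining pattern: one per novel category and fusion type by
  default;
* reads per isoform per sample drawn from 8–15, across two seedling and two
  floral-bud samples;
* 5' truncation as geometric prefix loss at 0.075 per nt (mean ~12 nt,
  matching the platform's 5'-end loss), junction jitter N(0, 1) rounded to
  integers, 3'-end wobble within ±2 nt (both disabled together in the
  noiseless limit, where every stage must recover truth exactly);
* a T-rich hexamer (`TTTGTA`) written 19 ± 5 nt upstream of every truth
  poly(A) site, with draws bounded to 14–24 nt — the stated placement range
  of the signal; an unbounded Normal would put only ~73% of copies in that
  window and would contradict the placement it is meant to encode;
* per-tissue Gamma poly(A) lengths (seedling mean 68 nt, bud mean 84 nt;
  most tails below 100 nt, floral buds slightly longer);
* differential panels: 200 loci with a 20-percentage-point isoform shift at
  200 reads/locus/tissue plus 500 null loci (three isoforms per locus,
  Dirichlet shares); 2000 gene loci with log-uniform 50–500 reads/tissue
  and 200 planted four-fold effects. The depth range was chosen so the
  exact binomial test's discreteness leaves its attained size near the
  nominal 5% — much shallower panels make any exact test visibly
  conservative;
* modification tables: m5C sites at 5% of positions with Beta(2, 8)
  fractions, doubled (capped at 1) in a 200-gene mobile set; three 100-gene
  TLS sets drawn *independently* of mobility, so TLS membership confers no
  effect and TLS-vs-total contrasts are null — drawing them disjoint from
  the mobile set would make them systematically mobile-depleted and bias
  the contrast negative; an adenine track with a Gaussian fraction peak
  (height 0.5, SD 8 nt) at the stop codon.

What the generator does **not** emulate: base-level sequencing errors,
raw signal, internal priming artifacts, overlapping gene models, multiple
annotated isoforms per gene, expression-dependent coverage bias, and
genome-wide scale. Passing tests therefore demonstrate the correctness and
calibration of the algorithms under the stated noise model, not performance
on real libraries.

# Numerical and implementation choices

* Junction tolerance 5 nt everywhere (matching, snapping, site identity);
  greedy in-order 1:1 junction matching is used rather than global optimal
  matching — junctions within a chain are strictly ordered, so greedy
  equals the bipartite optimum on realistic geometries, a property the test
  suite checks against an independent maximum-matching oracle on 1000
  random instances.
* Site absorption and junction snapping both break ties toward the smaller
  coordinate, making every collapse deterministic.
* Permutation p-values use the add-one estimator `(1 + #{|T*| >= |T|}) /
  (n_perm + 1)`, which is valid (super-uniform) under the null.
* Enrichment uses a 0.5 pseudocount on both numerator and denominator so
  motifs absent from the shuffles do not divide by zero.
* Degenerate inputs: empty read lists, empty samples, loci with zero counts
  in a tissue, and gene sets with fewer than two qualifying isoforms are
  skipped with a recorded reason rather than propagating NaNs.

# Problem sizes

The shipped tests and the acceptance script run, per invocation: a 53-truth
zero-noise panel (~60 genes), a 123-truth noisy panel (130 genes, five
events per category), a 700-locus DEI panel and 2000-locus DEG panels, and
a 600-gene modification panel with ten generator seeds at 1000 permutations
each. These sizes give stable rates (binomial standard errors of a few
percent or less) while keeping a full run in minutes on one CPU.

# Known limitations

* Cluster merging reconstructs a containment-style criterion; it is
  validated by truth recovery on synthetic data, not by bit-identity to any
  external clustering tool.
* The DEG test ignores biological dispersion between replicates (it pools
  them); with many replicates per tissue a dispersion-aware model would be
  preferable.
* Metagene rescaling interpolates linearly between bins; very short regions
  (close to one bin) are rendered as constants.
* The classifier reports one category per cluster by design; chains with
  several independent deviations receive the highest-priority label only,
  with the rest visible in the junction-level output rather than the label.
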