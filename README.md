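# nanotx

Isoform discovery, polyadenylation and RNA-modification profiling for
nanopore **direct RNA sequencing** (DRS).

DRS reads native mRNA molecules from the poly(A) tail inward: every read is
a full-length or 5'-degraded copy of one transcript, with reliable 3' ends,
noisy 5' ends, and a few nucleotides of splice-junction wobble from
alignment. `nanotx` turns spliced read alignments (BED12) plus a reference
annotation (GFF3) into:

* **isoform clusters** with per-sample counts — reads sharing a junction
  chain under a coordinate tolerance are grouped, and 5'-truncated reads are
  absorbed into their full-length isoform (support threshold ≥ 5 reads);
* **isoform categories** — each cluster is `known` or one of eleven novel
  categories (5'/3' extra or missing terminal exons, UTR extension or
  truncation, extra/missing internal exon, intron retention, novel
  junction, fusion), with fusion/readthrough transcripts typed into six
  structural classes;
* **poly(A) sites** — read 3' ends collapsed within 5 nt, kept at > 5-read
  support, matched across datasets within 5 nt, with hexamer-motif
  enrichment in the 50-nt upstream window scored against
  dinucleotide-shuffled backgrounds and positional occurrence in the
  canonical 14–24-nt signal zone;
* **differential calls** between two tissues — isoforms by a
  10-percentage-point shift in within-locus relative abundance, genes by
  CPM fold change > 2 with an exact conditional binomial test at
  BH-FDR < 0.05;
* **metagene modification profiles** — per-site modification fractions in
  transcript coordinates binned with the zero-fill ("w0") convention at
  5-nt resolution over 5'UTR/body/3'UTR, with permutation tests comparing
  gene sets (e.g. mobile mRNAs vs all mRNAs vs tRNA-like-structure genes)
  and a positional profile around the stop codon.

A fully deterministic synthetic-data module (`sim_config()`,
`simulate_dataset()`) generates genomes, annotations, noisy reads, count
panels and modification tables with planted ground truth for every one of
those stages, so the whole pipeline is testable end to end without any
external download. See the methods vignette
(`vignettes/nanotx-methods.Rmd`) for the models, parameter defaults and
design decisions.

## Worked example

The `analysis/` directory holds the numbered workflow. Step 01 simulates
130 genes with five planted events per novel category plus all six fusion
types (5622 reads over two seedling and two floral-bud samples) and writes
plain BED12/GFF3/FASTA/TSV under `results/data/`; the later steps consume
those files:

```sh
Rscript analysis/01_simulate_data.R
Rscript analysis/02_isoforms.R
Rscript analysis/03_apa.R
Rscript analysis/04_differential.R
Rscript analysis/05_modification.R
```

Step 02 (clustering + classification) prints:

```
5622 reads -> 123 clusters (support >= 5).
Planted novel isoforms correctly categorized: 100.0% (56/56)
Fusion types recovered: i, ii, iii, iv, v, vi
```

i.e. at the default noise level (geometric 5' truncation, ±1-nt junction
jitter, ±2-nt end wobble) every planted novel isoform receives its true
category and all six fusion classes are typed correctly. Step 03 prints

```
123 sites called; 100.0% of 123 planted sites recovered within 5 nt.
Planted hexamer rank: 1; present 14-24 nt upstream of 89.4% of sites.
```

— the planted T-rich hexamer tops the enrichment ranking against the
dinucleotide-shuffled background — and the per-sample poly(A) summary shows
floral-bud tails running longer than seedling tails (means ≈ 85 vs 68 nt)
with most tails under 100 nt. Step 04 reports DEI sensitivity 98.5% with a
2.7% false-call rate among null isoforms and 100% power on planted
four-fold DEGs; step 05 shows the mobile gene set m5C-enriched in every
region (permutation p ≈ 0.001) while the TLS sets show no enrichment, and
locates the planted adenine-modification peak within a few nt of the stop
codon.

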