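#!/usr/bin/env Rscript
# Generate the synthetic study dataset: a genome + annotation with planted
# novel-isoform and fusion events, four samples of noisy 3'-anchored spliced
# reads (two seedling, two floral-bud libraries), per-read poly(A) lengths,
# and planted poly(A)-signal hexamers. Writes standard formats under
# results/data/ so the downstream steps consume files, not R objects.

library(nanotx)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

events <- c(intron_retention = 5, extra_exon = 5, missing_exon = 5,
            five_extra = 5, three_extra = 5, five_missing = 5,
            three_missing = 5, extra_utr = 5, missing_utr = 5,
            new_junction = 5)
cfg <- sim_config(n_genes = 130, events = events, seed = 2024)
ds <- simulate_dataset(cfg)

write_genome(ds$genome, file.path(out, "genome.fa"))
write_gff3(ds$models, file.path(out, "annotation.gff3"))
for (s in cfg$samples$sample_id) {
  keep <- vapply(ds$reads, function(r) r$sample_id == s, logical(1))
  write_bed12(ds$reads[keep], file.path(out, paste0("reads_", s, ".bed")))
}
utils::write.table(ds$polya, file.path(out, "polya_lengths.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(ds$truth_table, file.path(out, "truth_isoforms.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(ds$truth_sites, file.path(out, "truth_polya_sites.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("Simulated %d genes, %d truth isoforms (%d planted novel, %d fusion reads),\n",
            cfg$n_genes, nrow(ds$truth_table),
            sum(!ds$truth_table$category %in% c("known", "fusion")),
            sum(ds$truth_table$category == "fusion")))
cat(sprintf("%d reads across %d samples; %d truth poly(A) sites.\n",
            length(ds$reads), nrow(cfg$samples), nrow(ds$truth_sites)))
cat("Outputs in", out, "\n")
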