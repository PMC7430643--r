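#!/usr/bin/env Rscript
# Cluster the simulated reads into isoforms, classify every cluster into
# "known", one of the eleven novel categories, or a fusion type, and score
# the calls against the planted truth.

library(nanotx)

data_dir <- "results/data"
out <- "results"
samples <- c("seedling1", "seedling2", "bud1", "bud2")

models <- read_gff3(file.path(data_dir, "annotation.gff3"))
reads <- unlist(lapply(samples, function(s)
  read_bed12(file.path(data_dir, paste0("reads_", s, ".bed")), s,
             control_seq = "ENO2")), recursive = FALSE)

clusters <- cluster_all_reads(reads, junction_tol = 5, end_window = 50,
                              min_support = 5)
ann <- annotation_index(models)
calls <- classify_all(clusters, ann)
write_bed12(clusters, file.path(out, "clusters.bed"))
utils::write.table(calls, file.path(out, "isoform_calls.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

truth <- utils::read.delim(file.path(data_dir, "truth_isoforms.tsv"))
truth_of <- vapply(clusters, function(c)
  names(sort(table(read_truth_id(unlist(c$read_ids))), decreasing = TRUE))[1], "")
tcat <- truth$category[match(truth_of, truth$truth_id)]
novel <- tcat != "known"

cat(sprintf("%d reads -> %d clusters (support >= 5).\n",
            length(reads), length(clusters)))
cat("Category table:\n")
print(table(calls$category))
cat(sprintf("Planted novel isoforms correctly categorized: %.1f%% (%d/%d)\n",
            100 * mean(calls$category[novel] == tcat[novel]),
            sum(calls$category[novel] == tcat[novel]), sum(novel)))
cat(sprintf("Fusion types recovered: %s\n",
            paste(sort(unique(calls$fusion_type[calls$fusion_type != "none"])),
                  collapse = ", ")))
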