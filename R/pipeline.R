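# End-to-end orchestration over a synthetic or user-supplied dataset, plus
# the PCR amplicon-size utility used to check unannotated genomic insertions.

#' Pipeline configuration
#'
#' Collects every stage threshold with its default: junction tolerance 5 nt,
#' isoform support >= 5 reads, poly(A)-site support strictly > 5 reads,
#' cross-dataset site shift 5 nt, 50-nt upstream motif scan with the
#' positional window at 14-24 nt, top 50 motifs, DEI threshold 10 percentage
#' points, DEG thresholds fold change > 2 at FDR < 0.05, metagene bin size
#' 5 nt with 50-nt minimum UTRs. The two read-support thresholds
#' (isoform `>= 5`, poly(A) site `> 5`) are deliberately separate keys.
#'
#' @param junction_tol,end_window,min_support Clustering parameters.
#' @param apa_min_support,site_shift,upstream_len,pos_near,pos_far,top_k APA
#'   parameters.
#' @param utr_tol,min_overlap Classification parameters.
#' @param dei_threshold,deg_lfc,deg_fdr Differential parameters.
#' @param bin_size,min_utr Metagene parameters.
#' @param control_seq Spike-in/control sequence name dropped at read load.
#' @param seed Master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(junction_tol = 5, end_window = 50, min_support = 5,
                            apa_min_support = 5, site_shift = 5,
                            upstream_len = 50, pos_near = 14, pos_far = 24,
                            top_k = 50, utr_tol = 20, min_overlap = 20,
                            dei_threshold = 0.10, deg_lfc = 1, deg_fdr = 0.05,
                            bin_size = 5, min_utr = 50,
                            control_seq = "ENO2", seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis over a dataset
#'
#' Stages run in dependency order: clustering, locus assignment and
#' classification, quantification, poly(A)-site calling with motif
#' enrichment, poly(A)-length summaries, differential isoform/gene calling
#' (two tissues, replicates pooled), and, when a modification table is
#' supplied, metagene set comparisons. Optional inputs skip their dependent
#' stages only. All tables are written as TSV under `out_dir` together with
#' a run manifest (per-stage record counts and the full parameter snapshot).
#'
#' @param dataset List with `reads`, `models`, and optionally `genome`,
#'   `polya`, `modtable`, `gene_sets`, `samples` (data.frame sample_id/
#'   tissue). [simulate_dataset()] output works directly.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisible list with all stage results.
#' @export
run_all <- function(dataset, config = pipeline_config(), out_dir = NULL) {
  stopifnot(!is.null(dataset$reads), !is.null(dataset$models))
  manifest <- list()
  note <- function(stage, n) manifest[[stage]] <<- n

  ann <- annotation_index(dataset$models)
  clusters <- cluster_all_reads(dataset$reads, config$junction_tol,
                                config$end_window, config$min_support)
  note("clusters", length(clusters))

  calls <- classify_all(clusters, ann, config$junction_tol, config$utr_tol,
                        config$min_overlap)
  note("calls", nrow(calls))

  locus_of <- stats::setNames(
    ifelse(calls$category %in% c("fusion", "intergenic", "antisense"),
           NA_character_, vapply(strsplit(calls$loci, ","), `[`, "", 1)),
    calls$cluster_id)
  counts <- quantify(clusters, locus_of)
  note("quantified_loci", nrow(counts$locus_counts))

  sites <- call_sites(dataset$reads, config$apa_min_support)
  note("apa_sites", nrow(sites))
  motifs <- NULL; positional <- NULL
  if (!is.null(dataset$genome) && nrow(sites) > 0) {
    motifs <- hexamer_enrichment(sites, dataset$genome, config$upstream_len,
                                 config$top_k, seed = config$seed)
    positional <- positional_occurrence(utils::head(motifs$motif, 10), sites,
                                        dataset$genome, config$pos_near,
                                        config$pos_far)
  }

  polya_summary <- if (!is.null(dataset$polya)) summarize_polya(dataset$polya)

  dei <- NULL; deg <- NULL; overlap <- NULL
  samples <- dataset$samples
  if (is.null(samples) && !is.null(dataset$truth_table))
    samples <- data.frame(sample_id = c("seedling1", "seedling2", "bud1", "bud2"),
                          tissue = c("seedling", "seedling", "bud", "bud"))
  if (!is.null(samples) && nrow(counts$cluster_counts) > 0) {
    tis <- unique(samples$tissue)
    cc <- counts$cluster_counts
    pool <- function(t) rowSums(cc[, samples$sample_id[samples$tissue == t],
                                   drop = FALSE])
    dei_in <- data.frame(cluster_id = cc$cluster_id,
                         locus_id = unname(locus_of[cc$cluster_id]),
                         count_a = pool(tis[1]), count_b = pool(tis[2]))
    dei <- call_dei(dei_in[!is.na(dei_in$locus_id), ], config$min_support,
                    config$dei_threshold)
    lc <- counts$locus_counts
    if (nrow(lc) > 0 && all(colSums(lc[, samples$sample_id]) > 0)) {
      mat <- as.matrix(lc[, samples$sample_id])
      rownames(mat) <- lc$locus_id
      deg <- call_deg(mat, samples, config$deg_lfc, config$deg_fdr)
      overlap <- overlap_deg_dei(deg$locus_id[deg$is_deg],
                                 unique(dei$locus_id[dei$is_dei]))
    }
  }

  profiles <- NULL; set_cmp <- NULL
  if (!is.null(dataset$modtable) && !is.null(dataset$gene_sets)) {
    set_cmp <- compare_sets(dataset$modtable, dataset$models,
                            dataset$gene_sets, seed = config$seed,
                            min_utr = config$min_utr)
    profiles <- lapply(dataset$gene_sets, function(gs)
      metagene_profile(dataset$modtable, dataset$models, gs,
                       config$bin_size, config$min_utr))
  }

  res <- list(clusters = clusters, calls = calls, counts = counts,
              sites = sites, motifs = motifs, positional = positional,
              polya_summary = polya_summary, dei = dei, deg = deg,
              deg_dei_overlap = overlap, profiles = profiles,
              set_comparison = set_cmp, manifest = manifest, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_bed12(clusters, file.path(out_dir, "clusters.bed"))
    write_tsv(calls, file.path(out_dir, "isoform_calls.tsv"))
    write_tsv(counts$cluster_counts, file.path(out_dir, "cluster_counts.tsv"))
    if (nrow(counts$locus_counts))
      write_tsv(counts$locus_counts, file.path(out_dir, "locus_counts.tsv"))
    write_tsv(sites, file.path(out_dir, "apa_sites.tsv"))
    if (!is.null(motifs)) write_tsv(motifs, file.path(out_dir, "apa_motifs.tsv"))
    if (!is.null(positional))
      write_tsv(positional, file.path(out_dir, "apa_motif_positions.tsv"))
    if (!is.null(polya_summary))
      write_tsv(polya_summary, file.path(out_dir, "polya_summary.tsv"))
    if (!is.null(dei)) write_tsv(dei, file.path(out_dir, "dei.tsv"))
    if (!is.null(deg)) write_tsv(deg, file.path(out_dir, "deg.tsv"))
    if (!is.null(set_cmp)) write_tsv(set_cmp, file.path(out_dir, "mod_set_comparison.tsv"))
    mf <- data.frame(stage = names(manifest), n_records = unlist(manifest))
    write_tsv(mf, file.path(out_dir, "manifest.tsv"))
    cfg <- data.frame(parameter = names(unclass(config)),
                      value = vapply(unclass(config), function(x)
                        paste(x, collapse = ","), ""))
    write_tsv(cfg, file.path(out_dir, "parameters.tsv"))
  }
  invisible(res)
}

#' PCR amplicon size, optionally with an unannotated insertion
#'
#' Locates the forward primer and the reverse primer (reverse-complemented)
#' on the supplied sequence(s); both must match exactly once, with the
#' forward site upstream. The product length spans the 5' end of the forward
#' primer to the 5' end of the reverse primer. An insertion contributes its
#' length only when its position falls strictly inside the product, modeling
#' genomic sequence missing from the assembly the primers were designed on.
#'
#' @param genome Named character vector of sequences (or a single string).
#' @param primer_fwd,primer_rev Primer sequences, 5'->3'.
#' @param insertion Optional `list(position = <0-based coordinate>,
#'   sequence = <string>)`.
#' @return Product length in bp.
#' @export
amplicon_length <- function(genome, primer_fwd, primer_rev, insertion = NULL) {
  if (is.null(names(genome))) names(genome) <- sprintf("seq%d", seq_along(genome))
  hits_f <- NULL; hits_r <- NULL
  for (nm in names(genome)) {
    subj <- Biostrings::DNAString(genome[[nm]])
    f <- Biostrings::matchPattern(primer_fwd, subj)
    r <- Biostrings::matchPattern(revcomp(primer_rev), subj)
    if (length(f)) hits_f <- rbind(hits_f, data.frame(seq = nm, start = BiocGenerics::start(f)))
    if (length(r)) hits_r <- rbind(hits_r, data.frame(seq = nm, end = BiocGenerics::end(r)))
  }
  nf <- if (is.null(hits_f)) 0L else nrow(hits_f)
  nr <- if (is.null(hits_r)) 0L else nrow(hits_r)
  if (nf != 1L || nr != 1L)
    stop(sprintf("amplicon_length: primers must match uniquely (forward: %d hit(s), reverse: %d hit(s))",
                 nf, nr))
  if (hits_f$seq != hits_r$seq)
    stop("amplicon_length: primers match different sequences")
  if (hits_f$start >= hits_r$end)
    stop("amplicon_length: forward primer must lie upstream of the reverse primer")
  len <- hits_r$end - hits_f$start + 1L
  if (!is.null(insertion)) {
    p <- insertion$position                     # 0-based insertion point
    if (p > hits_f$start - 1L && p < hits_r$end)
      len <- len + nchar(insertion$sequence)
  }
  len
}
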