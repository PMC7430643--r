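# Differential expression between two tissues from isoform/locus counts.
# Isoform-level calls (DEI) use the within-locus relative-abundance shift;
# gene-level calls (DEG) use a counts-per-million fold change with an exact
# conditional binomial test against the library-size ratio and BH-FDR.

#' Call differentially expressed isoforms
#'
#' An isoform's relative abundance in a tissue is its read count divided by
#' the total count of all retained isoforms at its locus. An isoform is a DEI
#' when that relative abundance changes by more than `threshold` between the
#' two tissues -- by default 0.10 read as percentage points (set
#' `relative = TRUE` for the relative-change reading). Isoforms with total
#' support below `min_support` are excluded from both numerator and
#' denominator; loci with zero retained count in either tissue are skipped.
#' An auxiliary two-proportion z-test column is provided but does not enter
#' the DEI rule.
#'
#' @param counts data.frame with columns cluster_id, locus_id, count_a,
#'   count_b (per-tissue pooled counts).
#' @param min_support Minimum total count (both tissues) to retain an isoform.
#' @param threshold Relative-abundance change threshold (default 0.10).
#' @param relative If `TRUE`, call `|rel_a - rel_b| / rel_a > threshold`
#'   instead of the percentage-point difference.
#' @return data.frame with rel_a, rel_b, delta_pp, is_dei, p_ztest per
#'   retained isoform.
#' @export
call_dei <- function(counts, min_support = 5, threshold = 0.10,
                     relative = FALSE) {
  stopifnot(all(c("cluster_id", "locus_id", "count_a", "count_b") %in% names(counts)))
  if (anyNA(counts$locus_id)) stop("call_dei: unknown locus id")
  keep <- counts$count_a + counts$count_b >= min_support
  x <- counts[keep, , drop = FALSE]
  tot_a <- tapply(x$count_a, x$locus_id, sum)
  tot_b <- tapply(x$count_b, x$locus_id, sum)
  ok_locus <- names(tot_a)[tot_a > 0 & tot_b > 0]
  x <- x[x$locus_id %in% ok_locus, , drop = FALSE]
  x$rel_a <- x$count_a / as.numeric(tot_a[x$locus_id])
  x$rel_b <- x$count_b / as.numeric(tot_b[x$locus_id])
  x$delta_pp <- x$rel_b - x$rel_a
  x$is_dei <- if (relative) abs(x$delta_pp) / pmax(x$rel_a, 1e-12) > threshold
              else abs(x$delta_pp) > threshold
  na_ <- as.numeric(tot_a[x$locus_id]); nb_ <- as.numeric(tot_b[x$locus_id])
  p_pool <- (x$count_a + x$count_b) / (na_ + nb_)
  se <- sqrt(pmax(p_pool * (1 - p_pool) * (1 / na_ + 1 / nb_), 1e-300))
  x$p_ztest <- 2 * stats::pnorm(-abs((x$rel_a - x$rel_b) / se))
  rownames(x) <- NULL
  x
}

#' Call differentially expressed genes
#'
#' Counts are normalized to counts per million (CPM) per sample; the log2
#' fold change contrasts tissue-mean CPM with a 0.5 pseudocount. The p-value
#' is an exact two-sided binomial test of the pooled tissue counts against
#' the library-size ratio (the conditional test of equal relative abundance);
#' FDR is Benjamini-Hochberg over all tested loci. A gene is a DEG when
#' |log2FC| > 1 and FDR < 0.05. A fold-change sign-consistency flag across
#' replicate pairs is emitted as a QC column.
#'
#' @param counts Numeric matrix or data.frame, loci x samples.
#' @param design data.frame with sample_id (matching `colnames(counts)`) and
#'   tissue (exactly two levels; the contrast is second tissue vs first, in
#'   the order of first appearance).
#' @param lfc_threshold,fdr_threshold DEG thresholds (defaults 1 and 0.05,
#'   i.e. fold change > 2 at FDR < 0.05).
#' @return data.frame per locus: cpm columns, log2fc, pvalue, fdr, is_deg,
#'   sign_consistent.
#' @export
call_deg <- function(counts, design, lfc_threshold = 1, fdr_threshold = 0.05) {
  counts <- as.matrix(counts)
  stopifnot(identical(sort(colnames(counts)), sort(design$sample_id)))
  counts <- counts[, design$sample_id, drop = FALSE]
  tissues <- unique(design$tissue)
  stopifnot(length(tissues) == 2)
  lib <- colSums(counts)
  if (any(lib == 0)) stop("call_deg: zero total count in a sample")
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  ix_a <- design$tissue == tissues[1]
  ix_b <- design$tissue == tissues[2]
  mean_a <- rowMeans(cpm[, ix_a, drop = FALSE])
  mean_b <- rowMeans(cpm[, ix_b, drop = FALSE])
  log2fc <- log2((mean_b + 0.5) / (mean_a + 0.5))
  a <- rowSums(counts[, ix_a, drop = FALSE])
  b <- rowSums(counts[, ix_b, drop = FALSE])
  p0 <- sum(lib[ix_a]) / sum(lib)
  pval <- vapply(seq_len(nrow(counts)), function(i) {
    n <- a[i] + b[i]
    if (n == 0) return(NA_real_)
    stats::binom.test(a[i], n, p0)$p.value
  }, numeric(1))
  fdr <- rep(NA_real_, length(pval))
  tested <- !is.na(pval)
  fdr[tested] <- stats::p.adjust(pval[tested], method = "BH")
  # replicate QC: do all replicate-pair contrasts agree in sign?
  sign_consistent <- rep(NA, nrow(counts))
  if (sum(ix_a) >= 1 && sum(ix_b) >= 1) {
    pairs <- expand.grid(i = which(ix_a), j = which(ix_b))
    signs <- vapply(seq_len(nrow(pairs)), function(k)
      sign(log2((cpm[, pairs$j[k]] + 0.5) / (cpm[, pairs$i[k]] + 0.5))),
      numeric(nrow(counts)))
    if (is.null(dim(signs))) signs <- matrix(signs, nrow = nrow(counts))
    sign_consistent <- apply(signs, 1, function(s) all(s >= 0) || all(s <= 0))
  }
  out <- data.frame(locus_id = rownames(counts), cpm_a = unname(mean_a),
                    cpm_b = unname(mean_b), count_a = unname(a),
                    count_b = unname(b), log2fc = unname(log2fc),
                    pvalue = pval, fdr = fdr,
                    sign_consistent = unname(sign_consistent),
                    row.names = NULL)
  out$is_deg <- !is.na(out$fdr) & abs(out$log2fc) > lfc_threshold &
    out$fdr < fdr_threshold
  rownames(out) <- NULL
  out
}

#' Overlap of DEG and DEI gene sets
#'
#' @param deg_genes Character vector of DEG locus ids.
#' @param dei_genes Character vector of loci carrying at least one DEI.
#' @return data.frame with Venn counts and the fraction of each set that
#'   overlaps the other.
#' @export
overlap_deg_dei <- function(deg_genes, dei_genes) {
  deg_genes <- unique(deg_genes); dei_genes <- unique(dei_genes)
  both <- intersect(deg_genes, dei_genes)
  data.frame(n_deg = length(deg_genes), n_dei_genes = length(dei_genes),
             n_both = length(both),
             deg_only = length(setdiff(deg_genes, both)),
             dei_only = length(setdiff(dei_genes, both)),
             frac_of_dei = if (length(dei_genes)) length(both) / length(dei_genes) else 0,
             frac_of_deg = if (length(deg_genes)) length(both) / length(deg_genes) else 0)
}
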