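# Metagene modification profiles and gene-set comparisons. Per-site
# modification fractions live in spliced transcript coordinates; profiles
# use the "w0" convention: positions without a reported site contribute zero
# to their bin, so binned values are coverage-normalized means rather than
# means over reported sites only.

utr_regions <- function(m) {
  L <- chain_len(m$chain)
  list(utr5 = c(0, m$utr5_len), body = c(m$utr5_len, L - m$utr3_len),
       utr3 = c(L - m$utr3_len, L), L = L)
}

# w0-binned values of one region: consecutive bin_size-nt bins,
# bin value = sum of site fractions in bin / bin_size
bin_region <- function(frac_vec, from, to, bin_size) {
  if (to <= from) return(numeric(0))
  v <- frac_vec[(from + 1):to]
  idx <- ceiling(seq_along(v) / bin_size)
  as.numeric(tapply(v, idx, sum)) / bin_size
}

rescale_bins <- function(vals, n_out) {
  if (length(vals) == 0) return(rep(NA_real_, n_out))
  if (length(vals) == 1) return(rep(vals, n_out))
  stats::approx(x = seq(0, 1, length.out = length(vals)), y = vals,
                xout = seq(0, 1, length.out = n_out))$y
}

#' Metagene modification profile of a gene set
#'
#' For every qualifying isoform (both UTRs longer than `min_utr` nt, gene in
#' `gene_set`), each region (5'UTR, body, 3'UTR) is cut into consecutive
#' `bin_size`-nt bins; a bin's value is the sum of reported site fractions in
#' the bin divided by `bin_size` (unreported positions count as zero). The
#' per-region bin series is rescaled to a fixed length by linear
#' interpolation and averaged over isoforms.
#'
#' @param modtable data.frame from [read_mod_table()] /
#'   [simulate_mod_fractions()].
#' @param models Named list of [transcript_model()].
#' @param gene_set Character vector of gene ids (use all genes for the total
#'   profile).
#' @param bin_size Bin width in nt (default 5).
#' @param min_utr Strict minimum UTR length in nt (default 50).
#' @param out_bins Output bins per region, `c(utr5, body, utr3)`.
#' @param modtype Modification track to profile.
#' @return List of class `metagene_profile`: `utr5`, `body`, `utr3` numeric
#'   vectors, `n_isoforms`, `set_label`.
#' @export
metagene_profile <- function(modtable, models, gene_set, bin_size = 5,
                             min_utr = 50, out_bins = c(20, 60, 20),
                             modtype = "m5C") {
  mt <- modtable[modtable$modtype == modtype, , drop = FALSE]
  sites <- split(mt[c("transcript_pos", "fraction")], mt$transcript_id)
  acc <- list(utr5 = NULL, body = NULL, utr3 = NULL)
  n <- 0L
  for (m in models) {
    if (!(m$gene_id %in% gene_set)) next
    if (m$utr5_len <= min_utr || m$utr3_len <= min_utr) next
    reg <- utr_regions(m)
    v <- numeric(reg$L)
    s <- sites[[m$transcript_id]]
    if (!is.null(s)) {
      if (any(s$transcript_pos >= reg$L))
        stop("metagene_profile: site position beyond transcript length for ",
             m$transcript_id)
      v[s$transcript_pos + 1] <- s$fraction
    }
    n <- n + 1L
    acc$utr5 <- rbind(acc$utr5, rescale_bins(
      bin_region(v, reg$utr5[1], reg$utr5[2], bin_size), out_bins[1]))
    acc$body <- rbind(acc$body, rescale_bins(
      bin_region(v, reg$body[1], reg$body[2], bin_size), out_bins[2]))
    acc$utr3 <- rbind(acc$utr3, rescale_bins(
      bin_region(v, reg$utr3[1], reg$utr3[2], bin_size), out_bins[3]))
  }
  structure(list(set_label = attr(gene_set, "label"),
                 utr5 = if (n) colMeans(acc$utr5) else rep(NA_real_, out_bins[1]),
                 body = if (n) colMeans(acc$body) else rep(NA_real_, out_bins[2]),
                 utr3 = if (n) colMeans(acc$utr3) else rep(NA_real_, out_bins[3]),
                 n_isoforms = n),
            class = "metagene_profile")
}

#' Per-isoform per-region modification means
#'
#' The coverage-normalized (w0) mean is the summed site fraction divided by
#' region length; the per-site mean averages reported sites only. Both views
#' are returned.
#'
#' @inheritParams metagene_profile
#' @return data.frame: transcript_id, gene_id, utr5, body, utr3 (w0 means),
#'   site_mean.
#' @export
region_means <- function(modtable, models, min_utr = 50, modtype = "m5C") {
  mt <- modtable[modtable$modtype == modtype, , drop = FALSE]
  sites <- split(mt[c("transcript_pos", "fraction")], mt$transcript_id)
  acc <- vector("list", length(models)); k <- 0L
  for (m in models) {
    if (m$utr5_len <= min_utr || m$utr3_len <= min_utr) next
    reg <- utr_regions(m)
    s <- sites[[m$transcript_id]]
    pos <- if (is.null(s)) numeric(0) else s$transcript_pos
    f <- if (is.null(s)) numeric(0) else s$fraction
    wsum <- function(r) sum(f[pos >= r[1] & pos < r[2]]) / max(1, r[2] - r[1])
    k <- k + 1L
    acc[[k]] <- data.frame(
      transcript_id = m$transcript_id, gene_id = m$gene_id,
      utr5 = wsum(reg$utr5), body = wsum(reg$body), utr3 = wsum(reg$utr3),
      site_mean = if (length(f)) mean(f) else 0)
  }
  out <- do.call(rbind, acc[seq_len(k)])
  rownames(out) <- NULL
  out
}

#' Compare modification levels between gene sets
#'
#' For each set, the statistic per region is the difference between the mean
#' per-isoform w0 modification level of set members and that of all
#' qualifying isoforms. The null is built by relabeling: `n_perm` random
#' subsets of the same size drawn from all qualifying isoforms. Two-sided
#' permutation p-values.
#'
#' @param modtable,models,min_utr,modtype As in [metagene_profile()].
#' @param sets Named list of gene-id vectors (e.g. mobile, tls_body, ...);
#'   a set named `total` is ignored as a contrast.
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed for the relabeling.
#' @return data.frame: set, region, n_set, diff, p_perm.
#' @export
compare_sets <- function(modtable, models, sets, n_perm = 1000, seed = 1,
                         min_utr = 50, modtype = "m5C") {
  rm_ <- region_means(modtable, models, min_utr, modtype)
  set.seed(seed)
  out <- NULL
  for (nm in setdiff(names(sets), "total")) {
    member <- rm_$gene_id %in% sets[[nm]]
    k <- sum(member)
    if (k < 2) { warning("compare_sets: set ", nm, " has <2 qualifying isoforms; skipped"); next }
    for (region in c("utr5", "body", "utr3")) {
      x <- rm_[[region]]
      obs <- mean(x[member]) - mean(x)
      perm <- vapply(seq_len(n_perm), function(i)
        mean(x[sample.int(length(x), k)]) - mean(x), numeric(1))
      p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
      out <- rbind(out, data.frame(set = nm, region = region, n_set = k,
                                   diff = obs, p_perm = p))
    }
  }
  rownames(out) <- NULL
  out
}

#' Positional modification profile around the stop codon
#'
#' Mean site fraction (w0 zero-fill) at each transcript-coordinate offset
#' from the stop codon; offset 0 is the first 3'UTR base. Only isoforms with
#' a non-empty 3'UTR contribute, and each offset averages over the isoforms
#' long enough to cover it.
#'
#' @param modtable Site table (typically the adenine/`deNovoA` track).
#' @param models Named list of transcript models.
#' @param window Half-width of the offset window in nt (default 200).
#' @param modtype Modification track (default `"deNovoA"`).
#' @return data.frame: offset, mean_fraction, n_isoforms.
#' @export
stopcodon_meta <- function(modtable, models, window = 200, modtype = "deNovoA") {
  mt <- modtable[modtable$modtype == modtype, , drop = FALSE]
  sites <- split(mt[c("transcript_pos", "fraction")], mt$transcript_id)
  offs <- seq(-window, window)
  total <- numeric(length(offs))
  nn <- numeric(length(offs))
  for (m in models) {
    if (m$utr3_len <= 0) next
    L <- chain_len(m$chain)
    stop_pos <- L - m$utr3_len
    valid <- stop_pos + offs >= 0 & stop_pos + offs < L
    v <- numeric(length(offs))
    s <- sites[[m$transcript_id]]
    if (!is.null(s)) {
      o <- s$transcript_pos - stop_pos
      keep <- o >= -window & o <= window
      v[o[keep] + window + 1] <- s$fraction[keep]
    }
    total <- total + v * valid
    nn <- nn + valid
  }
  data.frame(offset = offs, mean_fraction = ifelse(nn > 0, total / nn, NA_real_),
             n_isoforms = nn)
}

#' Overlap report for two gene sets
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @return data.frame with the intersection count and the fraction of each
#'   set covered by the other.
#' @export
set_overlap_report <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  n <- length(intersect(set_a, set_b))
  data.frame(n_a = length(set_a), n_b = length(set_b), n_both = n,
             frac_of_a = if (length(set_a)) n / length(set_a) else 0,
             frac_of_b = if (length(set_b)) n / length(set_b) else 0)
}
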