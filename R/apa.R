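# Alternative polyadenylation: site calling from read 3' ends, cross-dataset
# site matching, upstream hexamer-motif enrichment against dinucleotide-
# shuffled backgrounds, and positional motif occurrence in the canonical
# 14-24 nt signal zone.

#' Call poly(A) sites from read 3' ends
#'
#' Read 3' termini are collapsed at exact positions per chromosome/strand;
#' a position within `absorb` nt of a higher-support position is absorbed
#' into it (supports summed, ties broken toward the smaller coordinate);
#' sites with support strictly greater than `min_site_support` are retained.
#' Before the support filter, the summed site supports conserve the number
#' of contributing read ends.
#'
#' @param reads List of [read_alignment()].
#' @param min_site_support Strict lower bound on retained support (default 5:
#'   a site needs > 5 reads).
#' @param absorb Absorption radius in nt (default 5, matching the
#'   cross-dataset shift).
#' @return data.frame: chrom, strand, position, support (and per-sample
#'   support columns).
#' @export
call_sites <- function(reads, min_site_support = 5, absorb = 5) {
  if (length(reads) == 0L)
    return(data.frame(chrom = character(0), strand = character(0),
                      position = numeric(0), support = numeric(0)))
  df <- data.frame(
    chrom = vapply(reads, function(r) r$chain$chrom, ""),
    strand = vapply(reads, function(r) r$chain$strand, ""),
    pos = vapply(reads, `[[`, numeric(1), "three_prime_end"),
    sample = vapply(reads, `[[`, "", "sample_id"))
  samples <- sort(unique(df$sample))
  out <- NULL
  for (p in split(df, paste(df$chrom, df$strand))) {
    tab <- table(p$pos)
    pos <- as.numeric(names(tab)); supp <- as.vector(tab)
    o <- order(-supp, pos)
    pos <- pos[o]; supp <- supp[o]
    site_of <- rep(NA_integer_, length(pos))
    for (i in seq_along(pos)) {
      if (!is.na(site_of[i])) next
      hit <- which(is.na(site_of) & abs(pos - pos[i]) <= absorb)
      site_of[hit] <- i
    }
    for (s in unique(site_of)) {
      members <- pos[site_of == s]
      total <- sum(supp[site_of == s])
      persample <- vapply(samples, function(sm)
        sum(p$pos %in% members & p$sample == sm), numeric(1))
      out <- rbind(out, cbind(
        data.frame(chrom = p$chrom[1], strand = p$strand[1], position = pos[s],
                   support = total),
        as.data.frame(as.list(stats::setNames(persample, samples)))))
    }
  }
  out <- out[out$support > min_site_support, , drop = FALSE]
  out <- out[order(out$chrom, out$strand, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match two poly(A)-site sets
#'
#' 1:1 nearest matching within `shift` nt on the same chromosome and strand
#' (sites shifted by at most `shift` are identified as the same site).
#' Matched pairs plus the unique remainders partition both inputs.
#'
#' @param a,b data.frames with chrom, strand, position.
#' @param shift Maximum positional shift in nt (default 5).
#' @return List with `matched` (data.frame of index pairs and positions),
#'   `unique_to_a`, `unique_to_b` (row indices into `a`/`b`).
#' @export
match_site_sets <- function(a, b, shift = 5) {
  stopifnot(shift >= 0)
  ia <- integer(0); ib <- integer(0)
  for (key in unique(paste(a$chrom, a$strand))) {
    sa <- which(paste(a$chrom, a$strand) == key)
    sb <- which(paste(b$chrom, b$strand) == key)
    if (!length(sa) || !length(sb)) next
    sa <- sa[order(a$position[sa])]
    sb <- sb[order(b$position[sb])]
    i <- 1L; j <- 1L
    while (i <= length(sa) && j <= length(sb)) {
      d <- a$position[sa[i]] - b$position[sb[j]]
      if (abs(d) <= shift) {
        ia <- c(ia, sa[i]); ib <- c(ib, sb[j]); i <- i + 1L; j <- j + 1L
      } else if (d < 0) i <- i + 1L else j <- j + 1L
    }
  }
  list(matched = data.frame(index_a = ia, index_b = ib,
                            position_a = a$position[ia],
                            position_b = b$position[ib]),
       unique_to_a = setdiff(seq_len(nrow(a)), ia),
       unique_to_b = setdiff(seq_len(nrow(b)), ib))
}

## ---- dinucleotide-preserving shuffle (Altschul-Erickson) -------------------
## Random Eulerian rearrangement of the doublet graph: preserves the exact
## dinucleotide counts of each window, hence its local base composition.
dinuc_shuffle <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  if (n < 3) return(seq)
  verts <- unique(s)
  if (length(verts) == 1) return(seq)
  edges <- split(s[-1], factor(s[-n], levels = verts))  # out-edges per vertex
  last <- s[n]
  for (attempt in 1:100) {
    # pick a random candidate last-edge per vertex (except the final vertex)
    last_edge <- vapply(verts, function(v) {
      e <- edges[[v]]
      if (v == last || length(e) == 0) NA_character_
      else e[sample.int(length(e), 1)]
    }, character(1))
    # the chosen last edges must form a tree rooted at the final vertex
    ok <- TRUE
    for (v in verts) {
      if (v == last || is.na(last_edge[[v]])) next
      seen <- v; cur <- v
      repeat {
        cur <- last_edge[[cur]]
        if (is.na(cur)) { ok <- FALSE; break }
        if (cur == last) break
        if (cur %in% seen) { ok <- FALSE; break }
        seen <- c(seen, cur)
      }
      if (!ok) break
    }
    if (!ok) next
    # shuffle remaining edges, append the designated last edge
    sh <- edges
    for (v in verts) {
      e <- sh[[v]]
      if (!is.na(last_edge[[v]])) {
        drop1 <- match(last_edge[[v]], e)
        e <- e[-drop1]
      }
      e <- if (length(e) > 1) e[sample.int(length(e))] else e
      if (!is.na(last_edge[[v]])) e <- c(e, last_edge[[v]])
      sh[[v]] <- e
    }
    # walk the Eulerian path
    out <- character(n)
    out[1] <- s[1]
    ptr <- stats::setNames(rep(1L, length(verts)), verts)
    cur <- s[1]
    for (i in 2:n) {
      nxt <- sh[[cur]][ptr[[cur]]]
      ptr[[cur]] <- ptr[[cur]] + 1L
      out[i] <- nxt
      cur <- nxt
    }
    return(paste(out, collapse = ""))
  }
  seq
}

count_windows_with_motifs <- function(windows, k = 6) {
  # observed windows-containing counts for every k-mer present
  counts <- new.env(hash = TRUE)
  for (w in windows) {
    n <- nchar(w)
    if (n < k) next
    kmers <- unique(substring(w, 1:(n - k + 1), k:n))
    for (m in kmers) {
      v <- get0(m, envir = counts, ifnotfound = 0)
      assign(m, v + 1, envir = counts)
    }
  }
  ls_m <- ls(counts)
  stats::setNames(vapply(ls_m, function(m) get(m, envir = counts), numeric(1)), ls_m)
}

#' Hexamer enrichment upstream of poly(A) sites
#'
#' Scans the `upstream_len`-nt window upstream of each site for all hexamers.
#' `observed` is the number of windows containing a motif at least once;
#' `expected` is the mean of the same count over `n_shuffles`
#' dinucleotide-shuffled copies of the window set (shuffling preserves each
#' window's dinucleotide composition, so U-richness of 3'UTR sequence does
#' not masquerade as signal); `enrichment = (observed + 0.5) /
#' (expected + 0.5)`. Motifs rank by enrichment (ties by observed, then
#' lexicographic); the raw observed count provides the frequency view.
#'
#' @param sites data.frame with chrom, strand, position.
#' @param genome Named character vector of chromosome sequences.
#' @param upstream_len Window length (default 50).
#' @param top_k Number of motifs returned (default 50).
#' @param n_shuffles Number of shuffled window sets (default 20).
#' @param seed Seed for the shuffles.
#' @return data.frame: motif, observed, expected, enrichment, rank (by
#'   enrichment) and freq_rank (by observed); `n_windows` attribute gives the
#'   number of usable windows (off-chromosome windows are skipped).
#' @export
hexamer_enrichment <- function(sites, genome, upstream_len = 50, top_k = 50,
                               n_shuffles = 20, seed = 1) {
  windows <- vapply(seq_len(nrow(sites)), function(i)
    upstream_window(genome, sites$chrom[i], sites$strand[i], sites$position[i],
                    upstream_len), character(1))
  skipped <- sum(is.na(windows))
  windows <- windows[!is.na(windows)]
  obs <- count_windows_with_motifs(windows)

  set.seed(seed)
  exp_acc <- new.env(hash = TRUE)
  for (r in seq_len(n_shuffles)) {
    sh <- vapply(windows, dinuc_shuffle, character(1), USE.NAMES = FALSE)
    cs <- count_windows_with_motifs(sh)
    for (m in names(cs)) {
      v <- get0(m, envir = exp_acc, ifnotfound = 0)
      assign(m, v + cs[[m]], envir = exp_acc)
    }
  }
  motifs <- union(names(obs), ls(exp_acc))
  observed <- vapply(motifs, function(m) if (m %in% names(obs)) obs[[m]] else 0, numeric(1))
  expected <- vapply(motifs, function(m)
    get0(m, envir = exp_acc, ifnotfound = 0) / n_shuffles, numeric(1))
  enr <- (observed + 0.5) / (expected + 0.5)
  o <- order(-enr, -observed, motifs)
  out <- data.frame(motif = motifs[o], observed = observed[o],
                    expected = expected[o], enrichment = enr[o],
                    rank = seq_along(o))
  out$freq_rank <- rank(-out$observed, ties.method = "min")
  attr(out, "n_windows") <- length(windows)
  attr(out, "n_skipped") <- skipped
  utils::head(out, top_k)
}

#' Positional motif occurrence in the poly(A) signal zone
#'
#' Counts, per motif, the sites whose upstream sequence contains the motif
#' starting between `near` and `far` nt upstream of the 3' end (defaults
#' 14-24 nt, the canonical signal placement).
#'
#' @param motifs Character vector of motifs.
#' @param sites data.frame with chrom, strand, position.
#' @param genome Named character vector.
#' @param near,far Offset bounds in nt upstream of the site (motif start).
#' @return data.frame: motif, n_sites, fraction.
#' @export
positional_occurrence <- function(motifs, sites, genome, near = 14, far = 24) {
  stopifnot(near <= far)
  w <- nchar(motifs[1])
  windows <- vapply(seq_len(nrow(sites)), function(i)
    upstream_window(genome, sites$chrom[i], sites$strand[i], sites$position[i],
                    far), character(1))
  windows <- windows[!is.na(windows)]
  counts <- vapply(motifs, function(m) {
    sum(vapply(windows, function(win) {
      # window index len-o (0-based) is offset o upstream; o in [near, far]
      starts <- nchar(win) - seq(far, near) + 1L
      starts <- starts[starts >= 1 & starts + w - 1 <= nchar(win)]
      any(substring(win, starts, starts + w - 1) == m)
    }, logical(1)))
  }, numeric(1))
  data.frame(motif = motifs, n_sites = as.numeric(counts),
             fraction = as.numeric(counts) / max(1, length(windows)))
}

#' Summarize per-read poly(A) lengths per sample
#'
#' @param polya data.frame with read_id, sample_id, polya_len.
#' @param samples Optional sample labels; samples absent from the table get
#'   a row with n = 0 and NA statistics.
#' @return data.frame per sample: n, mean, median, fraction shorter than
#'   100 nt (NA statistics for empty samples).
#' @export
summarize_polya <- function(polya, samples = NULL) {
  if (any(polya$polya_len < 0, na.rm = TRUE))
    stop("summarize_polya: negative poly(A) length")
  if (is.null(samples)) samples <- sort(unique(polya$sample_id))
  if (length(samples) == 0L)
    return(data.frame(sample_id = character(0), n = integer(0),
                      mean = numeric(0), median = numeric(0),
                      frac_lt_100 = numeric(0)))
  do.call(rbind, lapply(samples, function(s) {
    x <- polya$polya_len[polya$sample_id == s & !is.na(polya$polya_len)]
    data.frame(sample_id = s, n = length(x),
               mean = if (length(x)) mean(x) else NA_real_,
               median = if (length(x)) stats::median(x) else NA_real_,
               frac_lt_100 = if (length(x)) mean(x < 100) else NA_real_)
  }))
}
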