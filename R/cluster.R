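# Read-to-isoform clustering with per-sample quantification. Reads sharing a
# junction chain (under a coordinate tolerance) are grouped, 5'-truncated
# groups are absorbed into their full-length parent, and clusters below the
# read-support threshold are discarded.

# Snap jittered junctions to canonical coordinates: unique (donor, acceptor)
# pairs are visited in order of decreasing support (ties toward smaller
# coordinates); each unassigned pair within `tol` of the visited pair (both
# ends) adopts its coordinates. Returns a data.frame keyed by "donor:acceptor"
# with canonical coordinates.
snap_junctions <- function(donor, acceptor, tol) {
  key <- paste(donor, acceptor, sep = ":")
  tab <- table(key)
  uk <- names(tab)
  parts <- matrix(as.numeric(unlist(strsplit(uk, ":", fixed = TRUE))),
                  ncol = 2, byrow = TRUE)
  o <- order(-as.vector(tab), parts[, 1], parts[, 2])
  ud <- parts[o, 1]; ua <- parts[o, 2]; uk <- uk[o]
  cd <- rep(NA_real_, length(uk)); ca <- rep(NA_real_, length(uk))
  for (i in seq_along(uk)) {
    if (!is.na(cd[i])) next
    hit <- which(is.na(cd) & abs(ud - ud[i]) <= tol & abs(ua - ua[i]) <= tol)
    cd[hit] <- ud[i]; ca[hit] <- ua[i]
  }
  data.frame(key = uk, donor = cd, acceptor = ca, stringsAsFactors = FALSE)
}

# strand-aware test: is `g` (junction index vector) a 3'-terminal suffix of `h`?
is_3p_suffix <- function(g, h, strand) {
  if (length(g) > length(h)) return(FALSE)
  if (length(g) == 0) return(TRUE)
  if (strand == "+") identical(g, h[(length(h) - length(g) + 1):length(h)])
  else identical(g, h[seq_along(g)])
}

#' Cluster spliced reads into isoforms
#'
#' All reads must lie on one chromosome/strand partition (see
#' [cluster_all_reads()] for the partitioning wrapper). The procedure:
#' (1) junctions are snapped to support-weighted modal coordinates under
#' `junction_tol` and reads are grouped by identical snapped junction chains
#' (zero-junction reads are grouped by single-linkage genomic overlap);
#' (2) a group whose junction chain is a strand-aware 3'-suffix of a larger
#' group's chain, whose 3' end lies within `end_window` of the larger group's
#' modal 3' end, and whose span introduces no junction of the larger chain
#' that it does not itself carry, is merged into the larger group
#' (5'-truncation absorption); (3) the representative chain takes the parent
#' junction chain, the 5'-most member start and the modal member 3' end;
#' (4) clusters with total support below `min_support` are discarded.
#' Output is invariant under permutation of the input reads.
#'
#' @param reads List of [read_alignment()] on one chromosome and strand.
#' @param junction_tol Junction coordinate tolerance (nt).
#' @param end_window 3'-end compatibility window for truncation absorption (nt).
#' @param min_support Minimum total read support to keep a cluster.
#' @param id_prefix Prefix for cluster ids.
#' @return List of `isoform_cluster` objects: `cluster_id`, `chain`,
#'   `read_ids` (per-sample list), `counts` (named per-sample vector).
#' @export
cluster_reads <- function(reads, junction_tol = 5, end_window = 50,
                          min_support = 5, id_prefix = "c") {
  stopifnot(min_support >= 1)
  if (length(reads) == 0L) return(list())
  chrom <- reads[[1]]$chain$chrom
  strand <- reads[[1]]$chain$strand
  for (r in reads) stopifnot(r$chain$chrom == chrom, r$chain$strand == strand)

  # canonical sort for permutation invariance
  rid <- vapply(reads, `[[`, "", "read_id")
  reads <- reads[order(rid)]
  rid <- sort(rid)

  jl <- lapply(reads, function(r) junctions_of(r$chain))
  all_d <- unlist(lapply(jl, `[[`, "donor"))
  all_a <- unlist(lapply(jl, `[[`, "acceptor"))

  if (length(all_d)) {
    snap <- snap_junctions(all_d, all_a, junction_tol)
    lut_d <- stats::setNames(snap$donor, snap$key)
    lut_a <- stats::setNames(snap$acceptor, snap$key)
  }
  read_keys <- vapply(jl, function(j) {
    if (nrow(j) == 0) return("")
    k <- paste(j$donor, j$acceptor, sep = ":")
    paste(lut_d[k], lut_a[k], sep = ":", collapse = ";")
  }, character(1))

  spans <- t(vapply(reads, function(r) chain_span(r$chain), numeric(2)))
  # zero-junction reads: single-linkage grouping by genomic overlap
  mono <- which(read_keys == "")
  if (length(mono)) {
    o <- mono[order(spans[mono, 1], spans[mono, 2])]
    comp <- 0L; reach <- -Inf
    for (i in o) {
      if (spans[i, 1] >= reach) comp <- comp + 1L
      reach <- max(reach, spans[i, 2])
      read_keys[i] <- sprintf("mono%06d", comp)
    }
  }

  groups <- split(seq_along(reads), read_keys)
  gkey <- names(groups)
  njunc <- function(key) if (startsWith(key, "mono")) 0L else length(strsplit(key, ";", fixed = TRUE)[[1]])
  gj <- vapply(gkey, njunc, integer(1))
  gsupport <- lengths(groups)
  g3p <- vapply(groups, function(ix) {
    ends <- vapply(ix, function(i) chain_3p(reads[[i]]$chain), numeric(1))
    tb <- sort(table(ends), decreasing = TRUE)
    cand <- as.numeric(names(tb)[tb == tb[1]])
    min(cand)                                   # modal 3' end, tie -> smaller
  }, numeric(1))
  gjunc <- lapply(gkey, function(key) {
    if (startsWith(key, "mono") || key == "") return(data.frame(donor = numeric(0), acceptor = numeric(0)))
    m <- matrix(as.numeric(unlist(strsplit(strsplit(key, ";", fixed = TRUE)[[1]], ":", fixed = TRUE))),
                ncol = 2, byrow = TRUE)
    data.frame(donor = m[, 1], acceptor = m[, 2])
  })
  g5p <- vapply(groups, function(ix) {
    s <- vapply(ix, function(i) chain_5p(reads[[i]]$chain), numeric(1))
    if (strand == "+") min(s) else max(s)
  }, numeric(1))

  # junction index chains for suffix testing (shared canonical universe)
  if (length(all_d)) {
    jkeys <- paste(snap$donor, snap$acceptor, sep = ":")
    jindex <- stats::setNames(match(jkeys, unique(jkeys)), snap$key)
  }
  gchain_idx <- lapply(gkey, function(key) {
    if (startsWith(key, "mono") || key == "") return(integer(0))
    unname(jindex[strsplit(key, ";", fixed = TRUE)[[1]]])
  })

  # truncation-containment merge: smaller-junction groups into larger
  parent <- seq_along(groups)
  ord <- order(gj, -gsupport, gkey)              # fewest junctions first
  for (gi in ord) {
    cand <- integer(0)
    for (hi in seq_along(groups)) {
      if (hi == gi || gj[hi] <= gj[gi]) next
      if (parent[hi] != hi) next
      if (!is_3p_suffix(gchain_idx[[gi]], gchain_idx[[hi]], strand)) next
      if (abs(g3p[gi] - g3p[hi]) > end_window) next
      # the truncated group's 5' end must not bridge an unshared parent junction
      hj <- gjunc[[hi]]
      k <- nrow(hj) - gj[gi]                     # parent junctions 5' of shared suffix
      if (strand == "+") {
        if (k >= 1 && g5p[gi] < hj$acceptor[k] - junction_tol) next
      } else {
        if (k >= 1 && g5p[gi] > hj$donor[nrow(hj) - k + 1] + junction_tol) next
      }
      cand <- c(cand, hi)
    }
    if (length(cand)) {
      best <- cand[order(-gsupport[cand], gkey[cand])][1]
      parent[gi] <- best
    }
  }
  # path-compress (a truncated group may point to a group that itself merged)
  root <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  roots <- vapply(seq_along(groups), root, integer(1))

  out <- list()
  samples <- sort(unique(vapply(reads, `[[`, "", "sample_id")))
  ci <- 0L
  for (rg in sort(unique(roots))) {
    member_groups <- which(roots == rg)
    ix <- sort(unlist(groups[member_groups]))
    if (length(ix) < min_support) next
    start5 <- if (strand == "+") min(spans[ix, 1]) else max(spans[ix, 2])
    ends <- vapply(ix, function(i) chain_3p(reads[[i]]$chain), numeric(1))
    tb <- sort(table(ends), decreasing = TRUE)
    end3 <- min(as.numeric(names(tb)[tb == tb[1]]))
    jn <- gjunc[[rg]]
    chain <- if (strand == "+")
      chain_from_junctions(chrom, strand, start5, end3, jn)
    else
      chain_from_junctions(chrom, strand, end3, start5, jn)
    sam <- vapply(ix, function(i) reads[[i]]$sample_id, "")
    ci <- ci + 1L
    cl <- list(cluster_id = sprintf("%s%04d", id_prefix, ci),
               chain = chain,
               read_ids = split(rid[ix], factor(sam, levels = samples)),
               counts = vapply(split(rid[ix], factor(sam, levels = samples)),
                               length, integer(1)))
    class(cl) <- "isoform_cluster"
    out[[cl$cluster_id]] <- cl
  }
  # deterministic ordering/ids by genomic position
  if (length(out)) {
    o <- order(vapply(out, function(c) chain_span(c$chain)[1], numeric(1)),
               vapply(out, function(c) chain_span(c$chain)[2], numeric(1)))
    out <- out[o]
    for (i in seq_along(out)) out[[i]]$cluster_id <- sprintf("%s%04d", id_prefix, i)
    names(out) <- vapply(out, `[[`, "", "cluster_id")
  }
  out
}

#' Cluster reads across all chromosome/strand partitions
#'
#' @param reads List of [read_alignment()] (any chromosomes/strands).
#' @inheritParams cluster_reads
#' @return Combined named list of clusters; ids encode the partition.
#' @export
cluster_all_reads <- function(reads, junction_tol = 5, end_window = 50,
                              min_support = 5) {
  part <- vapply(reads, function(r) paste(r$chain$chrom, r$chain$strand), "")
  out <- list()
  for (p in sort(unique(part))) {
    pr <- reads[part == p]
    pref <- sprintf("%s:%s:c", pr[[1]]$chain$chrom, pr[[1]]$chain$strand)
    out <- c(out, cluster_reads(pr, junction_tol, end_window, min_support,
                                id_prefix = pref))
  }
  out
}

#' Cluster- and locus-level expression tables
#'
#' @param clusters Named list of clusters.
#' @param locus_of Named character: locus (gene) id per cluster id; clusters
#'   mapping to `NA` are kept in the cluster table but excluded from the
#'   locus table.
#' @return List with `cluster_counts` and `locus_counts` (data.frames,
#'   one row per cluster/locus, one column per sample). Locus counts are the
#'   sums of their clusters' counts, so the table total equals the number of
#'   clustered reads.
#' @export
quantify <- function(clusters, locus_of = NULL) {
  if (length(clusters) == 0L)
    return(list(cluster_counts = data.frame(), locus_counts = data.frame()))
  samples <- names(clusters[[1]]$counts)
  cc <- do.call(rbind, lapply(clusters, function(cl)
    as.data.frame(as.list(cl$counts))))
  cc <- cbind(data.frame(cluster_id = names(clusters)), cc)
  rownames(cc) <- NULL
  lc <- data.frame()
  if (!is.null(locus_of)) {
    loc <- unname(locus_of[cc$cluster_id])
    keep <- !is.na(loc)
    if (any(keep)) {
      m <- rowsum(as.matrix(cc[keep, samples, drop = FALSE]), loc[keep])
      lc <- cbind(data.frame(locus_id = rownames(m)), as.data.frame(m))
      rownames(lc) <- NULL
    }
  }
  list(cluster_counts = cc, locus_counts = lc)
}
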