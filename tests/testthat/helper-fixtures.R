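# Shared fixtures and independent brute-force oracles. Oracles deliberately
# avoid the package's own code paths.

random_dna_str <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

mkchain <- function(..., chrom = "chr1", strand = "+") {
  exon_chain(chrom, strand, matrix(c(...), ncol = 2, byrow = TRUE))
}

mkread <- function(id, chain, sample = "s1") read_alignment(id, sample, chain)

# random multi-exon chain with realistic geometry (exons/introns >> tolerance)
random_chain <- function(n_exons = NULL, chrom = "chr1", strand = "+",
                         start = NULL) {
  if (is.null(n_exons)) n_exons <- sample(1:6, 1)
  if (is.null(start)) start <- sample(1000:50000, 1)
  widths <- sample(40:200, n_exons, replace = TRUE)
  gaps <- if (n_exons > 1) sample(40:300, n_exons - 1, replace = TRUE) else integer(0)
  starts <- start + cumsum(c(0, widths[-n_exons] + gaps))
  exon_chain(chrom, strand, cbind(starts, starts + widths))
}

# jittered copy of a chain (for matching tests)
jittered_copy <- function(chain, max_shift = 3) {
  ex <- chain$exons
  ex <- ex + matrix(sample(-max_shift:max_shift, length(ex), replace = TRUE),
                    ncol = 2)
  ex[, 2] <- pmax(ex[, 2], ex[, 1] + 5)
  if (nrow(ex) > 1) for (i in 2:nrow(ex)) ex[i, 1] <- max(ex[i, 1], ex[i - 1, 2] + 1)
  exon_chain(chain$chrom, chain$strand, ex)
}

# ---- oracles ----------------------------------------------------------------

# maximum bipartite matching size between two junction tables under tol,
# via igraph (independent of the greedy in-order implementation)
oracle_max_junction_matching <- function(ja, jb, tol) {
  na <- nrow(ja); nb <- nrow(jb)
  if (na == 0 || nb == 0) return(0L)
  edges <- NULL
  for (i in seq_len(na)) for (j in seq_len(nb))
    if (abs(ja$donor[i] - jb$donor[j]) <= tol &&
        abs(ja$acceptor[i] - jb$acceptor[j]) <= tol)
      edges <- rbind(edges, c(i, na + j))
  if (is.null(edges)) return(0L)
  g <- igraph::make_bipartite_graph(c(rep(FALSE, na), rep(TRUE, nb)),
                                    as.vector(t(edges)))
  igraph::max_bipartite_match(g)$matching_size
}

# maximum 1:1 site matching within +/- shift (bipartite oracle)
oracle_max_site_matching <- function(pa, pb, shift) {
  na <- length(pa); nb <- length(pb)
  if (na == 0 || nb == 0) return(0L)
  edges <- NULL
  for (i in seq_len(na)) for (j in seq_len(nb))
    if (abs(pa[i] - pb[j]) <= shift) edges <- rbind(edges, c(i, na + j))
  if (is.null(edges)) return(0L)
  g <- igraph::make_bipartite_graph(c(rep(FALSE, na), rep(TRUE, nb)),
                                    as.vector(t(edges)))
  igraph::max_bipartite_match(g)$matching_size
}

# absorb-by-support site collapsing, written independently of call_sites()
oracle_absorb_sites <- function(positions, absorb = 5) {
  tab <- table(positions)
  df <- data.frame(pos = as.numeric(names(tab)), supp = as.vector(tab))
  df <- df[order(-df$supp, df$pos), ]
  sites <- NULL
  taken <- rep(FALSE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (taken[i]) next
    grab <- !taken & abs(df$pos - df$pos[i]) <= absorb
    sites <- rbind(sites, data.frame(pos = df$pos[i], supp = sum(df$supp[grab])))
    taken[grab] <- TRUE
  }
  sites[order(sites$pos), ]
}

# brute-force exonic-overlap locus scan
oracle_assign_locus <- function(chain, models, min_overlap = 20) {
  ov_len <- function(a, b) {
    tot <- 0
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
      tot <- tot + max(0, min(a[i, 2], b[j, 2]) - max(a[i, 1], b[j, 1]))
    tot
  }
  hits <- list(same = character(0), antisense = character(0))
  for (gid in unique(vapply(models, `[[`, "", "gene_id"))) {
    ms <- Filter(function(m) m$gene_id == gid, models)
    if (ms[[1]]$chain$chrom != chain$chrom) next
    # merged exonic intervals of the gene
    ex <- do.call(rbind, lapply(ms, function(m) m$chain$exons))
    ex <- ex[order(ex[, 1]), , drop = FALSE]
    merged <- ex[1, , drop = FALSE]
    if (nrow(ex) > 1) for (i in 2:nrow(ex)) {
      if (ex[i, 1] <= merged[nrow(merged), 2])
        merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], ex[i, 2])
      else merged <- rbind(merged, ex[i, , drop = FALSE])
    }
    if (ov_len(chain$exons, merged) >= min_overlap) {
      side <- if (ms[[1]]$chain$strand == chain$strand) "same" else "antisense"
      hits[[side]] <- c(hits[[side]], gid)
    }
  }
  hits
}

# small default simulation shared by several tests (cached per session)
.shared <- new.env()
shared_zero_noise_dataset <- function() {
  if (is.null(.shared$zn)) {
    cfg <- sim_config(junction_jitter_sd = 0, truncation_prob_per_nt = 0,
                      seed = 11)
    .shared$zn <- list(cfg = cfg, ds = simulate_dataset(cfg))
  }
  .shared$zn
}
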