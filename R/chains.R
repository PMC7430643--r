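# Exon-chain algebra: the universal coordinate object for reads, isoforms and
# annotation. All internal coordinates are 0-based half-open; GFF3 is converted
# at the I/O boundary.

#' Construct an exon chain
#'
#' An exon chain is a strand-aware ordered list of exonic genomic intervals.
#' Gaps between consecutive exons are the introns; the chain describes one
#' read, one isoform or one annotated transcript.
#'
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column numeric matrix (start, end) in 0-based half-open
#'   coordinates, ascending, non-overlapping, with a gap of at least 1 nt
#'   between consecutive blocks.
#' @return An object of class `exon_chain`.
#' @export
exon_chain <- function(chrom, strand, exons) {
  if (is.vector(exons)) exons <- matrix(exons, ncol = 2, byrow = TRUE)
  exons <- matrix(as.numeric(exons), ncol = 2)
  stopifnot(length(chrom) == 1L, strand %in% c("+", "-"), nrow(exons) >= 1L)
  if (any(exons[, 1] >= exons[, 2]))
    stop("exon_chain: every exon must satisfy start < end")
  if (nrow(exons) > 1L) {
    if (is.unsorted(exons[, 1], strictly = TRUE))
      stop("exon_chain: exon starts must be strictly ascending")
    if (any(exons[-1L, 1] - exons[-nrow(exons), 2] < 1))
      stop("exon_chain: exons must be separated by a gap of >= 1 nt")
  }
  structure(list(chrom = as.character(chrom), strand = strand, exons = exons),
            class = "exon_chain")
}

#' @export
print.exon_chain <- function(x, ...) {
  cat(sprintf("<exon_chain> %s:%s %d exon(s) span [%d, %d)\n", x$chrom,
              x$strand, nrow(x$exons), chain_span(x)[1], chain_span(x)[2]))
  invisible(x)
}

#' Genomic span of a chain
#' @param chain An `exon_chain`.
#' @return Numeric `(start, end)`, 0-based half-open.
#' @export
chain_span <- function(chain) c(chain$exons[1, 1], chain$exons[nrow(chain$exons), 2])

#' Total exonic (spliced transcript) length of a chain
#' @param chain An `exon_chain`.
#' @export
chain_len <- function(chain) sum(chain$exons[, 2] - chain$exons[, 1])

#' Strand-aware 3' terminus of a chain
#'
#' On the plus strand this is the half-open end of the last exon; on the minus
#' strand the (inclusive) start coordinate of the first exon, i.e. the
#' coordinate at which a poly(A) site would be recorded for a 3'-anchored read.
#' @param chain An `exon_chain`.
#' @export
chain_3p <- function(chain) {
  if (chain$strand == "+") chain$exons[nrow(chain$exons), 2] else chain$exons[1, 1]
}

#' Strand-aware 5' terminus of a chain
#' @param chain An `exon_chain`.
#' @export
chain_5p <- function(chain) {
  if (chain$strand == "+") chain$exons[1, 1] else chain$exons[nrow(chain$exons), 2]
}

#' Splice junctions of a chain
#'
#' One junction per gap between consecutive exons: `donor` is the 0-based
#' genomic start of the intron, `acceptor` its half-open end. A single-exon
#' chain has no junctions. Note "donor"/"acceptor" are named in genomic
#' orientation here; transcript-level donor/acceptor roles swap on the minus
#' strand.
#'
#' @param chain An `exon_chain`.
#' @return data.frame with columns `donor`, `acceptor` (genomically ascending).
#' @export
junctions_of <- function(chain) {
  n <- nrow(chain$exons)
  if (n < 2L) return(data.frame(donor = numeric(0), acceptor = numeric(0)))
  data.frame(donor = chain$exons[-n, 2], acceptor = chain$exons[-1L, 1])
}

#' Rebuild an exon chain from its span and junctions
#'
#' @param chrom,strand Chain location.
#' @param start5,end3 Genomic span start/end (0-based half-open).
#' @param junctions data.frame with `donor`, `acceptor`, genomically sorted.
#' @export
chain_from_junctions <- function(chrom, strand, start5, end3, junctions) {
  starts <- c(start5, junctions$acceptor)
  ends <- c(junctions$donor, end3)
  exon_chain(chrom, strand, cbind(starts, ends))
}

## ---- plain interval helpers (0-based half-open two-column matrices) --------

iv_total_len <- function(m) sum(m[, 2] - m[, 1])

# length of the intersection of two sorted disjoint interval sets
iv_intersect_len <- function(a, b) {
  tot <- 0; i <- 1L; j <- 1L
  while (i <= nrow(a) && j <= nrow(b)) {
    lo <- max(a[i, 1], b[j, 1]); hi <- min(a[i, 2], b[j, 2])
    if (hi > lo) tot <- tot + (hi - lo)
    if (a[i, 2] < b[j, 2]) i <- i + 1L else j <- j + 1L
  }
  tot
}

iv_union_len <- function(a, b) iv_total_len(a) + iv_total_len(b) - iv_intersect_len(a, b)

## ---- junction matching ------------------------------------------------------

# Greedy in-order 1:1 matching of two genomically sorted junction tables.
# Junctions match iff |donor difference| <= tol AND |acceptor difference| <= tol.
# Returns a two-column matrix of matched row indices (index_a, index_b).
match_junctions <- function(ja, jb, tol) {
  ia <- integer(0); ib <- integer(0)
  i <- 1L; j <- 1L
  while (i <= nrow(ja) && j <= nrow(jb)) {
    if (abs(ja$donor[i] - jb$donor[j]) <= tol &&
        abs(ja$acceptor[i] - jb$acceptor[j]) <= tol) {
      ia <- c(ia, i); ib <- c(ib, j); i <- i + 1L; j <- j + 1L
    } else if (ja$donor[i] < jb$donor[j] ||
               (ja$donor[i] == jb$donor[j] && ja$acceptor[i] < jb$acceptor[j])) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  cbind(a = ia, b = ib)
}

#' Compare two exon chains
#'
#' Computes the shared/private junction structure under a junction tolerance,
#' the exonic Jaccard index, and a 5'-truncation containment flag used by the
#' read-clustering stage: `a_contains_b_5prime_truncated` is `TRUE` when every
#' junction of `b` matches a junction of `a` (with `b` having no more junctions
#' than `a`) and `b`'s span lies within `a`'s span (with `junction_tol` slack),
#' i.e. `b` looks like a 5'-degraded copy of `a`.
#'
#' Junction matching is greedy, in genomic order, 1:1; two junctions match iff
#' both the donor and the acceptor coordinates agree within `junction_tol`.
#'
#' @param a,b `exon_chain` objects on the same chromosome and strand.
#' @param junction_tol Non-negative coordinate tolerance in nt (default 5).
#' @return list with `shared_junctions`, `only_in_a`, `only_in_b` (junction
#'   data.frames), `a_contains_b_5prime_truncated`, `exonic_jaccard`.
#' @export
compare_chains <- function(a, b, junction_tol = 5) {
  if (a$chrom != b$chrom || a$strand != b$strand)
    stop("compare_chains: chains must share chromosome and strand")
  stopifnot(junction_tol >= 0)
  ja <- junctions_of(a); jb <- junctions_of(b)
  m <- match_junctions(ja, jb, junction_tol)
  sa <- chain_span(a); sb <- chain_span(b)
  contains <- nrow(jb) <= nrow(ja) && nrow(m) == nrow(jb) &&
    sb[1] >= sa[1] - junction_tol && sb[2] <= sa[2] + junction_tol
  list(
    shared_junctions = nrow(m),
    only_in_a = if (nrow(ja)) ja[setdiff(seq_len(nrow(ja)), m[, "a"]), , drop = FALSE] else ja,
    only_in_b = if (nrow(jb)) jb[setdiff(seq_len(nrow(jb)), m[, "b"]), , drop = FALSE] else jb,
    a_contains_b_5prime_truncated = contains,
    exonic_jaccard = iv_intersect_len(a$exons, b$exons) / iv_union_len(a$exons, b$exons)
  )
}

#' Construct a transcript model
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chain An `exon_chain`.
#' @param utr5_len,utr3_len UTR lengths in spliced transcript coordinates
#'   (0 when unknown).
#' @export
transcript_model <- function(transcript_id, gene_id, chain,
                             utr5_len = 0, utr3_len = 0) {
  stopifnot(inherits(chain, "exon_chain"), utr5_len >= 0, utr3_len >= 0)
  if (utr5_len + utr3_len > chain_len(chain))
    stop("transcript_model: utr5_len + utr3_len exceeds spliced length")
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chain = chain, utr5_len = utr5_len, utr3_len = utr3_len),
            class = "transcript_model")
}

#' Construct a read alignment
#'
#' @param read_id,sample_id Identifiers.
#' @param chain An `exon_chain`.
#' @param polya_len Optional non-negative poly(A) length estimate (nt).
#' @return list of class `read_alignment`; `three_prime_end` is derived from
#'   the chain (strand-aware).
#' @export
read_alignment <- function(read_id, sample_id, chain, polya_len = NA_real_) {
  stopifnot(inherits(chain, "exon_chain"))
  if (!is.na(polya_len) && polya_len < 0)
    stop("read_alignment: polya_len must be non-negative")
  structure(list(read_id = read_id, sample_id = sample_id, chain = chain,
                 three_prime_end = chain_3p(chain), polya_len = polya_len),
            class = "read_alignment")
}
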