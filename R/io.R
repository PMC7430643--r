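# Readers and writers for the external contracts: GFF3 (1-based closed),
# BED12 (0-based half-open), FASTA, and the plain TSV tables consumed by the
# poly(A) and modification stages. Parsing goes through rtracklayer/Biostrings;
# only deterministic line formatting is done by hand.

#' Read transcript models from GFF3
#'
#' Expects gene/mRNA/exon features with optional five_prime_UTR and
#' three_prime_UTR children. Coordinates are converted from the 1-based closed
#' GFF3 convention to the internal 0-based half-open convention; UTR lengths
#' are the summed widths of UTR features of each transcript (0 when absent).
#'
#' @param path Path to a GFF3 file.
#' @return Named list of [transcript_model()] objects (names = transcript ids).
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    bad <- which(body)[which(nf != 9L)[1]]
    stop(sprintf("read_gff3: malformed GFF3 line %d in %s (expected 9 fields, found %d)",
                 bad, path, nf[which(nf != 9L)[1]]))
  }
  g <- rtracklayer::import(path, format = "gff3")
  type <- as.character(g$type)
  first_parent <- function(x) vapply(as.list(x), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))

  tx <- g[type %in% c("mRNA", "transcript")]
  tx_id <- as.character(tx$ID)
  tx_gene <- first_parent(tx$Parent)

  ex <- g[type == "exon"]
  ex_parent <- first_parent(ex$Parent)
  utr5 <- g[type == "five_prime_UTR"]
  utr3 <- g[type == "three_prime_UTR"]
  u5_parent <- first_parent(utr5$Parent)
  u3_parent <- first_parent(utr3$Parent)

  out <- vector("list", length(tx))
  names(out) <- tx_id
  for (k in seq_along(tx)) {
    id <- tx_id[k]
    e <- ex[ex_parent == id]
    if (length(e) == 0L) stop(sprintf("read_gff3: transcript %s has no exons", id))
    o <- order(BiocGenerics::start(e))
    starts <- BiocGenerics::start(e)[o] - 1L  # to 0-based
    ends <- BiocGenerics::end(e)[o]
    if (any(starts < BiocGenerics::start(tx)[k] - 1L) ||
        any(ends > BiocGenerics::end(tx)[k]))
      stop(sprintf("read_gff3: exon outside mRNA span for transcript %s", id))
    chain <- exon_chain(as.character(GenomicRanges::seqnames(tx))[k],
                        as.character(BiocGenerics::strand(tx))[k],
                        cbind(starts, ends))
    out[[k]] <- transcript_model(
      id, tx_gene[k], chain,
      utr5_len = sum(BiocGenerics::width(utr5[u5_parent == id])),
      utr3_len = sum(BiocGenerics::width(utr3[u3_parent == id])))
  }
  out
}

#' Write transcript models to GFF3
#'
#' Emits gene, mRNA, exon and UTR features (UTR features only for transcripts
#' with non-zero UTR lengths), sorted by chromosome, gene start, gene id and
#' transcript id, so output is byte-stable for a given input.
#'
#' @param models List of [transcript_model()] objects.
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @export
write_gff3 <- function(models, path, source = "nanotx") {
  gene_id <- vapply(models, `[[`, "", "gene_id")
  tx_id <- vapply(models, `[[`, "", "transcript_id")
  chroms <- vapply(models, function(m) m$chain$chrom, "")
  spans <- t(vapply(models, function(m) chain_span(m$chain), numeric(2)))
  genes <- split(seq_along(models), gene_id)

  gstart <- vapply(genes, function(i) min(spans[i, 1]), numeric(1))
  gchrom <- vapply(genes, function(i) chroms[i[1]], "")
  gorder <- order(gchrom, gstart, names(genes))

  fmt <- function(chrom, src, type, s0, e0, strand, id, parent = NULL) {
    attr <- if (is.null(parent)) sprintf("ID=%s", id)
            else sprintf("ID=%s;Parent=%s", id, parent)
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, src, type, as.integer(s0) + 1L, as.integer(e0), strand, attr)
  }

  lines <- c("##gff-version 3")
  for (gi in gorder) {
    idx <- genes[[gi]]
    gid <- names(genes)[gi]
    strand <- models[[idx[1]]]$chain$strand
    lines <- c(lines, fmt(gchrom[gi], source, "gene",
                          min(spans[idx, 1]), max(spans[idx, 2]), strand, gid))
    for (k in idx[order(tx_id[idx])]) {
      m <- models[[k]]
      sp <- chain_span(m$chain)
      lines <- c(lines, fmt(m$chain$chrom, source, "mRNA", sp[1], sp[2],
                            strand, m$transcript_id, gid))
      ex <- m$chain$exons
      for (e in seq_len(nrow(ex)))
        lines <- c(lines, fmt(m$chain$chrom, source, "exon", ex[e, 1], ex[e, 2],
                              strand, sprintf("%s.exon%d", m$transcript_id, e),
                              m$transcript_id))
      L <- chain_len(m$chain)
      if (m$utr5_len > 0) {
        iv <- tx_to_genomic(m$chain, 0, m$utr5_len)
        for (e in seq_len(nrow(iv)))
          lines <- c(lines, fmt(m$chain$chrom, source, "five_prime_UTR",
                                iv[e, 1], iv[e, 2], strand,
                                sprintf("%s.utr5.%d", m$transcript_id, e),
                                m$transcript_id))
      }
      if (m$utr3_len > 0) {
        iv <- tx_to_genomic(m$chain, L - m$utr3_len, L)
        for (e in seq_len(nrow(iv)))
          lines <- c(lines, fmt(m$chain$chrom, source, "three_prime_UTR",
                                iv[e, 1], iv[e, 2], strand,
                                sprintf("%s.utr3.%d", m$transcript_id, e),
                                m$transcript_id))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Map a spliced-transcript interval to genomic intervals
#'
#' Transcript coordinate 0 is the 5' end of the chain (strand-aware).
#'
#' @param chain An `exon_chain`.
#' @param tx_from,tx_to Half-open transcript-coordinate interval.
#' @return Two-column matrix of genomic 0-based half-open intervals, ascending.
#' @export
tx_to_genomic <- function(chain, tx_from, tx_to) {
  L <- chain_len(chain)
  stopifnot(tx_from >= 0, tx_to <= L, tx_from < tx_to)
  ex <- chain$exons
  if (chain$strand == "-") {
    # walk exons from the genomic right; convert to equivalent plus interval
    tmp <- tx_from
    tx_from <- L - tx_to
    tx_to <- L - tmp
  }
  out <- NULL
  off <- 0
  for (e in seq_len(nrow(ex))) {
    w <- ex[e, 2] - ex[e, 1]
    lo <- max(tx_from, off); hi <- min(tx_to, off + w)
    if (hi > lo) out <- rbind(out, c(ex[e, 1] + (lo - off), ex[e, 1] + (hi - off)))
    off <- off + w
  }
  out
}

#' Remove a 5'-terminal prefix from a chain
#'
#' Models 5' degradation of a 3'-anchored direct-RNA read: the first
#' `prefix_len` spliced nucleotides are removed; exons fully covered by the
#' prefix disappear and a partially covered exon is shortened.
#'
#' @param chain An `exon_chain`.
#' @param prefix_len Number of transcript 5' nucleotides to remove
#'   (`0 <= prefix_len < chain_len(chain)`).
#' @export
truncate_chain_5p <- function(chain, prefix_len) {
  if (prefix_len <= 0) return(chain)
  L <- chain_len(chain)
  stopifnot(prefix_len < L)
  exon_chain(chain$chrom, chain$strand, tx_to_genomic(chain, prefix_len, L))
}

## ---- BED12 ------------------------------------------------------------------

#' Read spliced read alignments from BED12
#'
#' Block coordinates become absolute exons (0-based half-open); the strand is
#' taken from column 6 and the strand-aware 3' terminus is recorded per read.
#' Reads mapped to a spike-in/control sequence can be dropped at load time.
#'
#' @param path BED12 file.
#' @param sample_id Sample label attached to every read.
#' @param control_seq Optional name of a control sequence whose reads are
#'   discarded (e.g. an in-vitro control transcript).
#' @return List of [read_alignment()] objects.
#' @export
read_bed12 <- function(path, sample_id, control_seq = NULL) {
  g <- rtracklayer::import(path, format = "bed")
  if (length(g) == 0L) return(list())
  if (!is.null(control_seq)) g <- g[as.character(GenomicRanges::seqnames(g)) != control_seq]
  bl <- rtracklayer::blocks(g)  # absolute 1-based closed
  starts <- as.list(BiocGenerics::start(bl))
  ends <- as.list(BiocGenerics::end(bl))
  out <- vector("list", length(g))
  nm <- g$name
  strands <- as.character(BiocGenerics::strand(g))
  chroms <- as.character(GenomicRanges::seqnames(g))
  for (i in seq_along(g)) {
    chain <- exon_chain(chroms[i], strands[i],
                        cbind(starts[[i]] - 1L, ends[[i]]))
    out[[i]] <- read_alignment(nm[i], sample_id, chain)
  }
  names(out) <- nm
  out
}

#' Write exon chains to BED12
#'
#' Accepts read alignments, isoform clusters, or a named list of bare chains.
#' Records are sorted by chromosome, span start and name so output is
#' byte-stable under input permutation.
#'
#' @param records List of objects each carrying a `$chain` (or bare
#'   `exon_chain`s, in which case list names are used as record names).
#' @param path Output path.
#' @export
write_bed12 <- function(records, path) {
  if (length(records) == 0L) { writeLines(character(0), path); return(invisible(path)) }
  chains <- lapply(records, function(r) if (inherits(r, "exon_chain")) r else r$chain)
  nms <- vapply(seq_along(records), function(i) {
    r <- records[[i]]
    if (inherits(r, "exon_chain")) {
      if (!is.null(names(records))) names(records)[i] else sprintf("record%d", i)
    } else if (!is.null(r[["read_id"]])) r[["read_id"]] else r[["cluster_id"]]
  }, character(1))
  chrom <- vapply(chains, function(ch) ch$chrom, "")
  starts <- vapply(chains, function(ch) chain_span(ch)[1], numeric(1))
  o <- order(chrom, starts, nms)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom[o],
    ranges = IRanges::IRanges(
      start = starts[o] + 1L,
      end = vapply(chains[o], function(ch) chain_span(ch)[2], numeric(1))),
    strand = vapply(chains[o], function(ch) ch$strand, ""))
  gr$name <- nms[o]
  gr$score <- 0L
  gr$thick <- IRanges::ranges(gr)
  gr$blocks <- IRanges::IRangesList(lapply(chains[o], function(ch) {
    s0 <- chain_span(ch)[1]
    IRanges::IRanges(start = ch$exons[, 1] - s0 + 1L, end = ch$exons[, 2] - s0)
  }))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

## ---- FASTA and small TSV tables --------------------------------------------

#' Load a genome FASTA as a named character vector
#' @param path FASTA file.
#' @export
load_genome <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(s), sub("\\s.*$", "", names(s)))
}

#' Write a named character vector of sequences as FASTA
#' @param genome Named character vector.
#' @param path Output path.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# substring of a chromosome in 0-based half-open coordinates
genome_sub <- function(genome, chrom, start0, end0)
  substr(genome[[chrom]], start0 + 1L, end0)

`genome_sub<-` <- function(genome, chrom, start0, value) {
  substr(genome[[chrom]], start0 + 1L, start0 + nchar(value)) <- value
  genome
}

#' Strand-aware sequence upstream of a 3'-end position
#'
#' Returns the last `len` transcript-orientation bases ending at the poly(A)
#' site (the site base is the final character). `pos` follows the [chain_3p()]
#' convention: half-open end on `+`, inclusive start on `-`.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param chrom,strand,pos Site location.
#' @param len Window length in nt.
#' @return Character string, or `NA` if the window runs off the chromosome.
#' @export
upstream_window <- function(genome, chrom, strand, pos, len) {
  n <- nchar(genome[[chrom]])
  if (strand == "+") {
    if (pos - len < 0 || pos > n) return(NA_character_)
    genome_sub(genome, chrom, pos - len, pos)
  } else {
    if (pos < 0 || pos + len > n) return(NA_character_)
    revcomp(genome_sub(genome, chrom, pos, pos + len))
  }
}

# Write `motif` so that (in transcript orientation) its first base sits
# `offset` nt upstream of the 3'-end position `pos`.
plant_motif <- function(genome, chrom, strand, pos, offset, motif) {
  w <- nchar(motif)
  if (strand == "+") {
    genome_sub(genome, chrom, pos - offset) <- motif
  } else {
    genome_sub(genome, chrom, pos + offset - w) <- revcomp(motif)
  }
  genome
}

#' Read a per-read poly(A) length table
#'
#' TSV with columns `read_id`, `sample_id`, `polya_len`.
#' @param path TSV file.
#' @export
read_polya_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("read_id", "sample_id", "polya_len") %in% names(x)))
  if (any(x$polya_len < 0, na.rm = TRUE))
    stop("read_polya_table: negative poly(A) length")
  x
}

#' Read a per-site modification fraction table
#'
#' TSV with columns `transcript_id`, `transcript_pos` (0-based spliced
#' coordinate), `fraction` in `[0,1]`, and `modtype`.
#' @param path TSV file.
#' @export
read_mod_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("transcript_id", "transcript_pos", "fraction", "modtype") %in% names(x)))
  if (any(x$fraction < 0 | x$fraction > 1))
    stop("read_mod_table: fraction outside [0,1]")
  x
}

#' Read a gene set (one gene id per line)
#' @param path Text file.
#' @export
read_gene_set <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
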