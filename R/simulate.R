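# Synthetic-data generator: genome, annotation, spliced reads with planted
# novel-isoform and fusion events, poly(A) tables with planted upstream
# hexamer signals, two-condition count panels, and per-site modification
# tables -- all with known ground truth and full determinism under a seed.
#
# Each generator reseeds the RNG from config$seed plus a fixed stage offset,
# so stages are individually reproducible and composable.

#' Simulation configuration
#'
#' Defaults describe the study conditions the analysis targets: multi-exon
#' gene models on both strands, 3'-anchored long reads whose 5' ends decay
#' geometrically (mean loss ~13 nt), +/-1 nt splice-junction wobble, a T-rich
#' hexamer planted 19 +/- 5 nt (bounded to 14-24 nt) upstream of every
#' poly(A) site, floral-bud poly(A) tails slightly longer than seedling tails
#' with most tails < 100 nt, a 20-percentage-point differential-isoform shift,
#' four-fold differential-gene effects, and a two-fold modification enrichment
#' in a designated "mobile" gene set.
#'
#' @param n_genes Number of genes.
#' @param exons_per_gene,exon_len,intron_len,intergenic_len,utr_len Integer
#'   ranges `c(lo, hi)` in nt.
#' @param events Named counts of planted single-gene novel-isoform events
#'   (categories: intron_retention, extra_exon, missing_exon, five_extra,
#'   three_extra, five_missing, three_missing, extra_utr, missing_utr,
#'   new_junction).
#' @param fusion_events Named counts of planted fusion reads per structural
#'   type `i`..`vi`.
#' @param reads_per_isoform Range of reads planted per isoform per sample.
#' @param truncation_prob_per_nt Geometric 5'-truncation rate per nt
#'   (0 disables truncation).
#' @param junction_jitter_sd SD (nt) of Normal splice-site jitter (0 disables
#'   all alignment noise, including 3'-end wobble).
#' @param end_wobble_nt Maximum 3'-end wobble (applied only when
#'   `junction_jitter_sd > 0`).
#' @param apa_offset_mean,apa_offset_sd Hexamer offset distribution upstream
#'   of poly(A) sites; draws are bounded to `[14, 24]` nt.
#' @param hexamer Planted poly(A)-signal hexamer (T-rich by default).
#' @param polya_shape,polya_scale Gamma parameters of per-tissue poly(A)
#'   length distributions (`polya_scale` named by tissue).
#' @param dei_shift Planted differential-isoform shift in relative abundance.
#' @param dei_base_prop Pre-shift relative abundance of the planted isoform.
#' @param dei_n_planted,dei_n_null,dei_reads_per_locus Differential-isoform
#'   panel dimensions.
#' @param deg_log2fc Planted differential-gene effect (log2 fold change).
#' @param deg_n_loci,deg_n_planted,deg_lambda_range Differential-gene panel
#'   dimensions; locus means are drawn log-uniformly over `deg_lambda_range`
#'   reads per tissue.
#' @param mod_enrichment_factor Multiplier on modification fractions in the
#'   mobile gene set (capped at 1).
#' @param mod_site_density Per-nt probability of a reported m5C site.
#' @param mod_beta Beta parameters of baseline site fractions.
#' @param mod_peak_height,mod_peak_sd,mod_stop_density Adenine-modification
#'   peak at the stop codon (height, SD in nt, site density within the peak
#'   window).
#' @param n_mobile,n_tls Gene-set sizes (TLS sets are drawn disjoint from the
#'   mobile set, so TLS-vs-total contrasts are null by construction).
#' @param samples data.frame with columns `sample_id`, `tissue` (two tissues).
#' @param seed Integer master seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genes = 60,
                       exons_per_gene = c(4, 6),
                       exon_len = c(100, 250),
                       intron_len = c(80, 200),
                       intergenic_len = c(400, 800),
                       utr_len = c(60, 120),
                       events = c(intron_retention = 1, extra_exon = 1,
                                  missing_exon = 1, five_extra = 1,
                                  three_extra = 1, five_missing = 1,
                                  three_missing = 1, extra_utr = 1,
                                  missing_utr = 1, new_junction = 1),
                       fusion_events = c(i = 1, ii = 1, iii = 1, iv = 1,
                                         v = 1, vi = 1),
                       reads_per_isoform = c(8, 15),
                       truncation_prob_per_nt = 0.075,
                       junction_jitter_sd = 1,
                       end_wobble_nt = 2,
                       apa_offset_mean = 19,
                       apa_offset_sd = 5,
                       hexamer = "TTTGTA",
                       polya_shape = 4,
                       polya_scale = c(seedling = 17, bud = 21),
                       dei_shift = 0.20,
                       dei_base_prop = 0.25,
                       dei_n_planted = 200,
                       dei_n_null = 500,
                       dei_reads_per_locus = 200,
                       deg_log2fc = 2,
                       deg_n_loci = 2000,
                       deg_n_planted = 200,
                       deg_lambda_range = c(50, 500),
                       mod_enrichment_factor = 2,
                       mod_site_density = 0.05,
                       mod_beta = c(2, 8),
                       mod_peak_height = 0.5,
                       mod_peak_sd = 8,
                       mod_stop_density = 0.3,
                       n_mobile = 200,
                       n_tls = 100,
                       samples = data.frame(
                         sample_id = c("seedling1", "seedling2", "bud1", "bud2"),
                         tissue = c("seedling", "seedling", "bud", "bud")),
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_genes >= 1, all(events >= 0), all(fusion_events >= 0),
            truncation_prob_per_nt >= 0, truncation_prob_per_nt <= 1,
            junction_jitter_sd >= 0, dei_shift >= 0, dei_shift <= 1,
            dei_base_prop + dei_shift <= 1,
            mod_site_density >= 0, mod_site_density <= 1,
            length(unique(samples$tissue)) == 2)
  if (intergenic_len[1] < 300)
    stop("sim_config: intergenic_len must be >= 300 nt so planted terminal events cannot reach a neighboring gene")
  if (nchar(hexamer) != 6 || grepl("[^ACGT]", hexamer))
    stop("sim_config: hexamer must be a 6-mer over ACGT")
  structure(cfg, class = "sim_config")
}

rint <- function(n, lo, hi) lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

#' Simulate a genome and its reference annotation
#'
#' Genes are laid out along one chromosome with non-overlapping spans,
#' alternating strands at random, one reference transcript per gene with UTR
#' lengths bounded by the terminal exons.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (named character), `models` (named list of
#'   [transcript_model()]) and `genes` (data.frame of gene geometry).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 11L)
  pos <- 1000L
  models <- list()
  genes <- NULL
  for (g in seq_len(config$n_genes)) {
    pos <- pos + rint(1, config$intergenic_len[1], config$intergenic_len[2])
    n_ex <- rint(1, config$exons_per_gene[1], config$exons_per_gene[2])
    ex_len <- rint(n_ex, config$exon_len[1], config$exon_len[2])
    in_len <- if (n_ex > 1) rint(n_ex - 1, config$intron_len[1], config$intron_len[2]) else integer(0)
    starts <- pos + cumsum(c(0L, ex_len[-n_ex] + in_len))
    ends <- starts + ex_len
    strand <- sample(c("+", "-"), 1)
    chain <- exon_chain("chr1", strand, cbind(starts, ends))
    first_len <- if (strand == "+") ex_len[1] else ex_len[n_ex]
    last_len <- if (strand == "+") ex_len[n_ex] else ex_len[1]
    utr5 <- min(rint(1, config$utr_len[1], config$utr_len[2]), first_len - 20L)
    utr3 <- min(rint(1, config$utr_len[1], config$utr_len[2]), last_len - 20L)
    gid <- sprintf("G%04d", g)
    tid <- paste0(gid, ".1")
    models[[tid]] <- transcript_model(tid, gid, chain, utr5, utr3)
    genes <- rbind(genes, data.frame(gene_id = gid, chrom = "chr1",
                                     start = starts[1], end = ends[n_ex],
                                     strand = strand, n_exons = n_ex))
    pos <- ends[n_ex]
  }
  genome <- c(chr1 = random_dna(pos + 1000L))
  if (genes$end[nrow(genes)] > nchar(genome[[1]]))
    stop("simulate_annotation: gene geometry exceeds chromosome length")
  list(genome = genome, models = models, genes = genes)
}

## ---- planted-event constructors --------------------------------------------
## Each takes the reference exon matrix (genomic order) + strand and returns
## the variant exon matrix. All satisfy exactly their target category pattern.

.drop_row <- function(ex, i) ex[-i, , drop = FALSE]

plant_intron_retention <- function(ex, strand) {
  i <- rint(1, 1, nrow(ex) - 1)  # intron index
  merged <- c(ex[i, 1], ex[i + 1, 2])
  rbind(ex[seq_len(i - 1), , drop = FALSE], merged,
        ex[setdiff(seq_len(nrow(ex)), seq_len(i + 1)), , drop = FALSE])
}

plant_extra_exon <- function(ex, strand) {
  ig <- ex[-1, 1] - ex[-nrow(ex), 2]          # intron lengths
  ok <- which(ig >= 130)
  if (!length(ok)) return(NULL)
  i <- ok[rint(1, 1, length(ok))]
  mid <- floor((ex[i, 2] + ex[i + 1, 1]) / 2)
  new <- c(mid - 30, mid + 30)
  rbind(ex[seq_len(i), , drop = FALSE], new,
        ex[setdiff(seq_len(nrow(ex)), seq_len(i)), , drop = FALSE])
}

plant_missing_exon <- function(ex, strand) {
  if (nrow(ex) < 3) return(NULL)
  .drop_row(ex, rint(1, 2, nrow(ex) - 1))
}

plant_five_extra <- function(ex, strand) {
  if (strand == "+") rbind(c(ex[1, 1] - 180, ex[1, 1] - 100), ex)
  else rbind(ex, c(ex[nrow(ex), 2] + 100, ex[nrow(ex), 2] + 180))
}

plant_three_extra <- function(ex, strand) plant_five_extra(ex, if (strand == "+") "-" else "+")

plant_five_missing <- function(ex, strand) {
  if (nrow(ex) < 3) return(NULL)
  if (strand == "+") .drop_row(ex, 1) else .drop_row(ex, nrow(ex))
}

plant_three_missing <- function(ex, strand) {
  if (nrow(ex) < 3) return(NULL)
  if (strand == "+") .drop_row(ex, nrow(ex)) else .drop_row(ex, 1)
}

plant_extra_utr <- function(ex, strand) {
  if (strand == "+") ex[nrow(ex), 2] <- ex[nrow(ex), 2] + 60
  else ex[1, 1] <- ex[1, 1] - 60
  ex
}

plant_missing_utr <- function(ex, strand) {
  if (strand == "+") ex[nrow(ex), 2] <- ex[nrow(ex), 2] - 60
  else ex[1, 1] <- ex[1, 1] + 60
  ex
}

plant_new_junction <- function(ex, strand) {
  if (nrow(ex) < 2) return(NULL)
  i <- rint(1, 1, nrow(ex) - 1)
  if (ex[i, 2] - ex[i, 1] < 50) return(NULL)
  ex[i, 2] <- ex[i, 2] - 30   # alternative splice boundary, 30 nt shift
  ex
}

.event_fun <- list(intron_retention = plant_intron_retention,
                   extra_exon = plant_extra_exon,
                   missing_exon = plant_missing_exon,
                   five_extra = plant_five_extra,
                   three_extra = plant_three_extra,
                   five_missing = plant_five_missing,
                   three_missing = plant_three_missing,
                   extra_utr = plant_extra_utr,
                   missing_utr = plant_missing_utr,
                   new_junction = plant_new_junction)

## fusion constructors take a list of consecutive gene exon matrices (genomic
## order) + the shared gene strand; return list(exons, strand)
plant_fusion <- function(type, exs, strand) {
  a <- exs[[1]]; b <- exs[[length(exs)]]
  spanA2 <- a[nrow(a), 2]; spanB1 <- b[1, 1]
  switch(type,
    i = {
      ex <- a
      ex[nrow(ex), 2] <- spanA2 + 80
      ex <- rbind(ex, c(spanB1 - 80, b[1, 2]), b[-1, , drop = FALSE])
      list(exons = ex, strand = strand)
    },
    ii = list(exons = matrix(c(a[1, 1] + 50, b[nrow(b), 2] - 50), ncol = 2),
              strand = strand),
    iii = list(exons = do.call(rbind, exs), strand = strand),
    iv = list(exons = rbind(a[-nrow(a), , drop = FALSE],
                            c(a[nrow(a), 1], b[1, 2]),
                            b[-1, , drop = FALSE]),
              strand = strand),
    v = list(exons = rbind(c(spanA2 - 150, spanA2), c(spanB1, spanB1 + 150)),
             strand = if (strand == "+") "-" else "+"),
    vi = {
      a2 <- .drop_row(a, 2)
      list(exons = rbind(a2[-nrow(a2), , drop = FALSE],
                         c(a2[nrow(a2), 1], b[1, 2]),
                         b[-1, , drop = FALSE]),
           strand = strand)
    },
    stop("unknown fusion type ", type))
}

#' Plant novel-isoform and fusion events into an annotation
#'
#' Each requested event is hosted by its own dedicated gene (or run of
#' adjacent same-strand genes for fusions); genes not used by any event carry
#' reads for their reference isoform ("known"). Per-sample read counts are
#' drawn from `config$reads_per_isoform`.
#'
#' @param ann Output of [simulate_annotation()].
#' @param config A [sim_config()].
#' @return List with `truths` (list of truth isoforms: id, category,
#'   fusion_type, gene ids, chain, per-sample counts) and `truth_table`
#'   (data.frame summary).
#' @export
plant_novel_isoforms <- function(ann, config) {
  set.seed(config$seed + 22L)
  genes <- ann$genes
  used <- rep(FALSE, nrow(genes))
  truths <- list()
  samples <- config$samples$sample_id

  draw_counts <- function() stats::setNames(
    rint(length(samples), config$reads_per_isoform[1], config$reads_per_isoform[2]),
    samples)

  add_truth <- function(id, category, fusion_type, gene_ids, chain) {
    truths[[id]] <<- list(truth_id = id, category = category,
                          fusion_type = fusion_type, gene_ids = gene_ids,
                          chain = chain, counts = draw_counts())
  }

  # fusion events first: they need runs of adjacent same-strand genes
  # (allocate the longest runs first so short gene lists pack better)
  fusion_order <- names(config$fusion_events)[
    order(-(names(config$fusion_events) == "iii"), names(config$fusion_events))]
  for (type in fusion_order) {
    for (k in seq_len(config$fusion_events[[type]])) {
      need <- if (type == "iii") 3L else 2L
      found <- FALSE
      for (s in seq_len(nrow(genes) - need + 1)) {
        idx <- s:(s + need - 1)
        if (any(used[idx])) next
        if (length(unique(genes$strand[idx])) != 1) next
        strand <- genes$strand[s]
        exs <- lapply(idx, function(i)
          ann$models[[paste0(genes$gene_id[i], ".1")]]$chain$exons)
        fp <- plant_fusion(type, exs, strand)
        add_truth(sprintf("fusion_%s_%d", type, k), "fusion", type,
                  genes$gene_id[idx],
                  exon_chain("chr1", fp$strand, fp$exons))
        used[idx] <- TRUE
        found <- TRUE
        break
      }
      if (!found) stop("plant_novel_isoforms: no adjacent same-strand gene run for fusion type ", type)
    }
  }

  # single-gene events
  for (cat in names(config$events)) {
    for (k in seq_len(config$events[[cat]])) {
      found <- FALSE
      for (i in seq_len(nrow(genes))) {
        if (used[i]) next
        m <- ann$models[[paste0(genes$gene_id[i], ".1")]]
        ex <- .event_fun[[cat]](m$chain$exons, m$chain$strand)
        if (is.null(ex)) next
        add_truth(sprintf("%s_%d", cat, k), cat, "none", genes$gene_id[i],
                  exon_chain("chr1", m$chain$strand, ex))
        used[i] <- TRUE
        found <- TRUE
        break
      }
      if (!found) stop("plant_novel_isoforms: no suitable host gene for category ", cat)
    }
  }

  # unused genes express their reference isoform
  for (i in which(!used)) {
    m <- ann$models[[paste0(genes$gene_id[i], ".1")]]
    add_truth(sprintf("known_%s", genes$gene_id[i]), "known", "none",
              genes$gene_id[i], m$chain)
  }

  tt <- do.call(rbind, lapply(truths, function(t) {
    cbind(data.frame(truth_id = t$truth_id, category = t$category,
                     fusion_type = t$fusion_type,
                     gene_ids = paste(t$gene_ids, collapse = ","),
                     chrom = t$chain$chrom, strand = t$chain$strand,
                     n_exons = nrow(t$chain$exons),
                     three_prime_end = chain_3p(t$chain)),
          as.data.frame(as.list(t$counts)))
  }))
  rownames(tt) <- NULL
  list(truths = truths, truth_table = tt)
}

jitter_chain <- function(chain, sd, end_wobble) {
  ex <- chain$exons
  n <- nrow(ex)
  for (attempt in 1:10) {
    ex2 <- ex
    if (n > 1) {
      ex2[-n, 2] <- ex[-n, 2] + round(stats::rnorm(n - 1, 0, sd))   # donors
      ex2[-1, 1] <- ex[-1, 1] + round(stats::rnorm(n - 1, 0, sd))   # acceptors
    }
    w <- if (end_wobble > 0) sample(seq(-end_wobble, end_wobble), 1) else 0
    if (chain$strand == "+") ex2[n, 2] <- ex2[n, 2] + w else ex2[1, 1] <- ex2[1, 1] - w
    ok <- all(ex2[, 2] - ex2[, 1] >= 5) &&
      (n == 1 || all(ex2[-1, 1] - ex2[-n, 2] >= 1))
    if (ok) return(exon_chain(chain$chrom, chain$strand, ex2))
  }
  chain
}

#' Simulate spliced reads from truth isoforms
#'
#' Each read is the truth chain subjected to (a) geometric 5'-prefix loss
#' (whole exons vanish when the prefix crosses a junction), (b) Normal
#' splice-site jitter, and (c) small 3'-end wobble; with all noise parameters
#' zero, reads are identical to the truth chains. Read ids encode the truth
#' id (before the first `|`) for scoring.
#'
#' @param truths `truths` element of [plant_novel_isoforms()] output.
#' @param config A [sim_config()].
#' @return List of [read_alignment()] objects.
#' @export
simulate_reads <- function(truths, config) {
  set.seed(config$seed + 33L)
  out <- list()
  for (t in truths) {
    L <- chain_len(t$chain)
    for (s in names(t$counts)) {
      for (r in seq_len(t$counts[[s]])) {
        chain <- t$chain
        if (config$truncation_prob_per_nt > 0) {
          k <- stats::rgeom(1, config$truncation_prob_per_nt)
          k <- min(k, L - 50)
          if (k > 0) chain <- truncate_chain_5p(chain, k)
        }
        if (config$junction_jitter_sd > 0)
          chain <- jitter_chain(chain, config$junction_jitter_sd,
                                config$end_wobble_nt)
        id <- sprintf("%s|%s|r%02d", t$truth_id, s, r)
        out[[id]] <- read_alignment(id, s, chain)
      }
    }
  }
  out
}

#' Truth id encoded in a simulated read id
#' @param read_id Character vector of simulated read ids.
#' @export
read_truth_id <- function(read_id) sub("\\|.*$", "", read_id)

#' Simulate per-read poly(A) lengths and plant poly(A)-signal hexamers
#'
#' Poly(A) lengths are Gamma draws with a tissue-specific scale (floral-bud
#' tails slightly longer than seedling tails, most tails < 100 nt). For every
#' truth 3'-end site the configured hexamer is written into the genome at an
#' offset drawn from Normal(`apa_offset_mean`, `apa_offset_sd`) bounded to
#' 14-24 nt upstream.
#'
#' @param truths Truth list from [plant_novel_isoforms()].
#' @param genome Named character vector of chromosome sequences.
#' @param config A [sim_config()].
#' @return List with `polya` (data.frame read_id/sample_id/polya_len),
#'   `genome` (edited), `truth_sites` (data.frame chrom/strand/position/
#'   support/offset).
#' @export
simulate_polya_and_sites <- function(truths, genome, config) {
  set.seed(config$seed + 44L)
  tissue_of <- stats::setNames(config$samples$tissue, config$samples$sample_id)

  # per-read poly(A) lengths, ids aligned with simulate_reads()
  ids <- character(0); sams <- character(0); lens <- numeric(0)
  for (t in truths) {
    for (s in names(t$counts)) {
      n <- t$counts[[s]]
      if (n == 0) next
      ids <- c(ids, sprintf("%s|%s|r%02d", t$truth_id, s, seq_len(n)))
      sams <- c(sams, rep(s, n))
      lens <- c(lens, round(stats::rgamma(n, shape = config$polya_shape,
                                          scale = config$polya_scale[[tissue_of[[s]]]]), 1))
    }
  }

  # unique truth 3'-end sites with total planted support
  pos <- vapply(truths, function(t) chain_3p(t$chain), numeric(1))
  chrom <- vapply(truths, function(t) t$chain$chrom, "")
  strand <- vapply(truths, function(t) t$chain$strand, "")
  supp <- vapply(truths, function(t) sum(t$counts), numeric(1))
  key <- paste(chrom, strand, pos)
  agg <- rowsum(supp, key)
  first <- !duplicated(key)
  sites <- data.frame(chrom = chrom[first], strand = strand[first],
                      position = pos[first],
                      support = as.numeric(agg[key[first], 1]))
  sites <- sites[order(sites$chrom, sites$strand, sites$position), ]

  draw_offset <- function() {
    for (i in 1:50) {
      o <- round(stats::rnorm(1, config$apa_offset_mean, config$apa_offset_sd))
      if (o >= 14 && o <= 24) return(o)
    }
    config$apa_offset_mean
  }
  sites$offset <- vapply(seq_len(nrow(sites)), function(i) draw_offset(), numeric(1))
  for (i in seq_len(nrow(sites)))
    genome <- plant_motif(genome, sites$chrom[i], sites$strand[i],
                          sites$position[i], sites$offset[i], config$hexamer)
  rownames(sites) <- NULL
  list(polya = data.frame(read_id = ids, sample_id = sams, polya_len = lens),
       genome = genome, truth_sites = sites)
}

#' Draw mobile and TLS gene sets
#'
#' The mobile set is a random sample of genes; the three TLS sets (body,
#' 5'UTR, 3'UTR location) are drawn independently of mobility (they may
#' overlap the mobile set at the population rate), so TLS membership confers
#' no modification effect of its own and TLS-vs-total contrasts are null.
#'
#' @param models Named list of transcript models.
#' @param config A [sim_config()].
#' @return List of character vectors: `mobile`, `tls_body`, `tls_utr5`,
#'   `tls_utr3`, `total`.
#' @export
make_gene_sets <- function(models, config) {
  set.seed(config$seed + 55L)
  genes <- unique(vapply(models, `[[`, "", "gene_id"))
  stopifnot(length(genes) >= config$n_mobile, length(genes) >= 3 * config$n_tls)
  mobile <- sample(genes, config$n_mobile)
  tls <- sample(genes, 3 * config$n_tls)
  list(mobile = mobile,
       tls_body = tls[seq_len(config$n_tls)],
       tls_utr5 = tls[config$n_tls + seq_len(config$n_tls)],
       tls_utr3 = tls[2 * config$n_tls + seq_len(config$n_tls)],
       total = genes)
}

#' Simulate a per-site modification fraction table
#'
#' m5C sites appear at random spliced positions with Beta-distributed
#' fractions; fractions in mobile-set transcripts are multiplied by
#' `mod_enrichment_factor` (capped at 1); TLS-set transcripts receive no
#' enrichment. A second, adenine-modification track (`deNovoA`) carries a
#' Gaussian fraction peak centred on the stop codon (the first 3'UTR base).
#'
#' @param models Named list of transcript models.
#' @param gene_sets Output of [make_gene_sets()].
#' @param config A [sim_config()].
#' @return data.frame with columns transcript_id, transcript_pos, fraction,
#'   modtype.
#' @export
simulate_mod_fractions <- function(models, gene_sets, config) {
  set.seed(config$seed + 66L)
  acc <- vector("list", length(models) * 2L)
  k <- 0L
  for (m in models) {
    L <- chain_len(m$chain)
    mobile <- m$gene_id %in% gene_sets$mobile
    # m5C track
    p <- which(stats::runif(L) < config$mod_site_density) - 1L
    if (length(p)) {
      f <- stats::rbeta(length(p), config$mod_beta[1], config$mod_beta[2])
      if (mobile) f <- pmin(1, f * config$mod_enrichment_factor)
      k <- k + 1L
      acc[[k]] <- data.frame(transcript_id = m$transcript_id, transcript_pos = p,
                             fraction = f, modtype = "m5C")
    }
    # adenine track with stop-codon peak
    stop_pos <- L - m$utr3_len
    base <- which(stats::runif(L) < 0.02) - 1L
    win <- seq(max(0, stop_pos - 100), min(L - 1, stop_pos + 100))
    peak <- win[stats::runif(length(win)) < config$mod_stop_density]
    pa <- sort(unique(c(base, peak)))
    if (length(pa)) {
      f <- stats::rbeta(length(pa), 1, 20) +
        config$mod_peak_height * exp(-(pa - stop_pos)^2 / (2 * config$mod_peak_sd^2))
      k <- k + 1L
      acc[[k]] <- data.frame(transcript_id = m$transcript_id, transcript_pos = pa,
                             fraction = pmin(1, f), modtype = "deNovoA")
    }
  }
  out <- do.call(rbind, acc[seq_len(k)])
  rownames(out) <- NULL
  out
}

#' Simulate a differential-isoform count panel
#'
#' Loci carry three isoforms each at `dei_reads_per_locus` reads per tissue.
#' In planted loci the first isoform shifts from `dei_base_prop` to
#' `dei_base_prop + dei_shift` relative abundance between tissues (other
#' isoforms rescaled); null loci keep Dirichlet-drawn proportions in both
#' tissues. Counts are multinomial.
#'
#' @param config A [sim_config()].
#' @return data.frame with cluster_id, locus_id, per-tissue counts, and truth
#'   columns `truth_dei` (planted shifted isoform) and `truth_null`
#'   (isoform of an unshifted locus).
#' @export
simulate_dei_counts <- function(config) {
  set.seed(config$seed + 77L)
  rdirichlet1 <- function(alpha) { x <- stats::rgamma(length(alpha), alpha); x / sum(x) }
  n <- config$dei_n_planted + config$dei_n_null
  acc <- vector("list", n)
  for (i in seq_len(n)) {
    planted <- i <= config$dei_n_planted
    if (planted) {
      rest <- rdirichlet1(c(2, 2))
      pA <- c(config$dei_base_prop, (1 - config$dei_base_prop) * rest)
      p1 <- config$dei_base_prop + config$dei_shift
      pB <- c(p1, (1 - p1) * rest)
    } else {
      pA <- pB <- rdirichlet1(c(2, 2, 2))
    }
    cA <- as.vector(stats::rmultinom(1, config$dei_reads_per_locus, pA))
    cB <- as.vector(stats::rmultinom(1, config$dei_reads_per_locus, pB))
    lid <- sprintf("L%04d", i)
    acc[[i]] <- data.frame(cluster_id = sprintf("%s.%d", lid, 1:3),
                           locus_id = lid, count_a = cA, count_b = cB,
                           truth_dei = planted & (1:3 == 1),
                           truth_null = !planted)
  }
  out <- do.call(rbind, acc)
  rownames(out) <- NULL
  out
}

#' Simulate a differential-gene count panel
#'
#' Per-locus per-tissue means are log-uniform over `deg_lambda_range`;
#' planted loci get a `2^deg_log2fc` effect (alternating direction, with the
#' lower tissue mean still inside the range); counts are Poisson per
#' replicate (two replicates per tissue).
#'
#' @param config A [sim_config()].
#' @return List with `counts` (matrix loci x samples), `design` (data.frame
#'   sample_id/tissue) and `truth` (data.frame locus_id/is_deg/direction).
#' @export
simulate_deg_counts <- function(config) {
  set.seed(config$seed + 88L)
  n <- config$deg_n_loci
  n_deg <- config$deg_n_planted
  rlam <- function(k, lo, hi) exp(stats::runif(k, log(lo), log(hi)))
  lam_a <- rlam(n, config$deg_lambda_range[1], config$deg_lambda_range[2])
  lam_b <- lam_a
  fc <- 2^config$deg_log2fc
  dir <- rep(0L, n)
  if (n_deg > 0) {
    idx <- seq_len(n_deg)
    dir[idx] <- rep(c(1L, -1L), length.out = n_deg)
    base <- rlam(n_deg, config$deg_lambda_range[1], config$deg_lambda_range[2] / fc)
    lam_a[idx] <- ifelse(dir[idx] == 1L, base, base * fc)
    lam_b[idx] <- ifelse(dir[idx] == 1L, base * fc, base)
  }
  counts <- cbind(a1 = stats::rpois(n, lam_a / 2), a2 = stats::rpois(n, lam_a / 2),
                  b1 = stats::rpois(n, lam_b / 2), b2 = stats::rpois(n, lam_b / 2))
  rownames(counts) <- sprintf("L%04d", seq_len(n))
  list(counts = counts,
       design = data.frame(sample_id = c("a1", "a2", "b1", "b2"),
                           tissue = c("tissueA", "tissueA", "tissueB", "tissueB")),
       truth = data.frame(locus_id = rownames(counts), is_deg = dir != 0L,
                          direction = dir))
}

#' Generate a complete synthetic dataset
#'
#' Runs annotation simulation, event planting, read simulation and
#' poly(A)/hexamer planting in sequence.
#'
#' @param config A [sim_config()].
#' @return List with `genome`, `models`, `genes`, `truths`, `truth_table`,
#'   `reads`, `polya`, `truth_sites`.
#' @export
simulate_dataset <- function(config) {
  ann <- simulate_annotation(config)
  pl <- plant_novel_isoforms(ann, config)
  reads <- simulate_reads(pl$truths, config)
  ps <- simulate_polya_and_sites(pl$truths, ann$genome, config)
  list(genome = ps$genome, models = ann$models, genes = ann$genes,
       truths = pl$truths, truth_table = pl$truth_table, reads = reads,
       polya = ps$polya, truth_sites = ps$truth_sites)
}
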