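# Generator contracts: determinism, geometry, the noise model, planted
# poly(A) signals and modification structure.

test_that("simulate_annotation is deterministic and genes never overlap", {
  cfg <- sim_config(n_genes = 50, seed = 21)
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_identical(a1$genome, a2$genome)
  expect_identical(lapply(a1$models, `[[`, "chain"),
                   lapply(a2$models, `[[`, "chain"))
  expect_equal(nrow(a1$genes), 50)
  # interval sweep: sorted spans must not intersect
  g <- a1$genes[order(a1$genes$start), ]
  expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  # every transcript has UTRs of at least the configured floor
  expect_true(all(vapply(a1$models, `[[`, numeric(1), "utr5_len") >= 40))
  expect_true(all(vapply(a1$models, `[[`, numeric(1), "utr3_len") >= 40))
})

test_that("byte-identical file outputs under a fixed seed", {
  cfg <- sim_config(n_genes = 6, events = c(intron_retention = 1),
                    fusion_events = c(i = 1), seed = 22)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  for (f in c(f1, f2)) {
    ds <- simulate_dataset(cfg)
    write_gff3(ds$models, paste0(f, ".gff3"))
    write_bed12(ds$reads, paste0(f, ".bed"))
  }
  expect_identical(readLines(paste0(f1, ".gff3")), readLines(paste0(f2, ".gff3")))
  expect_identical(readLines(paste0(f1, ".bed")), readLines(paste0(f2, ".bed")))
})

test_that("planted chains satisfy their own category (zero-noise closure of labels)", {
  zn <- shared_zero_noise_dataset()
  ds <- zn$ds
  ann <- annotation_index(ds$models)
  for (t in ds$truths) {
    fake <- list(cluster_id = t$truth_id, chain = t$chain)
    call <- classify_isoform(fake, ann)
    expect_equal(call$category, t$category, label = t$truth_id)
    if (t$category == "fusion")
      expect_equal(call$fusion_type, t$fusion_type, label = t$truth_id)
  }
})

test_that("noiseless reads equal truth chains; per-isoform counts are exact", {
  zn <- shared_zero_noise_dataset()
  ds <- zn$ds
  by_truth <- split(ds$reads, read_truth_id(vapply(ds$reads, `[[`, "", "read_id")))
  for (t in ds$truths) {
    rs <- by_truth[[t$truth_id]]
    expect_length(rs, sum(t$counts))
    for (r in rs) expect_equal(r$chain$exons, t$chain$exons)
    # per-sample bookkeeping
    expect_equal(table(vapply(rs, `[[`, "", "sample_id"))[names(t$counts)],
                 table(factor(names(t$counts), levels = names(t$counts))) * 0 + t$counts,
                 ignore_attr = TRUE)
  }
})

test_that("junction jitter stays within tolerance for almost all junctions", {
  cfg <- sim_config(n_genes = 12, events = c(intron_retention = 0),
                    fusion_events = c(i = 0), reads_per_isoform = c(60, 60),
                    truncation_prob_per_nt = 0, junction_jitter_sd = 1,
                    seed = 23)
  ds <- simulate_dataset(cfg)
  devs <- c()
  truth_j <- lapply(ds$truths, function(t) junctions_of(t$chain))
  for (r in ds$reads) {
    tj <- truth_j[[read_truth_id(r$read_id)]]
    rj <- junctions_of(r$chain)
    if (nrow(rj) != nrow(tj)) next
    devs <- c(devs, abs(rj$donor - tj$donor), abs(rj$acceptor - tj$acceptor))
  }
  expect_gt(length(devs), 10000)
  expect_gt(mean(devs <= 5), 0.99)
})

test_that("5' truncation is geometric prefix loss with whole-exon removal", {
  cfg <- sim_config(n_genes = 10, events = c(intron_retention = 0),
                    fusion_events = c(i = 0), reads_per_isoform = c(50, 50),
                    truncation_prob_per_nt = 0.075, junction_jitter_sd = 0,
                    seed = 24)
  ds <- simulate_dataset(cfg)
  losses <- c()
  for (r in ds$reads) {
    t <- ds$truths[[read_truth_id(r$read_id)]]
    # 3' end always preserved, 5' side only ever shrinks
    expect_equal(chain_3p(r$chain), chain_3p(t$chain))
    loss <- chain_len(t$chain) - chain_len(r$chain)
    expect_gte(loss, 0)
    losses <- c(losses, loss)
  }
  # mean prefix loss near the geometric mean (1-p)/p ~ 12.3 nt
  expect_lt(abs(mean(losses) - (1 - 0.075) / 0.075), 2)
})

test_that("poly(A) lengths: tissue means, and most tails below 100 nt", {
  cfg <- sim_config(n_genes = 40, seed = 25)
  ds <- simulate_dataset(cfg)
  s <- summarize_polya(ds$polya)
  tissue <- c(seedling1 = "seedling", seedling2 = "seedling",
              bud1 = "bud", bud2 = "bud")[s$sample_id]
  for (i in seq_len(nrow(s))) {
    mu <- 4 * c(seedling = 17, bud = 21)[[tissue[i]]]
    se <- mu / sqrt(4) / sqrt(s$n[i])     # gamma sd = mean/sqrt(shape)
    expect_lt(abs(s$mean[i] - mu), 3 * se)
    expect_gt(s$frac_lt_100[i], 0.5)      # majority < 100 nt
  }
  # floral-bud tails longer on average than seedling tails
  expect_gt(mean(s$mean[tissue == "bud"]), mean(s$mean[tissue == "seedling"]))
})

test_that("planted hexamer sits in the 14-24 nt upstream window of every site", {
  cfg <- sim_config(n_genes = 40, seed = 26)
  ds <- simulate_dataset(cfg)
  occ <- positional_occurrence(cfg$hexamer, ds$truth_sites, ds$genome)
  expect_gte(occ$fraction, 0.95)
  # offsets are bounded draws around 19 nt
  expect_true(all(ds$truth_sites$offset >= 14 & ds$truth_sites$offset <= 24))
  expect_lt(abs(mean(ds$truth_sites$offset) - 19), 2)
})

test_that("modification table: mobile enrichment, TLS null, bounded fractions", {
  cfg <- sim_config(n_genes = 600, seed = 27)
  ann <- simulate_annotation(cfg)
  gs <- make_gene_sets(ann$models, cfg)
  mt <- simulate_mod_fractions(ann$models, gs, cfg)
  expect_true(all(mt$fraction >= 0 & mt$fraction <= 1))
  rm_ <- region_means(mt, ann$models)
  mob <- rm_$gene_id %in% gs$mobile
  tls <- rm_$gene_id %in% gs$tls_body
  for (region in c("utr5", "body", "utr3")) {
    expect_gt(mean(rm_[[region]][mob]), mean(rm_[[region]][!mob]))
    # TLS mean within 2 SE of the overall mean
    se <- stats::sd(rm_[[region]]) / sqrt(sum(tls))
    expect_lt(abs(mean(rm_[[region]][tls]) - mean(rm_[[region]])), 2 * se)
  }
  # enrichment factor 1 removes the mobile/total difference (null case)
  cfg0 <- sim_config(n_genes = 600, mod_enrichment_factor = 1, seed = 27)
  mt0 <- simulate_mod_fractions(ann$models, gs, cfg0)
  rm0 <- region_means(mt0, ann$models)
  mob0 <- rm0$gene_id %in% gs$mobile
  se0 <- stats::sd(rm0$body) * sqrt(1 / sum(mob0) + 1 / sum(!mob0))
  expect_lt(abs(mean(rm0$body[mob0]) - mean(rm0$body[!mob0])), 3 * se0)
})

test_that("differential panels plant the advertised effects", {
  cfg <- sim_config(seed = 28)
  dei <- simulate_dei_counts(cfg)
  expect_equal(sum(dei$truth_dei), 200)
  per_locus <- tapply(dei$count_a, dei$locus_id, sum)
  expect_true(all(per_locus == 200))
  planted <- dei[dei$truth_dei, ]
  shift <- planted$count_b / 200 - planted$count_a / 200
  expect_lt(abs(mean(shift) - 0.20), 0.02)

  dg <- simulate_deg_counts(cfg)
  expect_equal(dim(dg$counts), c(2000, 4))
  up <- dg$truth$direction == 1
  fc <- (rowSums(dg$counts[, 3:4]) + 1) / (rowSums(dg$counts[, 1:2]) + 1)
  expect_gt(median(fc[up]), 3)
  expect_lt(median(fc[dg$truth$direction == -1]), 1 / 3)
  expect_lt(abs(median(fc[!dg$truth$is_deg]) - 1), 0.2)
})
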