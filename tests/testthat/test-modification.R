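# Metagene modification profiles, w0 convention, set comparisons and the
# stop-codon positional profile.

one_tx <- function(L = 500, utr5 = 100, utr3 = 100) {
  list(t1 = transcript_model("t1", "g1", mkchain(0, L), utr5, utr3))
}

test_that("single site lands in exactly one 3'UTR bin at value 1/bin_size", {
  mods <- one_tx()
  # site mid-3'UTR: position 450 of [400, 500)
  mt <- data.frame(transcript_id = "t1", transcript_pos = 450,
                   fraction = 1.0, modtype = "m5C")
  p <- metagene_profile(mt, mods, "g1", bin_size = 5, out_bins = c(20, 60, 20))
  expect_equal(sum(p$utr5), 0)
  expect_equal(sum(p$body), 0)
  expect_equal(max(p$utr3), 1 / 5)
  expect_equal(sum(p$utr3 > 0), 1)
  expect_equal(p$n_isoforms, 1)
})

test_that("uniform field gives flat bins; bounds respected", {
  mods <- one_tx()
  mt <- data.frame(transcript_id = "t1", transcript_pos = 0:499,
                   fraction = 0.3, modtype = "m5C")
  p <- metagene_profile(mt, mods, "g1")
  for (reg in c("utr5", "body", "utr3"))
    expect_equal(p[[reg]], rep(0.3, length(p[[reg]])), tolerance = 1e-9)
  expect_true(all(unlist(p[c("utr5", "body", "utr3")]) >= 0))
  expect_true(all(unlist(p[c("utr5", "body", "utr3")]) <= 1))
})

test_that("w0 zero-fill: removing a zero-fraction site changes nothing", {
  mods <- one_tx()
  mt <- data.frame(transcript_id = "t1", transcript_pos = c(50, 250, 260, 450),
                   fraction = c(0.4, 0.8, 0, 0.2), modtype = "m5C")
  p_with <- metagene_profile(mt, mods, "g1")
  p_without <- metagene_profile(mt[mt$fraction > 0, ], mods, "g1")
  expect_equal(p_with, p_without)
})

test_that("no-interpolation limit: region length = bin_size x out_bins reproduces direct bins", {
  # 3'UTR of exactly 100 nt -> 20 bins of 5 nt: rescaling must be identity
  mods <- one_tx(L = 500, utr5 = 100, utr3 = 100)
  set.seed(61)
  pos <- 400:499
  frac <- round(stats::runif(100), 3)
  mt <- data.frame(transcript_id = "t1", transcript_pos = pos,
                   fraction = frac, modtype = "m5C")
  p <- metagene_profile(mt, mods, "g1", bin_size = 5, out_bins = c(20, 60, 20))
  direct <- as.numeric(tapply(frac, ceiling(seq_along(pos) / 5), sum)) / 5
  expect_equal(p$utr3, direct, tolerance = 1e-9)
})

test_that("UTR length filter excludes short-UTR isoforms strictly", {
  mods <- c(one_tx(), list(t2 = transcript_model(
    "t2", "g2", mkchain(1000, 1400), utr5_len = 50, utr3_len = 100)))
  mt <- data.frame(transcript_id = c("t1", "t2"), transcript_pos = c(10, 10),
                   fraction = 0.5, modtype = "m5C")
  p <- metagene_profile(mt, mods, c("g1", "g2"), min_utr = 50)
  expect_equal(p$n_isoforms, 1)   # 50 is not "longer than 50"
})

test_that("self-contrast gives zero difference and p ~ 1", {
  cfg <- sim_config(n_genes = 80, n_mobile = 20, n_tls = 10, seed = 62)
  ann <- simulate_annotation(cfg)
  gs <- make_gene_sets(ann$models, cfg)
  mt <- simulate_mod_fractions(ann$models, gs, cfg)
  cmp <- compare_sets(mt, ann$models, list(self = gs$total), n_perm = 200,
                      seed = 1)
  expect_equal(cmp$diff, rep(0, 3), tolerance = 1e-12)
  expect_true(all(cmp$p_perm > 0.9))
})

test_that("small sets are skipped with a warning", {
  cfg <- sim_config(n_genes = 80, n_mobile = 20, n_tls = 10, seed = 62)
  ann <- simulate_annotation(cfg)
  gs <- make_gene_sets(ann$models, cfg)
  mt <- simulate_mod_fractions(ann$models, gs, cfg)
  expect_warning(cmp <- compare_sets(mt, ann$models,
                                     list(tiny = gs$total[1]), n_perm = 50),
                 "skipped")
  expect_null(cmp)
})

test_that("stop-codon profile: planted offset recovered, flat field stays flat", {
  mods <- one_tx()
  mt <- data.frame(transcript_id = "t1", transcript_pos = 410,   # stop at 400
                   fraction = 1, modtype = "deNovoA")
  sc <- stopcodon_meta(mt, mods, window = 50)
  expect_equal(sc$offset[which.max(sc$mean_fraction)], 10)
  flat <- data.frame(transcript_id = "t1", transcript_pos = 350:449,
                     fraction = 0.2, modtype = "deNovoA")
  scf <- stopcodon_meta(flat, mods, window = 40)
  expect_equal(scf$mean_fraction, rep(0.2, 81), tolerance = 1e-9)
})

test_that("set overlap report matches brute-force intersection", {
  expect_equal(set_overlap_report(c("a", "b"), c("a", "b"))$frac_of_a, 1)
  expect_equal(set_overlap_report(c("a"), c("b"))$n_both, 0)
  set.seed(63)
  for (rep in 1:50) {
    a <- sample(LETTERS, sample(3:20, 1))
    b <- sample(LETTERS, sample(3:20, 1))
    r <- set_overlap_report(a, b)
    expect_equal(r$n_both, length(intersect(a, b)))
    expect_equal(r$frac_of_b, length(intersect(a, b)) / length(b))
  }
})

test_that("permutation p-values are super-uniform under the null", {
  # fixed per-isoform means, repeated random null sets: p should not be
  # anti-conservative
  cfg <- sim_config(n_genes = 150, n_mobile = 30, n_tls = 10,
                    mod_enrichment_factor = 1, seed = 64)
  ann <- simulate_annotation(cfg)
  gs <- make_gene_sets(ann$models, cfg)
  mt <- simulate_mod_fractions(ann$models, gs, cfg)
  rm_ <- region_means(mt, ann$models)
  set.seed(65)
  ps <- replicate(500, {
    idx <- sample.int(nrow(rm_), 30)
    obs <- mean(rm_$body[idx]) - mean(rm_$body)
    perm <- replicate(99, {
      j <- sample.int(nrow(rm_), 30)
      mean(rm_$body[j]) - mean(rm_$body)
    })
    (1 + sum(abs(perm) >= abs(obs))) / 100
  })
  for (alpha in c(0.05, 0.1, 0.25))
    expect_lte(mean(ps <= alpha), alpha + 2.5 * sqrt(alpha * (1 - alpha) / 500))
})
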