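# Category assignment: hand-built pattern cases, locus assignment against a
# brute-force oracle, and the planted-panel closure at zero noise.

ref_models <- function() {
  # one gene with a 4-exon transcript, plus a neighbor for fusion cases
  m1 <- transcript_model("gA.1", "gA",
                         mkchain(1000, 1200, 1300, 1500, 1600, 1800, 1900, 2100),
                         utr5_len = 80, utr3_len = 80)
  m2 <- transcript_model("gB.1", "gB", mkchain(2600, 2800, 2900, 3100),
                         utr5_len = 60, utr3_len = 60)
  list(gA.1 = m1, gB.1 = m2)
}

fake_cluster <- function(chain, id = "x") list(cluster_id = id, chain = chain)

test_that("identity, retention, skip and junction patterns get their category", {
  ann <- annotation_index(ref_models())
  cases <- list(
    known = mkchain(1000, 1200, 1300, 1500, 1600, 1800, 1900, 2100),
    # reference intron (1200,1300) covered by one cluster exon
    intron_retention = mkchain(1000, 1500, 1600, 1800, 1900, 2100),
    # novel exon inside intron (1500,1600)... use the larger intron pattern:
    extra_exon = mkchain(1000, 1200, 1300, 1500, 1530, 1570, 1600, 1800, 1900, 2100),
    # internal exon (1600,1800) skipped, flanking boundaries fused
    missing_exon = mkchain(1000, 1200, 1300, 1500, 1900, 2100),
    five_extra = mkchain(700, 800, 1000, 1200, 1300, 1500, 1600, 1800, 1900, 2100),
    three_extra = mkchain(1000, 1200, 1300, 1500, 1600, 1800, 1900, 2100, 2250, 2330),
    five_missing = mkchain(1300, 1500, 1600, 1800, 1900, 2100),
    three_missing = mkchain(1000, 1200, 1300, 1500, 1600, 1800),
    extra_utr = mkchain(1000, 1200, 1300, 1500, 1600, 1800, 1900, 2180),
    missing_utr = mkchain(1030, 1200, 1300, 1500, 1600, 1800, 1900, 2050),
    new_junction = mkchain(1000, 1170, 1300, 1500, 1600, 1800, 1900, 2100))
  for (cat in names(cases)) {
    call <- classify_isoform(fake_cluster(cases[[cat]], cat), ann)
    expect_equal(call$category, cat, label = cat)
    expect_equal(call$matched_ref, "gA.1", label = cat)
  }
})

test_that("spec boundary case: intron fully inside an exon is retention", {
  m <- transcript_model("g.1", "g", mkchain(0, 100, 200, 300), 0, 0)
  ann <- annotation_index(list(g.1 = m))
  call <- classify_isoform(fake_cluster(mkchain(50, 250)), ann)
  expect_equal(call$category, "intron_retention")
})

test_that("fusion typing on hand-built patterns", {
  ann <- annotation_index(ref_models())
  # single-exon read spanning both genes -> ii
  ii <- classify_isoform(fake_cluster(mkchain(1100, 2700)), ann)
  expect_equal(ii$category, "fusion")
  expect_equal(ii$fusion_type, "ii")
  expect_setequal(ii$loci, c("gA", "gB"))
  # all annotated junctions kept + intact intergenic -> iv
  iv <- classify_isoform(fake_cluster(
    mkchain(1000, 1200, 1300, 1500, 1600, 1800, 1900, 2800, 2900, 3100)), ann)
  expect_equal(iv$fusion_type, "iv")
  # novel junction strictly inside the intergenic region -> i
  i_ <- classify_isoform(fake_cluster(
    mkchain(1000, 1200, 1300, 1500, 1600, 1800, 1900, 2200, 2450, 2800, 2900, 3100)), ann)
  expect_equal(i_$fusion_type, "i")
  # a partner-internal junction deviating -> vi
  vi <- classify_isoform(fake_cluster(
    mkchain(1000, 1200, 1300, 1500, 1900, 2800, 2900, 3100)), ann)
  expect_equal(vi$fusion_type, "vi")
  # antisense spliced read across both loci, intergenic spliced out -> v
  v <- classify_isoform(fake_cluster(
    mkchain(1900, 2100, 2600, 2800, strand = "-")), ann)
  expect_equal(v$category, "fusion")
  expect_equal(v$fusion_type, "v")
})

test_that("antisense single locus and intergenic clusters are flagged, not categorized", {
  ann <- annotation_index(ref_models())
  anti <- classify_isoform(fake_cluster(mkchain(1000, 1200, strand = "-")), ann)
  expect_equal(anti$category, "antisense")
  inter <- classify_isoform(fake_cluster(mkchain(2200, 2400)), ann)
  expect_equal(inter$category, "intergenic")
})

test_that("locus assignment equals the brute-force overlap scan", {
  cfg <- sim_config(n_genes = 25, seed = 33)
  ann_raw <- simulate_annotation(cfg)
  ann <- annotation_index(ann_raw$models)
  set.seed(34)
  lo <- min(ann_raw$genes$start); hi <- max(ann_raw$genes$end)
  for (rep in 1:500) {
    ch <- random_chain(n_exons = sample(1:4, 1),
                       strand = sample(c("+", "-"), 1),
                       start = sample(lo:hi, 1))
    got <- assign_locus(fake_cluster(ch), ann)
    want <- oracle_assign_locus(ch, ann_raw$models)
    expect_setequal(got$same, want$same)
    expect_setequal(got$antisense, want$antisense)
  }
})

test_that("calls are invariant to annotation record order", {
  zn <- shared_zero_noise_dataset()
  ds <- zn$ds
  cl <- cluster_all_reads(ds$reads)
  ann1 <- annotation_index(ds$models)
  ann2 <- annotation_index(rev(ds$models))
  c1 <- classify_all(cl, ann1)
  c2 <- classify_all(cl, ann2)
  expect_equal(c1$category, c2$category)
  expect_equal(c1$fusion_type, c2$fusion_type)
})

test_that("full planted panel at zero noise: 100% label agreement", {
  zn <- shared_zero_noise_dataset()
  ds <- zn$ds
  cl <- cluster_all_reads(ds$reads)
  ann <- annotation_index(ds$models)
  calls <- classify_all(cl, ann)
  truth_of <- vapply(cl, function(c)
    names(sort(table(read_truth_id(unlist(c$read_ids))), decreasing = TRUE))[1], "")
  tt <- ds$truth_table
  tcat <- tt$category[match(truth_of, tt$truth_id)]
  tft <- tt$fusion_type[match(truth_of, tt$truth_id)]
  expect_equal(calls$category, unname(tcat))
  expect_equal(calls$fusion_type, unname(tft))
  # panel actually covers everything: 10 single-gene categories + 6 fusion types
  expect_setequal(setdiff(unique(tcat), "known"),
                  c("intron_retention", "extra_exon", "missing_exon",
                    "five_extra", "three_extra", "five_missing",
                    "three_missing", "extra_utr", "missing_utr",
                    "new_junction", "fusion"))
  expect_setequal(setdiff(unique(tft), "none"), c("i", "ii", "iii", "iv", "v", "vi"))
})
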