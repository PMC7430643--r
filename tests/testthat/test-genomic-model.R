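# Core exon-chain algebra and the GFF3/BED12 I/O contracts.

test_that("exon_chain enforces its invariants", {
  expect_error(exon_chain("chr1", "+", c(100, 100)), "start < end")
  expect_error(exon_chain("chr1", "+", c(0, 100, 100, 200)), "gap")
  expect_error(exon_chain("chr1", "+", c(200, 300, 0, 100)), "ascending")
  ch <- mkchain(0, 100, 200, 300)
  expect_equal(chain_span(ch), c(0, 300))
  expect_equal(chain_len(ch), 200)
})

test_that("3'/5' termini are strand-aware", {
  plus <- mkchain(10, 100, 200, 300)
  minus <- mkchain(10, 100, 200, 300, strand = "-")
  expect_equal(chain_3p(plus), 300)
  expect_equal(chain_5p(plus), 10)
  expect_equal(chain_3p(minus), 10)
  expect_equal(chain_5p(minus), 300)
})

test_that("junctions_of reproduces every inter-exon gap", {
  expect_equal(nrow(junctions_of(mkchain(0, 100))), 0)
  j <- junctions_of(mkchain(0, 100, 200, 300))
  expect_equal(j$donor, 100)
  expect_equal(j$acceptor, 200)
  set.seed(1)
  for (rep in 1:25) {
    ch <- random_chain(n_exons = sample(2:10, 1))
    j <- junctions_of(ch)
    expect_equal(nrow(j), nrow(ch$exons) - 1)
    # brute force over gaps
    for (i in seq_len(nrow(j))) {
      expect_equal(j$donor[i], ch$exons[i, 2])
      expect_equal(j$acceptor[i], ch$exons[i + 1, 1])
    }
    # round trip through span + junctions
    back <- chain_from_junctions(ch$chrom, ch$strand, chain_span(ch)[1],
                                 chain_span(ch)[2], j)
    expect_equal(back$exons, ch$exons, ignore_attr = TRUE)
  }
})

test_that("compare_chains: identity, truncation containment and symmetry", {
  x <- mkchain(0, 100, 200, 300, 400, 500)
  id <- compare_chains(x, x, 0)
  expect_equal(id$shared_junctions, 2)
  expect_equal(id$exonic_jaccard, 1.0)
  expect_true(id$a_contains_b_5prime_truncated)

  # read missing the first exon of a 3-exon transcript
  trunc <- mkchain(200, 300, 400, 500)
  rel <- compare_chains(x, trunc, 0)
  expect_true(rel$a_contains_b_5prime_truncated)
  expect_equal(rel$shared_junctions, 1)
  expect_equal(nrow(rel$only_in_a), 1)

  expect_error(compare_chains(x, mkchain(0, 100, strand = "-")), "strand")

  set.seed(2)
  for (rep in 1:50) {
    a <- random_chain(); b <- random_chain()
    ab <- compare_chains(a, b, 5); ba <- compare_chains(b, a, 5)
    expect_equal(ab$shared_junctions, ba$shared_junctions)
    expect_equal(ab$exonic_jaccard, ba$exonic_jaccard)
  }
})

test_that("greedy junction matching equals the bipartite optimum on realistic chains", {
  skip_if_not_installed("igraph")
  set.seed(3)
  for (rep in 1:1000) {
    a <- random_chain(n_exons = sample(2:6, 1), start = 1000)
    b <- if (rep %% 2 == 0) jittered_copy(a) else random_chain(n_exons = sample(2:6, 1), start = 1000)
    ja <- junctions_of(a); jb <- junctions_of(b)
    greedy <- nrow(match_junctions(ja, jb, 5))
    expect_equal(greedy, oracle_max_junction_matching(ja, jb, 5))
  }
})

test_that("GFF3 coordinate conventions and UTR lengths", {
  gff <- c("##gff-version 3",
           "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=gA",
           "chr1\tsrc\tmRNA\t1\t100\t.\t+\t.\tID=gA.1;Parent=gA",
           "chr1\tsrc\texon\t1\t100\t.\t+\t.\tID=gA.1.e1;Parent=gA.1",
           "chr1\tsrc\tgene\t201\t700\t.\t+\t.\tID=gB",
           "chr1\tsrc\tmRNA\t201\t700\t.\t+\t.\tID=gB.1;Parent=gB",
           "chr1\tsrc\texon\t201\t300\t.\t+\t.\tID=gB.1.e1;Parent=gB.1",
           "chr1\tsrc\texon\t401\t500\t.\t+\t.\tID=gB.1.e2;Parent=gB.1",
           "chr1\tsrc\texon\t601\t700\t.\t+\t.\tID=gB.1.e3;Parent=gB.1",
           "chr1\tsrc\tfive_prime_UTR\t201\t260\t.\t+\t.\tID=gB.1.u5;Parent=gB.1")
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff, f)
  mods <- read_gff3(f)
  expect_length(mods, 2)
  # 1-exon gene at GFF3 1..100 -> internal exons [(0,100)]
  expect_equal(mods[["gA.1"]]$chain$exons, cbind(start = 0, end = 100),
               ignore_attr = TRUE)
  # five_prime_UTR covering first 60 nt -> utr5_len 60
  expect_equal(mods[["gB.1"]]$utr5_len, 60)
  expect_equal(mods[["gB.1"]]$gene_id, "gB")

  bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(gff, "chr1\tsrc\tgene\t1\t2"), bad)
  expect_error(read_gff3(bad), "line 11")
})

test_that("GFF3 round trip preserves a multi-gene fixture", {
  cfg <- sim_config(n_genes = 8, seed = 4)
  ann <- simulate_annotation(cfg)
  # add a second transcript to some genes so genes/transcripts differ (5 genes,
  # 8 transcripts total is the fixture scale; here 8 genes + extras)
  mods <- ann$models
  extra <- mods[[1]]
  extra$transcript_id <- paste0(extra$gene_id, ".2")
  mods[[extra$transcript_id]] <- extra
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(mods, f)
  back <- read_gff3(f)
  expect_length(back, length(mods))
  for (id in names(mods)) {
    expect_equal(back[[id]]$chain$exons, mods[[id]]$chain$exons,
                 ignore_attr = TRUE)
    expect_equal(back[[id]]$gene_id, mods[[id]]$gene_id)
    expect_equal(back[[id]]$utr5_len, mods[[id]]$utr5_len)
    expect_equal(back[[id]]$utr3_len, mods[[id]]$utr3_len)
  }
})

test_that("BED12 block structure, strand rule and round trip", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t100\tr1\t0\t+\t10\t100\t0\t1\t90\t0", f)
  r <- read_bed12(f, "s1")
  expect_equal(r[[1]]$chain$exons, cbind(10, 100), ignore_attr = TRUE)
  expect_equal(r[[1]]$three_prime_end, 100)

  writeLines("chr1\t10\t300\tr2\t0\t-\t10\t300\t0\t2\t40,50\t0,250", f)
  r <- read_bed12(f, "s1")
  # minus-strand read: 3' terminus at chromStart
  expect_equal(r[[1]]$three_prime_end, 10)

  # empty output
  write_bed12(list(), f)
  expect_length(readLines(f), 0)

  # round trip on a 100-read fixture
  set.seed(5)
  reads <- lapply(1:100, function(i)
    mkread(sprintf("r%03d", i), random_chain(strand = sample(c("+", "-"), 1))))
  names(reads) <- vapply(reads, `[[`, "", "read_id")
  write_bed12(reads, f)
  back <- read_bed12(f, "s1")
  expect_length(back, 100)
  for (r in back) {
    orig <- reads[[r$read_id]]
    expect_equal(r$chain$exons, orig$chain$exons, ignore_attr = TRUE)
    expect_equal(r$chain$strand, orig$chain$strand)
    expect_equal(r$three_prime_end, orig$three_prime_end)
  }
  # control-sequence reads dropped at load
  ctrl <- c(reads, list(ctrl = mkread("ctrl1", random_chain(chrom = "ENO2"))))
  write_bed12(ctrl, f)
  expect_length(read_bed12(f, "s1", control_seq = "ENO2"), 100)
})

test_that("transcript-coordinate mapping and 5' truncation", {
  ch <- mkchain(0, 100, 200, 300)
  expect_equal(tx_to_genomic(ch, 0, 100), cbind(0, 100), ignore_attr = TRUE)
  expect_equal(tx_to_genomic(ch, 50, 150), rbind(c(50, 100), c(200, 250)),
               ignore_attr = TRUE)
  # minus strand: transcript 0 is the genomic right end
  chm <- mkchain(0, 100, 200, 300, strand = "-")
  expect_equal(tx_to_genomic(chm, 0, 50), cbind(250, 300), ignore_attr = TRUE)

  tr <- truncate_chain_5p(ch, 120)   # crosses the junction: first exon gone
  expect_equal(tr$exons, cbind(220, 300), ignore_attr = TRUE)
  trm <- truncate_chain_5p(chm, 120)
  expect_equal(trm$exons, cbind(0, 80), ignore_attr = TRUE)
})
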