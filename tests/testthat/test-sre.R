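test_that("SRE calling merges stacks, applies support and matches the oracle", {
  # one stack of five identical reads
  rs <- stack_reads("chr1", 100, 175, 5)
  sres <- call_sres(rs, min_support = 3, max_gap = 0)
  expect_length(sres, 1L)
  expect_equal(granges_as_df(sres), data.frame(chrom = "chr1", start = 100L,
                                               end = 175L))

  # two stacks separated by an uncovered 500 bp gap
  gr <- c(GRanges("chr1", IRanges(rep(100, 5), rep(175, 5))),
          GRanges("chr1", IRanges(rep(676, 5), rep(750, 5))))
  rs2 <- read_set(gr, "s1")
  sres2 <- call_sres(rs2, min_support = 3, max_gap = 0)
  expect_length(sres2, 2L)
  expect_equal(granges_as_df(sres2),
               oracle_segment(gr, min_support = 3, max_gap = 0))

  # support threshold
  expect_length(call_sres(stack_reads("chr1", 100, 175, 2), min_support = 3),
                0L)
  # empty input
  expect_length(call_sres(read_set(GRanges(), "s1", 0)), 0L)
})

test_that("emitted SREs are disjoint, sorted, and gap merging follows max_gap", {
  set.seed(42)
  gr <- random_reads(150, max_pos = 20000)
  rs <- read_set(gr, "s1")
  for (mg in c(0L, 25L, 400L)) {
    sres <- call_sres(rs, min_support = 2, max_gap = mg)
    expect_equal(granges_as_df(sres),
                 oracle_segment(gr, min_support = 2, max_gap = mg))
    if (length(sres) > 1L) {
      expect_true(all(countOverlaps(sres, sres) == 1L))
      by_chr <- split(start(sres), as.character(seqnames(sres)))
      expect_true(all(vapply(by_chr, function(s) !is.unsorted(s), TRUE)))
    }
  }
})

test_that("RPKM quantification follows the per-sample depth formula", {
  sre <- GRanges("chr1", IRanges(1001, 2000), sre_id = "SRE00001")
  rs <- stack_reads("chr1", 1200, 1275, 10, total = 1e6)
  q <- quantify_sres(sre, rs)
  expect_equal(unname(q$rpkm[1, 1]), 10)   # 10 reads / (1 kb x 1 M) x 1e9
  expect_equal(unname(q$counts[1, 1]), 10)

  # no overlapping reads
  far <- stack_reads("chr1", 50000, 50075, 4, total = 1e6)
  expect_equal(unname(quantify_sres(sre, far)$rpkm[1, 1]), 0)

  # identical values across samples -> SD 0
  two <- list(stack_reads("chr1", 1200, 1275, 10, "a", total = 1e6),
              stack_reads("chr1", 1200, 1275, 10, "b", total = 1e6))
  expect_equal(unname(quantify_sres(sre, two)$abundance_sd[1]), 0)

  expect_error(quantify_sres(sre, stack_reads("chr1", 1, 75, 3, total = 0)),
               "undefined denominator")
})

test_that("read counts over disjoint SREs never exceed the sample's records", {
  set.seed(7)
  gr <- random_reads(300, max_pos = 30000)
  rs <- read_set(gr, "s1")
  sres <- call_sres(rs, min_support = 1, max_gap = 0)
  q <- quantify_sres(sres, rs)
  expect_lte(sum(q$counts[, 1]), length(gr))
  # with max_gap = 0 every read is inside exactly one covered island
  expect_equal(sum(q$counts[, 1]), length(gr))
})

test_that("decile partition ranks by mean abundance with deterministic ties", {
  sres <- GRanges(rep("chr1", 10), IRanges((1:10) * 1000, width = 100),
                  sre_id = sprintf("SRE%05d", 1:10))
  counts <- matrix(c(10:1), ncol = 1, dimnames = list(sres$sre_id, "s1"))
  q <- list(rpkm = counts * 1.0, counts = counts,
            mean_abundance = setNames(as.numeric(10:1), sres$sre_id),
            abundance_sd = setNames(rep(0, 10), sres$sre_id), sres = sres)
  d <- partition_deciles(q)
  expect_equal(unname(d$decile), 1:10)        # one SRE per decile
  expect_equal(names(which(d$decile == 1L)), "SRE00001")
  expect_equal(unname(d$cumulative_share[10]), 100)

  # equal abundances: decile 1 holds 10% of the mass, ties broken by position
  q$mean_abundance[] <- 5
  q$counts[] <- 3
  d2 <- partition_deciles(q)
  expect_equal(unname(d2$share[1]), 10)
  expect_equal(unname(d2$decile), 1:10)

  q$sres <- sres[1:9]
  q$mean_abundance <- q$mean_abundance[1:9]
  expect_error(partition_deciles(q), "fewer than 10")
})

test_that("classification precedence and 10 kb window behave as specified", {
  ann <- tiny_annotation(
    data.frame(chrom = "chr1", start = 10000, end = 14000, gene_id = "gA"),
    data.frame(chrom = "chr1", start = c(10000, 13500), end = c(10500, 14000),
               gene_id = "gA"))
  mk <- function(s, e) GRanges("chr1", IRanges(s, e),
                               sre_id = "SRE00001")
  # inside an exon
  expect_equal(as.character(classify_sres(mk(10100, 10200), ann)$sre_class),
               "EXON")
  # gene body, no exon
  expect_equal(as.character(classify_sres(mk(11000, 11100), ann)$sre_class),
               "NOVEL_INTRONIC")
  # 5 kb downstream of the gene end
  down <- classify_sres(mk(19001, 19100), ann)
  expect_equal(as.character(down$sre_class), "UPDOWN10K")
  expect_equal(unlist(down$linked_genes), "gA")
  # exactly 10 kb away is still up/downstream; 10,001 bp is orphan
  expect_equal(as.character(classify_sres(mk(24001, 24100), ann)$sre_class),
               "UPDOWN10K")
  orp <- classify_sres(mk(24002, 24100), ann)
  expect_equal(as.character(orp$sre_class), "ORPHAN")
  expect_equal(orp$distance_to_nearest_gene, 10001)
  # far away: orphan at 50 kb
  far <- classify_sres(mk(64001, 64100), ann)
  expect_equal(as.character(far$sre_class), "ORPHAN")
  expect_equal(far$distance_to_nearest_gene, 50000)
})

test_that("every SRE receives exactly one class and multi-gene links survive", {
  ann <- tiny_annotation(
    data.frame(chrom = "chr1", start = c(1000, 1400), end = c(2000, 2600),
               gene_id = c("gA", "gB")))
  hit <- classify_sres(GRanges("chr1", IRanges(1450, 1550), sre_id = "x"),
                       ann)
  expect_equal(as.character(hit$sre_class), "EXON")
  expect_setequal(unlist(hit$linked_genes), c("gA", "gB"))

  set.seed(3)
  sres <- GRanges("chr1", IRanges(sample.int(80000, 50), width = 100),
                  sre_id = sprintf("SRE%05d", 1:50))
  cls <- classify_sres(sres, ann)$sre_class
  expect_false(anyNA(cls))
})

test_that("orphan proximity counts distances inclusively at the threshold", {
  ann <- tiny_annotation(
    data.frame(chrom = "chr1", start = 1000, end = 2000, gene_id = "gA"))
  orp <- GRanges("chr1", IRanges(c(27001, 32002), width = 100),
                 sre_id = c("SRE00001", "SRE00002"))
  orp <- classify_sres(orp, ann)
  expect_true(all(orp$sre_class == "ORPHAN"))
  res <- orphan_proximity(orp, ann, threshold = 30000)
  expect_equal(unname(res$distance), c(25000, 30001))
  expect_equal(res$fraction_within, 0.5)  # 25,000 in; 30,001 out

  # empty annotation: infinite distances, fraction 0
  empty_ann <- tiny_annotation(data.frame(chrom = "chr9", start = 1, end = 2,
                                          gene_id = "zzz"))
  empty_ann$genes <- empty_ann$genes[0]
  res2 <- orphan_proximity(orp, empty_ann)
  expect_true(all(is.infinite(res2$distance)))
  expect_equal(res2$fraction_within, 0)

  # no orphans at all
  none <- classify_sres(GRanges("chr1", IRanges(1100, 1200), sre_id = "a"),
                        ann)
  expect_true(is.na(orphan_proximity(none, ann)$fraction_within))
})

test_that("abundant gene set unions linked genes of non-orphan top-decile SREs", {
  ann <- tiny_annotation(
    data.frame(chrom = "chr1", start = c(1000, 40000), end = c(2000, 41000),
               gene_id = c("gA", "gB")))
  sres <- GRanges("chr1", IRanges(c(1100, 1300, 90000), width = 50),
                  sre_id = sprintf("SRE%05d", 1:3))
  sres <- classify_sres(sres, ann)
  decile <- setNames(c(1L, 1L, 1L), sres$sre_id)
  expect_equal(abundant_gene_set(sres, decile), "gA")  # gA once, orphan none
  decile2 <- setNames(c(1L, 2L, 1L), sres$sre_id)
  expect_equal(abundant_gene_set(sres, decile2), "gA")
})

test_that("synthetic cohorts put ~65% of read mass in the top decile on average", {
  # the share of a single small cohort is noisy (it hinges on the heaviest
  # log-normal draws), so the calibration is checked on the mean over seeds
  shares <- vapply(21:24, function(s) {
    cfg <- sim_config(seed = s)
    gen <- generate_annotation(cfg)
    sim <- simulate_reads(gen$annotation, cfg)
    q <- quantify_sres(call_sres(sim$read_sets), sim$read_sets)
    unname(partition_deciles(q)$share[1])
  }, 0)
  expect_gte(mean(shares), 55)
  expect_lte(mean(shares), 75)
})
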