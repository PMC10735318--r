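gr <- function(chrom, start, end)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))

test_that("conserved_regions sorts, merges and tracks coverage", {
  r <- conserved_regions(c(gr("chr1", 50, 80), gr("chr1", 10, 30),
                           gr("chr1", 25, 40)), genome_length = 1000)
  expect_equal(length(r$regions), 2L)
  expect_equal(GenomicRanges::start(r$regions), c(10L, 50L))
  expect_equal(GenomicRanges::end(r$regions), c(40L, 80L))
  expect_equal(r$total_span, 31L + 31L)
  expect_equal(r$genome_fraction, 62 / 1000)
  expect_error(conserved_regions(gr("chr1", 1, 2000), 1000), "exceeds")
})

test_that("reduction_factor is the inverse genome fraction", {
  r <- conserved_regions(gr("chr1", 1, 250), 1000)
  expect_equal(reduction_factor(r), 4)
  empty <- conserved_regions(GenomicRanges::GRanges(), 1000)
  expect_error(reduction_factor(empty), "empty")
})

test_that("merge_hits_to_regions respects merge_gap on the chosen side", {
  hits <- data.frame(
    query_id = "chrQ", query_start = c(100L, 131L, 400L),
    query_end = c(120L, 160L, 450L),
    target_id = "chrT", target_start = c(1L, 1000L, 2000L),
    target_end = c(21L, 1030L, 2050L),
    strand = "+", score = 50L, evalue = 1e-5)
  # gap of 10 between 120 and 131: not merged at merge_gap 0
  r0 <- merge_hits_to_regions(hits, "query", merge_gap = 0L,
                              genome_length = 10000)
  expect_equal(length(r0$regions), 3L)
  r10 <- merge_hits_to_regions(hits, "query", merge_gap = 10L,
                               genome_length = 10000)
  expect_equal(length(r10$regions), 2L)
  expect_equal(GenomicRanges::start(r10$regions)[1], 100L)
  expect_equal(GenomicRanges::end(r10$regions)[1], 160L)
  # target-side projection is independent of the query side
  rt <- merge_hits_to_regions(hits, "target", merge_gap = 0L,
                              genome_length = 10000)
  expect_equal(length(rt$regions), 3L)
  expect_equal(GenomicRanges::start(rt$regions), c(1L, 1000L, 2000L))
})

test_that("subtract_annotated removes excluded DNA and short fragments", {
  feats <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(150, 400), c(250, 500)),
    strand = "+", category = c("CDS", "tRNA"),
    feature_id = c("cds1", "trna1"), gene_id = c(NA, NA))
  ann <- annotation_set(feats, genes = NULL)
  r <- conserved_regions(gr("chr1", c(100, 390), c(300, 520)), 10000)
  out <- subtract_annotated(r, ann, min_fragment = 20L)
  # 100-300 minus 150-250 leaves 100-149 and 251-300;
  # 390-520 minus 400-500 leaves 390-399 (10 bp, dropped) and 501-520
  expect_equal(GenomicRanges::start(out$regions), c(100L, 251L, 501L))
  expect_equal(GenomicRanges::end(out$regions), c(149L, 300L, 520L))
  expect_error(subtract_annotated(r, ann, excluded = "nonsense"),
               "unknown")
})

test_that("introns and UTRs are not excluded by default", {
  excl <- default_excluded_categories()
  expect_true(all(c("CDS", "rRNA", "tRNA", "snRNA", "snoRNA", "miRNA",
                    "pseudogene") %in% excl))
  expect_false(any(c("exon", "five_prime_UTR", "three_prime_UTR",
                     "gene") %in% excl))
})

test_that("region sequence extraction round-trips through its keys", {
  genome <- c(chr1 = withr::with_seed(1L, random_dna(500L, 0.4)))
  r <- conserved_regions(gr("chr1", c(11, 101), c(40, 160)), 500)
  seqs <- extract_region_sequences(r, genome)
  expect_identical(names(seqs), c("chr1:11-40", "chr1:101-160"))
  expect_identical(unname(seqs[1]), substr(genome[["chr1"]], 11, 40))
  key <- parse_region_key(names(seqs))
  expect_identical(key$chrom, c("chr1", "chr1"))
  expect_identical(key$start, c(11L, 101L))
  expect_identical(key$end, c(40L, 160L))
  expect_error(parse_region_key("chr1_broken"), "malformed")
  expect_error(extract_region_sequences(
    conserved_regions(gr("chrX", 1, 10), 500), genome), "absent")
})
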