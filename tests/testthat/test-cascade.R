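sch <- scoring_scheme()
gum <- gumbel_params(0.18, 0.04)

test_that("search_space measures whole genomes and conserved subsets", {
  genome <- c(chr1 = withr::with_seed(1L, random_dna(4000L, 0.4)))
  whole <- search_space(genome, label = "test:genome")
  expect_equal(whole$length, 4000L)
  expect_equal(whole$reduction, 1)
  expect_false(whole$subset)
  r <- conserved_regions(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(1001, 2000)), 4000)
  sub <- search_space(genome, r, label = "test:conserved")
  expect_equal(sub$length, 1000L)
  expect_equal(sub$reduction, 4)
  expect_true(sub$subset)
  expect_identical(unname(sub$seqs),
                   substr(genome[["chr1"]], 1001, 2000))
})

test_that("staged_search maps subset hits back to genome coordinates", {
  el <- withr::with_seed(2L, random_dna(300L, 0.4))
  # guard bases that mismatch each other pin the optimal alignment
  # exactly to the shared element
  qgenome <- c(chrQ = paste0(withr::with_seed(3L, random_dna(1996L, 0.4)),
                             "AAAA", el, "AAAA",
                             withr::with_seed(4L, random_dna(1696L, 0.4))))
  tgenome <- c(chrT = paste0(withr::with_seed(5L, random_dna(496L, 0.4)),
                             "CCCC", el, "CCCC",
                             withr::with_seed(6L, random_dna(3196L, 0.4))))
  r <- conserved_regions(GenomicRanges::GRanges(
    "chrQ", IRanges::IRanges(1901, 2500)), 4000)
  res <- staged_search(search_space(qgenome, r), search_space(tgenome),
                       sch, gum, max_evalue = 1e-3)
  expect_gte(nrow(res$hits), 1)
  top <- res$hits[1, ]  # sorted by E-value
  expect_equal(top$query_id, "chrQ")
  expect_equal(c(top$query_start, top$query_end), c(2001L, 2300L))
  expect_equal(c(top$target_start, top$target_end), c(501L, 800L))
  expect_false(any(is.na(res$hits$evalue)))
  # the stage ledger records the reduced query length
  expect_equal(res$stage$n, 600L)
  expect_equal(res$stage$m, 4000L)
  expect_equal(res$stage$reduction_applied, 4000 / 600)
})

test_that("both-strand searches double the effective search space", {
  el <- withr::with_seed(7L, random_dna(300L, 0.4))
  q <- c(chrQ = el)
  t <- c(chrT = paste0(withr::with_seed(8L, random_dna(200L, 0.4)), el))
  r1 <- staged_search(search_space(q), search_space(t), sch, gum,
                      both_strands = TRUE)
  r2 <- staged_search(search_space(q), search_space(t), sch, gum,
                      both_strands = FALSE)
  s1 <- r1$hits[r1$hits$strand == "+", ][1, ]
  s2 <- r2$hits[1, ]
  expect_equal(s1$score, s2$score)
  expect_equal(s1$evalue, 2 * s2$evalue)
})

test_that("staged_search requires calibrated parameters", {
  q <- c(chrQ = "ACGTACGTACGT")
  expect_error(staged_search(search_space(q), search_space(q), sch,
                             gumbel = NULL),
               "calibrat")
})

test_that("nearest_gene signs distances by gene orientation", {
  genes <- data.frame(
    gene_id = c("gp", "gm"), seqnames = "chr1",
    start = c(5000L, 20000L), end = c(8000L, 23000L),
    strand = c("+", "-"), tss = c(5000L, 23000L),
    stringsAsFactors = FALSE)
  feats <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand, category = "gene",
    feature_id = genes$gene_id, gene_id = genes$gene_id)
  ann <- annotation_set(feats, genes)
  # left of the plus-strand gene: upstream, negative
  ng <- nearest_gene("chr1", 4000, 4100, ann)
  expect_equal(ng$gene_id, "gp")
  expect_equal(ng$distance, -900L)
  # right of the plus-strand gene: downstream, positive
  ng <- nearest_gene("chr1", 8500, 8600, ann)
  expect_equal(ng$gene_id, "gp")
  expect_equal(ng$distance, 500L)
  # right of the minus-strand gene: upstream in its reading direction
  ng <- nearest_gene("chr1", 23500, 23600, ann)
  expect_equal(ng$gene_id, "gm")
  expect_equal(ng$distance, -500L)
  # overlap gives distance zero
  expect_equal(nearest_gene("chr1", 7900, 8100, ann)$distance, 0L)
  # empty chromosome
  expect_true(is.na(nearest_gene("chr9", 1, 10, ann)$gene_id))
})

test_that("homology lookup is symmetric and rejects NA", {
  map <- homology_map(data.frame(gene_a = c("qa", "qb"),
                                 gene_b = c("ta", "tb")))
  expect_true(is_homolog(map, "qa", "ta"))
  expect_true(is_homolog(map, "ta", "qa"))
  expect_false(is_homolog(map, "qa", "tb"))
  expect_false(is_homolog(map, NA, "ta"))
  expect_equal(is_homolog(map, c("qa", "qb"), c("ta", "ta")),
               c(TRUE, FALSE))
})

test_that("accept_candidates applies strict and homolog-proximity paths", {
  fx <- make_accept_fixture()
  # strong hit: strict path regardless of gene context
  a <- accept_candidates(make_hit(1e-6), fx$query_ann, fx$target_ann,
                         fx$homology)
  expect_equal(nrow(a), 1L)
  expect_equal(a$acceptance_path, "strict_evalue")
  # weak hit near homologous genes: relaxed path
  a <- accept_candidates(make_hit(0.46), fx$query_ann, fx$target_ann,
                         fx$homology)
  expect_equal(a$acceptance_path, "homolog_proximity")
  expect_equal(a$query_gene, "qgene")
  expect_equal(a$target_gene, "tgene")
  # weak hit near a non-homologous gene: rejected
  a <- accept_candidates(make_hit(0.46, target_start = 49500L),
                         fx$query_ann, fx$target_ann, fx$homology)
  expect_equal(nrow(a), 0L)
  rej <- attr(a, "rejects")
  expect_equal(rej$reject_reason, "nearest_genes_not_homologous")
  # E above the relaxed threshold: rejected whatever the genes say
  a <- accept_candidates(make_hit(11), fx$query_ann, fx$target_ann,
                         fx$homology)
  expect_equal(attr(a, "rejects")$reject_reason, "evalue_above_relaxed")
  # thresholds must be ordered
  expect_error(accept_candidates(make_hit(1), fx$query_ann, fx$target_ann,
                                 fx$homology, strict = 10, relaxed = 1))
})

test_that("without annotations only the strict path applies, with a warning", {
  expect_warning(a <- accept_candidates(make_hit(0.46), NULL, NULL, NULL),
                 "strict")
  expect_equal(nrow(a), 0L)
  expect_silent(accept_candidates(make_hit(1e-6), NULL, NULL, NULL))
})

test_that("reversed_control reverses without complementing and counts chance hits", {
  el <- withr::with_seed(9L, random_dna(300L, 0.4))
  q <- c(chrQ = el)
  # target contains the element: a real search finds it, the reversed
  # control must not (reversal destroys homology)
  t <- c(chrT = paste0(withr::with_seed(10L, random_dna(400L, 0.4)), el))
  real <- staged_search(search_space(q), search_space(t), sch, gum)
  expect_gte(nrow(real$hits), 1L)
  ctl <- reversed_control(search_space(q), search_space(t), sch, gum,
                          threshold = 0.01)
  expect_s3_class(ctl, "null_report")
  expect_equal(ctl$count, 0L)
  expect_match(ctl$stage$target, "reversed")
  expect_output(print(ctl), "control hits")
})
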