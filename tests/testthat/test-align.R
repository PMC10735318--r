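sch <- scoring_scheme()

test_that("identical sequences align end to end at the maximum score", {
  s <- withr::with_seed(1L, random_dna(300L, 0.4))
  h <- local_align(c(q = s), c(t = s), sch, min_score = 100L,
                   both_strands = FALSE)
  expect_gte(nrow(h), 1)
  top <- h[which.max(h$score), ]
  expect_equal(top$score, 5L * 300L)
  expect_equal(c(top$query_start, top$query_end), c(1L, 300L))
  expect_equal(c(top$target_start, top$target_end), c(1L, 300L))
  expect_equal(top$strand, "+")
})

test_that("a reverse-complemented homolog is found on the minus strand", {
  s <- withr::with_seed(2L, random_dna(200L, 0.4))
  flank <- withr::with_seed(3L, random_dna(150L, 0.4))
  target <- paste0(flank, deepcne:::revcomp_chr(s), flank)
  h <- local_align(c(q = s), c(t = target), sch, min_score = 200L,
                   both_strands = TRUE)
  expect_gte(nrow(h), 1)
  top <- h[which.max(h$score), ]
  expect_equal(top$strand, "-")
  # coordinates are reported on the forward strand of the target
  expect_equal(c(top$target_start, top$target_end), c(151L, 350L))
  # and the same search without the minus strand finds nothing comparable
  h_fwd <- local_align(c(q = s), c(t = target), sch, min_score = 200L,
                       both_strands = FALSE)
  expect_equal(nrow(h_fwd), 0L)
})

test_that("min_score is a hard floor and validation rejects bad inputs", {
  q <- withr::with_seed(4L, random_dna(400L, 0.4))
  t <- withr::with_seed(5L, random_dna(400L, 0.4))
  h <- local_align(c(q = q), c(t = t), sch, min_score = 40L)
  if (nrow(h)) expect_true(all(h$score >= 40L))
  expect_error(local_align(c(q = q), c(t = t), sch, min_score = 0))
  expect_error(local_align(c(q = "ACGU"), c(t = t), sch, min_score = 10L))
})

test_that("the seed-and-extend path matches the exact path on a planted homology", {
  anc <- withr::with_seed(6L, random_dna(400L, 0.4))
  el_q <- evolve_sequence(anc, 0.15, seed = 61L)
  el_t <- evolve_sequence(anc, 0.15, seed = 62L)
  q <- paste0(withr::with_seed(63L, random_dna(800L, 0.4)), el_q,
              withr::with_seed(64L, random_dna(800L, 0.4)))
  t <- paste0(withr::with_seed(65L, random_dna(800L, 0.4)), el_t,
              withr::with_seed(66L, random_dna(800L, 0.4)))
  exact <- local_align(c(q = q), c(t = t), sch, min_score = 100L,
                       both_strands = FALSE, exact_limit = 1e10)
  heur <- local_align(c(q = q), c(t = t), sch, min_score = 100L,
                      both_strands = FALSE, exact_limit = 0)
  expect_equal(max(heur$score), max(exact$score))
})

test_that("gap-free blocks are consistent with hit coordinates and scores", {
  anc <- withr::with_seed(7L, random_dna(300L, 0.4))
  q <- evolve_sequence(anc, 0.10, indel_rate = 0.01, seed = 71L)
  t <- evolve_sequence(anc, 0.10, indel_rate = 0.01, seed = 72L)
  h <- local_align(c(q = q), c(t = t), sch, min_score = 100L,
                   both_strands = FALSE)
  expect_gte(nrow(h), 1)
  b <- deepcne:::hit_blocks(h)[[1]]
  expect_equal(unname(b[1, "q_start"]), h$query_start[1])
  expect_equal(unname(b[nrow(b), "q_end"]), h$query_end[1])
  expect_equal(unname(b[1, "t_start"]), h$target_start[1])
  expect_equal(unname(b[nrow(b), "t_end"]), h$target_end[1])
  # blocks are gap-free: equal spans on both sides, strictly ordered
  expect_equal(b[, "q_end"] - b[, "q_start"], b[, "t_end"] - b[, "t_start"])
  if (nrow(b) > 1) {
    expect_true(all(diff(b[, "q_start"]) > 0))
    expect_true(all(diff(b[, "t_start"]) > 0))
  }
})

test_that("hit_alignment_strings reconstructs rows that rescore correctly", {
  anc <- withr::with_seed(8L, random_dna(300L, 0.4))
  q <- evolve_sequence(anc, 0.10, indel_rate = 0.02, seed = 81L)
  t <- evolve_sequence(anc, 0.10, indel_rate = 0.02, seed = 82L)
  h <- local_align(c(q = q), c(t = t), sch, min_score = 100L,
                   both_strands = FALSE)
  al <- hit_alignment_strings(h, 1, q, t)
  expect_equal(nchar(al[["query"]]), nchar(al[["target"]]))
  # stripping gaps recovers the aligned substrings
  expect_equal(gsub("-", "", al[["query"]], fixed = TRUE),
               substr(q, h$query_start[1], h$query_end[1]))
  expect_equal(gsub("-", "", al[["target"]], fixed = TRUE),
               substr(t, h$target_start[1], h$target_end[1]))
  # rescoring the columns reproduces the reported score
  qc <- strsplit(al[["query"]], "", fixed = TRUE)[[1]]
  tc <- strsplit(al[["target"]], "", fixed = TRUE)[[1]]
  s <- sch$substitution_matrix
  sub_cols <- qc != "-" & tc != "-"
  subst <- sum(s[cbind(qc[sub_cols], tc[sub_cols])])
  gap_runs <- rle(qc == "-" | tc == "-")
  n_gaps <- sum(gap_runs$values)
  gap_bases <- sum(gap_runs$lengths[gap_runs$values])
  expect_equal(subst + n_gaps * sch$gap_open + gap_bases * sch$gap_extend,
               h$score[1])
})

test_that("minus-strand alignment strings read in query orientation", {
  s <- withr::with_seed(9L, random_dna(150L, 0.4))
  target <- paste0("ACGTACGTAC", deepcne:::revcomp_chr(s), "GGGTTTAAAC")
  h <- local_align(c(q = s), c(t = target), sch, min_score = 200L)
  top <- which(h$strand == "-")[1]
  al <- hit_alignment_strings(h, top, s, target)
  expect_equal(al[["query"]], al[["target"]])
  expect_equal(al[["query"]], s)
})

test_that("empty inputs and no-hit searches return a well-formed empty table", {
  h0 <- local_align(character(0), c(t = "ACGTACGT"), sch, min_score = 10L)
  expect_s3_class(h0, "alignment_hits")
  expect_equal(nrow(h0), 0L)
  q <- strrep("A", 100)
  t <- strrep("C", 100)
  expect_equal(nrow(local_align(c(q = q), c(t = t), sch, min_score = 30L,
                                both_strands = FALSE)), 0L)
})

test_that("N never seeds or scores positively", {
  s <- withr::with_seed(10L, random_dna(100L, 0.4))
  withN <- paste0(strrep("N", 50), s, strrep("N", 50))
  h <- local_align(c(q = s), c(t = withN), sch, min_score = 100L,
                   both_strands = FALSE)
  expect_gte(nrow(h), 1)
  top <- h[which.max(h$score), ]
  # alignment confined to the real bases
  expect_equal(c(top$target_start, top$target_end), c(51L, 150L))
  expect_equal(top$score, 5L * 100L)
})
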