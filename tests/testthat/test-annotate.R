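test_that("box_motif validates patterns and strand modes", {
  expect_error(box_motif("bad", "CCA"), "at least 4")
  expect_error(box_motif("bad", "CCXAT"), "IUPAC")
  expect_error(box_motif("bad", "CCAAT", "sideways"))
  m <- box_motif("CCAAT", "ccaat", "both")
  expect_equal(m$pattern, "CCAAT")
})

test_that("the built-in motif list has the documented patterns", {
  m <- conserved_box_motifs()
  expect_setequal(names(m), c("CCAAT", "E_box", "Wnt_RE", "CArG"))
  expect_equal(m$E_box$pattern, "CANNTG")
  expect_equal(m$CArG$pattern, "CCWWWWWWGG")
  expect_equal(m$CCAAT$strand_mode, "both")
  expect_equal(m$E_box$strand_mode, "forward")
})

test_that("scan_boxes reports perfect and near-perfect conservation", {
  al <- c(a = "AACACGTGAA", b = "AACACGTGAA", c = "AACACGTGAA")
  occ <- scan_boxes(al, max_mismatch_species = 1L)
  eb <- occ[occ$motif == "E_box", ]
  expect_equal(nrow(eb), 1L)
  expect_equal(c(eb$start, eb$end), c(3L, 8L))
  expect_equal(eb$conservation, "perfect")

  al2 <- c(a = "AACACGTGAA", b = "AACACGTGAA", c = "AACACGCGAA")
  occ2 <- scan_boxes(al2, max_mismatch_species = 1L)
  eb2 <- occ2[occ2$motif == "E_box", ]
  expect_equal(eb2$conservation, "near_perfect")
  expect_equal(eb2$mismatching_species, "c")
  # with zero tolerance the degraded window is not reported
  occ0 <- scan_boxes(al2, max_mismatch_species = 0L)
  expect_equal(nrow(occ0[occ0$motif == "E_box", ]), 0L)
})

test_that("occurrences at mismatch tolerance 0 are a subset of tolerance 1", {
  al <- withr::with_seed(5L, vapply(1:3, function(i)
    random_dna(400L, 0.4), character(1)))
  names(al) <- c("a", "b", "c")
  o0 <- scan_boxes(al, max_mismatch_species = 0L)
  o1 <- scan_boxes(al, max_mismatch_species = 1L)
  key <- function(d) paste(d$motif, d$start, d$strand)
  expect_true(all(key(o0) %in% key(o1)))
})

test_that("a gap column counts as a mismatch", {
  al <- c(a = "AACACGTGAA", b = "AACA-GTGAA")
  occ <- scan_boxes(al, max_mismatch_species = 1L)
  eb <- occ[occ$motif == "E_box", ]
  expect_equal(eb$conservation, "near_perfect")
  expect_equal(eb$mismatching_species, "b")
})

test_that("classify_element applies its precedence rules", {
  ann <- make_gene_ann()
  # overlaps the TSS window of g1 (tss 1001, window 500)
  expect_equal(classify_element("chr1", 900, 950, ann)$label, "promoter")
  # overlaps the 3'-UTR (2801-3000) but lies outside the TSS window
  expect_equal(classify_element("chr1", 2900, 2950, ann)$label, "utr3")
  # wholly inside the intron 1501-2500 (and past the TSS window)
  expect_equal(classify_element("chr1", 1700, 1900, ann)$label, "intron")
  # spanning the intron boundary is not "wholly inside"
  expect_equal(classify_element("chr1", 2450, 2550, ann)$label, "enhancer")
  # far from everything
  expect_equal(classify_element("chr1", 8000, 8100, ann)$label, "enhancer")
  # no annotation at all
  cls <- classify_element("chr1", 10, 20, NULL)
  expect_equal(cls$label, "enhancer")
  expect_true(cls$no_annotation)
})

test_that("relative_geometry is strand-aware and composes strands by parity", {
  plus <- data.frame(start = 1000L, end = 2000L, strand = "+",
                     stringsAsFactors = FALSE)
  minus <- data.frame(start = 1000L, end = 2000L, strand = "-",
                      stringsAsFactors = FALSE)
  expect_equal(relative_geometry(100, 200, plus)$position, "upstream")
  expect_equal(relative_geometry(2500, 2600, plus)$position, "downstream")
  # the same coordinates flip for a minus-strand gene
  expect_equal(relative_geometry(100, 200, minus)$position, "downstream")
  expect_equal(relative_geometry(2500, 2600, minus)$position, "upstream")
  expect_equal(relative_geometry(1500, 1600, plus)$position, "internal")
  expect_equal(relative_geometry(100, 200, NULL)$position, "unknown")

  expect_equal(relative_geometry(1, 2, NULL, character())$orientation,
               "same")
  expect_equal(relative_geometry(1, 2, NULL, "-")$orientation, "opposite")
  expect_equal(relative_geometry(1, 2, NULL, c("-", "-"))$orientation,
               "same")
  expect_equal(relative_geometry(1, 2, NULL, c("+", "-", "-"))$orientation,
               "same")
  expect_equal(relative_geometry(1, 2, NULL, NULL)$orientation, "unknown")
  expect_error(relative_geometry(1, 2, NULL, "x"))
})
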