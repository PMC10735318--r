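test_that("the default scheme has the documented scores", {
  sc <- scoring_scheme()
  s <- sc$substitution_matrix
  expect_equal(unname(diag(s)), rep(5L, 4))
  expect_equal(s["A", "G"], -4L)  # transition
  expect_equal(s["C", "T"], -4L)
  expect_equal(s["A", "C"], -6L)  # transversion
  expect_equal(s["G", "T"], -6L)
  expect_true(isSymmetric(s))
  expect_equal(sc$gap_open, -10L)
  expect_equal(sc$gap_extend, -4L)
  expect_true(sc$gapped)
  expect_equal(sum(sc$background_composition), 1)
  expect_equal(unname(sc$background_composition[c("C", "G")]),
               c(0.20, 0.20))
})

test_that("NA gap penalties give an ungapped scheme", {
  sc <- scoring_scheme(gap_open = NA, gap_extend = NA)
  expect_false(sc$gapped)
  expect_true(is.na(sc$gap_open))
})

test_that("schemes with non-negative expected score are rejected", {
  expect_error(scoring_scheme(match = 5L, transition = 5L,
                              transversion = 5L),
               "negative")
  expect_error(scoring_scheme(match = -1L, transition = -1L,
                              transversion = -1L))
})

test_that("background composition is validated", {
  expect_error(scoring_scheme(background_composition =
                                c(A = 0.5, C = 0.5, G = 0.5, T = 0.5)),
               "sum to 1")
  expect_error(scoring_scheme(background_composition =
                                c(A = 0.5, C = 0.5)))
})

test_that("a custom substitution matrix is used as given", {
  m <- matrix(-2L, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                         c("A", "C", "G", "T")))
  diag(m) <- 1L
  sc <- scoring_scheme(substitution_matrix = m)
  expect_equal(sc$substitution_matrix, m)
})

test_that("submat5 scores N as the worst mismatch", {
  sc <- scoring_scheme()
  m5 <- deepcne:::submat5(sc)
  expect_equal(dim(m5), c(5L, 5L))
  expect_true(all(m5[5, ] == min(sc$substitution_matrix)))
  expect_true(all(m5[, 5] == min(sc$substitution_matrix)))
})

test_that("solve_lambda_ungapped reproduces the closed-form anchors", {
  uniform <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  s_pm1 <- scoring_scheme(match = 1L, transition = -1L, transversion = -1L,
                          gap_open = NA, gap_extend = NA,
                          background_composition = uniform)
  # for +1/-1 at uniform composition the root is exactly ln 3
  expect_equal(solve_lambda_ungapped(s_pm1), log(3), tolerance = 1e-7)

  gc40 <- c(A = 0.30, C = 0.20, G = 0.20, T = 0.30)
  s_40 <- scoring_scheme(match = 1L, transition = -1L, transversion = -1L,
                         gap_open = NA, gap_extend = NA,
                         background_composition = gc40)
  expect_equal(solve_lambda_ungapped(s_40), 1.045969, tolerance = 1e-5)
})

test_that("solve_lambda_ungapped satisfies its defining equation", {
  sc <- scoring_scheme()
  lam <- solve_lambda_ungapped(sc)
  p <- sc$background_composition
  s <- sc$substitution_matrix
  expect_equal(sum(outer(p, p) * exp(lam * s)), 1, tolerance = 1e-6)
  expect_gt(lam, 0)
})
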