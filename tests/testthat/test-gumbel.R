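test_that("gumbel_params validates its arguments", {
  expect_error(gumbel_params(-1, 0.1))
  expect_error(gumbel_params(0.2, 0))
  expect_error(gumbel_params(0.2, 0.1, calibration_mode = "guessed"))
  g <- gumbel_params(0.2, 0.1, "analytic_ungapped")
  expect_s3_class(g, "gumbel_params")
  expect_output(print(g), "lambda")
})

test_that("evalue implements E = K m n exp(-lambda s)", {
  g <- gumbel_params(0.25, 0.05)
  expect_equal(evalue(100, g, m = 1e6, n = 5e4),
               0.05 * 1e6 * 5e4 * exp(-0.25 * 100))
  # strictly decreasing in score, linear in each length
  expect_gt(evalue(50, g, 1e6, 5e4), evalue(51, g, 1e6, 5e4))
  expect_equal(evalue(80, g, 2e6, 5e4), 2 * evalue(80, g, 1e6, 5e4))
  expect_equal(evalue(80, g, 1e6, 1e5), 2 * evalue(80, g, 1e6, 5e4))
  expect_error(evalue(Inf, g, 1e6, 5e4))
  expect_error(evalue(10, g, 0, 5e4))
})

test_that("min_score_for_evalue inverts evalue on the integer lattice", {
  g <- gumbel_params(0.18, 0.04)
  for (thr in c(10, 1e-3, 1e-4)) {
    s <- min_score_for_evalue(g, 1e6, 5e4, thr)
    expect_lte(evalue(s, g, 1e6, 5e4), thr)
    expect_gt(evalue(s - 1L, g, 1e6, 5e4), thr)
  }
})

test_that("calibrate_gumbel rejects undersized simulations", {
  sch <- scoring_scheme()
  expect_error(calibrate_gumbel(sch, n_sim = 50L), "at least 100")
  expect_error(calibrate_gumbel(sch, seq_len = 100L))
})

test_that("a small calibration of an ungapped scheme lands near the analytic lambda", {
  # a deliberately light run: wide 15% check that the machinery is sound;
  # the full-accuracy 5% check runs in the acceptance suite
  sch <- scoring_scheme(match = 1L, transition = -1L, transversion = -1L,
                        gap_open = NA, gap_extend = NA,
                        background_composition = c(A = 0.25, C = 0.25,
                                                   G = 0.25, T = 0.25))
  g <- calibrate_gumbel(sch, gc_content = 0.50, seq_len = 1000L,
                        n_sim = 100L, seed = 3L)
  expect_s3_class(g, "gumbel_params")
  lam <- solve_lambda_ungapped(sch)
  expect_lt(abs(g$lambda - lam) / lam, 0.15)
  expect_gt(g$K, 0)
  expect_identical(g$calibration_mode, "simulated")
  expect_gte(g$n_islands, 200L)
})

test_that("calibration is deterministic given the seed", {
  sch <- scoring_scheme(match = 1L, transition = -1L, transversion = -1L,
                        gap_open = NA, gap_extend = NA,
                        background_composition = c(A = 0.25, C = 0.25,
                                                   G = 0.25, T = 0.25))
  g1 <- calibrate_gumbel(sch, gc_content = 0.50, seq_len = 1000L,
                         n_sim = 100L, seed = 4L)
  g2 <- calibrate_gumbel(sch, gc_content = 0.50, seq_len = 1000L,
                         n_sim = 100L, seed = 4L)
  expect_identical(g1$lambda, g2$lambda)
  expect_identical(g1$K, g2$K)
})
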