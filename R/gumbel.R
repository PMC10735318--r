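#' Construct Gumbel (Karlin-Altschul) parameters manually
#'
#' Most users will obtain parameters from [calibrate_gumbel()]; this
#' constructor exists for analytic parameters and for tests.
#'
#' @param lambda positive scale, per score unit.
#' @param K positive prefactor.
#' @param calibration_mode `"analytic_ungapped"` or `"simulated"`.
#' @param n_sim,sim_seed calibration provenance (optional).
#' @return an object of class `gumbel_params`.
#' @export
gumbel_params <- function(lambda, K, calibration_mode = "simulated",
                          n_sim = NA_integer_, sim_seed = NA_integer_) {
  stopifnot(is.numeric(lambda), lambda > 0, is.numeric(K), K > 0)
  calibration_mode <- match.arg(calibration_mode,
                                c("simulated", "analytic_ungapped"))
  structure(list(lambda = lambda, K = K,
                 calibration_mode = calibration_mode,
                 n_sim = n_sim, sim_seed = sim_seed),
            class = "gumbel_params")
}

#' @export
print.gumbel_params <- function(x, ...) {
  cat(sprintf("gumbel_params: lambda = %.6g, K = %.6g (%s%s)\n",
              x$lambda, x$K, x$calibration_mode,
              if (!is.na(x$n_sim)) sprintf(", n_sim = %d", x$n_sim) else ""))
  invisible(x)
}

#' Calibrate Gumbel statistics for a scoring scheme by island simulation
#'
#' Estimates lambda from exact alignment statistics and K from the search
#' engine's own chance-hit rate, over simulated pairs of independent
#' random sequences at the given composition.  Three passes:
#'
#' 1. a small pilot pass records the optimal alignment score of each pair
#'    (exact dynamic programming) and fits a rough Gumbel by the method
#'    of moments with Sheppard's lattice correction, only to place the
#'    island floors of the next two passes;
#' 2. the exact island pass collects, by anchored score-only dynamic
#'    programming, the maxima of *all* positive excursions at or above a
#'    floor chosen for roughly 30 islands per pair.  Island score
#'    excesses over the floor are geometric with rate \eqn{\lambda}, so
#'    \eqn{\hat\lambda = \log(1 + 1/\overline{s - s_0})} (the lattice
#'    maximum-likelihood estimate), free of any heuristic search bias;
#' 3. the engine pass runs the genome-scale seed-and-extend engine on
#'    pairs of eight times `seq_len`, with its floor `s1` placed where a
#'    chance island becomes likely per pair -- i.e. at the score range
#'    genome-scale searches actually threshold on.  Island counts are
#'    Poisson with mean \eqn{K L^2 e^{-\lambda s_1}}, giving
#'    \eqn{\hat K = \overline{c}\, e^{\hat\lambda s_1} / L^2}.
#'
#' Measuring K on the engine's own output at operating scores (rather
#' than on exact optima) matters: the heuristic's sensitivity loss at
#' reporting thresholds is then absorbed into \eqn{\hat K}, keeping
#' E-values honest for the tool as used.  Lambda, in contrast, must come
#' from exact statistics: the engine finds higher-scoring chance islands
#' more readily than lower-scoring ones, which would flatten the fitted
#' tail.  For ungapped schemes the fitted lambda can be cross-checked
#' against the analytic root from [solve_lambda_ungapped()].
#'
#' @param scheme a [scoring_scheme()].
#' @param gc_content G+C fraction of the simulated random sequences
#'   (default 0.40).
#' @param seq_len length scale of the calibration (default 5000); the
#'   engine pass uses pairs of eight times this length so its island
#'   floor sits at genome-search operating scores.
#' @param n_sim number of engine-pass pairs (>= 100).  With ~1 island
#'   per pair the relative standard error of K is about
#'   \eqn{1/\sqrt{n_{sim}}}; lambda comes from ~30 exact islands per
#'   pair over 120 pairs, for ~2-3% relative standard error.
#' @param seed integer seed; calibration is deterministic given the seed.
#' @param seed_length,x_drop engine parameters, matching the search the
#'   calibration will be used for.
#' @return a `gumbel_params` object.
#' @export
calibrate_gumbel <- function(scheme, gc_content = 0.40, seq_len = 5000L,
                             n_sim = 300L, seed = 1L,
                             seed_length = 6L, x_drop = 50L) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  if (n_sim < 100) stop("n_sim must be at least 100")
  stopifnot(seq_len >= 1000)
  sm <- submat5(scheme)
  go <- if (scheme$gapped) scheme$gap_open else 0L
  ge <- if (scheme$gapped) scheme$gap_extend else 0L
  pilot_len <- 1000L
  res <- withr::with_seed(as.integer(seed), {
    pilot <- vapply(seq_len(50L), function(i) {
      q <- random_dna(pilot_len, gc_content)
      t <- random_dna(pilot_len, gc_content)
      cpp_best_local_score(q, t, sm, go, ge, scheme$gapped)
    }, integer(1))
    v <- var(pilot) - 1 / 12  # Sheppard's correction, unit score lattice
    if (v <= 0)
      stop("degenerate calibration: pilot score variance below lattice ",
           "resolution; check the scheme")
    lam0 <- pi / sqrt(6 * v)
    mu0 <- mean(pilot) - 0.5772156649015329 / lam0
    # exact island pass: location scales as log(L^2); place the floor
    # for ~30 islands per pair
    island_len <- 2500L
    n_exact <- 120L
    mu_I <- mu0 + 2 * log(island_len / pilot_len) / lam0
    s0 <- max(1L, as.integer(round(mu_I - log(30) / lam0)))
    exc <- vector("list", n_exact)
    for (i in seq_len(n_exact)) {
      q <- random_dna(island_len, gc_content)
      t <- random_dna(island_len, gc_content)
      sc <- cpp_island_scores(q, t, sm, go, ge, scheme$gapped, s0)
      exc[[i]] <- sc - s0
    }
    exc <- unlist(exc)
    if (length(exc) < 200)
      stop("degenerate calibration: too few chance islands at the floor; ",
           "check the scheme")
    lambda <- log(1 + 1 / mean(exc))
    K0 <- (length(exc) / n_exact) * exp(lambda * s0) /
      as.numeric(island_len)^2
    # high-floor pass: measure K where searches operate, placing the
    # floor for ~2 true islands per pair
    high_len <- 8L * as.integer(seq_len)
    s1 <- max(s0 + 1L,
              as.integer(round(log(K0 * as.numeric(high_len)^2 / 2) /
                                 lambda)))
    counts1 <- integer(n_sim)
    for (i in seq_len(n_sim)) {
      q <- random_dna(high_len, gc_content)
      t <- random_dna(high_len, gc_content)
      h <- local_align(c(q = q), c(t = t), scheme, min_score = s1,
                       both_strands = FALSE, seed_length = seed_length,
                       x_drop = x_drop, exact_limit = 0, max_hits = 10000L)
      counts1[i] <- nrow(h)
    }
    list(s0 = s0, s1 = s1, n_low = length(exc), counts1 = counts1,
         lambda = lambda, high_len = high_len)
  })
  if (sum(res$counts1) < 30)
    stop("degenerate calibration: too few chance islands at the ",
         "operating floor; increase seq_len or n_sim")
  lambda <- res$lambda
  K <- mean(res$counts1) * exp(lambda * res$s1) / as.numeric(res$high_len)^2
  out <- gumbel_params(lambda, K, "simulated", n_sim = as.integer(n_sim),
                       sim_seed = as.integer(seed))
  out$seq_len <- as.integer(seq_len)
  out$gc_content <- gc_content
  out$fit <- "engine_islands"
  out$island_floor <- res$s0
  out$operating_floor <- res$s1
  out$n_islands <- res$n_low
  out$n_operating_islands <- sum(res$counts1)
  out
}

#' Expected chance count (E-value) of a local alignment score
#'
#' Returns \eqn{E = K m n e^{-\lambda s}}: the number of times an alignment
#' of at least score `score` would be expected between random sequences of
#' lengths `m` and `n` at the calibrated composition.  E is strictly
#' decreasing in the score and linear in each search-space length, which is
#' what makes search-space reduction pay off: restricting the query side to
#' 1/174-th of a genome divides every E-value by 174.
#'
#' @param score alignment score (numeric).
#' @param params a [gumbel_params] object.
#' @param m target-side search length in bases.
#' @param n query-side search length in bases.
#' @return numeric E-value(s), non-negative.
#' @export
evalue <- function(score, params, m, n) {
  stopifnot(inherits(params, "gumbel_params"))
  if (!is.numeric(m) || !is.numeric(n) || m <= 0 || n <= 0)
    stop("search lengths m and n must be positive")
  if (any(!is.finite(score))) stop("score must be finite")
  params$K * as.numeric(m) * as.numeric(n) * exp(-params$lambda * score)
}

#' Smallest integer score whose E-value is at or below a threshold
#'
#' @inheritParams evalue
#' @param threshold E-value cutoff.
#' @export
min_score_for_evalue <- function(params, m, n, threshold) {
  stopifnot(inherits(params, "gumbel_params"), threshold > 0)
  if (m <= 0 || n <= 0) stop("search lengths m and n must be positive")
  as.integer(ceiling(log(params$K * as.numeric(m) * as.numeric(n) /
                           threshold) / params$lambda))
}
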