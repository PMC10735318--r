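#' Build a nucleotide scoring scheme
#'
#' A scoring scheme holds the 4x4 substitution score matrix, affine gap
#' penalties and the background base composition against which alignment
#' statistics are computed.  A gap of length L costs
#' `gap_open + L * gap_extend` (both non-positive).  For a scheme to admit
#' local-alignment statistics the expected substitution score under the
#' background composition must be negative while at least one score is
#' positive.
#'
#' The default scheme (match +5, transition -4, transversion -6, gap open
#' -10, gap extend -4) stays positive down to roughly 52% pairwise identity,
#' suiting searches for anciently diverged regulatory DNA where surviving
#' similarity is weak.  All parameters are overridable, and genome-pair
#' specific matrices can be supplied via `substitution_matrix`.
#'
#' @param match,transition,transversion integer scores used to build the
#'   matrix when `substitution_matrix` is not given.
#' @param gap_open non-positive integer, per-gap opening score.
#' @param gap_extend negative integer, per-base gap extension score.  Set
#'   both gap parameters to `NA` for an ungapped scheme.
#' @param background_composition named numeric of A/C/G/T frequencies
#'   summing to 1.  Default A=T=0.30, C=G=0.20 (40% G+C).
#' @param substitution_matrix optional 4x4 integer matrix with dimnames
#'   ACGT, overriding the match/transition/transversion construction.
#' @return an object of class `scoring_scheme`.
#' @examples
#' sc <- scoring_scheme(match = 1, transition = -1, transversion = -1,
#'                      gap_open = NA, gap_extend = NA)
#' solve_lambda_ungapped(sc)  # ln 3 for uniform +1/-1... at 40% gc ~ 1.046
#' @export
scoring_scheme <- function(match = 5L, transition = -4L, transversion = -6L,
                           gap_open = -10L, gap_extend = -4L,
                           background_composition = c(A = 0.30, C = 0.20,
                                                      G = 0.20, T = 0.30),
                           substitution_matrix = NULL) {
  bases <- c("A", "C", "G", "T")
  if (is.null(substitution_matrix)) {
    s <- matrix(as.integer(transversion), 4, 4, dimnames = list(bases, bases))
    s["A", "G"] <- s["G", "A"] <- s["C", "T"] <- s["T", "C"] <-
      as.integer(transition)
    diag(s) <- as.integer(match)
  } else {
    s <- substitution_matrix
    stopifnot(is.matrix(s), all(dim(s) == c(4, 4)))
    if (is.null(dimnames(s))) dimnames(s) <- list(bases, bases)
    s <- s[bases, bases]
    storage.mode(s) <- "integer"
  }
  p <- background_composition[bases]
  if (anyNA(p)) stop("background_composition must name A, C, G and T")
  if (abs(sum(p) - 1) > 1e-9) stop("background frequencies must sum to 1")
  if (any(p <= 0)) stop("background frequencies must be positive")

  exp_score <- sum(outer(p, p) * s)
  if (exp_score >= 0)
    stop("expected substitution score under the background must be negative")
  if (max(s) <= 0)
    stop("at least one substitution score must be positive")

  gapped <- !(is.na(gap_open) || is.na(gap_extend))
  if (gapped) {
    if (gap_open > 0) stop("gap_open must be non-positive")
    if (gap_extend >= 0) stop("gap_extend must be negative")
  }
  structure(list(substitution_matrix = s,
                 gap_open = if (gapped) as.integer(gap_open) else NA_integer_,
                 gap_extend = if (gapped) as.integer(gap_extend) else NA_integer_,
                 gapped = gapped,
                 background_composition = p),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("scoring_scheme\n")
  print(x$substitution_matrix)
  if (x$gapped)
    cat(sprintf("gap: open %d, extend %d per base\n", x$gap_open, x$gap_extend))
  else cat("ungapped\n")
  cat("background:", paste(sprintf("%s=%.2f", names(x$background_composition),
                                   x$background_composition), collapse = " "),
      "\n")
  invisible(x)
}

# 5x5 matrix including N (row/col 5); N scores as the worst mismatch and
# cannot take part in an exact-match seed.
submat5 <- function(scheme) {
  s <- scheme$substitution_matrix
  worst <- min(s)
  m <- matrix(worst, 5, 5)
  m[1:4, 1:4] <- s
  storage.mode(m) <- "integer"
  m
}

#' Karlin-Altschul lambda for an ungapped scheme
#'
#' Solves \eqn{\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1} for the unique
#' positive root, the scale parameter of the Gumbel law of ungapped local
#' alignment scores between random sequences of the scheme's background
#' composition.  Gap penalties are ignored.
#'
#' @param scheme a [scoring_scheme()].
#' @param tol relative tolerance of the root (default 1e-9).
#' @return lambda, in inverse score units.
#' @export
solve_lambda_ungapped <- function(scheme, tol = 1e-9) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  p <- scheme$background_composition
  s <- scheme$substitution_matrix
  pp <- as.vector(outer(p, p))
  sv <- as.vector(s)
  f <- function(lam) sum(pp * exp(lam * sv)) - 1
  # f(0) = 0, f'(0) = E[s] < 0, f(lam) -> Inf: bracket the positive root
  hi <- 1 / max(sv)
  while (f(hi) < 0) hi <- hi * 2
  lo <- hi / 2
  while (f(lo) > 0) { hi <- lo; lo <- lo / 2 }
  stats::uniroot(f, c(lo, hi), tol = tol * hi)$root
}
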