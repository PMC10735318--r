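#' Evolve a DNA sequence by substitutions and indels
#'
#' Applies independent per-site substitutions (each substituted site is
#' changed to one of the three other bases, uniformly) and Poisson-process
#' indels with geometric length distribution.  Used by the synthetic-genome
#' generator to model divergence of functional DNA between species; with
#' `subst_prob = p` per branch, two sequences evolved independently from a
#' common ancestor differ at a site with probability
#' \eqn{2p - 4p^2/3} (two branches, with a 1/3 chance that coincident
#' substitutions agree).
#'
#' @param seq a single DNA string over ACGT (no N).
#' @param subst_prob per-site substitution probability in `[0, 1]`.
#' @param indel_rate expected indel events per site (Poisson).
#' @param indel_len_mean mean indel length in bases (geometric).
#' @param seed integer seed; the result is deterministic given the seed.
#' @return the evolved DNA string.
#' @export
evolve_sequence <- function(seq, subst_prob, indel_rate = 0,
                            indel_len_mean = 3, seed = 1L) {
  if (!is.character(seq) || length(seq) != 1 || nchar(seq) == 0)
    stop("seq must be a single non-empty DNA string")
  check_dna_alphabet(seq, allow_n = FALSE)
  if (!is.numeric(subst_prob) || subst_prob < 0 || subst_prob > 1)
    stop("subst_prob must be in [0, 1]")
  if (indel_rate < 0) stop("indel_rate must be non-negative")
  if (subst_prob == 0 && indel_rate == 0) return(seq)
  withr::with_seed(as.integer(seed),
                   .evolve_chr(seq, subst_prob, indel_rate, indel_len_mean))
}

# same operation drawing from the current RNG stream (used by the
# generator so one seed governs a whole species)
.evolve_chr <- function(seq, subst_prob, indel_rate = 0, indel_len_mean = 3) {
  bases <- c("A", "C", "G", "T")
  x <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], bases)
  n <- length(x)
  hit <- which(runif(n) < subst_prob)
  if (length(hit)) {
    off <- sample.int(3L, length(hit), replace = TRUE)
    x[hit] <- (x[hit] - 1L + off) %% 4L + 1L
  }
  if (indel_rate > 0) {
    n_ev <- rpois(1, indel_rate * n)
    if (n_ev > 0) {
      pos <- sort(sample.int(length(x), min(n_ev, length(x))),
                  decreasing = TRUE)
      ins <- runif(length(pos)) < 0.5
      lens <- rgeom(length(pos), 1 / indel_len_mean) + 1L
      for (k in seq_along(pos)) {
        if (ins[k]) {
          x <- append(x, sample.int(4L, lens[k], replace = TRUE), pos[k])
        } else {
          drop <- pos[k]:min(length(x), pos[k] + lens[k] - 1L)
          if (length(drop) < length(x)) x <- x[-drop]
        }
      }
    }
  }
  paste(bases[x], collapse = "")
}
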