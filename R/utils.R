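`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a random DNA sequence at a given G+C content
#'
#' @param n sequence length in bases.
#' @param gc_content fraction of G+C bases (default 0.40, the null
#'   composition used throughout the package).
#' @return a single character string over ACGT.
#' @export
random_dna <- function(n, gc_content = 0.40) {
  stopifnot(n >= 0, gc_content > 0, gc_content < 1)
  at <- (1 - gc_content) / 2
  gcp <- gc_content / 2
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(at, gcp, gcp, at)), collapse = "")
}

#' Reverse a DNA sequence without complementing it
#'
#' Base-by-base reversal, used to build the negative-control genome.  DNA
#' does not evolve by reversal (that would flip the backbone bonds), so any
#' similarity to a reversed genome is chance.  This is distinct from
#' reverse-complementation: `reverse_sequence("AACG")` is `"GCAA"`, not
#' `"CGTT"`.
#'
#' @param x character vector of sequences (or a [Biostrings::DNAStringSet]).
#' @return object of the same type with every sequence reversed.
#' @export
reverse_sequence <- function(x) {
  if (methods::is(x, "DNAStringSet") || methods::is(x, "DNAString"))
    return(Biostrings::reverse(x))
  vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = !is.null(names(x)))
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# sequences must be plain character; accept DNAStringSet too
as_seq_chr <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    out <- as.character(x)
    names(out) <- names(x)
    return(out)
  }
  if (methods::is(x, "DNAString")) return(as.character(x))
  if (!is.character(x)) stop("sequences must be character or DNAStringSet")
  x
}

check_dna_alphabet <- function(x, allow_n = TRUE) {
  pat <- if (allow_n) "[^ACGTNacgtn]" else "[^ACGTacgt]"
  bad <- grepl(pat, x)
  if (any(bad)) {
    ch <- regmatches(x[bad][1], regexpr(pat, x[bad][1]))
    stop(sprintf("sequence contains a non-%s base: '%s'",
                 if (allow_n) "ACGTN" else "ACGT", ch))
  }
  invisible(TRUE)
}

# deterministic child seed derivation; keeps results < 2^31
child_seed <- function(seed, k) {
  (as.integer(seed) + 10007L * as.integer(k)) %% 2147483629L
}
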