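empty_hits <- function() {
  structure(
    data.frame(query_id = character(), query_start = integer(),
               query_end = integer(), target_id = character(),
               target_start = integer(), target_end = integer(),
               strand = character(), score = integer(),
               evalue = numeric(), stringsAsFactors = FALSE),
    blocks = list(), class = c("alignment_hits", "data.frame"))
}

hit_blocks <- function(hits) attr(hits, "blocks")

set_hit_blocks <- function(hits, blocks) {
  attr(hits, "blocks") <- blocks
  class(hits) <- c("alignment_hits", "data.frame")
  hits
}

rbind_hits <- function(lst) {
  lst <- Filter(function(h) nrow(h) > 0, lst)
  if (length(lst) == 0) return(empty_hits())
  df <- do.call(rbind, lapply(lst, function(h) {
    d <- h; attr(d, "blocks") <- NULL; class(d) <- "data.frame"; d
  }))
  rownames(df) <- NULL
  set_hit_blocks(df, do.call(c, lapply(lst, hit_blocks)))
}

#' Local alignment of sequence sets by seed-and-extend
#'
#' Finds local alignments with score at least `min_score` between every
#' query and every target sequence.  Small query/target pairs are aligned
#' by exact repeated (Waterman-Eggert) affine-gap dynamic programming, so
#' the best reported score equals the Smith-Waterman optimum; larger pairs
#' use exact-match seeds of length `seed_length`, X-drop ungapped
#' extension, and exact gapped dynamic programming inside windows around
#' extended segments.  `N` scores as the worst mismatch and can neither
#' start a seed nor contribute a positive score.  Overlapping hits are
#' deduplicated keeping the higher score, ties broken by smaller target
#' start.
#'
#' @param queries,targets named character vectors or
#'   [Biostrings::DNAStringSet]s over ACGTN.
#' @param scheme a [scoring_scheme()].
#' @param min_score positive integer score cutoff.
#' @param both_strands also search the reverse complement of each target;
#'   minus-strand hits are reported in forward-target coordinates with
#'   `strand == "-"`.
#' @param seed_length exact-match seed length for the genome-scale path.
#' @param x_drop score drop-off terminating ungapped extension.
#' @param exact_limit pairs with `nchar(q) * nchar(t)` at or below this use
#'   the exact path (default 4e6, i.e. up to ~2 kb x 2 kb).
#' @param max_hits cap on reported alignments per sequence pair and strand.
#' @return a data frame of class `alignment_hits` with columns `query_id`,
#'   `query_start`, `query_end`, `target_id`, `target_start`, `target_end`
#'   (1-based closed, forward strand of each sequence), `strand`, `score`
#'   and `evalue` (NA until assigned by [staged_search()]), plus a
#'   per-hit list of gap-free aligned blocks in `attr(, "blocks")`.
#' @export
local_align <- function(queries, targets, scheme, min_score,
                        both_strands = TRUE, seed_length = 6L, x_drop = 50L,
                        exact_limit = 4e6, max_hits = 100L) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  if (!is.numeric(min_score) || min_score <= 0)
    stop("min_score must be a positive integer")
  queries <- as_seq_chr(queries)
  targets <- as_seq_chr(targets)
  if (length(queries) == 0 || length(targets) == 0) return(empty_hits())
  if (is.null(names(queries)))
    names(queries) <- paste0("q", seq_along(queries))
  if (is.null(names(targets)))
    names(targets) <- paste0("t", seq_along(targets))
  check_dna_alphabet(queries); check_dna_alphabet(targets)

  sm <- submat5(scheme)
  go <- if (scheme$gapped) scheme$gap_open else 0L
  ge <- if (scheme$gapped) scheme$gap_extend else 0L
  strands <- if (both_strands) c("+", "-") else "+"
  qlen <- nchar(queries)

  pieces <- list()
  for (ti in seq_along(targets)) {
    tname <- names(targets)[ti]
    tlen <- nchar(targets[[ti]])
    for (st in strands) {
      tseq <- if (st == "+") targets[[ti]] else revcomp_chr(targets[[ti]])
      small <- as.numeric(qlen) * as.numeric(tlen) <= exact_limit
      raw <- list()
      for (qi in which(small)) {
        r <- cpp_waterman_eggert(queries[[qi]], tseq, sm, go, ge,
                                 as.integer(min_score), as.integer(max_hits),
                                 scheme$gapped)
        if (length(r$score)) { r$query <- rep(qi - 1L, length(r$score)); raw[[length(raw) + 1]] <- r }
      }
      if (any(!small)) {
        big <- which(!small)
        r <- cpp_seed_align(as.list(unname(queries[big])), tseq, sm, go, ge,
                            as.integer(min_score), as.integer(seed_length),
                            as.integer(x_drop), scheme$gapped, 10L,
                            as.integer(ceiling(min_score / 2)))
        if (length(r$score)) { r$query <- big[r$query + 1L] - 1L; raw[[length(raw) + 1]] <- r }
      }
      for (r in raw) {
        nh <- length(r$score)
        qs <- r$qs + 1L; qe <- r$qe; ts <- r$ts + 1L; te <- r$te
        blocks <- lapply(r$blocks, function(b) {
          b[, c(1, 3)] <- b[, c(1, 3)] + 1L
          colnames(b) <- c("q_start", "q_end", "t_start", "t_end")
          b
        })
        if (st == "-") {  # map to forward-target coordinates
          ts2 <- tlen - te + 1L; te2 <- tlen - ts + 1L
          ts <- ts2; te <- te2
          blocks <- lapply(blocks, function(b) {
            t2s <- tlen - b[, "t_end"] + 1L
            t2e <- tlen - b[, "t_start"] + 1L
            b[, "t_start"] <- t2s; b[, "t_end"] <- t2e
            b
          })
        }
        df <- data.frame(query_id = names(queries)[r$query + 1L],
                         query_start = qs, query_end = qe,
                         target_id = tname, target_start = ts,
                         target_end = te, strand = st,
                         score = r$score, evalue = NA_real_,
                         stringsAsFactors = FALSE)
        pieces[[length(pieces) + 1]] <- set_hit_blocks(df, blocks)
      }
    }
  }
  out <- rbind_hits(pieces)
  validate_hits(out)
  out
}

validate_hits <- function(hits) {
  if (nrow(hits) == 0) return(invisible(TRUE))
  stopifnot(all(hits$query_start <= hits$query_end),
            all(hits$target_start <= hits$target_end),
            all(hits$strand %in% c("+", "-")),
            all(is.na(hits$evalue) | hits$evalue >= 0))
  invisible(TRUE)
}

#' Reconstruct the aligned sequence strings of a hit
#'
#' Splices the gap-free blocks of one alignment hit back into a pair of
#' gapped strings sharing a column coordinate system (suitable for
#' [scan_boxes()]).  For minus-strand hits the target substring is
#' reverse-complemented so the rows read in query orientation.
#'
#' @param hits an `alignment_hits` data frame.
#' @param row which hit to reconstruct.
#' @param query_seq,target_seq the full sequences the hit refers to.
#' @return named character vector of two equal-length gapped strings.
#' @export
hit_alignment_strings <- function(hits, row, query_seq, target_seq) {
  stopifnot(row >= 1, row <= nrow(hits))
  query_seq <- as_seq_chr(query_seq)[[1]]
  target_seq <- as_seq_chr(target_seq)[[1]]
  b <- hit_blocks(hits)[[row]]
  minus <- hits$strand[row] == "-"
  tlen <- nchar(target_seq)
  tseq <- if (minus) revcomp_chr(target_seq) else target_seq
  # express target blocks in the aligned (possibly reverse-complemented) frame
  if (minus) {
    t_s <- tlen - b[, "t_end"] + 1L
    t_e <- tlen - b[, "t_start"] + 1L
  } else {
    t_s <- b[, "t_start"]; t_e <- b[, "t_end"]
  }
  qrow <- character(0); trow <- character(0)
  for (k in seq_len(nrow(b))) {
    if (k > 1) {
      qgap <- b[k, "q_start"] - b[k - 1, "q_end"] - 1L
      tgap <- t_s[k] - t_e[k - 1] - 1L
      if (qgap > 0) {
        qrow <- c(qrow, substr(query_seq, b[k - 1, "q_end"] + 1L, b[k, "q_start"] - 1L))
        trow <- c(trow, strrep("-", qgap))
      }
      if (tgap > 0) {
        qrow <- c(qrow, strrep("-", tgap))
        trow <- c(trow, substr(tseq, t_e[k - 1] + 1L, t_s[k] - 1L))
      }
    }
    qrow <- c(qrow, substr(query_seq, b[k, "q_start"], b[k, "q_end"]))
    trow <- c(trow, substr(tseq, t_s[k], t_e[k]))
  }
  c(query = paste(qrow, collapse = ""), target = paste(trow, collapse = ""))
}
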