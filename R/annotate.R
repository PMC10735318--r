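#' Construct a box-motif pattern
#'
#' A short DNA pattern in IUPAC degenerate code, with a strand reporting
#' mode.  `"forward"` motifs are scanned on the forward text only;
#' `"both"` motifs are also scanned as their reverse complement;
#' `"reverse_reported"` marks patterns (such as ATTGG) that are themselves
#' the reverse complement of the motif of interest, so a forward-text
#' match is reported as a reverse-strand occurrence of `name`.
#'
#' @param name motif name used in reports.
#' @param pattern IUPAC string (A C G T plus degenerate codes, e.g. N =
#'   any base, W = A or T); length at least 4.
#' @param strand_mode one of `"forward"`, `"reverse_reported"`, `"both"`.
#' @return object of class `box_motif`.
#' @export
box_motif <- function(name, pattern,
                      strand_mode = c("forward", "reverse_reported",
                                      "both")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(is.character(name), length(name) == 1, nzchar(name),
            is.character(pattern), length(pattern) == 1)
  pattern <- toupper(pattern)
  if (nchar(pattern) < 4)
    stop("box-motif patterns must be at least 4 bases long")
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", pattern))
    stop("pattern must use the IUPAC DNA alphabet: ", pattern)
  structure(list(name = name, pattern = pattern,
                 strand_mode = strand_mode),
            class = "box_motif")
}

#' Built-in conserved box motifs
#'
#' The transcription-factor binding boxes repeatedly seen perfectly or
#' near-perfectly conserved inside deeply conserved regulatory elements:
#' the CCAAT box (scanned on both strands, so a forward-text ATTGG is
#' reported as a reverse-strand CCAAT), the E-box CANNTG, the Wnt response
#' element CTTTG and the CArG box CCWWWWWWGG (CC, six A/T, GG).
#'
#' @return named list of [box_motif()] objects.
#' @export
conserved_box_motifs <- function() {
  list(CCAAT = box_motif("CCAAT", "CCAAT", "both"),
       E_box = box_motif("E_box", "CANNTG", "forward"),
       Wnt_RE = box_motif("Wnt_RE", "CTTTG", "forward"),
       CArG = box_motif("CArG", "CCWWWWWWGG", "forward"))
}

# expansion of one IUPAC code into the base set it matches
.iupac_sets <- list(A = "A", C = "C", G = "G", T = "T",
                    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                    W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                    B = c("C", "G", "T"), D = c("A", "G", "T"),
                    H = c("A", "C", "T"), V = c("A", "C", "G"),
                    N = c("A", "C", "G", "T"))

# does each window of `chars` (character vector of one aligned row,
# gaps as "-") match the IUPAC pattern? gap or N in window = mismatch
.match_positions <- function(chars, pattern) {
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  w <- length(pat)
  n <- length(chars)
  if (n < w) return(logical(0))
  ok <- rep(TRUE, n - w + 1L)
  for (j in seq_len(w)) {
    allowed <- .iupac_sets[[pat[j]]]
    ok <- ok & chars[seq_len(n - w + 1L) + j - 1L] %in% allowed
  }
  ok
}

#' Scan aligned segments for conserved box motifs
#'
#' Slides each motif pattern along the shared alignment columns and
#' reports a window when at least `species_count - max_mismatch_species`
#' rows match the pattern at those columns.  A gap character in the window
#' counts as a mismatch for that row.  Motifs with `strand_mode` `"both"`
#' are additionally scanned as their reverse complement and such matches
#' are reported with `strand == "-"` (e.g. forward-text ATTGG as a
#' reverse-strand CCAAT box).
#'
#' @param alignment named character vector of aligned sequences, one per
#'   species, equal length, gaps as `-`.
#' @param motifs list of [box_motif()] objects (default
#'   [conserved_box_motifs()]).
#' @param max_mismatch_species maximum number of deviating species for a
#'   reported occurrence (default 1; 0 reports only perfect conservation).
#' @return data frame of occurrences: `motif`, `start`/`end` (alignment
#'   columns, 1-based closed), `strand`, `n_matching`, `n_species`,
#'   `conservation` (`"perfect"` or `"near_perfect"`), and a
#'   comma-separated `mismatching_species` column.
#' @export
scan_boxes <- function(alignment, motifs = conserved_box_motifs(),
                       max_mismatch_species = 1L) {
  stopifnot(is.character(alignment), length(alignment) >= 1)
  if (is.null(names(alignment)) || any(!nzchar(names(alignment))))
    names(alignment) <- paste0("seq", seq_along(alignment))
  alignment <- toupper(alignment)
  if (length(unique(nchar(alignment))) != 1)
    stop("aligned segments must all have the same column count")
  stopifnot(max_mismatch_species >= 0,
            max_mismatch_species < length(alignment))
  if (inherits(motifs, "box_motif")) motifs <- list(motifs)
  stopifnot(all(vapply(motifs, inherits, TRUE, "box_motif")))

  rows <- lapply(alignment, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  n_sp <- length(rows)
  need <- n_sp - max_mismatch_species
  out <- list()
  for (m in motifs) {
    pats <- switch(m$strand_mode,
                   forward = list(`+` = m$pattern),
                   reverse_reported = list(`-` = revcomp_chr(m$pattern)),
                   both = list(`+` = m$pattern,
                               `-` = revcomp_chr(m$pattern)))
    # palindromic patterns would double-report on both strands
    if (length(pats) == 2 && pats[[1]] == pats[[2]]) pats <- pats[1]
    for (st in names(pats)) {
      hits <- vapply(rows, .match_positions, logical(
        max(0L, nchar(alignment[[1]]) - nchar(pats[[st]]) + 1L)),
        pattern = pats[[st]])
      if (length(hits) == 0) next
      hits <- matrix(hits, ncol = n_sp,
                     dimnames = list(NULL, names(rows)))
      n_match <- rowSums(hits)
      for (pos in which(n_match >= need)) {
        miss <- names(rows)[!hits[pos, ]]
        out[[length(out) + 1]] <- data.frame(
          motif = m$name, start = pos,
          end = pos + nchar(pats[[st]]) - 1L, strand = st,
          n_matching = as.integer(n_match[pos]), n_species = n_sp,
          conservation = if (n_match[pos] == n_sp) "perfect"
                         else "near_perfect",
          mismatching_species = paste(miss, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(motif = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_matching = integer(), n_species = integer(),
                      conservation = character(),
                      mismatching_species = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$motif, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify a candidate element by its genomic context
#'
#' Assigns one of four labels with fixed precedence: `promoter` if the
#' element overlaps `[tss - tss_window, tss + tss_window)` of any gene in
#' the best-annotated species; else `utr3` if it overlaps an annotated
#' 3'-UTR; else `intron` if it lies wholly inside an intron; else
#' `enhancer`.  Classification is total: every element gets exactly one
#' label.
#'
#' @param chrom,start,end element interval (1-based closed) in the
#'   annotated species' coordinates.
#' @param ann an [annotation_set()] carrying gene models; `NULL` or an
#'   empty set yields `enhancer` with `no_annotation = TRUE`.
#' @param tss_window half-width in bases of the promoter window around
#'   each transcription start site (default 500).
#' @return list of class `element_class` with fields `label`, `evidence`
#'   and `no_annotation`.
#' @export
classify_element <- function(chrom, start, end, ann, tss_window = 500L) {
  stopifnot(is.numeric(start), is.numeric(end), end >= start,
            tss_window >= 0)
  if (is.null(ann) || nrow(ann$genes) == 0)
    return(structure(list(label = "enhancer",
                          evidence = "no gene models available",
                          no_annotation = TRUE),
                     class = "element_class"))
  stopifnot(inherits(ann, "annotation_set"))
  g <- ann$genes[ann$genes$seqnames == chrom, , drop = FALSE]
  # promoter: overlap with the TSS window [tss - w, tss + w)
  if (nrow(g)) {
    lo <- g$tss - tss_window
    hi <- g$tss + tss_window - 1L
    hit <- which(start <= hi & end >= lo)
    if (length(hit)) {
      k <- hit[which.min(abs(g$tss[hit] - (start + end) / 2))]
      return(structure(list(
        label = "promoter",
        evidence = sprintf("overlaps TSS window of %s (TSS at %d)",
                           g$gene_id[k], g$tss[k]),
        no_annotation = FALSE), class = "element_class"))
    }
  }
  el <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  utr3 <- ann$features[ann$features$category == "three_prime_UTR"]
  if (length(utr3)) {
    ov <- GenomicRanges::findOverlaps(el, utr3, ignore.strand = TRUE)
    if (length(ov)) {
      f <- utr3[S4Vectors::subjectHits(ov)[1]]
      return(structure(list(
        label = "utr3",
        evidence = sprintf("overlaps 3'-UTR %s", f$feature_id),
        no_annotation = FALSE), class = "element_class"))
    }
  }
  intr <- intron_ranges(ann)
  if (length(intr)) {
    ov <- GenomicRanges::findOverlaps(el, intr, type = "within",
                                      ignore.strand = TRUE)
    if (length(ov)) {
      f <- intr[S4Vectors::subjectHits(ov)[1]]
      return(structure(list(
        label = "intron",
        evidence = sprintf("wholly inside an intron of %s", f$gene_id),
        no_annotation = FALSE), class = "element_class"))
    }
  }
  structure(list(label = "enhancer",
                 evidence = "no promoter/UTR/intron overlap",
                 no_annotation = FALSE), class = "element_class")
}

#' @export
print.element_class <- function(x, ...) {
  cat(sprintf("element_class: %s (%s)%s\n", x$label, x$evidence,
              if (x$no_annotation) " [no annotation]" else ""))
  invisible(x)
}

#' Gene-relative position and orientation of an element
#'
#' Position is computed strand-aware from the element span versus the
#' gene span: `internal` if they overlap, otherwise `upstream` or
#' `downstream` of the gene in its own reading direction (an element with
#' coordinates after the end of a minus-strand gene is *upstream* of it).
#' Orientation composes the chain of alignment strands leading back to an
#' arbitrarily fixed reference segment: an even number of `-` strands in
#' the chain means `same`, odd means `opposite`.  Once one segment's
#' orientation is fixed, this determines the orientation of all its
#' homologs.
#'
#' @param start,end element interval (1-based closed).
#' @param gene one row of an annotation set's `genes` table (fields
#'   `start`, `end`, `strand`), or `NULL`.
#' @param strand_chain character vector of alignment strands (`"+"`/`"-"`)
#'   linking this element to the reference segment; the reference segment
#'   itself has an empty chain and is `same` by definition.  `NULL` means
#'   the chain is unknown.
#' @return list of class `element_geometry` with fields `position`
#'   (`upstream`/`downstream`/`internal`, or `unknown` without a gene) and
#'   `orientation` (`same`/`opposite`/`unknown`).
#' @export
relative_geometry <- function(start, end, gene, strand_chain = character()) {
  stopifnot(is.numeric(start), is.numeric(end), end >= start)
  position <- if (is.null(gene) || !nrow(as.data.frame(gene))) {
    "unknown"
  } else if (start <= gene$end && end >= gene$start) {
    "internal"
  } else if (end < gene$start) {
    if (identical(gene$strand, "-")) "downstream" else "upstream"
  } else {
    if (identical(gene$strand, "-")) "upstream" else "downstream"
  }
  orientation <- if (is.null(strand_chain)) {
    "unknown"
  } else if (!all(strand_chain %in% c("+", "-"))) {
    stop("strand_chain must contain only '+' and '-'")
  } else if (sum(strand_chain == "-") %% 2 == 0) "same" else "opposite"
  structure(list(position = position, orientation = orientation),
            class = "element_geometry")
}

#' @export
print.element_geometry <- function(x, ...) {
  cat(sprintf("element_geometry: %s, orientation %s\n",
              x$position, x$orientation))
  invisible(x)
}
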