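#' Construct a conserved-region set
#'
#' Sorted, non-overlapping genomic intervals together with the genome
#' length they were drawn from, tracking the fraction of the genome they
#' cover.  The inverse of that fraction is the search-space reduction
#' factor gained by restricting later searches to these regions.
#'
#' @param regions a [GenomicRanges::GRanges] (strand is ignored and
#'   dropped; overlapping or bookended intervals are merged).
#' @param genome_length total genome length in bases.
#' @return object of class `conserved_regions` with fields `regions`,
#'   `total_span`, `genome_length` and `genome_fraction`.
#' @export
conserved_regions <- function(regions, genome_length) {
  stopifnot(methods::is(regions, "GRanges"), is.numeric(genome_length),
            genome_length > 0)
  regions <- GenomicRanges::reduce(GenomicRanges::granges(regions),
                                   ignore.strand = TRUE)
  regions <- GenomicRanges::sort(regions, ignore.strand = TRUE)
  span <- sum(GenomicRanges::width(regions))
  if (span > genome_length)
    stop("total region span exceeds genome_length")
  structure(list(regions = regions, total_span = span,
                 genome_length = as.numeric(genome_length),
                 genome_fraction = span / as.numeric(genome_length)),
            class = "conserved_regions")
}

#' @export
print.conserved_regions <- function(x, ...) {
  frac <- if (x$total_span > 0)
    sprintf("1/%.1f-th of the genome", 1 / x$genome_fraction) else "empty"
  cat(sprintf("conserved_regions: %d intervals, %d bases (%s)\n",
              length(x$regions), x$total_span, frac))
  invisible(x)
}

#' Merge alignment hits into conserved regions
#'
#' Projects hits onto the chosen side (query or target), discards strand,
#' and merges intervals that overlap or lie within `merge_gap` bases of
#' each other.
#'
#' @param hits an `alignment_hits` data frame from [local_align()] or
#'   [staged_search()].
#' @param side `"query"` or `"target"`: which projection to merge.
#' @param merge_gap merge intervals separated by at most this many bases
#'   (default 0: only overlapping or bookended intervals merge).
#' @param genome_length genome length of the chosen side.
#' @return a [conserved_regions()] object.
#' @export
merge_hits_to_regions <- function(hits, side = c("query", "target"),
                                  merge_gap = 0L, genome_length) {
  side <- match.arg(side)
  if (nrow(hits) == 0)
    return(conserved_regions(GenomicRanges::GRanges(), genome_length))
  chrom <- hits[[paste0(side, "_id")]]
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(hits[[paste0(side, "_start")]],
                            hits[[paste0(side, "_end")]]))
  gr <- GenomicRanges::reduce(gr, min.gapwidth = merge_gap + 1L,
                              ignore.strand = TRUE)
  conserved_regions(gr, genome_length)
}

#' Remove annotated DNA from conserved regions
#'
#' Subtracts every base covered by an excluded annotation category
#' (by default protein-coding sequence, rRNA/tRNA/snRNA/snoRNA/miRNA genes
#' and pseudogenes) from the conserved regions, then drops fragments
#' shorter than `min_fragment`.  What remains is conserved DNA whose
#' conservation is *not* explained by a known coding or structural role:
#' candidate regulatory sequence.
#'
#' @param regions a [conserved_regions()] object.
#' @param ann an [annotation_set()] in the same coordinate universe.
#' @param excluded character vector of categories to remove; must come
#'   from the annotation vocabulary.
#' @param min_fragment drop surviving fragments shorter than this
#'   (default 20 bases).
#' @return a new [conserved_regions()] object.
#' @export
subtract_annotated <- function(regions, ann,
                               excluded = default_excluded_categories(),
                               min_fragment = 20L) {
  stopifnot(inherits(regions, "conserved_regions"),
            inherits(ann, "annotation_set"))
  bad <- setdiff(excluded, ANNOTATION_CATEGORIES)
  if (length(bad))
    stop("unknown excluded categories: ", paste(bad, collapse = ", "))
  mask <- ann$features[ann$features$category %in% excluded]
  out <- GenomicRanges::setdiff(regions$regions,
                                GenomicRanges::reduce(
                                  GenomicRanges::granges(mask),
                                  ignore.strand = TRUE),
                                ignore.strand = TRUE)
  out <- out[GenomicRanges::width(out) >= min_fragment]
  conserved_regions(out, regions$genome_length)
}

#' Search-space reduction factor of a conserved-region set
#'
#' `genome_length / total_span`: how many fold the search space shrinks by
#' aligning only against these regions instead of the whole genome, and
#' hence how many fold fewer chance matches are expected at any score.
#'
#' @param regions a [conserved_regions()] object.
#' @return the fold reduction (>= 1 when the regions cover the genome
#'   at most once).
#' @export
reduction_factor <- function(regions) {
  stopifnot(inherits(regions, "conserved_regions"))
  if (regions$total_span == 0)
    stop("cannot compute a reduction factor for an empty region set")
  regions$genome_length / regions$total_span
}

#' Extract the sequences of conserved regions
#'
#' Region keys encode `chromosome:start-end` (1-based, closed) so that
#' hits found against the extracted sequences can be mapped back to
#' genome coordinates with [parse_region_key()].
#'
#' @param regions a [conserved_regions()] object.
#' @param genome a named [Biostrings::DNAStringSet] (or character vector)
#'   of chromosome sequences.
#' @return named character vector of region sequences.
#' @export
extract_region_sequences <- function(regions, genome) {
  stopifnot(inherits(regions, "conserved_regions"))
  genome <- as_seq_chr(genome)
  gr <- regions$regions
  if (length(gr) == 0) return(setNames(character(0), character(0)))
  chrom <- as.character(GenomicRanges::seqnames(gr))
  miss <- setdiff(unique(chrom), names(genome))
  if (length(miss))
    stop("regions refer to chromosomes absent from the genome: ",
         paste(miss, collapse = ", "))
  s <- GenomicRanges::start(gr); e <- GenomicRanges::end(gr)
  if (any(e > nchar(genome)[match(chrom, names(genome))]))
    stop("region extends beyond its chromosome")
  out <- substr(genome[match(chrom, names(genome))], s, e)
  names(out) <- sprintf("%s:%d-%d", chrom, s, e)
  out
}

#' Parse a region key back into genome coordinates
#'
#' @param key character vector of `chromosome:start-end` keys as produced
#'   by [extract_region_sequences()].
#' @return data frame with `chrom`, `start`, `end` (1-based closed).
#' @export
parse_region_key <- function(key) {
  m <- regmatches(key, regexec("^(.*):([0-9]+)-([0-9]+)$", key))
  if (any(vapply(m, length, 1L) != 4)) stop("malformed region key")
  data.frame(chrom = vapply(m, `[`, "", 2),
             start = as.integer(vapply(m, `[`, "", 3)),
             end = as.integer(vapply(m, `[`, "", 4)),
             stringsAsFactors = FALSE)
}
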