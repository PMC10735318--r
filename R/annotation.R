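ANNOTATION_CATEGORIES <- c("CDS", "rRNA", "tRNA", "snRNA", "snoRNA", "miRNA",
                           "pseudogene", "gene", "exon", "five_prime_UTR",
                           "three_prime_UTR")

#' Annotation categories excluded from conserved regions
#'
#' Conserved DNA is only interesting as candidate regulatory sequence once
#' everything whose conservation is otherwise explained has been removed:
#' protein-coding sequence, structural/small RNA genes, and pseudogenes
#' (DNA that used to encode such products).  Introns and UTRs are *not*
#' excluded: conserved elements are known to occur there.
#'
#' @return character vector of category names.
#' @export
default_excluded_categories <- function() {
  c("CDS", "rRNA", "tRNA", "snRNA", "snoRNA", "miRNA", "pseudogene")
}

#' Build an annotation set
#'
#' Container pairing a [GenomicRanges::GRanges] of categorised features
#' with a per-gene model table (TSS and strand).  Categories come from a
#' closed vocabulary; gene models must contain their exons.
#'
#' @param features GRanges with metadata columns `category`, `feature_id`
#'   and `gene_id` (NA where not applicable).
#' @param genes data frame with columns `gene_id`, `seqnames`, `start`,
#'   `end`, `strand`, `tss` (1-based).
#' @return object of class `annotation_set`.
#' @export
annotation_set <- function(features, genes) {
  stopifnot(methods::is(features, "GRanges"))
  md <- S4Vectors::mcols(features)
  stopifnot(all(c("category", "feature_id") %in% colnames(md)))
  bad <- setdiff(unique(md$category), ANNOTATION_CATEGORIES)
  if (length(bad))
    stop("unknown annotation categories: ", paste(bad, collapse = ", "))
  if (!"gene_id" %in% colnames(md)) features$gene_id <- NA_character_
  if (is.null(genes))
    genes <- data.frame(gene_id = character(), seqnames = character(),
                        start = integer(), end = integer(),
                        strand = character(), tss = integer(),
                        stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "seqnames", "start", "end", "strand", "tss")
                %in% colnames(genes)))
  # consistency: every exon lies within its gene's span
  ex <- features[md$category == "exon" & !is.na(features$gene_id)]
  if (length(ex) && nrow(genes)) {
    gidx <- match(ex$gene_id, genes$gene_id)
    ok <- is.na(gidx) |
      (GenomicRanges::start(ex) >= genes$start[gidx] &
         GenomicRanges::end(ex) <= genes$end[gidx])
    if (!all(ok)) stop("gene model inconsistent: exon outside gene span")
  }
  o <- GenomicRanges::order(features)
  structure(list(features = features[o],
                 genes = genes[order(genes$seqnames, genes$start,
                                     genes$gene_id), , drop = FALSE]),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d features, %d gene models\n",
              length(x$features), nrow(x$genes)))
  tab <- table(x$features$category)
  cat(paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

# intron ranges of one annotation set: per-gene span minus exons
intron_ranges <- function(ann) {
  ex <- ann$features[ann$features$category == "exon"]
  if (nrow(ann$genes) == 0) return(GenomicRanges::GRanges())
  out <- list()
  for (k in seq_len(nrow(ann$genes))) {
    g <- ann$genes[k, ]
    gr <- GenomicRanges::GRanges(g$seqnames,
                                 IRanges::IRanges(g$start, g$end))
    gex <- ex[!is.na(ex$gene_id) & ex$gene_id == g$gene_id]
    if (length(gex) == 0) next
    intr <- GenomicRanges::setdiff(gr, GenomicRanges::reduce(
      GenomicRanges::granges(gex), ignore.strand = TRUE))
    if (length(intr)) {
      intr$gene_id <- g$gene_id
      out[[length(out) + 1]] <- intr
    }
  }
  if (length(out) == 0) return(GenomicRanges::GRanges())
  suppressWarnings(do.call(c, out))
}
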