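#' Read and write FASTA sequence files
#'
#' Thin wrappers over Biostrings, fixed at 80-column sequence lines so
#' write/read round-trips are byte-stable.
#'
#' @param path file path.
#' @return `read_fasta`: a named [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such FASTA file: ", path)
  Biostrings::readDNAStringSet(path)
}

#' @param x named character vector or [Biostrings::DNAStringSet].
#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  if (!methods::is(x, "DNAStringSet"))
    x <- Biostrings::DNAStringSet(as_seq_chr(x))
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

# GFF3 type -> annotation category; gene rows are further refined by
# their biotype attribute when present
.gff_type_map <- c(CDS = "CDS", exon = "exon", gene = "gene",
                   five_prime_UTR = "five_prime_UTR",
                   three_prime_UTR = "three_prime_UTR",
                   rRNA = "rRNA", tRNA = "tRNA", snRNA = "snRNA",
                   snoRNA = "snoRNA", miRNA = "miRNA",
                   rRNA_gene = "rRNA", tRNA_gene = "tRNA",
                   pseudogene = "pseudogene",
                   processed_pseudogene = "pseudogene")

#' Read a GFF3 annotation file into an annotation set
#'
#' Maps GFF3 feature types (and, for `gene` rows, `gene_biotype` /
#' `biotype` attributes) onto the package's closed category vocabulary:
#' protein-coding gene models (gene/exon/CDS/UTR) plus the exclusion
#' classes rRNA, tRNA, snRNA, snoRNA, miRNA and pseudogene.  Feature types
#' outside the vocabulary (e.g. `mRNA` rows, chromosome records) are not
#' turned into categories; unrecognised biotypes are retained as plain
#' genes and reported via a message rather than silently excluded.
#'
#' @param path GFF3 file (1-based inclusive coordinates, per the format).
#' @return an [annotation_set()].
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such GFF3 file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  category <- unname(.gff_type_map[type])
  biotype <- if ("gene_biotype" %in% colnames(S4Vectors::mcols(gr)))
    as.character(gr$gene_biotype) else rep(NA_character_, length(gr))
  is_gene <- !is.na(category) & category == "gene"
  bt_mapped <- !is.na(biotype) & biotype %in%
    c("rRNA", "tRNA", "snRNA", "snoRNA", "miRNA", "pseudogene")
  category[is_gene & bt_mapped] <- biotype[is_gene & bt_mapped]
  odd <- is_gene & !bt_mapped & !is.na(biotype) & biotype != "protein_coding"
  if (any(odd))
    message("read_gff3: retaining genes with unmapped biotypes: ",
            paste(unique(biotype[odd]), collapse = ", "))
  keep <- !is.na(category)
  gr <- gr[keep]; category <- category[keep]; type <- type[keep]

  id <- if ("ID" %in% colnames(S4Vectors::mcols(gr)))
    as.character(gr$ID) else rep(NA_character_, length(gr))
  parent <- if ("Parent" %in% colnames(S4Vectors::mcols(gr)))
    vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
           character(1)) else rep(NA_character_, length(gr))
  is_child <- category %in% c("exon", "CDS", "five_prime_UTR",
                              "three_prime_UTR")
  gene_id <- ifelse(category == "gene", id,
                    ifelse(is_child, parent, NA_character_))
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                IRanges::ranges(gr),
                                strand = GenomicRanges::strand(gr))
  out$category <- category
  out$feature_id <- ifelse(is.na(id), paste0("f", seq_along(gr)), id)
  out$gene_id <- gene_id

  gidx <- which(category == "gene")
  genes <- if (length(gidx)) {
    st <- as.character(GenomicRanges::strand(out)[gidx])
    data.frame(gene_id = id[gidx],
               seqnames = as.character(GenomicRanges::seqnames(out)[gidx]),
               start = GenomicRanges::start(out)[gidx],
               end = GenomicRanges::end(out)[gidx],
               strand = st,
               tss = ifelse(st == "-", GenomicRanges::end(out)[gidx],
                            GenomicRanges::start(out)[gidx]),
               stringsAsFactors = FALSE)
  } else NULL
  annotation_set(out, genes)
}

#' Write an annotation set as GFF3
#'
#' @param ann an [annotation_set()].
#' @param path output path.
#' @export
write_gff3 <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  f <- ann$features
  gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(f),
                               IRanges::ranges(f),
                               strand = GenomicRanges::strand(f))
  cat_to_type <- setNames(ANNOTATION_CATEGORIES, ANNOTATION_CATEGORIES)
  gr$type <- unname(cat_to_type[f$category])
  gr$ID <- f$feature_id
  is_child <- f$category %in% c("exon", "CDS", "five_prime_UTR",
                                "three_prime_UTR") & !is.na(f$gene_id)
  gr$Parent <- ifelse(is_child, f$gene_id, NA_character_)
  # the generator's CDS features all start in frame
  gr$phase <- ifelse(f$category == "CDS", 0L, NA_integer_)
  gr$source <- "deepcne"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read and write BED interval files
#'
#' BED is 0-based half-open on disk; in memory intervals are 1-based
#' closed [GenomicRanges::GRanges] (rtracklayer converts at the boundary).
#'
#' @param path file path.
#' @return `read_bed`: a GRanges with `name` and `score` columns.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such BED file: ", path)
  rtracklayer::import(path, format = "bed")
}

#' @param gr a GRanges, optionally with `name` and `score` metadata.
#' @rdname read_bed
#' @export
write_bed <- function(gr, path) {
  stopifnot(methods::is(gr, "GRanges"))
  if (is.null(gr$name)) gr$name <- paste0("region", seq_along(gr))
  if (is.null(gr$score)) gr$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read an orthology table
#'
#' Two-column TSV of homologous gene-ID pairs (query gene, target gene).
#' Lookup is symmetric and genes may appear in several pairs (gene
#' duplicates keep 2-4 copies in vertebrates).
#'
#' @param path TSV path, with or without a header line.
#' @return data frame with columns `gene_a` and `gene_b`.
#' @export
read_orthology <- function(path) {
  if (!file.exists(path)) stop("no such orthology file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- vapply(parts, length, 1L)
  if (any(nc < 2))
    stop("malformed orthology record at line ", which(nc < 2)[1],
         ": expected two tab-separated gene IDs")
  header <- grepl("gene", parts[[1]][1], ignore.case = TRUE)
  if (header) parts <- parts[-1]
  data.frame(gene_a = vapply(parts, `[`, "", 1),
             gene_b = vapply(parts, `[`, "", 2),
             stringsAsFactors = FALSE)
}

#' Write alignment hits as a MAF file
#'
#' Each hit becomes one MAF block with two `s` lines: the query row on the
#' forward strand and the target row on the hit strand.  Per the MAF
#' convention, minus-strand coordinates count from the start of the
#' reverse-complemented source sequence.
#'
#' @param hits an `alignment_hits` data frame in genome coordinates.
#' @param query_genome,target_genome named sequence sets the hit
#'   coordinates refer to.
#' @param path output path.
#' @param query_name,target_name labels prefixed to chromosome names
#'   (typically species names).
#' @export
write_maf <- function(hits, query_genome, target_genome, path,
                      query_name = "query", target_name = "target") {
  query_genome <- as_seq_chr(query_genome)
  target_genome <- as_seq_chr(target_genome)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1 scoring=deepcne", con)
  if (nrow(hits) > 0) for (k in seq_len(nrow(hits))) {
    h <- hits[k, ]
    qsrc <- paste0(query_name, ".", h$query_id)
    tsrc <- paste0(target_name, ".", h$target_id)
    qlen <- nchar(query_genome[[h$query_id]])
    tlen <- nchar(target_genome[[h$target_id]])
    al <- hit_alignment_strings(hits, k, query_genome[[h$query_id]],
                                target_genome[[h$target_id]])
    tstart0 <- if (h$strand == "+") h$target_start - 1L else
      tlen - h$target_end
    w <- max(nchar(qsrc), nchar(tsrc))
    writeLines(sprintf("a score=%d", h$score), con)
    writeLines(sprintf("s %-*s %8d %6d + %9d %s", w, qsrc,
                       h$query_start - 1L,
                       h$query_end - h$query_start + 1L, qlen,
                       al[["query"]]), con)
    writeLines(sprintf("s %-*s %8d %6d %s %9d %s", w, tsrc, tstart0,
                       h$target_end - h$target_start + 1L, h$strand, tlen,
                       al[["target"]]), con)
    writeLines("", con)
  }
  invisible(path)
}
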