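#' Define one side of a homology search
#'
#' A search space is either a whole genome or a conserved-region subset of
#' it.  Its length enters the E-value of every hit, so restricting a side
#' to conserved regions divides all E-values — and multiplies sensitivity —
#' by the reduction factor.
#'
#' @param genome named [Biostrings::DNAStringSet] or character vector of
#'   chromosome sequences.
#' @param regions optional [conserved_regions()] restricting the space.
#' @param label human-readable description for the stage ledger.
#' @return object of class `search_space`.
#' @export
search_space <- function(genome, regions = NULL, label = "genome") {
  genome <- as_seq_chr(genome)
  if (is.null(names(genome)))
    names(genome) <- paste0("chr", seq_along(genome))
  glen <- sum(nchar(genome))
  if (is.null(regions)) {
    structure(list(seqs = genome, length = glen, genome = genome,
                   genome_length = glen, reduction = 1,
                   subset = FALSE, label = label),
              class = "search_space")
  } else {
    stopifnot(inherits(regions, "conserved_regions"))
    seqs <- extract_region_sequences(regions, genome)
    structure(list(seqs = seqs, length = regions$total_span,
                   genome = genome, genome_length = glen,
                   reduction = reduction_factor(regions),
                   subset = TRUE, label = label),
              class = "search_space")
  }
}

# map hit coordinates on extracted region sequences back to the genome
.backmap <- function(ids, starts, ends, space) {
  if (!space$subset)
    return(list(id = ids, start = starts, end = ends))
  key <- parse_region_key(ids)
  list(id = key$chrom, start = key$start + starts - 1L,
       end = key$start + ends - 1L)
}

#' Staged homology search with search-space-aware E-values
#'
#' Runs [local_align()] between two [search_space()]s and assigns each hit
#' the E-value \eqn{K n m e^{-\lambda s}} where `n` is the total query-side
#' search length (the span of the conserved regions when the query is a
#' subset) and `m` the target-side length.  Hits are reported in genome
#' coordinates on both sides.  The returned stage record keeps the
#' search-space bookkeeping — n, m and the cumulative fold reduction
#' relative to whole-genome searching — so the sensitivity gain of each
#' cascade stage is auditable.
#'
#' @param query,target [search_space()] objects.
#' @param scheme a [scoring_scheme()].
#' @param gumbel calibrated [gumbel_params] for the scheme.
#' @param min_score integer score floor; by default the smallest score
#'   whose E-value is at or below `max_evalue`.
#' @param max_evalue report hits with E-values up to this (default 10).
#' @param both_strands search both target strands.
#' @param seed_length,x_drop passed to [local_align()].
#' @return list with `hits` (an `alignment_hits` data frame with
#'   `evalue` filled in, sorted by E-value) and `stage` (a one-row data
#'   frame: labels, n, m, reduction_applied).
#' @export
staged_search <- function(query, target, scheme, gumbel, min_score = NULL,
                          max_evalue = 10, both_strands = TRUE,
                          seed_length = 6L, x_drop = 50L) {
  stopifnot(inherits(query, "search_space"),
            inherits(target, "search_space"),
            inherits(scheme, "scoring_scheme"))
  if (!inherits(gumbel, "gumbel_params"))
    stop("staged_search requires calibrated gumbel_params; ",
         "run calibrate_gumbel() first")
  n <- query$length; m <- target$length
  # searching both target strands doubles the chance-match space
  m_eff <- m * if (both_strands) 2 else 1
  stage <- data.frame(query = query$label, target = target$label,
                      n = n, m = m,
                      reduction_applied = query$reduction * target$reduction,
                      stringsAsFactors = FALSE)
  if (n == 0 || length(query$seqs) == 0) {
    return(list(hits = empty_hits(), stage = stage))
  }
  if (is.null(min_score))
    min_score <- max(1L, min_score_for_evalue(gumbel, m_eff, n, max_evalue))
  hits <- local_align(query$seqs, target$seqs, scheme, min_score,
                      both_strands = both_strands,
                      seed_length = seed_length, x_drop = x_drop)
  if (nrow(hits) > 0) {
    hits$evalue <- evalue(hits$score, gumbel, m_eff, n)
    qb <- .backmap(hits$query_id, hits$query_start, hits$query_end, query)
    tb <- .backmap(hits$target_id, hits$target_start, hits$target_end,
                   target)
    blocks <- hit_blocks(hits)
    if (query$subset || target$subset) {
      qoff <- qb$start - hits$query_start
      toff <- tb$start - hits$target_start
      blocks <- lapply(seq_along(blocks), function(k) {
        b <- blocks[[k]]
        b[, c("q_start", "q_end")] <- b[, c("q_start", "q_end")] + qoff[k]
        b[, c("t_start", "t_end")] <- b[, c("t_start", "t_end")] + toff[k]
        b
      })
    }
    hits$query_id <- qb$id; hits$query_start <- qb$start
    hits$query_end <- qb$end
    hits$target_id <- tb$id; hits$target_start <- tb$start
    hits$target_end <- tb$end
    o <- order(hits$evalue, hits$target_start, hits$query_start)
    df <- hits[o, ]; rownames(df) <- NULL
    hits <- set_hit_blocks(df, blocks[o])
  }
  list(hits = hits, stage = stage)
}

#' Nearest gene to a genomic interval
#'
#' Finds the gene model minimising the base gap to the interval (0 when
#' they overlap).  The sign of the distance encodes the side with respect
#' to gene orientation: negative upstream (5' of the TSS), positive
#' downstream.  Ties are broken by smaller gene start.
#'
#' @param chrom,start,end interval coordinates (1-based closed).
#' @param ann an [annotation_set()] with gene models.
#' @return list with `gene_id` (NA if no gene on the chromosome) and
#'   signed `distance`.
#' @export
nearest_gene <- function(chrom, start, end, ann) {
  stopifnot(inherits(ann, "annotation_set"))
  g <- ann$genes[ann$genes$seqnames == chrom, , drop = FALSE]
  if (nrow(g) == 0)
    return(list(gene_id = NA_character_, distance = NA_integer_))
  gap <- pmax(0L, g$start - end, start - g$end)
  best <- which(gap == min(gap))
  best <- best[which.min(g$start[best])]
  d <- gap[best]
  if (d > 0) {
    before <- end < g$start[best]  # interval left of the gene
    upstream <- (g$strand[best] == "+" & before) |
      (g$strand[best] == "-" & !before)
    d <- if (upstream) -d else d
  }
  list(gene_id = g$gene_id[best], distance = as.integer(d))
}

#' Build a homology map from an orthology table
#'
#' Symmetric lookup over unordered gene-ID pairs.
#'
#' @param orthology data frame with two columns of gene IDs
#'   (e.g. from [read_orthology()]).
#' @return object of class `homology_map`.
#' @export
homology_map <- function(orthology) {
  stopifnot(is.data.frame(orthology), ncol(orthology) >= 2)
  a <- as.character(orthology[[1]]); b <- as.character(orthology[[2]])
  keys <- unique(c(paste(a, b, sep = "\r"), paste(b, a, sep = "\r")))
  structure(list(keys = keys), class = "homology_map")
}

#' Test whether two genes are homologous
#'
#' @param map a [homology_map()].
#' @param gene_a,gene_b gene IDs (vectors recycle).
#' @return logical vector; symmetric in its arguments.
#' @export
is_homolog <- function(map, gene_a, gene_b) {
  stopifnot(inherits(map, "homology_map"))
  out <- paste(gene_a, gene_b, sep = "\r") %in% map$keys
  out & !is.na(gene_a) & !is.na(gene_b)
}

#' Accept candidate elements by E-value and homologous-gene proximity
#'
#' A hit becomes a candidate conserved element if its E-value is at or
#' below the strict threshold, or at or below the relaxed threshold with
#' the nearest gene on the query side and the nearest gene on the target
#' side forming an orthologous pair.  The relaxed path reflects that a
#' weak cross-phylum similarity sitting next to the *same* gene in both
#' genomes is far better evidence than its E-value alone: the E-value
#' measures chance similarity anywhere in the search space, not chance
#' similarity next to the right gene.  When both paths apply the strict
#' one is recorded.
#'
#' @param hits `alignment_hits` with E-values (from [staged_search()]).
#' @param query_ann,target_ann [annotation_set()]s for the two sides
#'   (either may be NULL: only the strict path then applies, with a
#'   warning if relaxed-path candidates existed).
#' @param homology a [homology_map()] (may be NULL, same effect).
#' @param strict strict E-value threshold (default 1e-4).
#' @param relaxed relaxed E-value threshold (default 10); must exceed
#'   `strict`.
#' @param max_gene_distance optional cap in bases on the nearest-gene
#'   distance for the relaxed path (default `Inf`: nearest gene at any
#'   distance, matching the published rule as far as it is stated).
#' @return data frame of accepted candidates: the hit columns plus
#'   `query_gene`, `query_gene_distance`, `target_gene`,
#'   `target_gene_distance`, `acceptance_path`; rejected hits are kept in
#'   `attr(, "rejects")` with a `reject_reason`.
#' @export
accept_candidates <- function(hits, query_ann, target_ann, homology,
                              strict = 1e-4, relaxed = 10,
                              max_gene_distance = Inf) {
  if (!(strict < relaxed)) stop("strict threshold must be below relaxed")
  if (nrow(hits) == 0) {
    out <- cbind(as.data.frame(hits),
                 data.frame(query_gene = character(),
                            query_gene_distance = integer(),
                            target_gene = character(),
                            target_gene_distance = integer(),
                            acceptance_path = character()))
    attr(out, "rejects") <- out
    attr(out, "blocks") <- list()
    return(out)
  }
  if (any(is.na(hits$evalue)))
    stop("hits carry no E-values; run staged_search first")
  have_ann <- !is.null(query_ann) && !is.null(target_ann) &&
    !is.null(homology)
  qg <- rep(NA_character_, nrow(hits)); qd <- rep(NA_integer_, nrow(hits))
  tg <- qg; td <- qd
  if (have_ann) {
    for (k in seq_len(nrow(hits))) {
      a <- nearest_gene(hits$query_id[k], hits$query_start[k],
                        hits$query_end[k], query_ann)
      b <- nearest_gene(hits$target_id[k], hits$target_start[k],
                        hits$target_end[k], target_ann)
      qg[k] <- a$gene_id; qd[k] <- a$distance
      tg[k] <- b$gene_id; td[k] <- b$distance
    }
  }
  strict_ok <- hits$evalue <= strict
  near_ok <- if (have_ann)
    is_homolog(homology, qg, tg) &
      abs(qd) <= max_gene_distance & abs(td) <= max_gene_distance
  else rep(FALSE, nrow(hits))
  relaxed_ok <- hits$evalue <= relaxed & near_ok
  if (!have_ann && any(hits$evalue <= relaxed & !strict_ok))
    warning("no annotations/homology available: only the strict E-value ",
            "path applies; ", sum(hits$evalue <= relaxed & !strict_ok),
            " relaxed-threshold hit(s) could not be evaluated")

  df <- as.data.frame(hits)
  df$query_gene <- qg; df$query_gene_distance <- qd
  df$target_gene <- tg; df$target_gene_distance <- td
  df$acceptance_path <- ifelse(strict_ok, "strict_evalue",
                               ifelse(relaxed_ok, "homolog_proximity",
                                      NA_character_))
  keep <- !is.na(df$acceptance_path)
  rejects <- df[!keep, , drop = FALSE]
  rejects$reject_reason <- ifelse(rejects$evalue > relaxed,
                                  "evalue_above_relaxed",
                                  "nearest_genes_not_homologous")
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL; rownames(rejects) <- NULL
  attr(out, "blocks") <- hit_blocks(hits)[keep]
  attr(out, "rejects") <- rejects
  class(out) <- c("candidate_elements", "data.frame")
  out
}

#' Reversed-genome negative control
#'
#' Repeats a staged search after reversing — but not complementing — every
#' target sequence.  DNA cannot evolve by reversal (that would flip the
#' 3'-to-5' backbone), so every hit against a reversed genome is chance,
#' and in a well-calibrated search the number of control hits with E-value
#' at or below t is approximately t.
#'
#' @inheritParams staged_search
#' @param threshold E-value threshold at which control hits are counted
#'   (default 10).
#' @return list of class `null_report`: `count` of hits with
#'   `E <= threshold`, `min_evalue` observed (NA if no hits), the full
#'   `evalues` vector, the `threshold` and the `stage` record.
#' @export
reversed_control <- function(query, target, scheme, gumbel,
                             min_score = NULL, threshold = 10,
                             both_strands = TRUE, seed_length = 6L,
                             x_drop = 50L) {
  stopifnot(inherits(target, "search_space"))
  rev_target <- target
  rev_target$seqs <- reverse_sequence(target$seqs)
  rev_target$label <- paste0("reversed(", target$label, ")")
  res <- staged_search(query, rev_target, scheme, gumbel,
                       min_score = min_score, max_evalue = threshold,
                       both_strands = both_strands,
                       seed_length = seed_length, x_drop = x_drop)
  ev <- res$hits$evalue
  structure(list(count = sum(ev <= threshold),
                 min_evalue = if (length(ev)) min(ev) else NA_real_,
                 evalues = sort(ev), threshold = threshold,
                 stage = res$stage),
            class = "null_report")
}

#' @export
print.null_report <- function(x, ...) {
  cat(sprintf("null_report: %d control hits with E <= %g (min E = %s)\n",
              x$count, x$threshold,
              if (is.na(x$min_evalue)) "none" else
                format(x$min_evalue, digits = 3)))
  invisible(x)
}
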