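#' Configuration for the synthetic multi-species fixture
#'
#' Describes a set of species genomes generated from a star phylogeny: an
#' unobserved ancestor carries gene loci, regulatory elements and
#' confounder features (conserved coding sequence, structural-RNA genes,
#' pseudogenes); each species evolves every conserved feature independently
#' at `regulatory_divergence` expected substitutions per site, while the
#' rest of the genome is either independent random sequence per species
#' (`background_divergence = "independent"`, the default: distantly related
#' genomes share no detectable background similarity) or ancestral sequence
#' evolved at a faster rate.
#'
#' One planted element (the first upstream element) is inserted in reverse
#' orientation in the last species, so orientation tracking always has
#' exactly one true flip to find.
#'
#' @param species_names species identifiers; the first is treated as the
#'   best-annotated reference by the default pipeline, the second as its
#'   stage-1 partner, the rest as distant targets.
#' @param genome_length bases per species (template length).
#' @param n_gene_loci number of gene loci, each with a full gene model.
#' @param elements_per_locus regulatory elements planted per locus.
#' @param element_length_range min/max element length in bases.
#' @param regulatory_divergence expected substitutions per site per species
#'   branch for conserved features (elements, CDS, RNA genes, pseudogenes).
#' @param background_divergence `"independent"` or a numeric rate greater
#'   than `regulatory_divergence`.
#' @param coding_fraction approximate fraction of the genome occupied by
#'   coding sequence (sets per-gene CDS length).
#' @param rna_gene_count,pseudogene_count numbers of confounder features.
#' @param gc_content background G+C fraction (default 0.40).
#' @param indel_rate indel events per site applied to evolved background
#'   segments (never inside planted features, so truth coordinates stay
#'   exact); ignored when the background is independent.
#' @param indel_len_mean mean indel length.
#' @param seed master seed; all randomness derives from it.
#' @return object of class `fixture_config`.
#' @export
fixture_config <- function(species_names = c("spA", "spB", "spC"),
                           genome_length = 150000L,
                           n_gene_loci = 20L,
                           elements_per_locus = 1L,
                           element_length_range = c(200L, 400L),
                           regulatory_divergence = 0.15,
                           background_divergence = "independent",
                           coding_fraction = 0.10,
                           rna_gene_count = 4L,
                           pseudogene_count = 3L,
                           gc_content = 0.40,
                           indel_rate = 0,
                           indel_len_mean = 3,
                           seed = 42L) {
  stopifnot(length(species_names) >= 2, !anyDuplicated(species_names),
            n_gene_loci >= 1, elements_per_locus >= 1,
            length(element_length_range) == 2,
            element_length_range[1] >= 50,
            element_length_range[1] <= element_length_range[2],
            coding_fraction > 0, coding_fraction < 0.5,
            rna_gene_count >= 0, pseudogene_count >= 0)
  if (!(gc_content > 0 && gc_content < 1)) stop("gc_content must be in (0,1)")
  if (!(regulatory_divergence > 0 && regulatory_divergence < 1))
    stop("regulatory_divergence must be in (0,1)")
  if (!identical(background_divergence, "independent")) {
    if (!is.numeric(background_divergence) ||
        background_divergence <= regulatory_divergence)
      stop("background_divergence must exceed regulatory_divergence ",
           "or be \"independent\"")
  }
  structure(list(species_names = species_names,
                 genome_length = as.integer(genome_length),
                 n_gene_loci = as.integer(n_gene_loci),
                 elements_per_locus = as.integer(elements_per_locus),
                 element_length_range = as.integer(element_length_range),
                 regulatory_divergence = regulatory_divergence,
                 background_divergence = background_divergence,
                 coding_fraction = coding_fraction,
                 rna_gene_count = as.integer(rna_gene_count),
                 pseudogene_count = as.integer(pseudogene_count),
                 gc_content = gc_content,
                 indel_rate = indel_rate,
                 indel_len_mean = indel_len_mean,
                 seed = as.integer(seed)),
            class = "fixture_config")
}

# fixed geometry of the synthetic loci (template coordinates)
.fx_geom <- function(cfg) {
  el_max <- cfg$element_length_range[2]
  cds_per_gene <- max(240L,
                      as.integer(round(cfg$coding_fraction *
                                         cfg$genome_length / cfg$n_gene_loci)))
  cds1 <- cds_per_gene %/% 2L
  cds2 <- cds_per_gene - cds1
  list(utr5 = 200L, intron = 700L, utr3 = 450L,
       cds1 = cds1, cds2 = cds2,
       pre_bg = 400L, post_bg = 400L,
       upstream_gap = 800L, downstream_gap = 500L,
       el_slot = el_max + 200L, el_max = el_max)
}

.fx_placement_cycle <- c("upstream", "tss", "upstream", "intron",
                         "upstream", "utr3", "downstream", "upstream")

.fx_rna_types <- c("tRNA", "rRNA", "snRNA", "snoRNA", "miRNA")
.fx_rna_lengths <- c(tRNA = 120L, rRNA = 400L, snRNA = 150L,
                     snoRNA = 100L, miRNA = 80L)

# clamp an element length so it fits its placement
.fx_clamp_len <- function(len, placement, g) {
  switch(placement,
         tss = min(len, 150L + g$utr5 - 30L),
         intron = min(len, g$intron - 60L),
         utr3 = min(len, g$utr3 - 70L),
         len)
}

#' Generate the synthetic fixture: genomes, annotations, orthology, truth
#'
#' Realises a [fixture_config()] into per-species genome sequences,
#' annotation sets, an orthology table pairing each locus's gene IDs across
#' species, and a truth table listing every planted feature (regulatory
#' elements plus coding/RNA-gene/pseudogene confounders) with exact
#' coordinates, strand and placement.  Deterministic given the config seed.
#'
#' @param config a [fixture_config()].
#' @return object of class `cne_fixture`: list with `genomes` (named list
#'   of [Biostrings::DNAStringSet]), `annotations` (named list of
#'   [annotation_set()]), `orthology` (data frame `gene_a`, `gene_b`),
#'   `truth` (data frame, one row per planted feature per species) and
#'   `config`.
#' @export
build_truth_set <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  cfg <- config
  g <- .fx_geom(cfg)
  epl <- cfg$elements_per_locus
  nl <- cfg$n_gene_loci
  indep_bg <- identical(cfg$background_divergence, "independent")

  pre_zone <- g$upstream_gap + g$el_slot * epl
  gene_len <- g$utr5 + g$cds1 + g$intron + g$cds2 + g$utr3
  post_zone <- g$downstream_gap + g$el_max
  block_len <- g$pre_bg + pre_zone + gene_len + post_zone + g$post_bg
  rna_types <- if (cfg$rna_gene_count > 0)
    .fx_rna_types[(seq_len(cfg$rna_gene_count) - 1L) %% 5L + 1L] else character()
  rna_lens <- unname(.fx_rna_lengths[rna_types])
  ps_len <- 500L
  conf_blocks <- sum(rna_lens + 500L) + cfg$pseudogene_count * (ps_len + 500L)
  total <- nl * block_len + conf_blocks
  if (total > cfg$genome_length)
    stop(sprintf(paste0("planted features (%d bases) exceed genome_length ",
                        "(%d); increase genome_length or reduce loci"),
                 total, cfg$genome_length))

  # --- ancestor: element geometry, lengths, conserved-feature sequences ---
  anc <- withr::with_seed(child_seed(cfg$seed, 0L), {
    els <- list()
    for (li in seq_len(nl)) {
      ups <- 0L
      for (j in seq_len(epl)) {
        k <- (li - 1L) * epl + j
        placement <- if (j == 1L)
          .fx_placement_cycle[(li - 1L) %% 8L + 1L] else "upstream"
        len <- sample(seq(cfg$element_length_range[1],
                          cfg$element_length_range[2]), 1L)
        len <- .fx_clamp_len(len, placement, g)
        if (placement == "upstream") ups <- ups + 1L
        els[[k]] <- list(locus = li, j = j, placement = placement, len = len,
                         slot = ups, seq = random_dna(len, cfg$gc_content),
                         element_id = sprintf("el_%02d_%d", li, j))
      }
    }
    list(elements = els,
         cds1 = replicate(nl, random_dna(g$cds1, cfg$gc_content)),
         cds2 = replicate(nl, random_dna(g$cds2, cfg$gc_content)),
         rna = if (length(rna_lens))
           mapply(function(l) random_dna(l, cfg$gc_content), rna_lens) else
             character(),
         pseudo = replicate(cfg$pseudogene_count,
                            random_dna(ps_len, cfg$gc_content)),
         bg = if (indep_bg) NULL else
           random_dna(cfg$genome_length, cfg$gc_content))
  })

  # template layout per gene locus --------------------------------------
  # all positions 1-based within the block; gene drawn on the forward
  # template strand, whole block reverse-complemented for minus loci
  loci <- vector("list", nl)
  for (li in seq_len(nl)) {
    tss <- g$pre_bg + pre_zone + 1L
    cds1_s <- tss + g$utr5
    cds1_e <- cds1_s + g$cds1 - 1L
    intron_s <- cds1_e + 1L
    intron_e <- intron_s + g$intron - 1L
    cds2_s <- intron_e + 1L
    cds2_e <- cds2_s + g$cds2 - 1L
    utr3_s <- cds2_e + 1L
    utr3_e <- utr3_s + g$utr3 - 1L
    els <- Filter(function(e) e$locus == li, anc$elements)
    epos <- lapply(els, function(e) {
      s <- switch(e$placement,
                  upstream = tss - g$upstream_gap -
                    (e$slot - 1L) * g$el_slot - e$len,
                  tss = tss - 150L,
                  intron = intron_s + (g$intron - e$len) %/% 2L,
                  utr3 = utr3_s + 30L,
                  downstream = utr3_e + g$downstream_gap + 1L)
      c(start = s, end = s + e$len - 1L)
    })
    loci[[li]] <- list(tss = tss, cds1 = c(cds1_s, cds1_e),
                       intron = c(intron_s, intron_e),
                       cds2 = c(cds2_s, cds2_e), utr3 = c(utr3_s, utr3_e),
                       gene_end = utr3_e, elements = els, epos = epos,
                       strand = if (li %% 2L == 1L) "+" else "-",
                       block_len = block_len)
  }

  species <- cfg$species_names
  n_sp <- length(species)
  inverted_sp <- species[n_sp]
  inv_idx <- which(vapply(anc$elements, function(e)
    e$placement == "upstream", logical(1)))[1]
  inverted_el <- if (is.na(inv_idx)) NA_character_ else
    anc$elements[[inv_idx]]$element_id

  genomes <- list(); annotations <- list(); truth_rows <- list()

  for (si in seq_len(n_sp)) {
    sp <- species[si]
    res <- withr::with_seed(child_seed(cfg$seed, si), {
      feats <- list(); genes <- list(); tr <- list()
      chrom_parts <- character(0)
      offset <- 0L

      evolve_feat <- function(s)
        .evolve_chr(s, cfg$regulatory_divergence, 0, cfg$indel_len_mean)
      # background: per-species independent draw, or the shared ancestral
      # background (at the same template coordinates) evolved fast
      bg_seq <- function(tpl_start, n) {
        if (indep_bg) random_dna(n, cfg$gc_content)
        else .evolve_chr(substr(anc$bg, tpl_start, tpl_start + n - 1L),
                         cfg$background_divergence, cfg$indel_rate,
                         cfg$indel_len_mean)
      }

      for (li in seq_len(nl)) {
        L <- loci[[li]]
        # ordered segments of the block: background between painted features
        fdf <- data.frame(start = c(vapply(L$epos, `[[`, 0L, "start"),
                                    L$cds1[1], L$cds2[1]),
                          end = c(vapply(L$epos, `[[`, 0L, "end"),
                                  L$cds1[2], L$cds2[2]),
                          id = c(vapply(L$elements, `[[`, "", "element_id"),
                                 "cds1", "cds2"),
                          stringsAsFactors = FALSE)
        fdf <- fdf[order(fdf$start), , drop = FALSE]
        evolved <- list()
        for (r in seq_len(nrow(fdf))) {
          id <- fdf$id[r]
          s <- if (id == "cds1") anc$cds1[[li]] else
            if (id == "cds2") anc$cds2[[li]] else
              anc$elements[[which(vapply(anc$elements, `[[`, "", "element_id")
                                  == id)]]$seq
          e <- evolve_feat(s)
          if (sp == inverted_sp && identical(id, inverted_el))
            e <- revcomp_chr(e)
          evolved[[id]] <- e
        }
        # breakpoints: feature bounds plus gene-model landmarks
        bps <- sort(unique(c(1L, block_len + 1L, fdf$start, fdf$end + 1L,
                             L$tss, L$intron[1], L$intron[2] + 1L,
                             L$utr3[1], L$utr3[2] + 1L)))
        seg_s <- bps[-length(bps)]; seg_e <- bps[-1] - 1L
        seg_seq <- character(length(seg_s))
        for (k in seq_along(seg_s)) {
          fi <- which(fdf$start <= seg_s[k] & fdf$end >= seg_e[k])
          if (length(fi) == 1) {
            seg_seq[k] <- substr(evolved[[fdf$id[fi]]],
                                 seg_s[k] - fdf$start[fi] + 1L,
                                 seg_e[k] - fdf$start[fi] + 1L)
          } else {
            seg_seq[k] <- bg_seq((li - 1L) * block_len + seg_s[k],
                                 seg_e[k] - seg_s[k] + 1L)
          }
        }
        lens <- nchar(seg_seq)
        sp_start <- cumsum(c(1L, lens[-length(lens)]))
        sp_end <- cumsum(lens)
        blk_len_sp <- sp_end[length(sp_end)]
        map_s <- function(p) sp_start[match(p, seg_s)]
        map_e <- function(p) sp_end[match(p, seg_e)]
        blk <- paste(seg_seq, collapse = "")

        flip <- L$strand == "-"
        tr_c <- function(a, b) {  # template interval -> species coords
          s <- map_s(a); e <- map_e(b)
          if (flip) c(blk_len_sp - e + 1L, blk_len_sp - s + 1L) else c(s, e)
        }
        if (flip) blk <- revcomp_chr(blk)
        gstrand <- if (flip) "-" else "+"

        gid <- sprintf("%s_g%02d", sp, li)
        gene_c <- tr_c(L$tss, L$gene_end)
        exon1_c <- tr_c(L$tss, L$cds1[2])
        exon2_c <- tr_c(L$cds2[1], L$utr3[2])
        cds1_c <- tr_c(L$cds1[1], L$cds1[2])
        cds2_c <- tr_c(L$cds2[1], L$cds2[2])
        utr5_c <- tr_c(L$tss, L$cds1[1] - 1L)
        utr3_c <- tr_c(L$utr3[1], L$utr3[2])
        intron_c <- tr_c(L$intron[1], L$intron[2])
        add <- function(cat, cc, fid)
          list(seqnames = "chr1", start = cc[1] + offset, end = cc[2] + offset,
               strand = gstrand, category = cat, feature_id = fid,
               gene_id = gid)
        feats <- c(feats, list(
          add("gene", gene_c, gid),
          add("exon", exon1_c, paste0(gid, ".e1")),
          add("exon", exon2_c, paste0(gid, ".e2")),
          add("CDS", cds1_c, paste0(gid, ".c1")),
          add("CDS", cds2_c, paste0(gid, ".c2")),
          add("five_prime_UTR", utr5_c, paste0(gid, ".u5")),
          add("three_prime_UTR", utr3_c, paste0(gid, ".u3"))))
        genes[[length(genes) + 1]] <- data.frame(
          gene_id = gid, seqnames = "chr1",
          start = gene_c[1] + offset, end = gene_c[2] + offset,
          strand = gstrand,
          tss = (if (flip) gene_c[2] else gene_c[1]) + offset,
          stringsAsFactors = FALSE)
        tr[[length(tr) + 1]] <- data.frame(
          element_id = c(paste0(gid, ".c1"), paste0(gid, ".c2")),
          species = sp, chromosome = "chr1",
          start = c(cds1_c[1], cds2_c[1]) + offset,
          end = c(cds1_c[2], cds2_c[2]) + offset,
          strand = gstrand, locus_id = sprintf("g%02d", li),
          element_class = "coding", placement = NA_character_,
          stringsAsFactors = FALSE)
        for (ei in seq_along(L$elements)) {
          e <- L$elements[[ei]]
          ec <- tr_c(L$epos[[ei]]["start"], L$epos[[ei]]["end"])
          el_strand <- if (flip) "-" else "+"
          if (sp == inverted_sp && identical(e$element_id, inverted_el))
            el_strand <- if (el_strand == "+") "-" else "+"
          tr[[length(tr) + 1]] <- data.frame(
            element_id = e$element_id, species = sp, chromosome = "chr1",
            start = ec[1] + offset, end = ec[2] + offset,
            strand = el_strand, locus_id = sprintf("g%02d", li),
            element_class = "regulatory", placement = e$placement,
            stringsAsFactors = FALSE)
        }
        chrom_parts <- c(chrom_parts, blk)
        offset <- offset + nchar(blk)
      }

      # confounder blocks: structural-RNA genes and pseudogenes
      conf <- list()
      for (ri in seq_along(rna_types))
        conf[[length(conf) + 1]] <- list(kind = rna_types[ri],
                                         id = sprintf("r%02d", ri),
                                         seq = anc$rna[[ri]])
      for (pi in seq_len(cfg$pseudogene_count))
        conf[[length(conf) + 1]] <- list(kind = "pseudogene",
                                         id = sprintf("ps%02d", pi),
                                         seq = anc$pseudo[[pi]])
      tpl_off <- nl * block_len
      for (cb in conf) {
        left <- bg_seq(tpl_off + 1L, 250L)
        right <- bg_seq(tpl_off + 250L + nchar(cb$seq) + 1L, 250L)
        tpl_off <- tpl_off + 500L + nchar(cb$seq)
        ev <- .evolve_chr(cb$seq, cfg$regulatory_divergence, 0,
                          cfg$indel_len_mean)
        s <- offset + nchar(left) + 1L
        e <- s + nchar(ev) - 1L
        feats[[length(feats) + 1]] <- list(
          seqnames = "chr1", start = s, end = e, strand = "+",
          category = cb$kind, feature_id = cb$id, gene_id = NA_character_)
        tr[[length(tr) + 1]] <- data.frame(
          element_id = cb$id, species = sp, chromosome = "chr1",
          start = s, end = e, strand = "+", locus_id = cb$id,
          element_class = if (cb$kind == "pseudogene") "pseudogene"
          else "rna_gene",
          placement = NA_character_, stringsAsFactors = FALSE)
        blk <- paste0(left, ev, right)
        chrom_parts <- c(chrom_parts, blk)
        offset <- offset + nchar(blk)
      }

      tail_len <- cfg$genome_length - total
      if (tail_len > 0)
        chrom_parts <- c(chrom_parts, bg_seq(total + 1L, tail_len))
      chrom <- paste(chrom_parts, collapse = "")

      adf <- do.call(rbind, lapply(feats, as.data.frame))
      gr <- GenomicRanges::GRanges(
        adf$seqnames, IRanges::IRanges(adf$start, adf$end),
        strand = adf$strand)
      gr$category <- adf$category
      gr$feature_id <- adf$feature_id
      gr$gene_id <- adf$gene_id
      list(chrom = chrom,
           ann = annotation_set(gr, do.call(rbind, genes)),
           truth = do.call(rbind, tr))
    })
    genomes[[sp]] <- Biostrings::DNAStringSet(c(chr1 = res$chrom))
    annotations[[sp]] <- res$ann
    truth_rows[[sp]] <- res$truth
  }

  orth <- list()
  for (a in seq_len(n_sp - 1)) for (b in seq((a + 1), n_sp))
    orth[[length(orth) + 1]] <- data.frame(
      gene_a = sprintf("%s_g%02d", species[a], seq_len(nl)),
      gene_b = sprintf("%s_g%02d", species[b], seq_len(nl)),
      stringsAsFactors = FALSE)

  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  structure(list(genomes = genomes, annotations = annotations,
                 orthology = do.call(rbind, orth), truth = truth,
                 config = cfg),
            class = "cne_fixture")
}

#' @export
print.cne_fixture <- function(x, ...) {
  cat(sprintf("cne_fixture: %d species x %d bases, %d planted features\n",
              length(x$genomes), x$config$genome_length, nrow(x$truth) /
                length(x$genomes)))
  print(table(x$truth$element_class) / length(x$genomes))
  invisible(x)
}
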