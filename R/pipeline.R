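#' Pipeline configuration
#'
#' Bundles every knob of the full analysis: the input genomes (either a
#' synthetic [fixture_config()] or paths to FASTA/GFF3/orthology files),
#' the scoring scheme, thresholds, calibration settings and the cascade
#' stage plan.  All randomness in a run derives from the single `seed`.
#'
#' The stage plan is an ordered list of species-pair searches executed
#' after the stage-1 discovery alignment.  Each entry is a list with
#' fields `target` (species name), optional `query` (default: the
#' reference, i.e. the first species) and optional `query_regions`
#' (`"masked"`, the default, to search only the masked conserved regions
#' of the query; `"genome"` for the whole genome).  The default plan
#' searches the reference's masked conserved regions against every
#' species beyond the second.
#'
#' @param fixture a [fixture_config()], or `NULL` when `species_files` is
#'   given.
#' @param species_files named list: for each species, a list with `fasta`
#'   and optionally `gff3` paths.  Ignored when `fixture` is given.
#' @param orthology_file path to an orthology TSV (ignored with a
#'   fixture, which carries its own orthology).
#' @param scheme a [scoring_scheme()].
#' @param strict_evalue,relaxed_evalue acceptance thresholds
#'   (strict < relaxed).
#' @param stage1_evalue E-value cutoff of the stage-1 discovery alignment.
#' @param min_score optional fixed score floor overriding the E-value
#'   derived one.
#' @param merge_gap gap tolerated when merging stage-1 hits into
#'   conserved regions.
#' @param min_fragment minimum surviving fragment after masking.
#' @param tss_window promoter window half-width for classification.
#' @param max_mismatch_species motif-scan tolerance (see [scan_boxes()]).
#' @param calibration_n_sim,calibration_seq_len,calibration_gc Gumbel
#'   calibration settings (see [calibrate_gumbel()]).
#' @param stage_plan cascade plan as described above; `NULL` for the
#'   default plan; `list()` for no cascade stages (stage-1 only).
#' @param run_control run a reversed-target negative control per cascade
#'   stage.
#' @param output_dir optional directory for report files.
#' @param seed master seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(fixture = fixture_config(),
                            species_files = NULL,
                            orthology_file = NULL,
                            scheme = scoring_scheme(),
                            strict_evalue = 1e-4,
                            relaxed_evalue = 10,
                            stage1_evalue = 1e-3,
                            min_score = NULL,
                            merge_gap = 0L,
                            min_fragment = 20L,
                            tss_window = 500L,
                            max_mismatch_species = 1L,
                            calibration_n_sim = 300L,
                            calibration_seq_len = 5000L,
                            calibration_gc = 0.40,
                            stage_plan = NULL,
                            run_control = TRUE,
                            output_dir = NULL,
                            seed = 1L) {
  stopifnot(inherits(scheme, "scoring_scheme"),
            strict_evalue > 0, relaxed_evalue > 0,
            stage1_evalue > 0, merge_gap >= 0, min_fragment >= 1,
            tss_window >= 0)
  if (!(strict_evalue < relaxed_evalue))
    stop("strict_evalue must be below relaxed_evalue")
  if (is.null(fixture) && is.null(species_files))
    stop("either a fixture or species_files must be given")
  if (!is.null(fixture)) stopifnot(inherits(fixture, "fixture_config"))
  species <- if (!is.null(fixture)) fixture$species_names else
    names(species_files)
  if (length(species) < 2) stop("at least two species are required")
  if (is.null(stage_plan)) {
    stage_plan <- lapply(setdiff(species, species[1:2]), function(sp)
      list(query = species[1], target = sp, query_regions = "masked"))
  }
  for (st in stage_plan) {
    if (is.null(st[["target"]]) || !st[["target"]] %in% species)
      stop("stage plan references an undeclared target species")
    if (!is.null(st[["query"]]) && !st[["query"]] %in% species)
      stop("stage plan references an undeclared query species")
    if (!is.null(st[["query_regions"]]) &&
        !st[["query_regions"]] %in% c("masked", "genome"))
      stop("stage plan query_regions must be \"masked\" or \"genome\"")
  }
  structure(list(fixture = fixture, species_files = species_files,
                 orthology_file = orthology_file, species = species,
                 scheme = scheme, strict_evalue = strict_evalue,
                 relaxed_evalue = relaxed_evalue,
                 stage1_evalue = stage1_evalue, min_score = min_score,
                 merge_gap = as.integer(merge_gap),
                 min_fragment = as.integer(min_fragment),
                 tss_window = as.integer(tss_window),
                 max_mismatch_species = as.integer(max_mismatch_species),
                 calibration_n_sim = as.integer(calibration_n_sim),
                 calibration_seq_len = as.integer(calibration_seq_len),
                 calibration_gc = calibration_gc,
                 stage_plan = stage_plan, run_control = isTRUE(run_control),
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised top-level keys mirror the [pipeline_config()] arguments;
#' `fixture:` and `scoring:` subsections map onto [fixture_config()] and
#' [scoring_scheme()] arguments.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$fixture)) {
    fx <- y$fixture
    if (!is.null(fx$species_names)) fx$species_names <-
        as.character(unlist(fx$species_names))
    if (!is.null(fx$element_length_range)) fx$element_length_range <-
        as.integer(unlist(fx$element_length_range))
    args$fixture <- do.call(fixture_config, fx)
  } else if (!is.null(y$species_files)) {
    args$fixture <- NULL
    args$species_files <- y$species_files
    args$orthology_file <- y$orthology_file
  }
  if (!is.null(y$scoring)) args$scheme <- do.call(scoring_scheme, y$scoring)
  passthrough <- c("strict_evalue", "relaxed_evalue", "stage1_evalue",
                   "min_score", "merge_gap", "min_fragment", "tss_window",
                   "max_mismatch_species", "calibration_n_sim",
                   "calibration_seq_len", "calibration_gc", "stage_plan",
                   "run_control", "output_dir", "seed")
  for (k in intersect(passthrough, names(y))) args[[k]] <- y[[k]]
  do.call(pipeline_config, args)
}

# load genomes/annotations/orthology from a config (fixture or files)
.load_inputs <- function(config) {
  if (!is.null(config$fixture)) {
    fx <- build_truth_set(config$fixture)
    list(genomes = fx$genomes, annotations = fx$annotations,
         orthology = fx$orthology, fixture = fx)
  } else {
    genomes <- list(); annotations <- list()
    for (sp in names(config$species_files)) {
      f <- config$species_files[[sp]]
      genomes[[sp]] <- read_fasta(f$fasta)
      annotations[[sp]] <- if (!is.null(f$gff3)) read_gff3(f$gff3) else NULL
    }
    orth <- if (!is.null(config$orthology_file))
      read_orthology(config$orthology_file) else
        data.frame(gene_a = character(), gene_b = character())
    list(genomes = genomes, annotations = annotations, orthology = orth,
         fixture = NULL)
  }
}

# motif summary string for one candidate's pairwise alignment
.candidate_motifs <- function(cand, k, genomes, query_sp, target_sp,
                              max_mismatch_species) {
  al <- tryCatch(
    hit_alignment_strings(cand, k,
                          as_seq_chr(genomes[[query_sp]])[[cand$query_id[k]]],
                          as_seq_chr(genomes[[target_sp]])[[cand$target_id[k]]]),
    error = function(e) NULL)
  if (is.null(al)) return(NA_character_)
  occ <- scan_boxes(c(al[["query"]], al[["target"]]),
                    max_mismatch_species = min(max_mismatch_species, 1L))
  if (nrow(occ) == 0) return("")
  paste(sprintf("%s@%d%s:%s", occ$motif, occ$start, occ$strand,
                occ$conservation), collapse = ";")
}

#' Run the full conserved-element analysis
#'
#' Executes, in order: Gumbel calibration for the configured scoring
#' scheme; the stage-1 discovery alignment between the first two species;
#' merging of stage-1 hits on the reference side into conserved regions;
#' masking of annotated coding/RNA/pseudogene DNA; one cascaded search per
#' stage-plan entry, with E-values computed against the reduced search
#' space; acceptance by strict E-value or homologous-gene proximity; a
#' reversed-target negative control per stage; and classification,
#' gene-relative geometry and box-motif scanning of every accepted
#' element.  Every stage is logged to stderr with its search-space sizes
#' and fold reduction.  Deterministic given the config seed.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with fields `elements` (the
#'   element report, sorted by E-value), `rejects`, `null` (list of
#'   `null_report`s), `stages` (stage ledger), `gumbel`, `scheme`,
#'   `regions` (masked conserved regions), `stage1`, `genomes`,
#'   `annotations`, `fixture` (when simulated) and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  written <- character(0)
  out_try <- function(expr, stage) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("pipeline stage [", stage, "] failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  message("stage [load]: preparing inputs")
  inputs <- out_try(.load_inputs(config), "load")
  genomes <- inputs$genomes
  annotations <- inputs$annotations
  species <- config$species
  ref <- species[1]; partner <- species[2]
  homology <- homology_map(inputs$orthology)

  message("stage [calibrate]: fitting Gumbel parameters (n_sim=",
          config$calibration_n_sim, ", L=", config$calibration_seq_len, ")")
  gum <- out_try(
    calibrate_gumbel(config$scheme, gc_content = config$calibration_gc,
                     seq_len = config$calibration_seq_len,
                     n_sim = config$calibration_n_sim,
                     seed = child_seed(config$seed, 1L)),
    "calibrate")
  message(sprintf("stage [calibrate]: lambda=%.4f K=%.4g",
                  gum$lambda, gum$K))

  ref_space <- search_space(genomes[[ref]], label = paste0(ref, ":genome"))
  partner_space <- search_space(genomes[[partner]],
                                label = paste0(partner, ":genome"))
  message(sprintf("stage [stage1]: %s (n=%d) vs %s (m=%d), E<=%g",
                  ref, ref_space$length, partner, partner_space$length,
                  config$stage1_evalue))
  stage1 <- out_try(
    staged_search(ref_space, partner_space, config$scheme, gum,
                  min_score = config$min_score,
                  max_evalue = config$stage1_evalue),
    "stage1")
  message("stage [stage1]: ", nrow(stage1$hits), " hits")

  message("stage [merge]: merging reference-side hits (gap <= ",
          config$merge_gap, ")")
  regions_raw <- out_try(
    merge_hits_to_regions(stage1$hits, side = "query",
                          merge_gap = config$merge_gap,
                          genome_length = ref_space$genome_length),
    "merge")
  message(sprintf("stage [merge]: %d regions, %d bases (1/%.1f of genome)",
                  length(regions_raw$regions), regions_raw$total_span,
                  if (regions_raw$total_span > 0)
                    1 / regions_raw$genome_fraction else Inf))

  regions <- if (!is.null(annotations[[ref]])) {
    message("stage [mask]: removing annotated coding/RNA/pseudogene DNA")
    out_try(subtract_annotated(regions_raw, annotations[[ref]],
                               min_fragment = config$min_fragment), "mask")
  } else {
    message("stage [mask]: no reference annotation; skipping")
    regions_raw
  }
  message(sprintf("stage [mask]: %d regions, %d bases remain",
                  length(regions$regions), regions$total_span))

  ledger <- stage1$stage
  ledger$stage <- "stage1"
  null_reports <- list()
  all_cands <- list(); all_blocks <- list(); all_rejects <- list()

  for (i in seq_along(config$stage_plan)) {
    st <- config$stage_plan[[i]]
    qsp <- st[["query"]] %||% ref
    qreg <- st[["query_regions"]] %||% "masked"
    sname <- sprintf("search:%s->%s", qsp, st$target)
    qspace <- if (qreg == "masked") {
      if (qsp != ref)
        out_try(stop("masked query regions are only tracked for the ",
                     "reference species ", ref), sname)
      if (regions$total_span == 0) {
        message("stage [", sname, "]: conserved region set is empty")
      }
      search_space(genomes[[qsp]], regions,
                   label = paste0(qsp, ":conserved"))
    } else {
      search_space(genomes[[qsp]], label = paste0(qsp, ":genome"))
    }
    tspace <- search_space(genomes[[st$target]],
                           label = paste0(st$target, ":genome"))
    message(sprintf("stage [%s]: n=%d m=%d, %.0f-fold reduction, E<=%g",
                    sname, qspace$length, tspace$length,
                    qspace$reduction * tspace$reduction,
                    config$relaxed_evalue))
    res <- out_try(
      staged_search(qspace, tspace, config$scheme, gum,
                    min_score = config$min_score,
                    max_evalue = config$relaxed_evalue),
      sname)
    message("stage [", sname, "]: ", nrow(res$hits), " hits")
    srow <- res$stage; srow$stage <- sname
    ledger <- rbind(ledger, srow)

    cand <- out_try(
      accept_candidates(res$hits, annotations[[qsp]],
                        annotations[[st$target]], homology,
                        strict = config$strict_evalue,
                        relaxed = config$relaxed_evalue),
      paste0("accept:", st$target))
    message(sprintf("stage [accept:%s]: %d accepted, %d rejected",
                    st$target, nrow(cand), nrow(attr(cand, "rejects"))))
    if (nrow(cand)) {
      cand$query_species <- qsp
      cand$target_species <- st$target
      all_blocks <- c(all_blocks, attr(cand, "blocks"))
      all_cands[[length(all_cands) + 1]] <- as.data.frame(cand)
    }
    rej <- attr(cand, "rejects")
    if (nrow(rej)) {
      rej$query_species <- qsp; rej$target_species <- st$target
      all_rejects[[length(all_rejects) + 1]] <- rej
    }

    if (config$run_control) {
      ctl <- out_try(
        reversed_control(qspace, tspace, config$scheme, gum,
                         min_score = config$min_score,
                         threshold = config$relaxed_evalue),
        paste0("control:", st$target))
      message(sprintf("stage [control:%s]: %d reversed-target hits at E<=%g",
                      st$target, ctl$count, ctl$threshold))
      null_reports[[sname]] <- ctl
    }
  }

  elements <- if (length(all_cands)) {
    el <- do.call(rbind, all_cands)
    rownames(el) <- NULL
    message("stage [annotate]: classifying ", nrow(el), " elements")
    cls <- character(nrow(el)); pos <- cls; ori <- cls; mot <- cls
    for (k in seq_len(nrow(el))) {
      ec <- classify_element(el$query_id[k], el$query_start[k],
                             el$query_end[k],
                             annotations[[el$query_species[k]]],
                             tss_window = config$tss_window)
      cls[k] <- ec$label
      qann <- annotations[[el$query_species[k]]]
      gene <- if (!is.null(qann) && !is.na(el$query_gene[k]))
        qann$genes[qann$genes$gene_id == el$query_gene[k], , drop = FALSE]
      else NULL
      geo <- relative_geometry(el$query_start[k], el$query_end[k],
                               if (!is.null(gene) && nrow(gene)) gene else
                                 NULL,
                               strand_chain = el$strand[k])
      pos[k] <- geo$position; ori[k] <- geo$orientation
      cand_k <- set_hit_blocks(el, all_blocks)
      mot[k] <- .candidate_motifs(cand_k, k, genomes, el$query_species[k],
                                  el$target_species[k],
                                  config$max_mismatch_species)
    }
    el$element_class <- cls; el$position <- pos; el$orientation <- ori
    el$motifs <- mot
    o <- order(el$evalue, el$query_start, el$target_start)
    el <- el[o, , drop = FALSE]
    rownames(el) <- NULL
    set_hit_blocks(el, all_blocks[o])
  } else {
    el <- cbind(as.data.frame(empty_hits()),
                data.frame(query_gene = character(),
                           query_gene_distance = integer(),
                           target_gene = character(),
                           target_gene_distance = integer(),
                           acceptance_path = character(),
                           query_species = character(),
                           target_species = character(),
                           element_class = character(),
                           position = character(),
                           orientation = character(),
                           motifs = character()))
    set_hit_blocks(el, list())
  }

  rejects <- if (length(all_rejects)) {
    r <- do.call(rbind, all_rejects); rownames(r) <- NULL; r
  } else NULL

  result <- structure(
    list(elements = elements, rejects = rejects, null = null_reports,
         stages = ledger, gumbel = gum, scheme = config$scheme,
         regions = regions, regions_unmasked = regions_raw,
         stage1 = stage1, genomes = genomes, annotations = annotations,
         orthology = inputs$orthology, fixture = inputs$fixture,
         config = config),
    class = "pipeline_result")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(fn, f) {
      p <- file.path(config$output_dir, fn)
      written <<- c(written, p); f(p); p
    }
    out_try({
      wr("elements.tsv", function(p) write_element_report(elements, p))
      wr("stages.tsv", function(p)
        utils::write.table(ledger, p, sep = "\t", quote = FALSE,
                           row.names = FALSE))
      if (regions$total_span > 0)
        wr("conserved_regions.bed", function(p)
          write_bed(regions$regions, p))
      if (length(null_reports))
        wr("null_control.tsv", function(p) {
          nd <- data.frame(stage = names(null_reports),
                           count = vapply(null_reports, `[[`, 0L, "count"),
                           threshold = vapply(null_reports, `[[`, 0,
                                              "threshold"))
          utils::write.table(nd, p, sep = "\t", quote = FALSE,
                             row.names = FALSE)
        })
    }, "report")
    message("stage [report]: wrote ", length(written), " files to ",
            config$output_dir)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d accepted elements across %d stages\n",
              nrow(x$elements), nrow(x$stages)))
  if (nrow(x$elements)) {
    cat("  classes:", paste(sprintf("%s=%d",
                                    names(table(x$elements$element_class)),
                                    table(x$elements$element_class)),
                            collapse = " "), "\n")
    cat(sprintf("  best E-value: %.3g\n", min(x$elements$evalue)))
  }
  for (nm in names(x$null))
    cat(sprintf("  control %s: %d hits at E<=%g\n", nm,
                x$null[[nm]]$count, x$null[[nm]]$threshold))
  invisible(x)
}

#' Write the element report as TSV
#'
#' Coordinates are written 0-based half-open (as in BED); in-memory
#' objects remain 1-based closed.
#'
#' @param elements the `elements` data frame of a `pipeline_result`.
#' @param path output path.
#' @export
write_element_report <- function(elements, path) {
  df <- as.data.frame(elements)
  cols <- c("query_species", "query_id", "query_start", "query_end",
            "target_species", "target_id", "target_start", "target_end",
            "strand", "score", "evalue", "acceptance_path",
            "query_gene", "query_gene_distance", "target_gene",
            "target_gene_distance", "element_class", "position",
            "orientation", "motifs")
  df <- df[, intersect(cols, colnames(df)), drop = FALSE]
  if (nrow(df)) {
    df$query_start <- df$query_start - 1L
    df$target_start <- df$target_start - 1L
    df$evalue <- sprintf("%.6g", df$evalue)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Score a pipeline result against the fixture truth table
#'
#' Compares the accepted elements with the planted truth: a planted
#' regulatory element counts as recovered when some accepted element
#' overlaps its interval in the query species *and* its interval in the
#' target species of the same row.  Confounder hits are accepted elements
#' overlapping a planted coding/RNA-gene/pseudogene interval on the query
#' side; background hits are strict-path acceptances overlapping no
#' planted feature at all.  Orientation flips are counted among
#' truth-matched elements only, and compared with the strand recorded in
#' the truth table.
#'
#' @param result a `pipeline_result` run on a fixture.
#' @param truth the fixture truth table (default: the one inside
#'   `result`).
#' @return list of class `truth_score`: `n_elements`, `n_recovered`,
#'   `recall`, `confounder_hits`, `background_strict_hits`, `n_flipped`,
#'   `flipped_elements`, `expected_flips`, and the per-element
#'   `recovered` logical vector.
#' @export
score_truth <- function(result, truth = NULL) {
  stopifnot(inherits(result, "pipeline_result"))
  if (is.null(truth)) {
    if (is.null(result$fixture))
      stop("no truth table: result was not produced from a fixture")
    truth <- result$fixture$truth
  }
  el <- as.data.frame(result$elements)
  reg <- truth[truth$element_class == "regulatory", , drop = FALSE]
  conf <- truth[truth$element_class %in%
                  c("coding", "rna_gene", "pseudogene"), , drop = FALSE]

  ov <- function(s1, e1, s2, e2) s1 <= e2 & e1 >= s2
  # which truth row (by element_id+species) does each candidate overlap?
  match_el <- function(k, trows, sp_col, id_col, s_col, e_col) {
    t_sp <- trows[trows$species == el[[sp_col]][k] &
                    trows$chromosome == el[[id_col]][k], , drop = FALSE]
    t_sp$element_id[ov(el[[s_col]][k], el[[e_col]][k],
                       t_sp$start, t_sp$end)]
  }

  ids <- unique(reg$element_id)
  recovered <- setNames(rep(FALSE, length(ids)), ids)
  truth_matched <- rep(FALSE, nrow(el))
  flipped <- character(0)
  if (nrow(el)) for (k in seq_len(nrow(el))) {
    q_ids <- match_el(k, reg, "query_species", "query_id",
                      "query_start", "query_end")
    t_ids <- match_el(k, reg, "target_species", "target_id",
                      "target_start", "target_end")
    both <- intersect(q_ids, t_ids)
    if (length(both)) {
      recovered[both] <- TRUE
      truth_matched[k] <- TRUE
      if (identical(el$orientation[k], "opposite"))
        flipped <- union(flipped, both)
    }
  }

  confounder_hits <- 0L; background_strict <- 0L
  if (nrow(el)) for (k in seq_len(nrow(el))) {
    c_ids <- match_el(k, conf, "query_species", "query_id",
                      "query_start", "query_end")
    if (length(c_ids)) {
      confounder_hits <- confounder_hits + 1L
    } else if (!truth_matched[k] &&
               identical(el$acceptance_path[k], "strict_evalue")) {
      background_strict <- background_strict + 1L
    }
  }

  # the planted inversion: elements whose truth strand differs between
  # the reference species and some searched target species
  exp_flips <- character(0)
  for (id in ids) {
    tr <- reg[reg$element_id == id, , drop = FALSE]
    sts <- setNames(tr$strand, tr$species)
    for (st in result$config$stage_plan) {
      qsp <- st[["query"]] %||% result$config$species[1]
      if (qsp %in% names(sts) && st$target %in% names(sts) &&
          sts[[qsp]] != sts[[st$target]])
        exp_flips <- union(exp_flips, id)
    }
  }

  structure(list(n_elements = length(ids),
                 n_recovered = sum(recovered),
                 recall = sum(recovered) / max(1L, length(ids)),
                 confounder_hits = confounder_hits,
                 background_strict_hits = background_strict,
                 n_flipped = length(flipped),
                 flipped_elements = sort(flipped),
                 expected_flips = sort(exp_flips),
                 recovered = recovered),
            class = "truth_score")
}

#' @export
print.truth_score <- function(x, ...) {
  cat(sprintf(paste0("truth_score: recall %d/%d (%.1f%%), ",
                     "%d confounder hits, %d strict background hits, ",
                     "%d orientation flips (expected: %s)\n"),
              x$n_recovered, x$n_elements, 100 * x$recall,
              x$confounder_hits, x$background_strict_hits, x$n_flipped,
              if (length(x$expected_flips))
                paste(x$expected_flips, collapse = ",") else "none"))
  invisible(x)
}
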