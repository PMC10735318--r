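# a small fixture shared by the tests in this file (built once)
small_cfg <- fixture_config(genome_length = 60000L, n_gene_loci = 6L,
                            rna_gene_count = 2L, pseudogene_count = 1L,
                            seed = 42L)
small_fx <- build_truth_set(small_cfg)

test_that("fixture_config validates its arguments", {
  expect_error(fixture_config(species_names = "only_one"))
  expect_error(fixture_config(element_length_range = c(10L, 400L)))
  expect_error(fixture_config(gc_content = 1.2), "gc_content")
  expect_error(fixture_config(regulatory_divergence = 0))
  expect_error(fixture_config(background_divergence = 0.05),
               "background_divergence")
  expect_error(build_truth_set(fixture_config(genome_length = 10000L,
                                              n_gene_loci = 20L)),
               "exceed")
})

test_that("the generator is deterministic given the seed", {
  fx2 <- build_truth_set(small_cfg)
  expect_identical(deepcne:::as_seq_chr(small_fx$genomes$spA),
                   deepcne:::as_seq_chr(fx2$genomes$spA))
  expect_identical(small_fx$truth, fx2$truth)
  fx3 <- build_truth_set(fixture_config(genome_length = 60000L,
                                        n_gene_loci = 6L,
                                        rna_gene_count = 2L,
                                        pseudogene_count = 1L,
                                        seed = 43L))
  expect_false(identical(deepcne:::as_seq_chr(small_fx$genomes$spA),
                         deepcne:::as_seq_chr(fx3$genomes$spA)))
})

test_that("genomes have the configured length and per-species annotations", {
  expect_setequal(names(small_fx$genomes), c("spA", "spB", "spC"))
  for (sp in names(small_fx$genomes)) {
    expect_equal(sum(Biostrings::width(small_fx$genomes[[sp]])), 60000L)
    expect_s3_class(small_fx$annotations[[sp]], "annotation_set")
    expect_equal(nrow(small_fx$annotations[[sp]]$genes), 6L)
  }
})

test_that("the truth table lists every planted feature for every species", {
  tr <- small_fx$truth
  expect_setequal(unique(tr$species), c("spA", "spB", "spC"))
  per_sp <- table(tr$species, tr$element_class)
  # per species: 6 regulatory elements, 12 CDS, 2 RNA genes, 1 pseudogene
  expect_true(all(per_sp[, "regulatory"] == 6L))
  expect_true(all(per_sp[, "coding"] == 12L))
  expect_true(all(per_sp[, "rna_gene"] == 2L))
  expect_true(all(per_sp[, "pseudogene"] == 1L))
  expect_true(all(tr$end >= tr$start))
  expect_true(all(tr$start >= 1 & tr$end <= 60000L))
})

test_that("truth coordinates point at the planted sequences", {
  tr <- small_fx$truth
  reg <- tr[tr$element_class == "regulatory", ]
  # the same element in two species is recognisably similar: both copies
  # diverged 15% from the ancestor, so ~73% identity, far above chance
  id1 <- reg[reg$element_id == "el_02_1" & reg$species == "spA", ]
  id2 <- reg[reg$element_id == "el_02_1" & reg$species == "spB", ]
  s1 <- substr(deepcne:::as_seq_chr(small_fx$genomes$spA)[["chr1"]],
               id1$start, id1$end)
  s2 <- substr(deepcne:::as_seq_chr(small_fx$genomes$spB)[["chr1"]],
               id2$start, id2$end)
  if (id1$strand != id2$strand) s2 <- deepcne:::revcomp_chr(s2)
  if (id1$strand == "-") { s1 <- deepcne:::revcomp_chr(s1)
                           s2 <- deepcne:::revcomp_chr(s2) }
  expect_equal(nchar(s1), nchar(s2))  # no indels inside planted features
  idy <- mean(strsplit(s1, "")[[1]] == strsplit(s2, "")[[1]])
  expect_gt(idy, 0.6)
})

test_that("exactly one element is inverted, in the last species only", {
  reg <- small_fx$truth[small_fx$truth$element_class == "regulatory", ]
  flips <- vapply(split(reg, reg$element_id), function(d) {
    st <- setNames(d$strand, d$species)
    st[["spC"]] != st[["spA"]]
  }, logical(1))
  expect_equal(sum(flips), 1L)
  # the inverted element is the first upstream-placed element
  first_up <- reg[reg$placement == "upstream" & reg$species == "spA", ]
  first_up <- first_up$element_id[order(first_up$element_id)][1]
  expect_equal(names(flips)[flips], first_up)
  # spA and spB agree everywhere
  agree <- vapply(split(reg, reg$element_id), function(d) {
    st <- setNames(d$strand, d$species)
    st[["spB"]] == st[["spA"]]
  }, logical(1))
  expect_true(all(agree))
})

test_that("orthology pairs every locus across every species pair", {
  o <- small_fx$orthology
  expect_equal(nrow(o), 3L * 6L)  # 3 species pairs x 6 loci
  expect_true("spA_g01" %in% o$gene_a)
  map <- homology_map(o)
  expect_true(is_homolog(map, "spA_g03", "spC_g03"))
  expect_false(is_homolog(map, "spA_g03", "spC_g04"))
})

test_that("annotations and truth agree on CDS placement", {
  ann <- small_fx$annotations$spB
  cds <- ann$features[ann$features$category == "CDS"]
  tr_cds <- small_fx$truth[small_fx$truth$species == "spB" &
                             small_fx$truth$element_class == "coding", ]
  expect_equal(sort(GenomicRanges::start(cds)), sort(tr_cds$start))
  expect_equal(sort(GenomicRanges::end(cds)), sort(tr_cds$end))
})

test_that("alternating loci sit on alternating strands", {
  g <- small_fx$annotations$spA$genes
  g <- g[order(g$start), ]
  expect_equal(g$strand, rep(c("+", "-"), 3L))
})
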