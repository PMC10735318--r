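make_accept_fixture <- function() {
  genes_q <- data.frame(gene_id = "qgene", seqnames = "chrQ",
                        start = 2000L, end = 4000L, strand = "+",
                        tss = 2000L, stringsAsFactors = FALSE)
  genes_t <- data.frame(gene_id = c("tgene", "other"), seqnames = "chrT",
                        start = c(5000L, 50000L), end = c(7000L, 52000L),
                        strand = "+", tss = c(5000L, 50000L),
                        stringsAsFactors = FALSE)
  fq <- GenomicRanges::GRanges("chrQ", IRanges::IRanges(2000, 4000),
                               strand = "+", category = "gene",
                               feature_id = "qgene", gene_id = "qgene")
  ft <- GenomicRanges::GRanges("chrT",
                               IRanges::IRanges(c(5000, 50000),
                                                c(7000, 52000)),
                               strand = "+", category = "gene",
                               feature_id = c("tgene", "other"),
                               gene_id = c("tgene", "other"))
  list(query_ann = annotation_set(fq, genes_q),
       target_ann = annotation_set(ft, genes_t),
       homology = homology_map(data.frame(gene_a = "qgene",
                                          gene_b = "tgene")))
}

make_hit <- function(evalue, target_start = 4500L) {
  h <- data.frame(query_id = "chrQ", query_start = 1000L,
                  query_end = 1200L, target_id = "chrT",
                  target_start = target_start,
                  target_end = target_start + 200L,
                  strand = "+", score = 80L, evalue = evalue,
                  stringsAsFactors = FALSE)
  deepcne:::set_hit_blocks(h, list(cbind(q_start = 1000L, q_end = 1200L,
                                         t_start = target_start,
                                         t_end = target_start + 200L)))
}
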