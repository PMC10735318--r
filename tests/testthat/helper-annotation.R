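make_gene_ann <- function() {
  # one plus-strand gene 1001-3000: exons 1001-1500 and 2501-3000,
  # intron 1501-2500; CDS 1201-1500 and 2501-2800; UTRs at the ends
  feats <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(c(1001, 1001, 2501, 1201, 2501, 1001, 2801),
                     c(3000, 1500, 3000, 1500, 2800, 1200, 3000)),
    strand = "+",
    category = c("gene", "exon", "exon", "CDS", "CDS",
                 "five_prime_UTR", "three_prime_UTR"),
    feature_id = c("g1", "g1.e1", "g1.e2", "g1.c1", "g1.c2",
                   "g1.u5", "g1.u3"),
    gene_id = "g1")
  genes <- data.frame(gene_id = "g1", seqnames = "chr1", start = 1001L,
                      end = 3000L, strand = "+", tss = 1001L,
                      stringsAsFactors = FALSE)
  annotation_set(feats, genes)
}
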