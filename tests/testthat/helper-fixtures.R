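# Shared fixture builders (everything is generated in code).

# A midpoint track from raw positions on one chromosome.
track_from <- function(pos, chrom = "chrA", label = "total") {
  midpoint_track(data.frame(chrom = chrom, pos = as.integer(pos),
                            stringsAsFactors = FALSE), label = label)
}

# A minimal two-gene annotation on one 20-kb chromosome:
#   geneP: "+" strand, body [2000, 5000), exons [2000,3000)+[4000,5000)
#   geneM: "-" strand, body [12000, 15000), exons [12000,13000)+[14000,15000)
toy_genes <- function() {
  gene_models(
    data.frame(gene_id = c("geneM", "geneP"),
               transcript_id = c("geneM.t1", "geneP.t1"),
               chrom = "chrA",
               start = c(12000L, 2000L), end = c(15000L, 5000L),
               strand = c("-", "+"), stringsAsFactors = FALSE),
    data.frame(transcript_id = rep(c("geneM.t1", "geneP.t1"), each = 2L),
               start = c(12000L, 14000L, 2000L, 4000L),
               end = c(13000L, 15000L, 3000L, 5000L),
               stringsAsFactors = FALSE))
}

toy_genome <- c(chrA = 20000L)
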