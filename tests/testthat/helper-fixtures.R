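# Small fixtures built in code at test time.

writeTempLines <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# A hand-built annotation: two genes on chr1 with known exon/intron layout,
# wide intergenic space on either side. Coordinates are 1-based closed.
#   geneA (+): exons [101,200], [301,400], [501,600]; introns between.
#   geneB (-): exons [2001,2100], [2301,2400]; one intron.
tinyAnnotation <- function() {
  exons <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(c(101, 301, 501, 2001, 2301),
                     c(200, 400, 600, 2100, 2400)),
    strand = c("+", "+", "+", "-", "-"),
    gene_id = c("geneA", "geneA", "geneA", "geneB", "geneB"),
    transcript_id = c("txA", "txA", "txA", "txB", "txB"),
    exon_index = c(1L, 2L, 3L, 1L, 2L))
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(101, 2001), c(600, 2400)),
    strand = c("+", "-"), gene_id = c("geneA", "geneB"))
  introns <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(201, 401, 2101), c(300, 500, 2300)),
    strand = c("+", "+", "-"),
    gene_id = c("geneA", "geneA", "geneB"),
    transcript_id = c("txA", "txA", "txB"))
  methods::new("CircAnnotation", genes = genes, exons = exons,
               introns = introns)
}

# GRanges circRNA from BED-convention coordinates.
circGR <- function(chrom, start0, end0, strand = "+", id = "c1") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0),
                               strand = strand, circ_id = id)
  names(gr) <- id
  gr
}

# Alignment data.frame row(s) in the package's 0-based half-open convention.
alnDf <- function(read_id, ref_name, ref_start, ref_end, is_mapped = TRUE,
                  flag = 0L) {
  data.frame(read_id = read_id, flag = rep_len(flag, length(read_id)),
             ref_name = ref_name,
             ref_start = as.integer(ref_start), ref_end = as.integer(ref_end),
             is_mapped = rep_len(is_mapped, length(read_id)))
}
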