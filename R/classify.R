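#' @importFrom GenomicRanges findOverlaps
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' The seven back-splice-junction categories
#'
#' CircRNAs are categorized by where the two boundaries of the back-splice
#' junction fall relative to the gene annotation: both in the same exon,
#' in different exons, one in an exon and one in an intron, both in
#' introns, one in an intron and one in intergenic space, one in an exon
#' and one in intergenic space, or both intergenic.
#'
#' @return character vector of the seven category labels.
#' @export
junctionCategories <- function() {
  c("same_exon", "different_exon", "intron_exon", "intron",
    "intron_intergenic", "exon_intergenic", "intergenic")
}

#' Locate junction boundary positions against the annotation
#'
#' For each (chromosome, position) pair, reports whether the position falls
#' in an exon, an intron (within a gene span but no exon), or intergenic
#' space. Exon beats intron when transcripts disagree; among exon hits the
#' transcript with the most exons wins, ties broken by lexicographic
#' transcript id. Positions on chromosomes unknown to the annotation are
#' intergenic (reported via a message).
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based genomic positions.
#' @param annot a [CircAnnotation-class].
#' @return data.frame with columns `context` (exon/intron/intergenic),
#'   `gene_id`, `transcript_id`, `exon_index` (NA unless applicable).
#' @export
locateBoundary <- function(chrom, pos, annot) {
  n <- length(pos)
  stopifnot(length(chrom) == n)
  out <- data.frame(context = rep("intergenic", n),
                    gene_id = rep(NA_character_, n),
                    transcript_id = rep(NA_character_, n),
                    exon_index = rep(NA_integer_, n))
  if (!n) return(out)
  ex <- annotExons(annot)
  genes <- annotGenes(annot)
  known <- unique(c(as.character(GenomicRanges::seqnames(ex)),
                    as.character(GenomicRanges::seqnames(genes))))
  unknown <- !chrom %in% known
  if (any(unknown)) {
    message(sum(unknown), " boundary position(s) on chromosomes absent from ",
            "the annotation; treated as intergenic")
  }
  qi <- which(!unknown)
  if (!length(qi)) return(out)
  pts <- GRanges(chrom[qi], IRanges(pos[qi], pos[qi]))

  if (length(ex)) {
    exonsPerTx <- table(mcols(ex)$transcript_id)
    hits <- suppressWarnings(findOverlaps(pts, ex, ignore.strand = TRUE))
    if (length(hits)) {
      qh <- queryHits(hits); sh <- subjectHits(hits)
      tx <- as.character(mcols(ex)$transcript_id[sh])
      nex <- as.integer(exonsPerTx[tx])
      # best hit per query: most exons, then lexicographic transcript id
      o <- order(qh, -nex, tx)
      best <- o[!duplicated(qh[o])]
      i <- qi[qh[best]]
      out$context[i] <- "exon"
      out$gene_id[i] <- as.character(mcols(ex)$gene_id[sh[best]])
      out$transcript_id[i] <- tx[best]
      out$exon_index[i] <- as.integer(mcols(ex)$exon_index[sh[best]])
    }
  }
  rest <- which(!unknown & out$context == "intergenic")
  if (length(rest) && length(genes)) {
    pts2 <- GRanges(chrom[rest], IRanges(pos[rest], pos[rest]))
    hits <- suppressWarnings(findOverlaps(pts2, genes, ignore.strand = TRUE))
    if (length(hits)) {
      qh <- queryHits(hits); sh <- subjectHits(hits)
      gid <- as.character(mcols(genes)$gene_id[sh])
      o <- order(qh, gid)
      best <- o[!duplicated(qh[o])]
      i <- rest[qh[best]]
      out$context[i] <- "intron"
      out$gene_id[i] <- gid[best]
    }
  }
  out
}

## Internal: map a pair of boundary contexts to a category label.
categoryFromContexts <- function(a, b) {
  pair <- sort(c(a$context, b$context))
  if (identical(pair, c("exon", "exon"))) {
    same <- !is.na(a$transcript_id) && identical(a$transcript_id, b$transcript_id) &&
      identical(a$exon_index, b$exon_index)
    if (same) "same_exon" else "different_exon"
  } else if (identical(pair, c("exon", "intron"))) "intron_exon"
  else if (identical(pair, c("intron", "intron"))) "intron"
  else if (identical(pair, c("intergenic", "intron"))) "intron_intergenic"
  else if (identical(pair, c("exon", "intergenic"))) "exon_intergenic"
  else "intergenic"
}

#' Classify circRNAs by back-splice junction position
#'
#' Evaluates the annotation context at the first and last base inside each
#' circRNA and assigns one of the seven categories (see
#' [junctionCategories()]). Classification is total: every circRNA receives
#' exactly one label, and the label does not depend on which end is which.
#'
#' @param circs `GRanges` of circRNAs.
#' @param annot a [CircAnnotation-class].
#' @return data.frame with columns `circ_id`, `label`, `chrom`, `start`,
#'   `end` (BED convention, 0-based half-open), `length`, `strand`,
#'   `gene_id_start`, `gene_id_end`.
#' @export
classifyAll <- function(circs, annot) {
  n <- length(circs)
  if (!n) {
    return(data.frame(circ_id = character(0), label = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      strand = character(0), gene_id_start = character(0),
                      gene_id_end = character(0)))
  }
  chrom <- as.character(GenomicRanges::seqnames(circs))
  ctxStart <- locateBoundary(chrom, GenomicRanges::start(circs), annot)
  ctxEnd <- locateBoundary(chrom, GenomicRanges::end(circs), annot)
  label <- vapply(seq_len(n), function(i) {
    categoryFromContexts(ctxStart[i, ], ctxEnd[i, ])
  }, "")
  data.frame(circ_id = circIds(circs), label = label, chrom = chrom,
             start = bedStart(circs), end = bedEnd(circs),
             length = GenomicRanges::width(circs),
             strand = as.character(GenomicRanges::strand(circs)),
             gene_id_start = ctxStart$gene_id, gene_id_end = ctxEnd$gene_id)
}

#' @describeIn classifyAll classify a single circRNA; returns the label.
#' @export
classifyCirc <- function(circs, annot) classifyAll(circs, annot)$label

#' Binned per-chromosome classification density
#'
#' Counts circRNA midpoints in `nBins` equal-width bins per chromosome,
#' split by category label. Bins are half-open on the right, so a midpoint
#' exactly on an interior edge belongs to the bin to its right. Total
#' counts equal the number of input circRNAs.
#'
#' @param classTable data.frame from [classifyAll()].
#' @param chromLengths named integer vector of chromosome lengths.
#' @param nBins number of bins per chromosome (>= 1).
#' @return data.frame with columns `chrom`, `bin_start`, `bin_end` (BED
#'   convention), `label`, `count`; only non-empty cells are reported.
#' @export
classificationDensity <- function(classTable, chromLengths, nBins = 100L) {
  if (nBins < 1L) stop("nBins must be >= 1")
  missing <- setdiff(unique(classTable$chrom), names(chromLengths))
  if (length(missing)) {
    stop("chromosome(s) absent from chromLengths: ",
         paste(missing, collapse = ", "))
  }
  if (!nrow(classTable)) {
    return(data.frame(chrom = character(0), bin_start = integer(0),
                      bin_end = integer(0), label = character(0),
                      count = integer(0)))
  }
  len <- as.numeric(chromLengths[classTable$chrom])
  width <- len / nBins
  mid <- floor((classTable$start + classTable$end) / 2)
  bin <- pmin(floor(mid / width), nBins - 1L)
  key <- data.frame(chrom = classTable$chrom, bin = bin,
                    label = classTable$label)
  agg <- stats::aggregate(list(count = rep(1L, nrow(key))), key, sum)
  width_out <- as.numeric(chromLengths[agg$chrom]) / nBins
  out <- data.frame(chrom = agg$chrom,
                    bin_start = floor(agg$bin * width_out),
                    bin_end = pmin(floor((agg$bin + 1L) * width_out),
                                   as.numeric(chromLengths[agg$chrom])),
                    label = agg$label, count = agg$count)
  out[order(out$chrom, out$bin_start, out$label), , drop = FALSE]
}
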