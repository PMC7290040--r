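#' @importFrom Biostrings reverseComplement DNAString
NULL

#' Extract the circRNA sequence from the genome
#'
#' Returns the genomic substring covered by the circRNA. Minus-strand
#' circRNAs are reverse-complemented so the returned string reads 5'->3' on
#' the transcribed circular molecule.
#'
#' @param circs `GRanges` of circRNAs (see [readCircBed()]).
#' @param genome named `DNAStringSet` (see [readGenomeFasta()]).
#' @return named `DNAStringSet`, one sequence per circRNA.
#' @export
extractCircSequence <- function(circs, genome) {
  ids <- circIds(circs)
  chrom <- as.character(GenomicRanges::seqnames(circs))
  missing <- setdiff(unique(chrom), names(genome))
  if (length(missing)) {
    bad <- ids[chrom %in% missing][1L]
    stop("chromosome not in genome for circRNA '", bad, "'")
  }
  lens <- Biostrings::width(genome)[match(chrom, names(genome))]
  oob <- GenomicRanges::start(circs) < 1L | GenomicRanges::end(circs) > lens
  if (any(oob)) {
    stop("circRNA '", ids[which(oob)[1L]], "' extends beyond chromosome bounds")
  }
  seqs <- DNAStringSet(vapply(seq_along(circs), function(i) {
    s <- subseq(genome[[chrom[i]]], GenomicRanges::start(circs)[i],
                GenomicRanges::end(circs)[i])
    if (as.character(GenomicRanges::strand(circs)[i]) == "-") {
      s <- reverseComplement(s)
    }
    as.character(s)
  }, ""))
  names(seqs) <- ids
  seqs
}

#' Build doubled pseudo-circular junction references
#'
#' Concatenates each circRNA sequence to itself so the back-splice junction
#' appears as an ordinary internal position (at offset `L`, the circle
#' length) that linear aligners can span.
#'
#' @inheritParams extractCircSequence
#' @return a [JunctionRefSet-class].
#' @examples
#' genome <- Biostrings::DNAStringSet(c(chr1 = "AAACGTTT"))
#' circ <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4, 6),
#'                                strand = "+", circ_id = "c1")
#' refs <- buildJunctionRefs(circ, genome)
#' junctionSeqs(refs)   # CGTCGT
#' junctionOffset(refs) # 3
#' @export
buildJunctionRefs <- function(circs, genome) {
  s <- extractCircSequence(circs, genome)
  doubled <- Biostrings::xscat(s, s)
  names(doubled) <- names(s)
  methods::new("JunctionRefSet", seqs = doubled,
               offset = Biostrings::width(s), circ = circs)
}

#' Write junction references as FASTA
#'
#' One record per doubled reference, header = circRNA id, input order
#' preserved. Ids containing whitespace are sanitized by replacing each
#' whitespace run with `_` (with a message), since FASTA names are the token
#' before the first whitespace.
#'
#' @param refs a [JunctionRefSet-class].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeJunctionFasta <- function(refs, path) {
  if (!length(refs)) stop("no junction references to write")
  seqs <- junctionSeqs(refs)
  ids <- names(seqs)
  if (anyDuplicated(ids)) stop("duplicate circRNA ids")
  ws <- grepl("\\s", ids)
  if (any(ws)) {
    message("sanitizing whitespace in ", sum(ws), " circRNA id(s)")
    ids <- gsub("\\s+", "_", ids)
    names(seqs) <- ids
  }
  writeXStringSet(seqs, path)
  invisible(path)
}
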