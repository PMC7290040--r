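#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end strand width
#' @importFrom IRanges IRanges
#' @importFrom Biostrings DNAStringSet
NULL

#' Gene annotation container for circRNA classification
#'
#' Holds the three annotation layers used to place back-splice junction
#' boundaries: exons (with `gene_id`, `transcript_id` and `exon_index`
#' metadata), gene spans, and per-transcript introns derived as the gaps
#' between consecutive exons. All ranges are `GRanges` (1-based, closed),
#' the native Bioconductor convention; conversion from GTF/GFF happens in
#' [readAnnotation()].
#'
#' @slot genes `GRanges` of gene spans with a `gene_id` metadata column.
#' @slot exons `GRanges` of exons with `gene_id`, `transcript_id` and
#'   `exon_index` (1-based ordinal along the transcript) metadata columns.
#' @slot introns `GRanges` of derived introns with `gene_id` and
#'   `transcript_id` metadata columns.
#'
#' @seealso [readAnnotation()], [classifyAll()]
#' @export
setClass("CircAnnotation",
  representation(genes = "GRanges", exons = "GRanges", introns = "GRanges")
)

setValidity("CircAnnotation", function(object) {
  msgs <- character()
  ex <- object@exons
  if (length(ex)) {
    need <- c("gene_id", "transcript_id", "exon_index")
    if (!all(need %in% colnames(mcols(ex)))) {
      msgs <- c(msgs, "exons must carry gene_id, transcript_id and exon_index")
    } else {
      by_tx <- split(ex, mcols(ex)$transcript_id)
      for (tx in names(by_tx)) {
        e <- by_tx[[tx]]
        o <- order(start(e))
        if (length(e) > 1 && any(start(e)[o][-1] <= end(e)[o][-length(e)])) {
          msgs <- c(msgs, sprintf("overlapping exons within transcript '%s'", tx))
        }
      }
    }
  }
  if (length(object@genes) && !"gene_id" %in% colnames(mcols(object@genes))) {
    msgs <- c(msgs, "genes must carry gene_id")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn CircAnnotation exon ranges
#' @param x,object a `CircAnnotation`
#' @export
annotExons <- function(x) x@exons

#' @describeIn CircAnnotation gene spans
#' @export
annotGenes <- function(x) x@genes

#' @describeIn CircAnnotation derived introns
#' @export
annotIntrons <- function(x) x@introns

setMethod("show", "CircAnnotation", function(object) {
  cat("CircAnnotation:", length(object@genes), "genes,",
      length(object@exons), "exons,",
      length(object@introns), "derived introns\n")
})

#' Doubled pseudo-circular junction references
#'
#' Each circRNA sequence is concatenated to itself so that a linear aligner
#' can place reads across the back-splice junction. For a circle of length
#' `L` the doubled sequence has length `2L` and the junction lies between
#' 0-based positions `L - 1` and `L`; `junctionOffset()` returns `L`.
#'
#' @slot seqs `DNAStringSet` of doubled sequences, named by circRNA id.
#' @slot offset integer vector of junction offsets (`L`), parallel to `seqs`.
#' @slot circ source `GRanges` of the circRNAs (with `circ_id` metadata).
#'
#' @seealso [buildJunctionRefs()], [countJunctionReads()]
#' @export
setClass("JunctionRefSet",
  representation(seqs = "DNAStringSet", offset = "integer", circ = "GRanges")
)

setValidity("JunctionRefSet", function(object) {
  msgs <- character()
  n <- length(object@seqs)
  if (length(object@offset) != n || length(object@circ) != n) {
    msgs <- c(msgs, "seqs, offset and circ must have equal length")
  } else if (n) {
    w <- Biostrings::width(object@seqs)
    if (any(w != 2L * object@offset)) {
      msgs <- c(msgs, "each doubled sequence must have width 2 * junction offset")
    }
    half1 <- Biostrings::subseq(object@seqs, 1L, object@offset)
    half2 <- Biostrings::subseq(object@seqs, object@offset + 1L, w)
    if (!all(as.character(half1) == as.character(half2))) {
      msgs <- c(msgs, "the two halves of each doubled sequence must be identical")
    }
    if (anyDuplicated(names(object@seqs))) {
      msgs <- c(msgs, "circRNA ids must be unique")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn JunctionRefSet the doubled sequences as a named `DNAStringSet`
#' @param x,object a `JunctionRefSet`
#' @export
junctionSeqs <- function(x) x@seqs

#' @describeIn JunctionRefSet integer junction offsets (circle lengths), named
#'   by circRNA id
#' @export
junctionOffset <- function(x) stats::setNames(x@offset, names(x@seqs))

#' @describeIn JunctionRefSet source circRNA ranges
#' @export
junctionCirc <- function(x) x@circ

setMethod("show", "JunctionRefSet", function(object) {
  cat("JunctionRefSet:", length(object@seqs), "doubled references")
  if (length(object@seqs)) {
    cat(", circle lengths", paste(range(object@offset), collapse = "-"), "nt")
  }
  cat("\n")
})

setMethod("length", "JunctionRefSet", function(x) length(x@seqs))
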