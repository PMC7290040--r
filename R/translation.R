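#' Subtract reads mappable to rRNA or linear transcripts
#'
#' Ribosome-profiling reads are short (generally under 50 nt), so a read
#' that also aligns to rRNA or anywhere on the linear genome/transcriptome
#' is not trustworthy evidence at a back-splice junction. This filter keeps
#' only reads that failed to align in both subtraction passes. A read mapped
#' in both inputs is attributed to the rRNA pass.
#'
#' @param allReadIds character vector: the read universe.
#' @param rrnaAln,linearAln alignment data frames from
#'   [readSamAlignments()]; either may be empty. Alignment read ids outside
#'   the universe are reported via a message and ignored. Secondary and
#'   supplementary alignments count the same as primary.
#' @return list with `kept_ids` (character), `removed_rrna` and
#'   `removed_linear` (integer counts).
#' @export
subtractMappedReads <- function(allReadIds, rrnaAln, linearAln) {
  allReadIds <- unique(as.character(allReadIds))
  mappedIds <- function(aln) {
    if (is.null(aln) || !nrow(aln)) character(0)
    else unique(aln$read_id[aln$is_mapped])
  }
  rr <- mappedIds(rrnaAln)
  li <- mappedIds(linearAln)
  unknown <- setdiff(c(rr, li), allReadIds)
  if (length(unknown)) {
    message(length(unknown), " aligned read id(s) not in the read universe; ignored")
    rr <- intersect(rr, allReadIds)
    li <- intersect(li, allReadIds)
  }
  removed_rrna <- length(rr)
  removed_linear <- length(setdiff(li, rr))
  list(kept_ids = setdiff(allReadIds, union(rr, li)),
       removed_rrna = removed_rrna, removed_linear = removed_linear)
}

#' Does an alignment span the back-splice junction?
#'
#' An alignment with 0-based half-open span `[ref_start, ref_end)` on the
#' doubled reference spans the junction at `junctionOffset` when it covers
#' at least `minOverhang` bases on each side:
#' `ref_start <= offset - minOverhang` and `ref_end >= offset + minOverhang`.
#'
#' @param refStart,refEnd integer vectors, 0-based half-open span.
#' @param junctionOffset integer, circle length `L`.
#' @param minOverhang minimum bases required on each side of the junction
#'   (default 5).
#' @return logical vector.
#' @export
spansJunction <- function(refStart, refEnd, junctionOffset, minOverhang = 5L) {
  if (any(minOverhang < 1L)) stop("minOverhang must be >= 1")
  refStart <= junctionOffset - minOverhang & refEnd >= junctionOffset + minOverhang
}

#' Count junction-spanning reads per circRNA
#'
#' For each doubled reference, counts the distinct kept read ids whose
#' alignment spans the back-splice junction. A read aligning multiple times
#' to one reference counts once (the doubled sequence guarantees duplicate
#' internal placements). Alignments to references absent from `refs` are
#' reported via a message and skipped.
#'
#' @param refs a [JunctionRefSet-class].
#' @param junctionAln alignments of kept reads against the doubled
#'   references ([readSamAlignments()]).
#' @param kept result of [subtractMappedReads()], or a character vector of
#'   kept read ids.
#' @param minOverhang see [spansJunction()].
#' @return data.frame with columns `circ_id`, `junction_reads`; one row per
#'   reference in `refs`, in `refs` order.
#' @export
countJunctionReads <- function(refs, junctionAln, kept, minOverhang = 5L) {
  keptIds <- if (is.list(kept)) kept$kept_ids else as.character(kept)
  ids <- names(junctionSeqs(refs))
  offs <- junctionOffset(refs)
  counts <- stats::setNames(integer(length(ids)), ids)
  aln <- junctionAln[junctionAln$is_mapped & junctionAln$read_id %in% keptIds, ,
                     drop = FALSE]
  if (nrow(aln)) {
    unknown <- setdiff(unique(aln$ref_name), ids)
    if (length(unknown)) {
      message("skipping alignments to ", length(unknown),
              " unknown reference(s)")
      aln <- aln[aln$ref_name %in% ids, , drop = FALSE]
    }
  }
  if (nrow(aln)) {
    sp <- spansJunction(aln$ref_start, aln$ref_end,
                        unname(offs[aln$ref_name]), minOverhang)
    aln <- aln[sp, , drop = FALSE]
    if (nrow(aln)) {
      tab <- table(unique(aln[, c("ref_name", "read_id")])$ref_name)
      counts[names(tab)] <- as.integer(tab)
    }
  }
  data.frame(circ_id = ids, junction_reads = unname(counts))
}

#' Call translated circRNAs from junction read counts
#'
#' A circRNA is called translated when at least `threshold` distinct
#' junction-spanning ribosome-profiling reads survive the subtraction
#' filter (default 3).
#'
#' @param counts data.frame from [countJunctionReads()].
#' @param threshold minimum junction read count (default 3).
#' @return `counts` with an added logical `translated` column.
#' @export
callTranslation <- function(counts, threshold = 3L) {
  if (threshold < 1L) stop("threshold must be >= 1")
  counts$translated <- counts$junction_reads >= threshold
  counts
}

#' Combine translation calls into the mapping table
#'
#' One row per circRNA with its junction-spanning read count and translation
#' call, sorted by `junction_reads` descending, ties broken by `circ_id`.
#'
#' @param calls data.frame from [callTranslation()].
#' @param path optional CSV output path.
#' @return the sorted data.frame (columns `circ_id`, `junction_reads`,
#'   `translated`), invisibly written to `path` when given.
#' @export
mappingTable <- function(calls, path = NULL) {
  need <- c("circ_id", "junction_reads", "translated")
  if (!all(need %in% names(calls))) {
    stop("calls must have columns: ", paste(need, collapse = ", "))
  }
  out <- calls[order(-calls$junction_reads, calls$circ_id), need, drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) writeCsv(out, path)
  out
}
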