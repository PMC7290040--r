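#' @importFrom utils read.table write.csv
#' @importFrom Biostrings readBStringSet DNAStringSet writeXStringSet subseq
#' @importFrom GenomicAlignments cigarWidthAlongReferenceSpace
NULL

## Internal: BED-convention (0-based half-open) start/end from a GRanges.
bedStart <- function(gr) GenomicRanges::start(gr) - 1L
bedEnd <- function(gr) GenomicRanges::end(gr)

#' Read circRNAs from a BED file
#'
#' Parses BED3+ into a `GRanges` of circRNA intervals. BED is 0-based
#' half-open; the returned `GRanges` uses the Bioconductor 1-based closed
#' convention, so a BED line `chr1 100 400` becomes `chr1:101-400`. A missing
#' name column yields a synthesized id `"chrom:start-end"` in BED
#' coordinates; a missing strand column yields `"*"`. Columns beyond the
#' sixth are ignored.
#'
#' @param path path to a BED file; lines starting with `#`, `track` or
#'   `browser` are skipped.
#' @return `GRanges` with a `circ_id` metadata column (also used as names).
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t400\tcircA\t0\t+", bed)
#' readCircBed(bed)
#' @export
readCircBed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(circ_id = character(0))
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_field <- lengths(fields)
  if (any(n_field < 3L)) {
    stop("BED line ", lineno[which(n_field < 3L)[1L]], ": fewer than 3 columns")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  s_raw <- vapply(fields, `[[`, "", 2L)
  e_raw <- vapply(fields, `[[`, "", 3L)
  start0 <- suppressWarnings(as.integer(s_raw))
  end0 <- suppressWarnings(as.integer(e_raw))
  bad <- is.na(start0) | is.na(end0) | as.character(start0) != s_raw |
    as.character(end0) != e_raw
  if (any(bad)) {
    stop("BED line ", lineno[which(bad)[1L]], ": non-integer coordinates")
  }
  bad <- start0 < 0L | start0 >= end0
  if (any(bad)) {
    stop("BED line ", lineno[which(bad)[1L]],
         ": requires 0 <= start < end, got [", start0[which(bad)[1L]], ",",
         end0[which(bad)[1L]], ")")
  }
  has_name <- n_field >= 4L
  circ_id <- ifelse(has_name,
                    vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else "", ""),
                    paste0(chrom, ":", start0, "-", end0))
  circ_id[circ_id == "" | circ_id == "."] <-
    paste0(chrom, ":", start0, "-", end0)[circ_id == "" | circ_id == "."]
  explicit <- circ_id[has_name & vapply(fields, function(f)
    length(f) >= 4L && !f[[4L]] %in% c("", "."), FALSE)]
  if (anyDuplicated(explicit)) {
    stop("duplicate circRNA ids in BED: ",
         paste(unique(explicit[duplicated(explicit)]), collapse = ", "))
  }
  strand <- vapply(fields, function(f) {
    if (length(f) >= 6L && f[[6L]] %in% c("+", "-")) f[[6L]] else "*"
  }, "")
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand,
                circ_id = circ_id)
  names(gr) <- circ_id
  gr
}

#' Write circRNAs to a BED6 file
#'
#' Inverse of [readCircBed()]: coordinates are converted back to the BED
#' 0-based half-open convention; `*` strand is written as `.`.
#'
#' @param circs `GRanges` with a `circ_id` metadata column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCircBed <- function(circs, path) {
  strand <- as.character(GenomicRanges::strand(circs))
  strand[strand == "*"] <- "."
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(circs)),
    start = bedStart(circs), end = bedEnd(circs),
    name = circIds(circs), score = 0L, strand = strand
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## Internal: circ_id vector from a circRNA GRanges.
circIds <- function(circs) {
  if (!is.null(mcols(circs)$circ_id)) as.character(mcols(circs)$circ_id)
  else if (!is.null(names(circs))) names(circs)
  else stop("circRNA GRanges carries no circ_id")
}

#' Read a genome FASTA
#'
#' Sequences are uppercased; the header token before the first whitespace is
#' the chromosome name. By default any character outside `{A,C,G,T,N}` is an
#' error; with `strict = FALSE` such characters are replaced by `N`.
#'
#' @param path FASTA path.
#' @param strict error on non-ACGTN characters (default) instead of
#'   N-substituting them.
#' @return named `DNAStringSet`.
#' @export
readGenomeFasta <- function(path, strict = TRUE) {
  raw <- readBStringSet(path)
  if (!length(raw)) stop("empty FASTA: ", path)
  nm <- sub("\\s.*$", "", names(raw))
  if (any(!nzchar(nm))) stop("empty sequence name in FASTA: ", path)
  if (anyDuplicated(nm)) {
    stop("duplicate sequence names in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  chars <- toupper(as.character(raw))
  bad <- grepl("[^ACGTN]", chars)
  if (any(bad)) {
    if (strict) {
      stop("sequence '", nm[which(bad)[1L]],
           "' contains characters outside {A,C,G,T,N}")
    }
    chars <- gsub("[^ACGTN]", "N", chars)
  }
  out <- DNAStringSet(chars)
  names(out) <- nm
  out
}

#' Write a named DNAStringSet as FASTA
#' @param seqs named `DNAStringSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(seqs, path) {
  writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a gene annotation (GTF or GFF3) for junction classification
#'
#' Imports gene and exon features via `rtracklayer`, derives per-transcript
#' introns as the gaps between consecutive exons, and returns a
#' [CircAnnotation-class]. GTF attributes `gene_id`/`transcript_id` are used
#' directly; in GFF3 the exon `Parent` is taken as the transcript and the
#' transcript's `Parent` (when present) as the gene. When no gene features
#' are present, gene spans are derived as the range of each gene's exons.
#' Exons within one transcript must not overlap.
#'
#' @param path GTF/GFF path (dialect detected by `rtracklayer`).
#' @return a [CircAnnotation-class].
#' @export
readAnnotation <- function(path) {
  gff <- rtracklayer::import(path)
  type <- tolower(as.character(gff$type))
  md <- mcols(gff)

  getAttr <- function(x, col) {
    if (col %in% colnames(mcols(x))) as.character(mcols(x)[[col]]) else
      rep(NA_character_, length(x))
  }

  exons <- gff[type == "exon"]
  if (!length(exons)) stop("annotation contains no exon features: ", path)
  tx_id <- getAttr(exons, "transcript_id")
  if (all(is.na(tx_id)) && "Parent" %in% colnames(mcols(exons))) {
    p <- mcols(exons)$Parent
    tx_id <- vapply(as.list(p), function(v)
      if (length(v)) as.character(v[[1L]]) else NA_character_, "")
  }
  if (anyNA(tx_id)) stop("exon without transcript_id/Parent in ", path)
  gene_id <- getAttr(exons, "gene_id")
  if (anyNA(gene_id)) {
    # GFF3: map transcript -> gene through the mRNA/transcript features
    txf <- gff[type %in% c("mrna", "transcript")]
    tx2gene <- character(0)
    if (length(txf)) {
      tid <- getAttr(txf, "ID")
      par <- if ("Parent" %in% colnames(mcols(txf))) {
        vapply(as.list(mcols(txf)$Parent), function(v)
          if (length(v)) as.character(v[[1L]]) else NA_character_, "")
      } else rep(NA_character_, length(txf))
      tx2gene <- stats::setNames(par, tid)
    }
    gene_id <- ifelse(is.na(gene_id), unname(tx2gene[tx_id]), gene_id)
    gene_id[is.na(gene_id)] <- tx_id[is.na(gene_id)]
  }

  ex <- GRanges(GenomicRanges::seqnames(exons),
                IRanges(GenomicRanges::start(exons), GenomicRanges::end(exons)),
                strand = GenomicRanges::strand(exons),
                gene_id = gene_id, transcript_id = tx_id)
  # order and index exons within each transcript; reject overlaps
  ord <- order(tx_id, GenomicRanges::start(ex))
  ex <- ex[ord]
  idx <- integer(length(ex))
  for (tx in unique(mcols(ex)$transcript_id)) {
    i <- which(mcols(ex)$transcript_id == tx)
    if (length(i) > 1L &&
        any(GenomicRanges::start(ex)[i][-1L] <= GenomicRanges::end(ex)[i][-length(i)])) {
      stop("overlapping exons within transcript '", tx, "'")
    }
    idx[i] <- seq_along(i)
  }
  mcols(ex)$exon_index <- idx

  genesf <- gff[type == "gene"]
  if (length(genesf)) {
    g_id <- getAttr(genesf, "gene_id")
    if (anyNA(g_id)) g_id <- getAttr(genesf, "ID")
    genes <- GRanges(GenomicRanges::seqnames(genesf),
                     IRanges(GenomicRanges::start(genesf), GenomicRanges::end(genesf)),
                     strand = GenomicRanges::strand(genesf), gene_id = g_id)
  } else {
    spl <- split(ex, mcols(ex)$gene_id)
    genes <- unlist(GenomicRanges::GRangesList(lapply(spl, range)), use.names = FALSE)
    mcols(genes)$gene_id <- names(spl)
  }
  out_of_gene <- !is.na(match(mcols(ex)$gene_id, mcols(genes)$gene_id))
  if (any(out_of_gene)) {
    gi <- match(mcols(ex)$gene_id, mcols(genes)$gene_id)
    ok <- is.na(gi) |
      (GenomicRanges::start(ex) >= GenomicRanges::start(genes)[gi] &
       GenomicRanges::end(ex) <= GenomicRanges::end(genes)[gi])
    if (!all(ok)) stop("exon outside its gene span for gene '",
                       mcols(ex)$gene_id[which(!ok)[1L]], "'")
  }

  methods::new("CircAnnotation", genes = genes, exons = ex,
               introns = deriveIntrons(ex))
}

## Internal: per-transcript introns = gaps between consecutive sorted exons.
deriveIntrons <- function(ex) {
  res <- list()
  for (tx in unique(mcols(ex)$transcript_id)) {
    e <- ex[mcols(ex)$transcript_id == tx]
    e <- e[order(GenomicRanges::start(e))]
    if (length(e) < 2L) next
    s <- GenomicRanges::end(e)[-length(e)] + 1L
    t <- GenomicRanges::start(e)[-1L] - 1L
    keep <- s <= t
    if (!any(keep)) next
    res[[tx]] <- GRanges(GenomicRanges::seqnames(e)[1L], IRanges(s[keep], t[keep]),
                         strand = GenomicRanges::strand(e)[1L],
                         gene_id = mcols(e)$gene_id[1L], transcript_id = tx)
  }
  if (!length(res)) {
    g <- GRanges()
    mcols(g) <- DataFrame(gene_id = character(0), transcript_id = character(0))
    g
  } else {
    unlist(GenomicRanges::GRangesList(res), use.names = FALSE)
  }
}

#' Write a CircAnnotation as GTF
#'
#' Emits gene and exon lines with `gene_id`/`transcript_id` attributes,
#' 1-based inclusive coordinates. Round trips through [readAnnotation()].
#'
#' @param annot a [CircAnnotation-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnnotationGtf <- function(annot, path) {
  fmt <- function(gr, feature, attrs) {
    strand <- as.character(GenomicRanges::strand(gr))
    strand[strand == "*"] <- "."
    paste(as.character(GenomicRanges::seqnames(gr)), "circkit", feature,
          GenomicRanges::start(gr), GenomicRanges::end(gr), ".", strand, ".",
          attrs, sep = "\t")
  }
  g <- annotGenes(annot)
  e <- annotExons(annot)
  lines <- c(
    fmt(g, "gene", sprintf('gene_id "%s";', mcols(g)$gene_id)),
    fmt(e, "exon", sprintf('gene_id "%s"; transcript_id "%s";',
                           mcols(e)$gene_id, mcols(e)$transcript_id))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Reference-consumed width of a CIGAR string
#'
#' Sums the reference-consuming operations (M, D, N, =, X); insertions and
#' clips do not extend the reference span.
#'
#' @param cigar character vector of CIGAR strings.
#' @return integer vector of reference widths.
#' @export
cigarRefWidth <- function(cigar) {
  cigarWidthAlongReferenceSpace(cigar)
}

#' Read a SAM file into alignment records
#'
#' Parses SAM alignment lines into a data frame of alignment spans. Spans
#' follow the 0-based half-open convention: `ref_start = POS - 1` and
#' `ref_end = ref_start +` reference-consumed CIGAR width. Records with flag
#' bit 0x4 are returned with `is_mapped = FALSE` and `NA` span. A mapped
#' record with CIGAR `*` is an error.
#'
#' @param path SAM path; a header (`@` lines) is required.
#' @return data.frame with columns `read_id`, `flag`, `ref_name`,
#'   `ref_start`, `ref_end`, `is_mapped`.
#' @export
readSamAlignments <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], "@")) {
    stop("not a valid SAM file (header required): ", path)
  }
  aln <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (!length(aln)) {
    return(data.frame(read_id = character(0), flag = integer(0),
                      ref_name = character(0), ref_start = integer(0),
                      ref_end = integer(0), is_mapped = logical(0)))
  }
  fields <- strsplit(aln, "\t", fixed = TRUE)
  if (any(lengths(fields) < 6L)) stop("malformed SAM alignment line in ", path)
  read_id <- vapply(fields, `[[`, "", 1L)
  flag <- as.integer(vapply(fields, `[[`, "", 2L))
  ref_name <- vapply(fields, `[[`, "", 3L)
  pos <- as.integer(vapply(fields, `[[`, "", 4L))
  cigar <- vapply(fields, `[[`, "", 6L)
  is_mapped <- bitwAnd(flag, 4L) == 0L
  if (any(is_mapped & cigar == "*")) {
    stop("mapped SAM record with CIGAR '*' in ", path)
  }
  ref_start <- ifelse(is_mapped, pos - 1L, NA_integer_)
  ref_end <- rep(NA_integer_, length(aln))
  if (any(is_mapped)) {
    ref_end[is_mapped] <- ref_start[is_mapped] + cigarRefWidth(cigar[is_mapped])
  }
  ref_name[!is_mapped & ref_name == "*"] <- NA_character_
  data.frame(read_id = read_id, flag = flag, ref_name = ref_name,
             ref_start = as.integer(ref_start), ref_end = as.integer(ref_end),
             is_mapped = is_mapped)
}

## Internal: write a table as CSV with header, no row names.
writeCsv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
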