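#' @importFrom Biostrings pairwiseAlignment nucleotideSubstitutionMatrix
#'   nmatch alignedPattern alignedSubject score
#' @importFrom BiocGenerics start end
NULL

#' Reverse complement of a nucleotide string
#'
#' @param seq character string over `{A,C,G,T,N}` (empty allowed).
#' @return the reverse-complemented string.
#' @export
revComp <- function(seq) {
  if (!nzchar(seq)) return("")
  if (grepl("[^ACGTN]", seq)) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }
  as.character(reverseComplement(DNAString(seq)))
}

#' Extract the sequences flanking each circRNA
#'
#' Returns `flank` nt immediately upstream and downstream of each circRNA,
#' in genomic plus-strand orientation, truncated at chromosome ends (a
#' message reports truncations).
#'
#' @param circs `GRanges` of circRNAs.
#' @param genome named `DNAStringSet`.
#' @param flank flank width in nt (>= 1).
#' @return data.frame with columns `circ_id`, `upstream`, `downstream`,
#'   `up_len`, `down_len` (actual lengths after truncation).
#' @export
extractFlanks <- function(circs, genome, flank = 200L) {
  if (flank < 1L) stop("flank must be >= 1")
  ids <- circIds(circs)
  chrom <- as.character(GenomicRanges::seqnames(circs))
  start0 <- bedStart(circs)
  end0 <- bedEnd(circs)
  up <- character(length(circs))
  down <- character(length(circs))
  truncated <- 0L
  for (i in seq_along(circs)) {
    if (!chrom[i] %in% names(genome)) {
      stop("chromosome not in genome for circRNA '", ids[i], "'")
    }
    cs <- genome[[chrom[i]]]
    len <- length(cs)
    us <- max(0L, start0[i] - flank)
    de <- min(len, end0[i] + flank)
    up[i] <- if (us < start0[i]) as.character(subseq(cs, us + 1L, start0[i])) else ""
    down[i] <- if (end0[i] < de) as.character(subseq(cs, end0[i] + 1L, de)) else ""
    if (nchar(up[i]) < flank || nchar(down[i]) < flank) truncated <- truncated + 1L
  }
  if (truncated) {
    message(truncated, " circRNA(s) had flanks truncated at chromosome ends")
  }
  data.frame(circ_id = ids, upstream = up, downstream = down,
             up_len = nchar(up), down_len = nchar(down))
}

#' Best local alignment between two nucleotide strings
#'
#' Smith-Waterman local alignment with affine gaps: a gap of length `k`
#' costs `|gapOpen| + k * |gapExtend|`. Returns the optimal score with one
#' traceback; when no positive-scoring local alignment exists (or either
#' input is empty) the hit is empty with score 0.
#'
#' @param a,b nucleotide strings.
#' @param match match score (> 0); default 2.
#' @param mismatch mismatch score (<= 0); default -3.
#' @param gapOpen gap opening score (<= 0); default -5.
#' @param gapExtend gap extension score (<= 0); default -2.
#' @return list with `score`, spans `a_start`, `a_end`, `b_start`, `b_end`
#'   (0-based half-open within `a` and `b`), gapped strings `aligned_a`,
#'   `aligned_b`, and `identity` (matches / alignment columns; `NA` for an
#'   empty hit).
#' @export
localAlign <- function(a, b, match = 2L, mismatch = -3L,
                       gapOpen = -5L, gapExtend = -2L) {
  if (match <= 0) stop("match must be > 0")
  if (mismatch > 0 || gapOpen > 0 || gapExtend > 0) {
    stop("mismatch and gap penalties must be <= 0")
  }
  empty <- list(score = 0, a_start = 0L, a_end = 0L, b_start = 0L,
                b_end = 0L, aligned_a = "", aligned_b = "", identity = NA_real_)
  if (!nzchar(a) || !nzchar(b)) return(empty)
  sub <- nucleotideSubstitutionMatrix(match = match, mismatch = mismatch)
  pa <- pairwiseAlignment(DNAString(a), DNAString(b), type = "local",
                          substitutionMatrix = sub,
                          gapOpening = abs(gapOpen), gapExtension = abs(gapExtend))
  sc <- score(pa)
  if (sc <= 0) return(empty)
  pr <- Biostrings::pattern(pa)
  sr <- Biostrings::subject(pa)
  al_a <- as.character(alignedPattern(pa))
  al_b <- as.character(alignedSubject(pa))
  list(score = sc,
       a_start = BiocGenerics::start(pr) - 1L, a_end = BiocGenerics::end(pr),
       b_start = BiocGenerics::start(sr) - 1L, b_end = BiocGenerics::end(sr),
       aligned_a = al_a, aligned_b = al_b,
       identity = nmatch(pa) / nchar(al_a))
}

#' Scan circRNA flanks for reverse-complementary stem-loop pairings
#'
#' For each circRNA, extracts flanking sequences and locally aligns the
#' reverse complement of the upstream flank against the downstream flank.
#' A high-identity hit indicates reverse-complementary repeats that can
#' base-pair across the circle and promote circularization. Alignment spans
#' are reported in the coordinates of the extracted flanks (0-based
#' half-open, genomic plus-strand orientation; the span on the upstream
#' flank is mapped back from reverse-complement space).
#'
#' @param circs `GRanges` of circRNAs.
#' @param genome named `DNAStringSet`.
#' @param flank flank width in nt (default 200).
#' @inheritParams localAlign
#' @param path optional CSV output path.
#' @return data.frame, one row per circRNA in input order, with columns
#'   `circ_id`, `chrom`, `start`, `end`, `strand`, `up_aln_start`,
#'   `up_aln_end`, `down_aln_start`, `down_aln_end`, `score`, `identity`,
#'   `aligned_up`, `aligned_down`.
#' @export
stemRingScan <- function(circs, genome, flank = 200L, match = 2L,
                         mismatch = -3L, gapOpen = -5L, gapExtend = -2L,
                         path = NULL) {
  fl <- extractFlanks(circs, genome, flank)
  n <- nrow(fl)
  rows <- vector("list", n)
  strand <- as.character(GenomicRanges::strand(circs))
  strand[strand == "*"] <- "."
  for (i in seq_len(n)) {
    a <- if (nzchar(fl$upstream[i])) revComp(fl$upstream[i]) else ""
    hit <- localAlign(a, fl$downstream[i], match, mismatch, gapOpen, gapExtend)
    n_up <- fl$up_len[i]
    rows[[i]] <- data.frame(
      circ_id = fl$circ_id[i],
      chrom = as.character(GenomicRanges::seqnames(circs))[i],
      start = bedStart(circs)[i], end = bedEnd(circs)[i],
      strand = strand[i],
      up_aln_start = n_up - hit$a_end, up_aln_end = n_up - hit$a_start,
      down_aln_start = hit$b_start, down_aln_end = hit$b_end,
      score = hit$score, identity = hit$identity,
      aligned_up = hit$aligned_a, aligned_down = hit$aligned_b
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(circ_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), up_aln_start = integer(0),
                      up_aln_end = integer(0), down_aln_start = integer(0),
                      down_aln_end = integer(0), score = numeric(0),
                      identity = numeric(0), aligned_up = character(0),
                      aligned_down = character(0))
  }
  rownames(out) <- NULL
  if (!is.null(path)) writeCsv(out, path)
  out
}
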