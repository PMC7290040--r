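#' @import ggplot2
NULL

#' Per-position circular read coverage of one circRNA
#'
#' Projects kept alignments on the doubled reference onto the circle:
#' coverage at circular position `p` (0-based, `0 <= p < L`) counts the
#' alignments covering doubled-reference position `p` or `p + L`, each
#' alignment contributing at most once per circular position. Total
#' coverage mass therefore equals the sum over alignments of
#' `min(aligned length, L)`.
#'
#' @param refs a [JunctionRefSet-class].
#' @param circId which reference to project.
#' @param junctionAln alignments from [readSamAlignments()].
#' @param kept kept read ids ([subtractMappedReads()] result or character
#'   vector); `NULL` keeps every aligned read.
#' @return integer vector of length `L`; position 1 of the vector is
#'   circular position 0 (the base just after the back-splice junction).
#' @export
circularCoverage <- function(refs, circId, junctionAln, kept = NULL) {
  ids <- names(junctionSeqs(refs))
  if (!circId %in% ids) stop("unknown circRNA id: ", circId)
  L <- unname(junctionOffset(refs)[circId])
  cov <- integer(L)
  aln <- junctionAln[junctionAln$is_mapped & junctionAln$ref_name == circId, ,
                     drop = FALSE]
  if (!is.null(kept)) {
    keptIds <- if (is.list(kept)) kept$kept_ids else as.character(kept)
    aln <- aln[aln$read_id %in% keptIds, , drop = FALSE]
  }
  for (i in seq_len(nrow(aln))) {
    s <- max(aln$ref_start[i], 0L)
    e <- min(aln$ref_end[i], 2L * L)
    if (s >= e) next
    p <- unique((s:(e - 1L)) %% L)
    cov[p + 1L] <- cov[p + 1L] + 1L
  }
  cov
}

#' Start and stop codon positions around the circle
#'
#' Scans the circle in all reading frames, including codons that wrap
#' around the back-splice junction, by scanning the doubled sequence and
#' keeping codon start positions below the circle length.
#'
#' @param circSeq single-copy circle sequence (character).
#' @return list with integer vectors `start` (positions of `ATG`) and
#'   `stop` (positions of `TAA`/`TAG`/`TGA`), 0-based circular coordinates.
#' @export
findCodons <- function(circSeq) {
  L <- nchar(circSeq)
  if (L == 0L) return(list(start = integer(0), stop = integer(0)))
  doubled <- paste0(circSeq, circSeq)
  hitPos <- function(codons) {
    pos <- integer(0)
    for (cd in codons) {
      m <- gregexpr(cd, doubled, fixed = TRUE)[[1L]]
      if (m[1L] != -1L) pos <- c(pos, as.integer(m) - 1L)
    }
    sort(unique(pos[pos < L]))
  }
  list(start = hitPos("ATG"), stop = hitPos(c("TAA", "TAG", "TGA")))
}

## Internal: check required columns before drawing.
checkCols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " table lacks column(s): ", paste(miss, collapse = ", "))
  }
}

## Internal: save a ggplot; device picked from the file extension.
saveplot <- function(p, path, width = 7, height = 7) {
  ggsave(path, p, width = width, height = height, dpi = 150)
  invisible(path)
}

#' Circular read-mapping plot for one circRNA
#'
#' Renders the junction-read alignments of one circRNA as arcs on a ring:
#' the back-splice junction is anchored at angle 0 and the circle proceeds
#' clockwise 5'->3'. Layers: per-position coverage (outer ring), one arc
#' per junction alignment, and start/stop codon marks. All numbers come
#' from [circularCoverage()] and [findCodons()]; nothing is recomputed
#' here.
#'
#' @param refs a [JunctionRefSet-class].
#' @param circId circRNA to draw.
#' @param junctionAln,kept see [circularCoverage()].
#' @param path output image path (extension selects the device, e.g.
#'   `.png`).
#' @param zoom optional numeric `c(lo, hi)` fraction of the circle
#'   (containing the junction at 0) to restrict the angular range to.
#' @return `path`, invisibly.
#' @export
renderMappingPlot <- function(refs, circId, junctionAln, kept = NULL,
                              path, zoom = NULL) {
  cov <- circularCoverage(refs, circId, junctionAln, kept)
  L <- length(cov)
  seqs <- junctionSeqs(refs)
  codons <- findCodons(as.character(subseq(seqs[[circId]], 1L, L)))
  covdf <- data.frame(pos = seq_len(L) - 1L, coverage = cov)
  aln <- junctionAln[junctionAln$is_mapped & junctionAln$ref_name == circId, ,
                     drop = FALSE]
  if (!is.null(kept)) {
    keptIds <- if (is.list(kept)) kept$kept_ids else as.character(kept)
    aln <- aln[aln$read_id %in% keptIds, , drop = FALSE]
  }
  arcs <- if (nrow(aln)) {
    data.frame(read = seq_len(nrow(aln)),
               from = aln$ref_start %% L,
               len = pmin(aln$ref_end - aln$ref_start, L))
  } else data.frame(read = integer(0), from = integer(0), len = integer(0))
  if (!is.null(zoom)) {
    stopifnot(length(zoom) == 2L, zoom[1L] < zoom[2L])
    lo <- zoom[1L] * L; hi <- zoom[2L] * L
    sel <- covdf$pos >= lo & covdf$pos < hi
    covdf <- covdf[sel, , drop = FALSE]
  }
  p <- ggplot(covdf, aes(x = .data$pos, y = 1, fill = .data$coverage)) +
    geom_tile(height = 0.3) +
    scale_fill_gradient(low = "steelblue", high = "red") +
    geom_vline(xintercept = 0, linewidth = 1) +
    coord_polar(direction = -1) +
    ylim(-2, 1.3) +
    labs(title = paste0(circId, " junction read mapping"),
         x = NULL, y = NULL, fill = "coverage") +
    theme_minimal() +
    theme(axis.text.y = element_blank())
  if (nrow(arcs)) {
    arcs$y <- 0.6 - 0.05 * (arcs$read %% 10)
    segs <- do.call(rbind, lapply(seq_len(nrow(arcs)), function(i) {
      pos <- (arcs$from[i] + seq_len(arcs$len[i]) - 1L) %% L
      data.frame(pos = pos, y = arcs$y[i], read = arcs$read[i])
    }))
    p <- p + geom_point(data = segs, aes(x = .data$pos, y = .data$y),
                        inherit.aes = FALSE, colour = "darkgreen", size = 0.2)
  }
  if (length(codons$start)) {
    p <- p + geom_point(data = data.frame(pos = codons$start),
                        aes(x = .data$pos, y = -0.2), inherit.aes = FALSE,
                        colour = "forestgreen", shape = 17, size = 2)
  }
  if (length(codons$stop)) {
    p <- p + geom_point(data = data.frame(pos = codons$stop),
                        aes(x = .data$pos, y = -0.2), inherit.aes = FALSE,
                        colour = "firebrick", shape = 15, size = 2)
  }
  saveplot(p, path)
}

#' Genome overview ring
#'
#' Ring-style overview combining the computed tables: circRNA lengths by
#' category (dot layer), binned circRNA density, and the GC-content track,
#' laid out along concatenated chromosome coordinates and wrapped on a
#' polar axis.
#'
#' @param classTable data.frame from [classifyAll()] (non-empty).
#' @param gcTrack data.frame from [gcWindows()].
#' @param chromLengths named integer vector.
#' @param path output image path.
#' @param nBins density bins per chromosome (default 50).
#' @return `path`, invisibly.
#' @export
renderOverview <- function(classTable, gcTrack, chromLengths, path,
                           nBins = 50L) {
  checkCols(classTable, c("chrom", "start", "end", "length", "label"),
            "classification")
  checkCols(gcTrack, c("chrom", "window_start", "window_end", "gc_fraction"),
            "GC")
  if (!nrow(classTable)) stop("no circRNAs to draw")
  chroms <- names(chromLengths)[naturalChromOrder(names(chromLengths))]
  offset <- stats::setNames(cumsum(c(0, as.numeric(chromLengths[chroms])))[
    seq_along(chroms)], chroms)
  cls <- classTable[classTable$chrom %in% chroms, , drop = FALSE]
  cls$gpos <- offset[cls$chrom] + (cls$start + cls$end) / 2
  gc <- gcTrack[gcTrack$chrom %in% chroms & !is.na(gcTrack$gc_fraction), ,
                drop = FALSE]
  gc$gpos <- offset[gc$chrom] + (gc$window_start + gc$window_end) / 2
  dens <- classificationDensity(cls, chromLengths, nBins)
  dens <- stats::aggregate(count ~ chrom + bin_start + bin_end, dens, sum)
  dens$gpos <- offset[dens$chrom] + (dens$bin_start + dens$bin_end) / 2
  p <- ggplot() +
    geom_point(data = cls, aes(x = .data$gpos, y = 2 + .data$length /
                                 max(.data$length), colour = .data$label),
               size = 0.8) +
    geom_col(data = dens, aes(x = .data$gpos, y = 1 + .data$count /
                                max(.data$count)), width = 0.8,
             fill = "grey40") +
    geom_tile(data = gc, aes(x = .data$gpos, y = 0.5,
                             fill = .data$gc_fraction), height = 0.4) +
    scale_fill_gradient(low = "white", high = "red") +
    coord_polar() +
    ylim(0, 3.2) +
    labs(title = "circRNA overview", x = NULL, y = NULL,
         colour = "category", fill = "GC") +
    theme_minimal() +
    theme(axis.text = element_blank())
  saveplot(p, path)
}

#' Per-chromosome classification density rings
#'
#' @param density data.frame from [classificationDensity()] (non-empty).
#' @param path output image path.
#' @return `path`, invisibly.
#' @export
renderClassDensity <- function(density, path) {
  checkCols(density, c("chrom", "bin_start", "bin_end", "label", "count"),
            "density")
  if (!nrow(density)) stop("no density cells to draw")
  density$mid <- (density$bin_start + density$bin_end) / 2
  p <- ggplot(density, aes(x = .data$mid, y = .data$count,
                           fill = .data$label)) +
    geom_col(position = "stack") +
    coord_polar() +
    facet_wrap(~chrom) +
    labs(title = "circRNA category density", x = NULL, y = "count",
         fill = "category") +
    theme_minimal()
  saveplot(p, path)
}

#' Splice-signal histogram
#'
#' @param signalCounts data.frame from [spliceSignalCounts()] (non-empty).
#' @param path output image path.
#' @param topN show at most this many signals (default 20).
#' @return `path`, invisibly.
#' @export
renderSignalHist <- function(signalCounts, path, topN = 20L) {
  checkCols(signalCounts, c("signal", "count", "fraction"), "splice-signal")
  if (!nrow(signalCounts)) stop("no splice signals to draw")
  df <- utils::head(signalCounts, topN)
  df$signal <- factor(df$signal, levels = df$signal)
  p <- ggplot(df, aes(x = .data$signal, y = .data$count)) +
    geom_col(fill = "steelblue") +
    labs(title = "Back-splice junction splice signals",
         x = "upstream/downstream dinucleotides", y = "count") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 60, hjust = 1))
  saveplot(p, path)
}
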