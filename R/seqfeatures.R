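#' @importFrom Biostrings letterFrequency
NULL

## Internal: substring of a chromosome by 0-based half-open coords, padded
## with N outside the chromosome bounds.
paddedSubstr <- function(chromSeq, start0, end0) {
  len <- length(chromSeq)
  left <- max(0L, -start0)
  right <- max(0L, end0 - len)
  s <- max(start0, 0L)
  e <- min(end0, len)
  core <- if (s < e) as.character(subseq(chromSeq, s + 1L, e)) else ""
  paste0(strrep("N", left), core, strrep("N", right))
}

#' Splice-signal dinucleotides at the back-splice junction
#'
#' Extracts the two bases immediately upstream and downstream of each
#' circRNA on the transcribed strand, reported as `"upstream/downstream"`.
#' On the plus strand the upstream dinucleotide precedes the circRNA start
#' and the downstream one follows its end; on the minus strand the flanks
#' are mirrored and reverse-complemented so the pair reads 5'->3' on the
#' transcribed molecule. Flanks extending past a chromosome end are padded
#' with `N`.
#'
#' @param circs `GRanges` of circRNAs.
#' @param genome named `DNAStringSet`.
#' @return data.frame with columns `circ_id`, `upstream_dinuc`,
#'   `downstream_dinuc`, `signal`.
#' @export
spliceSignal <- function(circs, genome) {
  ids <- circIds(circs)
  chrom <- as.character(GenomicRanges::seqnames(circs))
  start0 <- bedStart(circs)
  end0 <- bedEnd(circs)
  st <- as.character(GenomicRanges::strand(circs))
  up <- character(length(circs))
  down <- character(length(circs))
  for (i in seq_along(circs)) {
    if (!chrom[i] %in% names(genome)) {
      stop("chromosome not in genome for circRNA '", ids[i], "'")
    }
    cs <- genome[[chrom[i]]]
    left <- paddedSubstr(cs, start0[i] - 2L, start0[i])
    right <- paddedSubstr(cs, end0[i], end0[i] + 2L)
    if (st[i] == "-") {
      up[i] <- revComp(right)
      down[i] <- revComp(left)
    } else {
      up[i] <- left
      down[i] <- right
    }
  }
  data.frame(circ_id = ids, upstream_dinuc = up, downstream_dinuc = down,
             signal = paste0(up, "/", down))
}

#' Tabulate splice signals over a circRNA set
#'
#' @inheritParams spliceSignal
#' @return data.frame with columns `signal`, `count`, `fraction`, sorted by
#'   count descending (ties by signal); fractions sum to 1 for non-empty
#'   input.
#' @export
spliceSignalCounts <- function(circs, genome) {
  if (!length(circs)) {
    return(data.frame(signal = character(0), count = integer(0),
                      fraction = numeric(0)))
  }
  sig <- spliceSignal(circs, genome)$signal
  tab <- table(sig)
  out <- data.frame(signal = names(tab), count = as.integer(tab))
  out$fraction <- out$count / sum(out$count)
  out <- out[order(-out$count, out$signal), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' CircRNA length histogram
#'
#' Counts circRNA lengths in half-open bins `[k*w, (k+1)*w)`. When a
#' classification table is supplied, counts are additionally split by
#' category label.
#'
#' @param circs `GRanges` of circRNAs.
#' @param binWidth bin width in nt (>= 1).
#' @param classTable optional data.frame from [classifyAll()].
#' @return data.frame with columns `bin_start`, `bin_end`, (`label`,)
#'   `count`; empty bins are omitted, counts sum to the input size.
#' @export
lengthDistribution <- function(circs, binWidth = 200L, classTable = NULL) {
  if (binWidth < 1L) stop("binWidth must be >= 1")
  len <- GenomicRanges::width(circs)
  if (!length(len)) {
    out <- data.frame(bin_start = integer(0), bin_end = integer(0),
                      count = integer(0))
    if (!is.null(classTable)) out$label <- character(0)
    return(out)
  }
  bin <- len %/% binWidth
  if (is.null(classTable)) {
    tab <- table(bin)
    out <- data.frame(bin_start = as.integer(names(tab)) * binWidth,
                      count = as.integer(tab))
  } else {
    label <- classTable$label[match(circIds(circs), classTable$circ_id)]
    agg <- stats::aggregate(list(count = rep(1L, length(bin))),
                            data.frame(bin = bin, label = label), sum)
    out <- data.frame(bin_start = agg$bin * binWidth, label = agg$label,
                      count = agg$count)
  }
  out$bin_end <- out$bin_start + binWidth
  cols <- c("bin_start", "bin_end",
            if (!is.null(classTable)) "label", "count")
  out <- out[order(out$bin_start), cols, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Natural (version-style) ordering of chromosome names
#'
#' Orders `chr2` before `chr10`: names are split into a leading non-numeric
#' prefix and a numeric suffix, sorted by prefix then numeric value, with
#' purely non-numeric names after numeric ones of the same prefix.
#'
#' @param x character vector of chromosome names.
#' @return integer permutation ordering `x` naturally.
#' @export
naturalChromOrder <- function(x) {
  prefix <- sub("[0-9]+$", "", x)
  numstr <- sub("^.*?([0-9]+)$", "\\1", x)
  num <- suppressWarnings(ifelse(grepl("[0-9]+$", x), as.numeric(numstr), Inf))
  order(prefix, num, x)
}

#' CircRNA counts per chromosome
#'
#' @param circs `GRanges` of circRNAs.
#' @return data.frame with columns `chrom`, `count`, chromosomes in natural
#'   order (`chr2` before `chr10`); counts sum to the input size.
#' @export
chromosomeDistribution <- function(circs) {
  if (!length(circs)) {
    return(data.frame(chrom = character(0), count = integer(0)))
  }
  tab <- table(as.character(GenomicRanges::seqnames(circs)))
  tab <- tab[tab > 0L]
  out <- data.frame(chrom = names(tab), count = as.integer(tab))
  out <- out[naturalChromOrder(out$chrom), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Windowed GC content across the genome
#'
#' Tiles each chromosome with non-overlapping windows (the last window may
#' be shorter) and reports the GC fraction over non-N bases;
#' all-N windows yield `NA` rather than zero, so assembly gaps are not
#' painted as AT-rich.
#'
#' @param genome named `DNAStringSet`.
#' @param window window width in nt (>= 1).
#' @return data.frame with columns `chrom`, `window_start`, `window_end`
#'   (BED convention, 0-based half-open) and `gc_fraction`.
#' @export
gcWindows <- function(genome, window = 10000L) {
  if (window < 1L) stop("window must be >= 1")
  res <- lapply(names(genome), function(nm) {
    len <- length(genome[[nm]])
    starts <- seq(0L, len - 1L, by = window)
    ends <- pmin(starts + window, len)
    v <- Biostrings::Views(genome[[nm]], start = starts + 1L, end = ends)
    freq <- letterFrequency(v, c("A", "C", "G", "T"))
    denom <- rowSums(freq)
    gc <- ifelse(denom > 0, (freq[, "G"] + freq[, "C"]) / denom, NA_real_)
    data.frame(chrom = nm, window_start = starts, window_end = ends,
               gc_fraction = gc)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write a GC track as bedGraph
#'
#' @param gc data.frame from [gcWindows()]; `NA` windows are skipped.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGcBedGraph <- function(gc, path) {
  keep <- !is.na(gc$gc_fraction)
  lines <- sprintf("%s\t%d\t%d\t%.6g", gc$chrom[keep], gc$window_start[keep],
                   gc$window_end[keep], gc$gc_fraction[keep])
  writeLines(c("track type=bedGraph name=gc_content", lines), path)
  invisible(path)
}
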