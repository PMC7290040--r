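#' Configuration for the synthetic fixture generator
#'
#' Defines a small self-consistent study: a random genome with annotated
#' multi-exon genes and intergenic space plus an rRNA contig, circRNAs of
#' every junction category, and ribosome-profiling reads (junction-spanning,
#' rRNA-derived and linear-transcript-derived) emitted as SAM. Identical
#' configurations produce byte-identical outputs.
#'
#' @param seed integer RNG seed; all generator randomness derives from it.
#' @param nChroms number of annotated chromosomes (default 2).
#' @param chromLength chromosome length in nt (default 20000).
#' @param nGenesPerChrom genes per chromosome (default 3).
#' @param exonsPerGene exons per gene (default 4; intron-containing
#'   categories require at least 3).
#' @param nCircPerCategory circRNAs per junction category (default 5).
#' @param readLength ribosome-footprint read length in nt (default 30,
#'   within the under-50-nt regime typical of ribosome profiling).
#' @param nJunctionReadsPerTranslated surviving junction-spanning reads
#'   planted per translated circRNA (default 5; must be >= 3 for the
#'   planted truth to be recoverable at the default threshold).
#' @param nDecoyReads background reads mapped to rRNA or the linear genome
#'   (default 300).
#' @param plantedStemRepeatLength length of the reverse-complement repeat
#'   planted in the flanks of intergenic-category circRNAs (default 20).
#' @param minOverhang junction overhang the planted reads satisfy
#'   (default 5).
#' @param rrnaLength length of the rRNA contig (default 2000).
#' @return a named list of class `circkit_sim_config`.
#' @export
simConfig <- function(seed = 1L, nChroms = 2L, chromLength = 20000L,
                      nGenesPerChrom = 3L, exonsPerGene = 4L,
                      nCircPerCategory = 5L, readLength = 30L,
                      nJunctionReadsPerTranslated = 5L, nDecoyReads = 300L,
                      plantedStemRepeatLength = 20L, minOverhang = 5L,
                      rrnaLength = 2000L) {
  cfg <- list(seed = as.integer(seed), nChroms = as.integer(nChroms),
              chromLength = as.integer(chromLength),
              nGenesPerChrom = as.integer(nGenesPerChrom),
              exonsPerGene = as.integer(exonsPerGene),
              nCircPerCategory = as.integer(nCircPerCategory),
              readLength = as.integer(readLength),
              nJunctionReadsPerTranslated = as.integer(nJunctionReadsPerTranslated),
              nDecoyReads = as.integer(nDecoyReads),
              plantedStemRepeatLength = as.integer(plantedStemRepeatLength),
              minOverhang = as.integer(minOverhang),
              rrnaLength = as.integer(rrnaLength))
  stopifnot(cfg$nChroms >= 1L, cfg$chromLength >= 10000L,
            cfg$nGenesPerChrom >= 1L, cfg$nCircPerCategory >= 1L,
            cfg$readLength >= 10L, cfg$minOverhang >= 1L)
  if (cfg$readLength >= 60L) {
    stop("readLength must be below the shortest simulated circRNA (60 nt)")
  }
  if (cfg$nJunctionReadsPerTranslated < 3L) {
    warning("fewer than 3 junction reads per translated circRNA: ",
            "planted truth is unreachable at the default threshold")
  }
  class(cfg) <- "circkit_sim_config"
  cfg
}

## Internal: random DNA string of length n.
randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a genome and gene annotation
#'
#' Lays out `nGenesPerChrom` multi-exon genes per chromosome, separated by
#' wide intergenic gaps, over a random nucleotide sequence; an unannotated
#' `rRNA` contig is appended for the subtraction filter. Exon and intron
#' widths are drawn within fixed bounds so that every junction category is
#' geometrically realizable.
#'
#' @param cfg a [simConfig()].
#' @return list with `genome` (`DNAStringSet`, includes the rRNA contig),
#'   `annot` ([CircAnnotation-class]), and `truth` (data.frame of every
#'   exon/intron/intergenic interval, BED convention).
#' @export
simulateGenomeAnnotation <- function(cfg) {
  set.seed(cfg$seed)
  chroms <- paste0("chr", seq_len(cfg$nChroms))
  genome <- DNAStringSet(vapply(chroms, function(x) randomDna(cfg$chromLength), ""))
  names(genome) <- chroms
  rrna <- DNAStringSet(randomDna(cfg$rrnaLength))
  names(rrna) <- "rRNA"

  margin <- 1500L
  gap <- 2200L
  exon_rows <- list(); gene_rows <- list()
  for (ci in seq_along(chroms)) {
    pos <- margin + 1L
    for (gi in seq_len(cfg$nGenesPerChrom)) {
      we <- sample(250:350, cfg$exonsPerGene, replace = TRUE)
      wi <- if (cfg$exonsPerGene > 1L) {
        sample(400:600, cfg$exonsPerGene - 1L, replace = TRUE)
      } else integer(0)
      gene_id <- sprintf("g_%s_%d", chroms[ci], gi)
      tx_id <- sprintf("t_%s_%d", chroms[ci], gi)
      strand <- if (gi %% 2L == 0L) "-" else "+"
      p <- pos
      for (ei in seq_len(cfg$exonsPerGene)) {
        exon_rows[[length(exon_rows) + 1L]] <- data.frame(
          chrom = chroms[ci], start = p, end = p + we[ei] - 1L,
          strand = strand, gene_id = gene_id, transcript_id = tx_id,
          exon_index = ei)
        p <- p + we[ei]
        if (ei < cfg$exonsPerGene) p <- p + wi[ei]
      }
      gene_end <- p - 1L
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        chrom = chroms[ci], start = pos, end = gene_end, strand = strand,
        gene_id = gene_id)
      pos <- gene_end + 1L + gap
    }
    if (pos - gap + margin - 1L > cfg$chromLength) {
      stop("infeasible geometry: genes do not fit on ", chroms[ci],
           " at chromLength ", cfg$chromLength)
    }
  }
  exdf <- do.call(rbind, exon_rows)
  gdf <- do.call(rbind, gene_rows)
  exons <- GRanges(exdf$chrom, IRanges(exdf$start, exdf$end),
                   strand = exdf$strand, gene_id = exdf$gene_id,
                   transcript_id = exdf$transcript_id,
                   exon_index = exdf$exon_index)
  genes <- GRanges(gdf$chrom, IRanges(gdf$start, gdf$end),
                   strand = gdf$strand, gene_id = gdf$gene_id)
  annot <- methods::new("CircAnnotation", genes = genes, exons = exons,
                        introns = deriveIntrons(exons))

  truth <- rbind(
    data.frame(chrom = exdf$chrom, start = exdf$start - 1L, end = exdf$end,
               type = "exon", gene_id = exdf$gene_id,
               transcript_id = exdf$transcript_id),
    {
      intr <- annotIntrons(annot)
      if (length(intr)) data.frame(
        chrom = as.character(GenomicRanges::seqnames(intr)),
        start = GenomicRanges::start(intr) - 1L,
        end = GenomicRanges::end(intr), type = "intron",
        gene_id = mcols(intr)$gene_id,
        transcript_id = mcols(intr)$transcript_id)
      else NULL
    }
  )
  list(genome = c(genome, rrna), annot = annot, truth = truth)
}

## Internal: intergenic gaps (1-based closed) per chromosome, from gene spans.
intergenicGaps <- function(annot, chromLength, chroms) {
  gaps <- list()
  genes <- annotGenes(annot)
  for (ch in chroms) {
    g <- genes[as.character(GenomicRanges::seqnames(genes)) == ch]
    g <- g[order(GenomicRanges::start(g))]
    bounds <- c(1L, as.vector(rbind(GenomicRanges::start(g) - 1L,
                                    GenomicRanges::end(g) + 1L)), chromLength)
    for (i in seq(1L, length(bounds), by = 2L)) {
      s <- bounds[i]; e <- bounds[i + 1L]
      if (e - s >= 800L) {
        gaps[[length(gaps) + 1L]] <- list(chrom = ch, start = s, end = e)
      }
    }
  }
  gaps
}

#' Simulate circRNAs of every junction category
#'
#' Constructs `nCircPerCategory` circRNAs per category by placing junction
#' boundaries inside the appropriate annotation features (with small random
#' jitter), recording the intended category as planted truth.
#' [classifyAll()] must recover the truth exactly. Translation roles are
#' assigned cyclically: `translated` (gets surviving junction reads),
#' `decoy_low` (at most 2 surviving reads), `decoy_filtered` (junction
#' reads that are also rRNA/linear-mapped and therefore subtracted).
#'
#' @param cfg a [simConfig()].
#' @param sim result of [simulateGenomeAnnotation()].
#' @return `GRanges` with metadata `circ_id`, `truth_label`, `role`.
#' @export
simulateCircRNAs <- function(cfg, sim) {
  set.seed(cfg$seed + 1L)
  if (cfg$exonsPerGene < 3L) {
    stop("categories requiring introns (intron, intron_exon) need ",
         "exonsPerGene >= 3")
  }
  annot <- sim$annot
  genes <- annotGenes(annot)
  exons <- annotExons(annot)
  introns <- annotIntrons(annot)
  chroms <- setdiff(names(sim$genome), "rRNA")
  gaps <- intergenicGaps(annot, cfg$chromLength, chroms)
  gene_ids <- mcols(genes)$gene_id
  rows <- list()
  for (cat in junctionCategories()) {
    for (k in seq_len(cfg$nCircPerCategory)) {
      jit <- function() sample(0:10, 1L)
      gi <- ((k - 1L) %% length(gene_ids)) + 1L
      gene <- genes[gi]
      ch <- as.character(GenomicRanges::seqnames(gene))
      ex <- exons[mcols(exons)$gene_id == gene_ids[gi]]
      ex <- ex[order(mcols(ex)$exon_index)]
      intr <- introns[mcols(introns)$gene_id == gene_ids[gi]]
      intr <- intr[order(GenomicRanges::start(intr))]
      span <- switch(cat,
        same_exon = {
          e <- ex[2L]
          c(GenomicRanges::start(e) + 5L + jit(), GenomicRanges::end(e) - 5L - jit())
        },
        different_exon = c(GenomicRanges::start(ex[1L]) + 10L + jit(),
                           GenomicRanges::end(ex[length(ex)]) - 10L - jit()),
        intron_exon = c(GenomicRanges::start(ex[1L]) + 10L + jit(),
                        GenomicRanges::end(intr[2L]) - 10L - jit()),
        intron = c(GenomicRanges::start(intr[1L]) + 10L + jit(),
                   GenomicRanges::end(intr[length(intr)]) - 10L - jit()),
        intron_intergenic = c(GenomicRanges::start(intr[length(intr)]) + 10L + jit(),
                              GenomicRanges::end(gene) + 150L + jit()),
        exon_intergenic = c(GenomicRanges::start(ex[length(ex)]) + 10L + jit(),
                            GenomicRanges::end(gene) + 120L + jit()),
        intergenic = {
          gp <- gaps[[((k - 1L) %% length(gaps)) + 1L]]
          ch <- gp$chrom
          s <- gp$start + 300L + jit()
          c(s, s + 150L + jit())
        })
      if (cat == "intergenic") {
        gp <- gaps[[((k - 1L) %% length(gaps)) + 1L]]
        ch <- gp$chrom
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = span[1L], end = span[2L],
        strand = if (length(rows) %% 2L == 0L) "+" else "-",
        circ_id = sprintf("circ_%s_%d", cat, k), truth_label = cat)
    }
  }
  df <- do.call(rbind, rows)
  roles <- c("translated", "decoy_low", "decoy_filtered")
  df$role <- roles[(seq_len(nrow(df)) - 1L) %% 3L + 1L]
  circs <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand,
                   circ_id = df$circ_id, truth_label = df$truth_label,
                   role = df$role)
  names(circs) <- df$circ_id
  stopifnot(all(GenomicRanges::width(circs) >= 60L),
            all(GenomicRanges::start(circs) >= 1L),
            all(GenomicRanges::end(circs) <= cfg$chromLength))
  circs
}

#' Plant a reverse-complement repeat in a circRNA's flanks
#'
#' Writes a random motif of the given length into the upstream flank and
#' its reverse complement into the downstream flank, so the stem-loop scan
#' has a recoverable planted pairing.
#'
#' @param genome named `DNAStringSet`.
#' @param circ single-element circRNA `GRanges`.
#' @param repeatLength motif length (>= 1).
#' @param offset distance of the motif from the circRNA boundary
#'   (default 30 nt).
#' @return the modified genome.
#' @export
plantStemRepeat <- function(genome, circ, repeatLength, offset = 30L) {
  stopifnot(length(circ) == 1L, repeatLength >= 1L)
  motif <- randomDna(repeatLength)
  ch <- as.character(GenomicRanges::seqnames(circ))
  s0 <- bedStart(circ); e0 <- bedEnd(circ)
  up_start <- s0 - offset - repeatLength   # 0-based
  down_start <- e0 + offset
  stopifnot(up_start >= 0L, down_start + repeatLength <= length(genome[[ch]]))
  x <- as.character(genome)
  s <- x[[ch]]
  substr(s, up_start + 1L, up_start + repeatLength) <- motif
  substr(s, down_start + 1L, down_start + repeatLength) <- revComp(motif)
  x[[ch]] <- s
  out <- DNAStringSet(x)
  names(out) <- names(genome)
  out
}

## Internal: SAM record table constructor.
samRecord <- function(qname, flag, rname, pos, cigar, seq) {
  data.frame(qname = qname, flag = as.integer(flag), rname = rname,
             pos = as.integer(pos), cigar = cigar, seq = seq)
}

#' Write SAM records with a header
#'
#' @param records data.frame with columns `qname`, `flag`, `rname`, `pos`,
#'   `cigar`, `seq` (may have zero rows).
#' @param refLengths named integer vector for the `@SQ` header lines.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSamFile <- function(records, refLengths, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(refLengths),
                      as.integer(refLengths)))
  body <- if (nrow(records)) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
            records$qname, records$flag, records$rname, records$pos,
            ifelse(bitwAnd(records$flag, 4L) == 0L, 60L, 0L),
            records$cigar, records$seq)
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Simulate ribosome-profiling reads and their three alignment files
#'
#' Plants junction-spanning reads on the doubled references according to
#' each circRNA's role: `translated` circRNAs receive
#' `nJunctionReadsPerTranslated` surviving junction reads; `decoy_low`
#' circRNAs at most 2; `decoy_filtered` circRNAs receive 4 junction reads
#' whose ids are also mapped in the rRNA or linear SAM and are therefore
#' removed by the subtraction filter. Background reads map to the rRNA
#' contig or the linear genome only. All CIGARs are pure match; read
#' starts are drawn so each junction read satisfies the configured
#' overhang on both sides.
#'
#' @param cfg a [simConfig()].
#' @param circs `GRanges` from [simulateCircRNAs()].
#' @param genome named `DNAStringSet` including the `rRNA` contig.
#' @return list with `read_ids` (the read universe), SAM record tables
#'   `rrna`, `linear`, `junction` (see [writeSamFile()]), `refs` (the
#'   [JunctionRefSet-class]), and `truth_translated` (circ ids planted as
#'   translated).
#' @export
simulateRiboReads <- function(cfg, circs, genome) {
  set.seed(cfg$seed + 2L)
  refs <- buildJunctionRefs(circs, genome)
  L <- junctionOffset(refs)
  rl <- cfg$readLength
  ov <- cfg$minOverhang
  ids <- names(junctionSeqs(refs))
  roles <- stats::setNames(mcols(circs)$role, mcols(circs)$circ_id)

  jrec <- list(); rrec <- list(); lrec <- list()
  chroms <- setdiff(names(genome), "rRNA")
  junctionReadsFor <- function(id, n, prefix) {
    if (n == 0L) return(NULL)
    lo <- L[[id]] + ov - rl
    hi <- L[[id]] - ov
    starts <- sample(seq(lo, hi), n, replace = TRUE)  # 0-based on doubled ref
    seqs <- vapply(starts, function(s)
      as.character(subseq(junctionSeqs(refs)[[id]], s + 1L, s + rl)), "")
    samRecord(sprintf("%s_%s_%d", prefix, id, seq_len(n)), 0L, id,
              starts + 1L, paste0(rl, "M"), seqs)
  }
  low_counts <- c(0L, 1L, 2L)
  li <- 0L
  for (id in ids) {
    role <- roles[[id]]
    if (role == "translated") {
      rec <- junctionReadsFor(id, cfg$nJunctionReadsPerTranslated, "rj")
      jrec[[length(jrec) + 1L]] <- rec
      # realistic: these reads failed to align linearly (flag 4 records)
      lrec[[length(lrec) + 1L]] <- samRecord(rec$qname, 4L, "*", 0L, "*", rec$seq)
    } else if (role == "decoy_low") {
      li <- li + 1L
      n <- low_counts[(li - 1L) %% 3L + 1L]
      jrec[[length(jrec) + 1L]] <- junctionReadsFor(id, n, "rl")
      # plus non-spanning alignments that must never be counted
      jrec[[length(jrec) + 1L]] <- samRecord(
        sprintf("rn_%s_%d", id, 1:2), 0L, id, 3L, paste0(rl, "M"),
        vapply(1:2, function(i)
          as.character(subseq(junctionSeqs(refs)[[id]], 3L, 2L + rl)), ""))
    } else { # decoy_filtered: spanning reads that the filter removes
      rec <- junctionReadsFor(id, 4L, "rf")
      jrec[[length(jrec) + 1L]] <- rec
      half <- seq_len(nrow(rec)) %% 2L == 0L
      if (any(half)) {
        rrec[[length(rrec) + 1L]] <- samRecord(
          rec$qname[half], 0L, "rRNA",
          sample(seq_len(cfg$rrnaLength - rl), sum(half), replace = TRUE),
          paste0(rl, "M"), rec$seq[half])
      }
      if (any(!half)) {
        lrec[[length(lrec) + 1L]] <- samRecord(
          rec$qname[!half], 0L, sample(chroms, sum(!half), replace = TRUE),
          sample(seq_len(cfg$chromLength - rl), sum(!half), replace = TRUE),
          paste0(rl, "M"), rec$seq[!half])
      }
    }
  }
  # background reads: never on the junction references
  nbg <- cfg$nDecoyReads
  if (nbg > 0L) {
    n_rrna <- nbg %/% 2L
    n_lin <- nbg - n_rrna
    if (n_rrna > 0L) {
      rrec[[length(rrec) + 1L]] <- samRecord(
        sprintf("bg_rrna_%d", seq_len(n_rrna)), 0L, "rRNA",
        sample(seq_len(cfg$rrnaLength - rl), n_rrna, replace = TRUE),
        paste0(rl, "M"), strrep("A", rl))
    }
    if (n_lin > 0L) {
      lrec[[length(lrec) + 1L]] <- samRecord(
        sprintf("bg_lin_%d", seq_len(n_lin)), 0L,
        sample(chroms, n_lin, replace = TRUE),
        sample(seq_len(cfg$chromLength - rl), n_lin, replace = TRUE),
        paste0(rl, "M"), strrep("A", rl))
    }
  }
  bindRecords <- function(x) {
    x <- Filter(Negate(is.null), x)
    if (length(x)) do.call(rbind, x) else
      samRecord(character(0), integer(0), character(0), integer(0),
                character(0), character(0))
  }
  junction <- bindRecords(jrec)
  rrna <- bindRecords(rrec)
  linear <- bindRecords(lrec)
  read_ids <- unique(c(junction$qname, rrna$qname, linear$qname))
  list(read_ids = read_ids, rrna = rrna, linear = linear,
       junction = junction, refs = refs,
       truth_translated = ids[roles[ids] == "translated"])
}

#' Generate a complete synthetic fixture set on disk
#'
#' Runs the three simulation stages and writes `genome.fa`,
#' `annotation.gtf`, `circ.bed`, `reads.ids`, `rrna.sam`, `linear.sam`,
#' `junction.sam` and `truth.csv` to `outDir`. A reverse-complement stem
#' repeat is planted in the flanks of each intergenic-category circRNA
#' before reads are drawn, so the stem-loop scan has recoverable signal.
#'
#' @param cfg a [simConfig()].
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the in-memory objects (`genome`, `annot`,
#'   `circs`, `reads`) and the written file paths.
#' @export
simulateCircData <- function(cfg, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateGenomeAnnotation(cfg)
  circs <- simulateCircRNAs(cfg, sim)
  genome <- sim$genome
  if (cfg$plantedStemRepeatLength > 0L) {
    set.seed(cfg$seed + 3L)
    for (i in which(mcols(circs)$truth_label == "intergenic")) {
      genome <- plantStemRepeat(genome, circs[i], cfg$plantedStemRepeatLength)
    }
  }
  reads <- simulateRiboReads(cfg, circs, genome)

  paths <- list(
    genome = file.path(outDir, "genome.fa"),
    gtf = file.path(outDir, "annotation.gtf"),
    bed = file.path(outDir, "circ.bed"),
    read_ids = file.path(outDir, "reads.ids"),
    rrna_sam = file.path(outDir, "rrna.sam"),
    linear_sam = file.path(outDir, "linear.sam"),
    junction_sam = file.path(outDir, "junction.sam"),
    truth = file.path(outDir, "truth.csv")
  )
  writeGenomeFasta(genome, paths$genome)
  writeAnnotationGtf(sim$annot, paths$gtf)
  writeCircBed(circs, paths$bed)
  writeLines(sort(reads$read_ids), paths$read_ids)
  writeSamFile(reads$rrna, c(rRNA = cfg$rrnaLength), paths$rrna_sam)
  chromLens <- stats::setNames(Biostrings::width(genome), names(genome))
  writeSamFile(reads$linear, chromLens[setdiff(names(genome), "rRNA")],
               paths$linear_sam)
  writeSamFile(reads$junction,
               stats::setNames(Biostrings::width(junctionSeqs(reads$refs)),
                               names(junctionSeqs(reads$refs))),
               paths$junction_sam)
  writeCsv(data.frame(circ_id = mcols(circs)$circ_id,
                      truth_label = mcols(circs)$truth_label,
                      role = mcols(circs)$role,
                      translated = mcols(circs)$role == "translated"),
           paths$truth)
  invisible(list(genome = genome, annot = sim$annot, circs = circs,
                 reads = reads, paths = paths, truth = sim$truth))
}
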