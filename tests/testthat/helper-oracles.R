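# Independent oracles used across the suite. Each is a deliberately plain
# re-derivation of the quantity it checks, sharing no code with the package.

# Affine-gap local alignment score by a plain three-matrix DP
# (gap of length k costs |open| + k*|extend|).
gotohLocalScore <- function(a, b, match = 2, mismatch = -3,
                            open = -5, extend = -2) {
  n <- nchar(a); m <- nchar(b)
  if (n == 0 || m == 0) return(0)
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] + open + extend, E[i, j - 1] + extend)
      F[i, j] <- max(H[i - 1, j] + open + extend, F[i - 1, j] + extend)
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Reference-consumed CIGAR length by per-op accumulation.
cigarRefLenOracle <- function(cigar) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  total <- 0L
  for (op in ops) {
    n <- as.integer(sub("[A-Z=]$", "", op))
    type <- sub("^[0-9]+", "", op)
    if (type %in% c("M", "D", "N", "=", "X")) total <- total + n
  }
  total
}

# Circular (wraparound) substring of width w starting at 0-based pos.
circularSubstrOracle <- function(seq, pos, w) {
  L <- nchar(seq)
  idx <- ((pos + seq_len(w) - 1L) %% L) + 1L
  paste(strsplit(seq, "")[[1]][idx], collapse = "")
}

# Junction read counts by a brute-force scan over every alignment row.
bruteJunctionCounts <- function(ids, offsets, aln, keptIds, minOverhang) {
  counts <- stats::setNames(integer(length(ids)), ids)
  for (id in ids) {
    spanning <- character(0)
    for (r in seq_len(nrow(aln))) {
      if (!isTRUE(aln$is_mapped[r])) next
      if (!identical(aln$ref_name[r], id)) next
      if (!aln$read_id[r] %in% keptIds) next
      off <- offsets[[id]]
      if (aln$ref_start[r] <= off - minOverhang &&
          aln$ref_end[r] >= off + minOverhang) {
        spanning <- union(spanning, aln$read_id[r])
      }
    }
    counts[[id]] <- length(spanning)
  }
  counts
}

# All codon start positions on a circle by scanning the doubled string.
codonPosOracle <- function(circSeq, codons) {
  L <- nchar(circSeq)
  d <- strsplit(paste0(circSeq, circSeq), "")[[1]]
  pos <- integer(0)
  for (p in seq_len(L) - 1L) {
    tri <- paste(d[p + 1:3], collapse = "")
    if (tri %in% codons) pos <- c(pos, p)
  }
  pos
}

randomDnaStr <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
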