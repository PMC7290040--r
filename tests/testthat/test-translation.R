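test_that("subtraction filter removes mapped reads with rRNA precedence", {
  res <- subtractMappedReads(c("r1", "r2", "r3"),
                             alnDf("r1", "rRNA", 0, 30),
                             alnDf("r2", "chr1", 0, 30))
  expect_equal(res$kept_ids, "r3")
  expect_equal(res$removed_rrna, 1L)
  expect_equal(res$removed_linear, 1L)

  both <- subtractMappedReads("r1", alnDf("r1", "rRNA", 0, 30),
                              alnDf("r1", "chr1", 0, 30))
  expect_equal(both$removed_rrna, 1L)
  expect_equal(both$removed_linear, 0L)

  none <- subtractMappedReads(c("a", "b"), alnDf(character(0), character(0),
    integer(0), integer(0)), NULL)
  expect_setequal(none$kept_ids, c("a", "b"))

  # unmapped records must not subtract, unknown ids are ignored with a note
  unm <- alnDf("a", NA, NA, NA, is_mapped = FALSE, flag = 4L)
  expect_setequal(subtractMappedReads(c("a", "b"), unm, NULL)$kept_ids,
                  c("a", "b"))
  expect_message(subtractMappedReads("a", alnDf("zz", "rRNA", 0, 30), NULL),
                 "not in the read universe")
})

test_that("junction spanning is a two-sided overhang inequality", {
  expect_true(spansJunction(90L, 110L, 100L, 5L))
  expect_false(spansJunction(96L, 110L, 100L, 5L))  # only 4 nt on the left
  expect_false(spansJunction(90L, 104L, 100L, 5L))  # only 4 nt on the right
  expect_true(spansJunction(95L, 105L, 100L, 5L))   # exactly 5 both sides
  expect_true(spansJunction(99L, 101L, 100L, 1L))   # minimal 1-nt overhang
  expect_error(spansJunction(0L, 10L, 5L, 0L), "minOverhang")
})

mkRefs <- function(ids, L) {
  seqs <- Biostrings::DNAStringSet(vapply(L, function(l)
    strrep("ACGT", l / 2)[1], ""))
  seqs <- Biostrings::subseq(seqs, 1, 2 * L)
  names(seqs) <- ids
  circs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, L),
                                  circ_id = ids)
  names(circs) <- ids
  methods::new("JunctionRefSet", seqs = seqs, offset = as.integer(L),
               circ = circs)
}

test_that("junction read counting is per distinct kept read", {
  refs <- mkRefs("circA", 100L)
  kept <- c("r1", "r2", "r3", "r5")
  aln <- rbind(
    alnDf("r1", "circA", 80, 110),   # spans
    alnDf("r2", "circA", 90, 120),   # spans
    alnDf("r2", "circA", 94, 124),   # same read again: counts once
    alnDf("r3", "circA", 0, 30),     # does not span
    alnDf("r4", "circA", 85, 115),   # spans but filtered out
    alnDf("r5", "circA", 96, 126))   # 4 nt left overhang: no
  counts <- countJunctionReads(refs, aln, kept, minOverhang = 5L)
  expect_equal(counts$junction_reads, 2L)
  # brute-force (read x alignment) scan agrees
  oracle <- bruteJunctionCounts("circA", c(circA = 100L), aln, kept, 5L)
  expect_equal(counts$junction_reads, unname(oracle))
  expect_message(
    countJunctionReads(refs, alnDf("r1", "nope", 80, 110), kept), "unknown")
})

test_that("count oracle equivalence holds on random alignment sets", {
  set.seed(31)
  ids <- paste0("c", 1:6)
  L <- sample(seq(60, 160, by = 4), 6)  # period-4 repeat keeps halves identical
  refs <- mkRefs(ids, L)
  offs <- stats::setNames(as.integer(L), ids)
  for (rep in 1:5) {
    n <- 80
    aln <- alnDf(sample(paste0("r", 1:30), n, replace = TRUE),
                 sample(ids, n, replace = TRUE),
                 rs <- sample(0:250, n, replace = TRUE), rs + 30L)
    aln$is_mapped <- sample(c(TRUE, TRUE, TRUE, FALSE), n, replace = TRUE)
    kept <- sample(paste0("r", 1:30), 18)
    got <- countJunctionReads(refs, aln, kept, minOverhang = 5L)
    oracle <- bruteJunctionCounts(ids, offs, aln, kept, 5L)
    expect_equal(stats::setNames(got$junction_reads, got$circ_id), oracle)
  }
})

test_that("adding spanning evidence never decreases a count", {
  refs <- mkRefs("circA", 100L)
  kept <- paste0("r", 1:10)
  aln <- alnDf(paste0("r", 1:4), "circA", 90, 120)
  base <- countJunctionReads(refs, aln, kept)$junction_reads
  more <- countJunctionReads(refs, rbind(aln, alnDf("r9", "circA", 85, 115)),
                             kept)$junction_reads
  expect_gte(more, base)
  fewer <- countJunctionReads(refs, aln, setdiff(kept, "r1"))$junction_reads
  expect_lte(fewer, base)
})

test_that("translation is called at the read-count threshold", {
  counts <- data.frame(circ_id = c("A", "B", "C"),
                       junction_reads = c(3L, 2L, 0L))
  calls <- callTranslation(counts)
  expect_equal(calls$translated, c(TRUE, FALSE, FALSE))
  expect_true(callTranslation(data.frame(circ_id = "A",
    junction_reads = 100L))$translated)
  expect_false(callTranslation(data.frame(circ_id = "A",
    junction_reads = 0L), threshold = 1L)$translated)
  expect_error(callTranslation(counts, threshold = 0L), "threshold")
})

test_that("the translated set shrinks monotonically as threshold rises", {
  set.seed(9)
  counts <- data.frame(circ_id = paste0("c", 1:30),
                       junction_reads = rpois(30, 3))
  prev <- NULL
  for (th in 1:8) {
    cur <- callTranslation(counts, th)$circ_id[
      callTranslation(counts, th)$translated]
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("mapping table sorts by count then id and round trips via CSV", {
  calls <- callTranslation(data.frame(
    circ_id = c("B", "A", "C", "D"), junction_reads = c(3L, 3L, 0L, 7L)))
  f <- tempfile(fileext = ".csv")
  tab <- mappingTable(calls, f)
  expect_equal(tab$circ_id, c("D", "A", "B", "C"))  # ties lexicographic
  back <- utils::read.csv(f)
  expect_equal(back$circ_id, tab$circ_id)
  expect_equal(back$junction_reads, tab$junction_reads)

  empty <- mappingTable(callTranslation(data.frame(
    circ_id = character(0), junction_reads = integer(0))), f)
  expect_equal(nrow(empty), 0L)
  expect_equal(nrow(utils::read.csv(f)), 0L)  # header-only file
  expect_error(mappingTable(data.frame(circ_id = "A")), "columns")
})
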