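test_that("flank extraction truncates at chromosome ends", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "AAACGTTTGG"))
  fl <- extractFlanks(circGR("chr1", 3, 6, "+"), genome, flank = 3L)
  expect_equal(fl$upstream, "AAA")
  expect_equal(fl$downstream, "TTG")
  expect_message(
    fl2 <- extractFlanks(circGR("chr1", 1, 6, "+"), genome, flank = 5L),
    "truncated")
  expect_equal(fl2$upstream, "A")
  expect_equal(fl2$up_len, 1L)
  expect_error(extractFlanks(circGR("chr1", 3, 6), genome, flank = 0L),
               "flank")
})

test_that("reverse complement follows base-pairing rules", {
  expect_equal(revComp("ACGT"), "ACGT")  # palindrome
  expect_equal(revComp("AAGC"), "GCTT")
  expect_equal(revComp(""), "")
  expect_equal(revComp("ANT"), "ANT")
  expect_error(revComp("ACGU"), "outside")
})

test_that("local alignment reproduces known scores and handles empties", {
  perfect <- localAlign("ACGT", "ACGT")
  expect_equal(perfect$score, 8)
  expect_equal(perfect$identity, 1.0)
  expect_equal(localAlign("AAAA", "CCCC")$score, 0)
  hit <- localAlign("ACGTACGT", "CGTA")
  expect_equal(hit$score, 8)  # exact 4-mer match
  expect_equal(hit$b_start, 0L)
  expect_equal(hit$b_end, 4L)
  expect_equal(localAlign("", "ACGT")$score, 0)
  expect_equal(localAlign("ACGT", "")$aligned_a, "")
  expect_error(localAlign("A", "A", match = 0L), "match")
  expect_error(localAlign("A", "A", mismatch = 1L), "penalties")
})

test_that("scores equal an independent affine-gap DP on random short pairs", {
  set.seed(57)
  for (rep in 1:150) {
    a <- randomDnaStr(sample(1:8, 1))
    b <- randomDnaStr(sample(1:8, 1))
    expect_equal(localAlign(a, b)$score, gotohLocalScore(a, b),
                 label = paste(a, b))
  }
})

test_that("local score is symmetric and strand-invariant", {
  set.seed(71)
  for (rep in 1:25) {
    a <- randomDnaStr(sample(5:30, 1))
    b <- randomDnaStr(sample(5:30, 1))
    s <- localAlign(a, b)$score
    expect_equal(localAlign(b, a)$score, s)
    expect_equal(localAlign(revComp(a), revComp(b))$score, s)
  }
})

test_that("appending sequence never decreases the optimal local score", {
  set.seed(83)
  for (rep in 1:20) {
    a <- randomDnaStr(sample(5:20, 1))
    b <- randomDnaStr(sample(5:20, 1))
    s <- localAlign(a, b)$score
    expect_gte(localAlign(paste0(a, randomDnaStr(4)), b)$score, s)
    expect_gte(localAlign(a, paste0(randomDnaStr(4), b))$score, s)
  }
})

test_that("planted reverse-complement repeats are recovered across seeds", {
  k <- 20L
  for (seed in 1:20) {
    set.seed(seed)
    motif <- randomDnaStr(k)
    up <- paste0(randomDnaStr(60), motif, randomDnaStr(30))
    down <- paste0(randomDnaStr(30), revComp(motif), randomDnaStr(60))
    hit <- localAlign(revComp(up), down)
    expect_gte(hit$score, 2 * k)  # at least the perfect planted pairing
    # the planted span aligns at identity 1.0: a >= k run of matches
    cols_a <- strsplit(hit$aligned_a, "")[[1]]
    cols_b <- strsplit(hit$aligned_b, "")[[1]]
    runs <- rle(cols_a == cols_b)
    expect_gte(max(runs$lengths[runs$values]), k)
  }
})

test_that("random flanks score below a planted repeat", {
  set.seed(97)
  planted_scores <- numeric(20)
  for (i in 1:20) {
    motif <- randomDnaStr(20)
    up <- paste0(randomDnaStr(90), motif, randomDnaStr(90))
    down <- paste0(randomDnaStr(90), revComp(motif), randomDnaStr(90))
    planted_scores[i] <- localAlign(revComp(up), down)$score
  }
  null_scores <- vapply(1:100, function(i)
    localAlign(randomDnaStr(200), randomDnaStr(200))$score, 0)
  expect_gte(mean(null_scores < min(planted_scores)), 0.95)
})

test_that("stem scan reports per-circRNA rows with flank coordinates", {
  set.seed(7)
  motif <- randomDnaStr(20)
  chrseq <- paste0(randomDnaStr(100), motif, randomDnaStr(80),
                   strrep("G", 100),  # the circle
                   randomDnaStr(80), revComp(motif), randomDnaStr(100))
  genome <- Biostrings::DNAStringSet(c(chr1 = chrseq))
  circs <- c(circGR("chr1", 200, 300, id = "planted"),
             circGR("chr1", 0, 60, id = "edge"))
  res <- stemRingScan(circs, genome, flank = 200L)
  expect_equal(res$circ_id, c("planted", "edge"))  # input order
  expect_gte(res$score[1], 40)
  # the planted 20-mer aligns perfectly inside the hit
  runs <- rle(strsplit(res$aligned_up[1], "")[[1]] ==
              strsplit(res$aligned_down[1], "")[[1]])
  expect_gte(max(runs$lengths[runs$values]), 20L)
  expect_gte(res$identity[1], 0.9)
  # the hit covers the planted motif: upstream flank is [0,200) = chrseq[0:200)
  expect_lte(res$up_aln_start[1], 100L)
  expect_gte(res$up_aln_end[1], 120L)
  expect_true(all(res$up_aln_start >= 0 & res$up_aln_end <= 200))
  f <- tempfile(fileext = ".csv")
  stemRingScan(circs, genome, flank = 200L, path = f)
  expect_equal(utils::read.csv(f)$circ_id, c("planted", "edge"))
})

test_that("a circRNA with an empty upstream flank yields a score-0 row", {
  genome <- Biostrings::DNAStringSet(c(chr1 = randomDnaStr(120)))
  res <- suppressMessages(
    stemRingScan(circGR("chr1", 0, 60, id = "atStart"), genome, flank = 50L))
  expect_equal(nrow(res), 1L)
  expect_equal(res$score, 0)
  expect_equal(res$aligned_up, "")
})
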