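test_that("boundary positions resolve to exon, intron or intergenic", {
  annot <- tinyAnnotation()
  b <- locateBoundary(rep("chr1", 3), c(150L, 250L, 5000L), annot)
  expect_equal(b$context, c("exon", "intron", "intergenic"))
  expect_equal(b$gene_id, c("geneA", "geneA", NA))
  expect_equal(b$transcript_id[1], "txA")
  expect_equal(b$exon_index[1], 1L)
  expect_message(locateBoundary("chrZ", 10L, annot), "absent")
  expect_equal(locateBoundary("chrZ", 10L, annot)$context, "intergenic")
})

test_that("exon beats intron and richer transcripts win ties", {
  # two transcripts disagree: t_big (3 exons) calls the point exonic,
  # t_small (1 exon elsewhere) leaves it intronic
  exons <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(101, 301, 501, 101), c(200, 400, 600, 600)),
    strand = "+",
    gene_id = "gX",
    transcript_id = c("t_big", "t_big", "t_big", "t_small"),
    exon_index = c(1L, 2L, 3L, 1L))
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 600),
                                  strand = "+", gene_id = "gX")
  annot <- methods::new("CircAnnotation", genes = genes, exons = exons,
                        introns = circkit:::deriveIntrons(exons))
  b <- locateBoundary("chr1", 250L, annot)
  expect_equal(b$context, "exon")        # t_small covers 250; exon wins
  expect_equal(b$transcript_id, "t_small")
  b2 <- locateBoundary("chr1", 150L, annot)
  expect_equal(b2$transcript_id, "t_big")  # both cover: most exons wins
})

test_that("the seven categories arise from the boundary-context pairs", {
  annot <- tinyAnnotation()
  # BED-convention coordinates chosen against the tiny annotation layout
  cases <- list(
    list(120, 180, "same_exon"),        # both in exon 1 of txA
    list(120, 550, "different_exon"),   # exon 1 -> exon 3
    list(120, 250, "intron_exon"),      # exon 1 -> intron 1
    list(220, 450, "intron"),           # intron 1 -> intron 2
    list(420, 1000, "intron_intergenic"),
    list(520, 1000, "exon_intergenic"),
    list(700, 1000, "intergenic"))
  for (cs in cases) {
    circ <- circGR("chr1", cs[[1]], cs[[2]])
    expect_equal(classifyCirc(circ, annot), cs[[3]],
                 label = sprintf("[%d,%d)", cs[[1]], cs[[2]]))
  }
  labels <- vapply(cases, `[[`, "", 3)
  expect_setequal(labels, junctionCategories())
  expect_equal(length(junctionCategories()), 7L)
})

test_that("category labels are unordered in the boundary pair", {
  annot <- tinyAnnotation()
  # exon start / intergenic end vs intergenic start / exon end
  a <- classifyCirc(circGR("chr1", 520, 1000), annot)
  b <- classifyCirc(circGR("chr1", 1000, 2050), annot)
  expect_equal(a, "exon_intergenic")
  expect_equal(b, "exon_intergenic")
  # intron start / exon end vs exon start / intron end
  expect_equal(classifyCirc(circGR("chr1", 250, 350), annot), "intron_exon")
  expect_equal(classifyCirc(circGR("chr1", 120, 250), annot), "intron_exon")
})

test_that("two ends in exons of different genes are different_exon", {
  annot <- tinyAnnotation()
  tab <- classifyAll(circGR("chr1", 150, 2050), annot)
  expect_equal(tab$label, "different_exon")
  expect_equal(tab$gene_id_start, "geneA")
  expect_equal(tab$gene_id_end, "geneB")
})

test_that("classification is total and order-independent", {
  annot <- tinyAnnotation()
  set.seed(77)
  starts <- sample(0:2800, 40)
  circs <- do.call(c, lapply(seq_along(starts), function(i)
    circGR("chr1", starts[i], starts[i] + 120L, id = paste0("c", i))))
  tab1 <- classifyAll(circs, annot)
  expect_equal(nrow(tab1), 40L)
  perm <- sample(40)
  tab2 <- classifyAll(circs[perm], annot)
  m1 <- stats::setNames(tab1$label, tab1$circ_id)
  m2 <- stats::setNames(tab2$label, tab2$circ_id)
  expect_equal(m2[names(m1)], m1)
  # duplicated coordinates with distinct ids classify identically
  dup <- c(circGR("chr1", 120, 180, id = "d1"), circGR("chr1", 120, 180, id = "d2"))
  expect_equal(unique(classifyAll(dup, annot)$label), "same_exon")
})

test_that("classification density conserves totals and bins half-open", {
  annot <- tinyAnnotation()
  set.seed(13)
  starts <- sample(0:2500, 25)
  circs <- do.call(c, lapply(seq_along(starts), function(i)
    circGR("chr1", starts[i], starts[i] + 100L, id = paste0("c", i))))
  tab <- classifyAll(circs, annot)
  for (nb in c(1L, 3L, 10L)) {
    dens <- classificationDensity(tab, c(chr1 = 3000L), nb)
    expect_equal(sum(dens$count), 25L)
  }
  # midpoint exactly on an interior edge goes to the right-hand bin
  one <- classifyAll(circGR("chr1", 1400, 1600), annot)  # midpoint 1500
  dens <- classificationDensity(one, c(chr1 = 3000L), 2L)
  expect_equal(dens$bin_start, 1500)
  expect_error(classificationDensity(tab, c(chrZ = 100L), 2L), "absent")

  # brute-force binning oracle on a 2-label x 2-chrom grid
  tab2 <- rbind(tab, transform(tab, chrom = "chr2"))
  tab2$circ_id <- paste0(tab2$circ_id, "_", seq_len(nrow(tab2)))
  dens2 <- classificationDensity(tab2, c(chr1 = 3000L, chr2 = 3000L), 4L)
  expect_equal(sum(dens2$count), nrow(tab2))
  brute <- 0L
  for (r in seq_len(nrow(tab2))) {
    mid <- floor((tab2$start[r] + tab2$end[r]) / 2)
    bin <- min(floor(mid / 750), 3)
    cell <- dens2[dens2$chrom == tab2$chrom[r] &
                  dens2$bin_start == floor(bin * 750) &
                  dens2$label == tab2$label[r], ]
    brute <- brute + (nrow(cell) == 1L)
  }
  expect_equal(brute, nrow(tab2))
})
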