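# Gene-model loading and splice-region classification.

gtf_line <- function(chrom, feat, start, end, strand, gene, tx, biotype) {
  paste(chrom, "src", feat, start, end, ".", strand, ".",
        sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                gene, tx, biotype), sep = "\t")
}

test_that("GTF loading filters by biotype and sorts exons", {
  path <- tempfile(fileext = ".gtf")
  writeLines(c(
    gtf_line("chr1", "exon", 1001, 1100, "+", "gA", "gA.t1", "protein_coding"),
    gtf_line("chr1", "exon", 1501, 1600, "+", "gA", "gA.t1", "protein_coding"),
    gtf_line("chr1", "exon", 1201, 1300, "+", "gA", "gA.t1", "protein_coding"),
    gtf_line("chr1", "exon", 5001, 5100, "-", "gB", "gB.t1", "lincRNA")
  ), path)
  models <- load_gene_models(path)
  expect_length(models, 1L)
  expect_equal(names(models), "gA")
  ex <- models$gA$transcripts[[1]]$exons
  # exons given out of order come back sorted by genomic coordinate
  expect_equal(ex[, "start"], sort(c(1000L, 1500L, 1200L)))
  expect_equal(ex[, "end"], c(1100L, 1300L, 1600L))

  # no biotype filter keeps both genes
  expect_length(load_gene_models(path, biotype_filter = NULL), 2L)
})

test_that("malformed GTF lines are reported with their line number", {
  path <- tempfile(fileext = ".gtf")
  writeLines(c(
    gtf_line("chr1", "exon", 1, 100, "+", "g", "t", "protein_coding"),
    "chr1\texon\tnot-enough-fields"
  ), path)
  expect_error(load_gene_models(path), "line 2")
})

test_that("empty result warns rather than errors", {
  path <- tempfile(fileext = ".gtf")
  writeLines(gtf_line("chr1", "exon", 1, 100, "+", "g", "t", "lincRNA"), path)
  expect_warning(models <- load_gene_models(path), "biotype")
  expect_length(models, 0L)
})

test_that("BED input yields single-exon region records without structure", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tregA", "chr2\t500\t800\tregB"), path)
  models <- load_gene_models(path)
  expect_length(models, 2L)
  expect_false(models[[1]]$structure_known)
  expect_equal(models[["regA"]]$transcripts[[1]]$exons[1, ],
               c(start = 100L, end = 200L))
})

test_that("plus-strand donor and acceptor windows follow the 3+6 / 3+12 rule", {
  tx <- make_tx(c(900, 2000), c(1000, 2100))
  expect_equal(classify_region(998, tx, "+"), "donor")
  expect_equal(classify_region(1000, tx, "+"), "donor")
  expect_equal(classify_region(1006, tx, "+"), "donor")
  expect_equal(classify_region(1007, tx, "+"), "intron")
  expect_equal(classify_region(997, tx, "+"), "exon")
  expect_equal(classify_region(1988, tx, "+"), "acceptor")   # 12th intronic
  expect_equal(classify_region(1987, tx, "+"), "intron")
  expect_equal(classify_region(2002, tx, "+"), "acceptor")
  expect_equal(classify_region(2003, tx, "+"), "exon")
  expect_equal(classify_region(899, tx, "+"), "intergenic")
  expect_equal(classify_region(2101, tx, "+"), "intergenic")
  expect_error(classify_region(-5, tx, "+"), "off the chromosome")
})

test_that("region classification partitions the transcript span", {
  tx <- make_tx(c(101, 301, 601), c(200, 400, 700))
  classes <- vapply(101:700, classify_region, character(1),
                    transcript = tx, strand = "+")
  expect_true(all(classes %in% c("donor", "acceptor", "exon", "intron")))
  # each intron is long enough: window sizes are exactly 3+6 and 3+12
  expect_equal(sum(classes == "donor"), 2L * 9L)
  expect_equal(sum(classes == "acceptor"), 2L * 15L)
})

test_that("minus-strand classification mirrors the plus-strand rule", {
  # mirror oracle: reflect coordinates around the span and classify "+"
  set.seed(11)
  for (rep in 1:5) {
    n_ex <- sample(2:4, 1)
    lens <- sample(30:80, n_ex, replace = TRUE)
    gaps <- sample(40:90, n_ex - 1, replace = TRUE)
    starts <- 50 + cumsum(c(0, head(lens, -1) + gaps))
    ends <- starts + lens - 1
    tx_minus <- make_tx(starts, ends)
    L <- max(ends) + 50
    # reflected transcript: position p -> L - p + 1
    tx_plus <- make_tx(rev(L - ends + 1), rev(L - starts + 1))
    for (pos in seq(min(starts), max(ends))) {
      expect_equal(classify_region(pos, tx_minus, "-"),
                   classify_region(L - pos + 1, tx_plus, "+"),
                   info = paste("pos", pos, "rep", rep))
    }
  }
})

test_that("intron_context reports transcript-sense distances", {
  tx <- make_tx(c(101, 301), c(200, 400))
  ic <- intron_context(201, tx, "+")
  expect_equal(ic$d5, 1L)
  expect_equal(ic$d3, 100L)
  ic <- intron_context(300, tx, "+")
  expect_equal(ic$d3, 1L)
  # minus strand: 5' and 3' swap
  ic <- intron_context(300, tx, "-")
  expect_equal(ic$d5, 1L)
  expect_equal(intron_context(300, tx, "-")$d3, 100L)
  expect_null(intron_context(150, tx, "+"))   # exonic
  expect_null(intron_context(500, tx, "+"))   # outside
})

test_that("variant-level classification takes the most splice-proximal class", {
  m1 <- make_model("chr1", "+", make_tx(c(101, 301), c(200, 400)), "g1")
  m2 <- make_model("chr1", "+", make_tx(c(101, 351), c(250, 400)), "g2")
  models <- list(g1 = m1, g2 = m2)
  # 199 is donor for g1 (exon ends 200) but plain exon for g2
  res <- splicetree:::classify_variant_region("chr1", 199, models)
  expect_equal(res$region, "donor")
  expect_equal(nrow(res$hits), 2L)
  expect_setequal(res$hits$region, c("donor", "exon"))
})
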