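test_that("GTF coordinates convert to 0-based half-open and back", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\ttranscript_id "t1"; gene_id "g1";',
    'chr1\tsrc\texon\t301\t400\t.\t+\t.\ttranscript_id "t1"; gene_id "g1";',
    'chr1\tsrc\texon\t101\t200\t.\t-\t.\ttranscript_id "t2"; gene_id "g2";',
    'chr1\tsrc\texon\t301\t400\t.\t-\t.\ttranscript_id "t2"; gene_id "g2";'
  ), gtf)
  a <- read_annotation(gtf, source_tag = "reference")
  ch <- exon_chains(a, "t1")[["t1"]]
  expect_equal(unname(ch[1, ]), c(100, 200))
  expect_equal(unname(ch[2, ]), c(300, 400))
  ic <- intron_chains(a, "t1")[["t1"]]
  expect_equal(unname(ic[1, ]), c(200, 300))
  # minus strand: biological termini swap
  tx <- a$transcripts
  expect_equal(tx[tx$transcript_id == "t2", "tss"], 400)
  expect_equal(tx[tx$transcript_id == "t2", "tes"], 100)

  # round-trip through write_annotation
  out <- tempfile(fileext = ".gtf")
  write_annotation(a, out)
  b <- read_annotation(out)
  expect_equal(exon_chains(b), exon_chains(a))
  expect_setequal(b$transcripts$transcript_id, a$transcripts$transcript_id)
  expect_equal(b$transcripts[a$transcripts$transcript_id, "gene_id"],
               a$transcripts$gene_id)
})

test_that("writing an annotation twice is byte-stable, empty set allowed", {
  sim <- simulate_reference(sim_config(n_genes = 15), seed = 5)
  f1 <- tempfile(); f2 <- tempfile()
  write_annotation(sim$annotation, f1)
  write_annotation(sim$annotation, f2)
  expect_identical(readLines(f1), readLines(f2))
  rt <- read_annotation(f1)
  expect_equal(exon_chains(rt), exon_chains(sim$annotation))

  empty <- annotation_set(data.frame(transcript_id = character(0),
                                     chrom = character(0), strand = character(0),
                                     start = numeric(0), end = numeric(0)))
  f3 <- tempfile()
  write_annotation(empty, f3)
  expect_true(all(startsWith(readLines(f3), "#")))
})

test_that("annotation validation rejects malformed transcripts", {
  expect_error(annotation_set(data.frame(
    transcript_id = "t", chrom = "c", strand = "+", start = 10, end = 10)),
    "start < end")
  expect_error(annotation_set(data.frame(
    transcript_id = c("t", "t"), chrom = "c", strand = "+",
    start = c(0, 50), end = c(60, 100))), "overlap")
  expect_error(annotation_set(data.frame(
    transcript_id = "t", chrom = "c", strand = "*", start = 0, end = 10)),
    "strand")
})

test_that("BED12 blocks expand to exon chains", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t400\ttb\t7\t+\t100\t400\t0\t2\t50,100\t0,200", bed)
  a <- read_bed12(bed)
  ch <- exon_chains(a, "tb")[["tb"]]
  expect_equal(unname(ch[, "start"]), c(100, 300))
  expect_equal(unname(ch[, "end"]), c(150, 400))
  expect_equal(a$transcripts["tb", "read_support"], 7L)
})

test_that("expression table reading enforces design and validity", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts2", "f1\t1\t2", "f2\t0\t4"), tsv)
  m <- read_expression(tsv, c(s1 = "A", s2 = "B"))
  expect_equal(unname(m$values["f2", "s2"]), 4)
  writeLines(c("id\ts1\ts2", "f1\t1\t2", "f1\t0\t4"), tsv)
  expect_error(read_expression(tsv, c(s1 = "A", s2 = "B")), "duplicate")
  expect_error(expression_matrix(matrix(1, 1, 1, dimnames = list("f", "sX")),
                                 c(s1 = "A", s2 = "B")), "missing")
  expect_error(expression_matrix(matrix(-1, 1, 2, dimnames = list("f", c("s1", "s2"))),
                                 c(s1 = "A", s2 = "B")), "negative")
})

test_that("CPM columns sum to 1e6 and FPKM obeys the CPM relation", {
  expect_equal(unname(compute_cpm(toy_counts(matrix(5, 1, 2)))$values[1, ]),
               c(1e6, 1e6))
  set.seed(42)
  v <- matrix(rpois(300, 40), 50, 6,
              dimnames = list(paste0("f", 1:50), NULL))
  m <- toy_counts(v)
  cpm <- compute_cpm(m)
  expect_equal(unname(colSums(cpm$values)), rep(1e6, 6), tolerance = 1e-9)

  len <- stats::setNames(sample(500:3000, 50), rownames(v))
  mf <- expression_matrix(m$values, m$design, feature_lengths = len)
  fpkm <- compute_fpkm(mf)
  expect_equal(fpkm$values, cpm$values * 1e3 / len, tolerance = 1e-9)
  # count 10, length 1000, library 1e6 -> FPKM 10
  one <- expression_matrix(
    matrix(c(10, 999990, 10, 999990), 2, 2,
           dimnames = list(c("a", "b"), c("s1", "s2"))),
    c(s1 = "A", s2 = "B"), feature_lengths = c(a = 1000, b = 99000))
  expect_equal(unname(compute_fpkm(one)$values["a", 1]), 10)
  expect_error(compute_cpm(toy_counts(matrix(0, 2, 2))), "zero library")
})

test_that("strand reflection preserves exon/intron lengths and swaps termini", {
  exons <- list(c(100, 250), c(400, 520), c(700, 900))
  a <- ann(tx("t", "chr1", "+", exons, gene = "g"))
  C <- 10000
  b <- ann(tx("t", "chr1", "-", mirror_exons(exons, C), gene = "g"))
  ea <- exon_chains(a)[["t"]]; eb <- exon_chains(b)[["t"]]
  expect_equal(sort(ea[, "end"] - ea[, "start"]),
               sort(eb[, "end"] - eb[, "start"]))
  ia <- intron_chains(a)[["t"]]; ib <- intron_chains(b)[["t"]]
  expect_equal(sort(ia[, "end"] - ia[, "start"]),
               sort(ib[, "end"] - ib[, "start"]))
  expect_equal(b$transcripts["t", "tss"], C - a$transcripts["t", "tss"])
  expect_equal(b$transcripts["t", "tes"], C - a$transcripts["t", "tes"])
})
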