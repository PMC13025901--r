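# a small hand-built reference: gene gA (+) with two isoforms over 5 exons,
# gene gB (+) downstream, gene gC (-) overlapping nothing
ref_fixture <- function() {
  e <- list(c(1000, 1100), c(1300, 1400), c(1600, 1700), c(1900, 2000),
            c(2200, 2500))
  ann(
    tx("gA.t1", "chr1", "+", e, gene = "gA", source = "reference"),
    tx("gA.t2", "chr1", "+", e[c(1, 2, 4, 5)], gene = "gA", source = "reference"),
    tx("gB.t1", "chr1", "+", list(c(6000, 6200), c(6500, 6800)), gene = "gB",
       source = "reference"),
    tx("gC.t1", "chr1", "-", list(c(9000, 9200), c(9500, 9700)), gene = "gC",
       source = "reference"),
    source_tag = "reference"
  )
}

test_that("alignment filter applies thresholds and 5'-merge rule", {
  rec <- data.frame(
    transcript_id = c("a", "b", "c", "d", "e"),
    identity = c(0.89, 0.90, 0.99, 0.95, 0.95),
    coverage = c(0.99, 0.85, 0.80, 0.90, 0.90),
    tss_equivalence_group = c(NA, NA, NA, "grp1", "grp1"),
    length = c(1000, 1000, 1000, 950, 1000),
    stringsAsFactors = FALSE
  )
  kept <- filter_alignments(rec)
  expect_false("a" %in% kept)          # identity 0.89 < 0.9 removed
  expect_true("b" %in% kept)           # boundary values retained
  expect_false("c" %in% kept)          # coverage below threshold
  expect_true("e" %in% kept)           # longest of the 5'-equivalence group
  expect_false("d" %in% kept)
  expect_equal(filter_alignments(rec[0, ]), character(0))
})

test_that("classification cascade covers the eight categories", {
  ref <- ref_fixture()
  e <- list(c(1000, 1100), c(1300, 1400), c(1600, 1700), c(1900, 2000),
            c(2200, 2500))
  obs <- ann(
    tx("fsm", "chr1", "+", list(c(1020, 1100), c(1300, 1400), c(1600, 1700),
                                c(1900, 2000), c(2200, 2430))),
    tx("ism", "chr1", "+", e[2:5]),
    # gA.t2 junction set combined with skipped e2: known sites, new chain
    tx("nic", "chr1", "+", e[c(1, 3, 4, 5)]),
    tx("nnc", "chr1", "+", list(c(1000, 1100), c(1300, 1455), c(1600, 1700),
                                c(1900, 2000), c(2200, 2500))),
    tx("fus", "chr1", "+", c(e, list(c(6000, 6200), c(6500, 6800)))),
    tx("gen", "chr1", "+", list(c(1150, 1250))),
    tx("anti", "chr1", "-", list(c(1200, 1500))),
    tx("inter", "chr1", "+", list(c(4000, 4300)))
  )
  calls <- classify_transcripts(obs, ref)
  got <- stats::setNames(calls$category, calls$transcript_id)
  expect_equal(got[["fsm"]], "FSM")
  expect_equal(got[["ism"]], "ISM")
  expect_equal(got[["nic"]], "NIC")
  expect_equal(got[["nnc"]], "NNC")
  expect_equal(got[["fus"]], "fusion")
  expect_equal(got[["gen"]], "genic")
  expect_equal(got[["anti"]], "antisense")
  expect_equal(got[["inter"]], "intergenic")
  # every transcript classified exactly once: partition property
  expect_equal(sort(names(got)), sort(obs$transcripts$transcript_id))
  expect_true(all(got %in% c("FSM", "ISM", "NIC", "NNC", "fusion", "genic",
                             "antisense", "intergenic")))
  # FSM/ISM carry a matched reference transcript, novel-gene calls a locus id
  expect_false(is.na(calls$matched_reference_transcript[calls$transcript_id == "fsm"]))
  expect_true(startsWith(calls$assigned_gene_id[calls$transcript_id == "anti"], "NOVELG"))
  expect_true(startsWith(calls$assigned_gene_id[calls$transcript_id == "inter"], "NOVELG"))
})

test_that("sub-chain calls match exhaustive enumeration over a toy gene", {
  ref <- ref_fixture()
  full <- intron_chains(ref, "gA.t1")[["gA.t1"]]
  e <- exon_chains(ref, "gA.t1")[["gA.t1"]]
  # all contiguous exon windows of the 5-exon chain
  for (i in 1:4) for (j in (i + 1):5) {
    em <- e[i:j, , drop = FALSE]
    obs <- annotation_set(data.frame(transcript_id = "w", chrom = "chr1",
                                     strand = "+", start = em[, "start"],
                                     end = em[, "end"]),
                          source_tag = "observed")
    call <- classify_transcripts(obs, ref)$category
    ic <- em[-nrow(em), "end"]
    # independent expectation: equality or contiguous subchain of either
    # reference isoform
    chains <- intron_chains(ref, c("gA.t1", "gA.t2"))
    eq <- any(vapply(chains, function(rc) {
      nrow(rc) == j - i && all(rc[, 1] == em[-nrow(em), "end"]) &&
        all(rc[, 2] == em[-1, "start"])
    }, logical(1)))
    sub <- any(vapply(chains, function(rc) {
      m <- j - i
      if (m >= nrow(rc)) return(FALSE)
      any(vapply(0:(nrow(rc) - m), function(off) {
        all(rc[(off + 1):(off + m), 1] == em[-nrow(em), "end"]) &&
          all(rc[(off + 1):(off + m), 2] == em[-1, "start"])
      }, logical(1)))
    }, logical(1)))
    expect_equal(call, if (eq) "FSM" else if (sub) "ISM" else "NIC",
                 info = sprintf("window %d..%d", i, j))
  }
})

test_that("classification is invariant under translation and reflection", {
  sim <- simulate_dataset(sim_config(n_genes = 20, n_observed = 80), seed = 3)
  obs <- sim$observed$annotation; ref <- sim$reference$annotation
  base <- classify_transcripts(obs, ref)

  remake <- function(a, ex) annotation_set(
    ex, meta = a$transcripts[, c("transcript_id", "gene_id", "read_support",
                                 "source")])
  translate <- function(a, d) {
    ex <- a$exons; ex$start <- ex$start + d; ex$end <- ex$end + d
    remake(a, ex)
  }
  t1 <- classify_transcripts(translate(obs, 5000), translate(ref, 5000))
  expect_equal(t1$category[match(base$transcript_id, t1$transcript_id)],
               base$category)

  C <- max(ref$exons$end, obs$exons$end) + 1000
  reflect <- function(a) {
    ex <- a$exons
    new <- data.frame(transcript_id = ex$transcript_id, chrom = ex$chrom,
                      strand = ifelse(ex$strand == "+", "-", "+"),
                      start = C - ex$end, end = C - ex$start,
                      stringsAsFactors = FALSE)
    remake(a, new)
  }
  r1 <- classify_transcripts(reflect(obs), reflect(ref))
  expect_equal(r1$category[match(base$transcript_id, r1$transcript_id)],
               base$category)
})

test_that("catalog summary tallies agree with planted truth", {
  sim <- simulate_dataset(sim_config(n_genes = 30, n_observed = 150), seed = 9)
  calls <- classify_transcripts(sim$observed$annotation, sim$reference$annotation)
  s <- summarize_catalog(calls, sim$observed$annotation)
  truth_tab <- table(sim$observed$truth$category)
  got <- stats::setNames(s$category_counts, s$category_names)
  for (nm in names(truth_tab)) expect_equal(got[[nm]], unname(truth_tab[[nm]]))
  expect_equal(sum(s$category_counts), s$n_transcripts)
  expect_equal(s$n_known + s$n_novel, s$n_transcripts)
  expect_equal(s$n_known, unname(truth_tab["FSM"]))
  # single FSM gene has no multi-isoform genes
  ref <- ref_fixture()
  one <- ann(tx("o1", "chr1", "+", list(c(6000, 6200), c(6500, 6800))))
  s1 <- summarize_catalog(classify_transcripts(one, ref), one)
  expect_equal(s1$genes_with_multiple_isoforms, 0)
})

test_that("ORF prediction matches a brute-force scan", {
  expect_equal(predict_orf("ATGAAATAA")$length_aa, 2)
  expect_equal(predict_orf("ATGAAATAA")$start, 1)
  expect_null(predict_orf("CCCCCCAAATTTGGG"))

  brute_orf <- function(s) {
    n <- nchar(s); best <- 0
    for (i in seq_len(max(0, n - 5))) {
      if (substr(s, i, i + 2) != "ATG") next
      j <- i + 3
      while (j + 2 <= n) {
        cod <- substr(s, j, j + 2)
        if (cod %in% c("TAA", "TAG", "TGA")) {
          best <- max(best, (j - i) / 3); break
        }
        j <- j + 3
      }
    }
    best
  }
  set.seed(11)
  for (k in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = "")
    o <- predict_orf(s)
    expect_equal(if (is.null(o)) 0 else o$length_aa, brute_orf(s))
  }
})

test_that("spliced sequences honour strand and splicing", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "AAACCCGGGTTTAAACCCGGGTTT"))
  a <- ann(tx("p", "chr1", "+", list(c(0, 3), c(6, 9))),
           tx("m", "chr1", "-", list(c(0, 3), c(6, 9))))
  ss <- spliced_sequences(a, genome)
  expect_equal(as.character(ss[["p"]]), "AAAGGG")
  expect_equal(as.character(ss[["m"]]), "CCCTTT")
})
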