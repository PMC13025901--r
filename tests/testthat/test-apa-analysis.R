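# observed set with controllable 3' ends on one plus-strand gene
ends_ann <- function(ends, support = NULL, strand = "+", gene = "g1") {
  if (is.null(support)) support <- rep(1L, length(ends))
  rows <- do.call(rbind, lapply(seq_along(ends), function(i) {
    ex <- if (strand == "+") list(c(0, 50), c(100, ends[i])) else
      list(c(ends[i], 900), c(950, 1000))
    tx(paste0("t", i), "chr1", strand, ex, gene = gene,
       support = support[i])
  }))
  annotation_set(rows[, c("transcript_id", "chrom", "strand", "start", "end")],
                 meta = unique(rows[, c("transcript_id", "gene_id",
                                        "read_support", "source")]))
}

test_that("single-linkage clustering splits ends by the window rule", {
  a <- ends_ann(c(200, 205, 230))
  cl <- cluster_pas(a, cluster_window = 24, min_support = 1)
  expect_equal(nrow(cl), 2)                 # 230 - 205 = 25 > 24 splits
  expect_equal(sort(cl$n_members), c(1, 2))
  one <- cluster_pas(ends_ann(c(200, 210, 220)), cluster_window = 24,
                     min_support = 1)
  expect_equal(nrow(one), 1)                # all within window -> one cluster
  expect_equal(one$n_members, 3)
})

test_that("cluster representative is the support-weighted mode, downstream ties", {
  a <- ends_ann(c(200, 210, 210), support = c(5, 2, 2))
  cl <- cluster_pas(a, min_support = 1)
  expect_equal(cl$position, 200)            # weight 5 beats 4
  b <- ends_ann(c(200, 210), support = c(3, 3))
  expect_equal(cluster_pas(b, min_support = 1)$position, 210)  # downstream tie
  bm <- ends_ann(c(200, 210), support = c(3, 3), strand = "-")
  expect_equal(cluster_pas(bm, min_support = 1)$position, 200) # minus strand
})

test_that("support threshold is monotone and conserves member support", {
  a <- ends_ann(c(200, 205, 400, 405, 600), support = c(3, 2, 1, 1, 9))
  n_pas <- vapply(1:6, function(ms)
    nrow(cluster_pas(a, min_support = ms)), integer(1))
  expect_true(all(diff(n_pas) <= 0))        # raising min_support never adds PASs
  cl <- cluster_pas(a, min_support = 1)
  expect_equal(sum(cl$read_support), sum(a$transcripts$read_support))
  members <- unlist(strsplit(cl$member_ids, ","))
  expect_setequal(members, a$transcripts$transcript_id)  # each end in one cluster
})

test_that("UTRR geometry and M/m classification follow the midpoint rule", {
  a <- ends_ann(c(200, 500), support = c(3, 3))
  fake_expr <- expression_matrix(
    matrix(c(30, 30, 10, 10), 2, 2, byrow = TRUE,
           dimnames = list(c("t2", "t1"), c("s1", "s2"))),
    c(s1 = "c1", s2 = "c2"))
  cl <- cluster_pas(a, tx_expr = fake_expr)
  apa <- call_apa_genes(cl)
  expect_equal(apa$n_pas, 2)
  expect_equal(apa$utrr_length, 300)
  expect_equal(apa$midpoint, 350)
  apa <- classify_mp(apa, cl, c("c1", "c2"))
  # isoform ending 500 (t2, expr 30) is distal M; 200 (t1, 10) proximal m
  expect_equal(apa$M_c1, 30)
  expect_equal(apa$m_c1, 10)
  expect_equal(apa$mp_status_c1, "M")

  # mirrored gene on the minus strand gives identical labels
  am <- ends_ann(c(200, 500), support = c(3, 3), strand = "-")
  clm <- cluster_pas(am, tx_expr = fake_expr)
  apam <- classify_mp(call_apa_genes(clm), clm, c("c1", "c2"))
  expect_equal(apam$utrr_length, 300)
  # on the minus-strand fixture t1 ends at 200 which is now the distal end
  expect_equal(apam$mp_status_c1, "P")
})

test_that("mPAS calls shift when the dominant site changes", {
  a <- ends_ann(c(200, 500), support = c(3, 3))
  ex <- expression_matrix(
    matrix(c(10, 1, 2, 9), 2, 2, byrow = TRUE,
           dimnames = list(c("t1", "t2"), c("s1", "s2"))),
    c(s1 = "c1", s2 = "c2"))
  cl <- cluster_pas(a, tx_expr = ex)
  apa <- call_apa_genes(cl)
  mp <- call_mpas(apa, cl, c("c1", "c2"))
  expect_true(mp$mpas_shift)
  ex2 <- expression_matrix(
    matrix(c(10, 8, 2, 1), 2, 2, byrow = TRUE,
           dimnames = list(c("t1", "t2"), c("s1", "s2"))),
    c(s1 = "c1", s2 = "c2"))
  cl2 <- cluster_pas(a, tx_expr = ex2)
  mp2 <- call_mpas(call_apa_genes(cl2), cl2, c("c1", "c2"))
  expect_false(mp2$mpas_shift)
})

test_that("hexamer scan counts planted signals in upstream windows", {
  seqs <- paste(rep("C", 200), collapse = "")
  g <- Biostrings::DNAStringSet(c(chr1 = seqs))
  # plant AATAAA 20 nt upstream of a + strand PAS at position 150
  s <- strsplit(seqs, "")[[1]]
  s[125:130] <- c("A", "A", "T", "A", "A", "A")
  g <- Biostrings::DNAStringSet(c(chr1 = paste(s, collapse = "")))
  cl <- data.frame(gene_id = "g1", cluster_id = "g1:PAS1", position = 150,
                   chrom = "chr1", strand = "+", n_members = 1,
                   read_support = 3, member_ids = "t1",
                   stringsAsFactors = FALSE)
  res <- scan_pas_signal(g, cl, window_up = 50)
  expect_equal(res$table$count[res$table$hexamer == "AATAAA"], 1)
  # all-C window has no A-containing hexamers
  cl2 <- cl; cl2$position <- 60
  res2 <- scan_pas_signal(g, cl2, window_up = 50)
  expect_false("AATAAA" %in% res2$table$hexamer)
})

test_that("planted AATAAA is the top-ranked hexamer genome-wide", {
  cfg <- sim_config(n_genes = 120, n_observed = 300, pas_signal_rate = 0.8)
  sim <- simulate_dataset(cfg, seed = 19)
  obs <- sim$observed$annotation
  calls <- classify_transcripts(obs, sim$reference$annotation)
  obs$transcripts$gene_id <- calls$assigned_gene_id[
    match(obs$transcripts$transcript_id, calls$transcript_id)]
  keep <- calls$transcript_id[calls$category %in% c("FSM", "ISM", "NIC", "NNC")]
  cl <- cluster_pas(subset_transcripts(obs, keep))
  expect_gt(nrow(cl), 100)
  res <- scan_pas_signal(sim$reference$genome, cl)
  expect_equal(res$aataaa_rank, 1)
})

test_that("3'-UTR lengths are measured from the planted stop codon", {
  sim <- simulate_dataset(sim_config(n_genes = 40, n_observed = 200), seed = 23)
  obs <- sim$observed$annotation
  truth <- sim$observed$truth
  ids <- truth$transcript_id[!is.na(truth$pas_index)]
  u <- utr3_length_distribution(obs, sim$reference$genome, ids = ids,
                                min_aa = 150)
  expect_gt(nrow(u$per_transcript), 50)
  # proximal-PAS isoforms end 250 nt after the planted stop (up to TES
  # jitter); longer UTRs belong to more distal sites
  m <- merge(u$per_transcript, truth, by = "transcript_id")
  expect_true(all(m$utr3_length >= 230))
  prox <- m$utr3_length[m$pas_index == 1]
  expect_true(length(prox) > 0 && all(abs(prox - 250) <= 10))
  expect_true(all(m$utr3_length[m$pas_index > 1] > 350))
  # histogram mode sits in the planted 200-300 bin
  expect_equal(u$histogram$bin_start[which.max(u$histogram$count)], 200)
})
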