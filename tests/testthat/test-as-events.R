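test_that("canonical events of all five types are detected and typed", {
  # ES: t2 skips the middle exon
  a <- toy_gene_ann(list(
    cbind(start = c(0, 100, 200), end = c(50, 150, 250)),
    cbind(start = c(0, 200), end = c(50, 250))))
  ev <- detect_as_events(a)
  expect_equal(ev$event_type, "ES")
  expect_equal(ev$region_start, 100)
  expect_equal(ev$region_end, 150)

  # IR: retaining form is a single exon spanning both
  b <- toy_gene_ann(list(
    cbind(start = c(0, 100), end = c(50, 150)),
    cbind(start = 0, end = 150)))
  ev <- detect_as_events(b)
  expect_equal(ev$event_type, "IR")
  expect_equal(c(ev$region_start, ev$region_end), c(50, 100))

  # A5SS on + strand: donors differ, acceptor shared
  c5 <- toy_gene_ann(list(
    cbind(start = c(0, 200), end = c(100, 300)),
    cbind(start = c(0, 200), end = c(130, 300))))
  expect_equal(detect_as_events(c5)$event_type, "A5SS")

  # same structure on the minus strand is an A3SS
  c3 <- toy_gene_ann(list(
    cbind(start = c(0, 200), end = c(100, 300)),
    cbind(start = c(0, 200), end = c(130, 300))), strand = "-")
  expect_equal(detect_as_events(c3)$event_type, "A3SS")

  # MEE: middle exons mutually exclusive
  m <- toy_gene_ann(list(
    cbind(start = c(0, 100, 600), end = c(50, 200, 700)),
    cbind(start = c(0, 400, 600), end = c(50, 500, 700))))
  expect_equal(detect_as_events(m)$event_type, "MEE")
})

test_that("alternative termini are not events; strand mixing errors", {
  a <- toy_gene_ann(list(
    cbind(start = c(0, 100, 200), end = c(50, 150, 250)),
    cbind(start = c(100, 200), end = c(150, 250))))   # 5' truncation only
  expect_equal(nrow(detect_as_events(a)), 0)
  rows <- rbind(tx("t1", "chr1", "+", list(c(0, 50), c(100, 150)), gene = "g"),
                tx("t2", "chr1", "-", list(c(300, 400), c(500, 600)), gene = "g"))
  mixed <- annotation_set(rows[, c("transcript_id", "chrom", "strand", "start", "end")],
                          meta = unique(rows[, c("transcript_id", "gene_id")]))
  expect_error(detect_as_events(mixed), "different strands")
})

test_that("event multiset is independent of transcript order", {
  set.seed(21)
  ems <- random_toy_gene(n_tx = 4)
  a <- toy_gene_ann(ems)
  b <- toy_gene_ann(rev(ems))
  expect_equal(event_key(detect_as_events(a)), event_key(detect_as_events(b)))
})

test_that("detection equals the brute-force per-base oracle on toy genes", {
  set.seed(1234)
  n_checked <- 0
  for (rep in 1:120) {
    ems <- random_toy_gene(n_tx = sample(2:4, 1), max_exons = 6)
    strand <- sample(c("+", "-"), 1)
    got <- detect_as_events(toy_gene_ann(ems, strand = strand))
    want <- oracle_gene_events(ems, strand)
    expect_equal(event_key(got), event_key(want),
                 info = sprintf("toy gene %d (%s)", rep, strand))
    n_checked <- n_checked + nrow(want)
  }
  expect_gt(n_checked, 100)  # the sweep actually exercised events
})

test_that("event typing is strand-correct under flips and mirrors", {
  swap <- c(ES = "ES", IR = "IR", A5SS = "A3SS", A3SS = "A5SS",
            MEE = "MEE", complex = "complex")
  set.seed(77)
  for (rep in 1:40) {
    ems <- random_toy_gene(n_tx = 3, max_exons = 5)
    fwd <- detect_as_events(toy_gene_ann(ems, strand = "+"))
    # relabelling the strand with the same coordinates exchanges donor and
    # acceptor roles: A5SS <-> A3SS
    flp <- detect_as_events(toy_gene_ann(ems, strand = "-"))
    expect_equal(sort(unname(swap[fwd$event_type])), sort(flp$event_type),
                 info = paste("flip rep", rep))
    # a true mirror (reflected coordinates + flipped strand) is the same
    # molecule: all labels preserved
    C <- 1000
    ems_m <- lapply(ems, function(em) {
      m <- cbind(start = C - em[, "end"], end = C - em[, "start"])
      m[order(m[, "start"]), , drop = FALSE]
    })
    mir <- detect_as_events(toy_gene_ann(ems_m, strand = "-"))
    expect_equal(sort(fwd$event_type), sort(mir$event_type),
                 info = paste("mirror rep", rep))
  }
})

test_that("gene profiles and proportions summarise events", {
  # two identical transcripts: no events
  no_ev <- detect_as_events(toy_gene_ann(list(
    cbind(start = c(0, 100), end = c(50, 150)),
    cbind(start = c(0, 100), end = c(50, 150)))))
  expect_equal(nrow(no_ev), 0)
  empty <- profile_as_genes(no_ev)
  expect_true(all(is.na(empty$type_proportions)))

  a <- toy_gene_ann(list(
    cbind(start = c(0, 100, 200), end = c(50, 150, 250)),
    cbind(start = c(0, 200), end = c(50, 250))))
  pr <- profile_as_genes(detect_as_events(a))
  expect_equal(pr$profiles$patterns, "ES")
  expect_equal(unname(pr$type_proportions["ES"]), 100)
  expect_equal(pr$n_events, 1)
})

test_that("planted AS mix is recovered from the reference catalog", {
  cfg <- sim_config(n_genes = 220, n_observed = 10,
                    isoform_weights = c(0.1, 0.3, 0.3, 0.3))
  ref <- simulate_reference(cfg, seed = 31)
  ev <- detect_as_events(ref$annotation)
  truth <- table(factor(ref$as_truth$event_type,
                        levels = c("ES", "IR", "A3SS", "A5SS", "MEE")))
  got <- table(factor(ev$event_type[ev$event_type != "complex"],
                      levels = c("ES", "IR", "A3SS", "A5SS", "MEE")))
  expect_gt(sum(truth), 150)
  # proportions within 5 points of the planted mix
  expect_lt(max(abs(got / sum(got) - truth / sum(truth))), 0.05)
})

test_that("diversity correlations behave at the degenerate and ideal limits", {
  sim <- simulate_dataset(sim_config(n_genes = 25, n_observed = 120), seed = 13)
  obs <- sim$observed$annotation
  # constant transcript counts -> NA
  tx1 <- obs$transcripts$transcript_id[!is.na(obs$transcripts$gene_id)]
  g <- obs$transcripts[tx1, "gene_id"]
  one_each <- tx1[!duplicated(g)]
  sub <- subset_transcripts(obs, one_each)
  fpkm <- stats::setNames(rep(5, length(unique(g))), unique(g))
  r <- correlate_diversity(sub, fpkm)
  expect_true(is.na(r$r[r$stratum == "tx_vs_exons"]))
  # perfectly linear planted relation -> r = 1
  ntx <- table(g)
  fake_fpkm <- stats::setNames(as.numeric(ntx) * 2 + 1, names(ntx))
  r2 <- correlate_diversity(obs, fake_fpkm)
  expect_equal(r2$r[r2$stratum == "tx_vs_expression"], 1, tolerance = 1e-12)
})
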