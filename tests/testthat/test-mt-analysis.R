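test_that("major-transcript margin rule arithmetic", {
  expect_equal(call_major_transcript(c(t1 = 50, t2 = 5))$mt_id, "t1")       # 45 > 10
  expect_true(is.na(call_major_transcript(c(t1 = 12, t2 = 11))$mt_id))      # 1 <= 10
  expect_true(is.na(call_major_transcript(c(t1 = 20, t2 = 10))$mt_id))      # boundary: 10 not > 10
  single <- call_major_transcript(c(t1 = 7))
  expect_equal(single$mt_id, "t1")
  expect_true(single$margin_satisfied)
  # fold mode
  expect_equal(call_major_transcript(c(t1 = 55, t2 = 5), margin = 10,
                                     margin_mode = "fold")$mt_id, "t1")
  expect_true(is.na(call_major_transcript(c(t1 = 50, t2 = 5), margin = 10,
                                          margin_mode = "fold")$mt_id))
  expect_equal(call_major_transcript(c(t1 = 3, t2 = 0), margin = 10,
                                     margin_mode = "fold")$mt_id, "t1")
  expect_error(call_major_transcript(c(t1 = -1)), "negative")
})

test_that("margin modes respond to rescaling as expected", {
  x <- c(a = 120, b = 40, c = 10)
  for (cc in c(0.5, 2, 10)) {
    # fold mode is scale-invariant
    f1 <- call_major_transcript(x, margin = 2, margin_mode = "fold")
    f2 <- call_major_transcript(x * cc, margin = 2, margin_mode = "fold")
    expect_equal(f1$mt_id, f2$mt_id)
    expect_equal(f1$margin_satisfied, f2$margin_satisfied)
    # absolute mode is scale-covariant: margin scales with c
    a1 <- call_major_transcript(x, margin = 50)
    a2 <- call_major_transcript(x * cc, margin = 50 * cc)
    expect_equal(a1$mt_id, a2$mt_id)
    expect_equal(a1$margin_satisfied, a2$margin_satisfied)
  }
})

test_that("AMT detection separates switches, constants and indeterminates", {
  calls <- data.frame(
    gene_id = rep(c("g1", "g2", "g3"), 2),
    condition = rep(c("c1", "c2"), each = 3),
    mt_id = c("tA", "tA", "tA", "tA", "tB", NA),
    mt_level = 1, runner_up_level = 0, margin_satisfied = TRUE,
    stringsAsFactors = FALSE)
  res <- detect_amt(calls)
  expect_equal(res$constant, "g1")
  expect_equal(res$amt$gene_id, "g2")
  expect_equal(res$indeterminate, "g3")
})

test_that("expression-change binning uses half-open absolute-ratio bins", {
  amt <- list(amt = data.frame(gene_id = "gA", mt_condition1 = "x",
                               mt_condition2 = "y"),
              constant = c("gB", "gC", "gD"), indeterminate = character(0),
              conditions = c("c1", "c2"))
  expr <- rbind(gA = c(10, 25),    # +150% -> 100-200%
                gB = c(10, 10),    # 0 -> 0-50%
                gC = c(10, 2),     # -80% -> 50-100%
                gD = c(10, 65))    # +550% -> >200%
  res <- categorize_change(amt, expr)
  got <- stats::setNames(as.character(res$per_gene$category), res$per_gene$gene_id)
  expect_equal(unname(got[c("gA", "gB", "gC", "gD")]),
               c("100-200%", "0-50%", "50-100%", ">200%"))
  # zero baseline excluded with a count
  expr2 <- rbind(expr, gE = c(0, 5))
  amt2 <- amt; amt2$constant <- c(amt$constant, "gE")
  expect_equal(categorize_change(amt2, expr2)$n_excluded_zero_baseline, 1)
  # every included gene falls in exactly one bin
  expect_false(any(is.na(res$per_gene$category)))
})

test_that("DE-AMT intersection splits by direction", {
  de <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                   direction = c("up", "down", "up", "nodiff"),
                   stringsAsFactors = FALSE)
  res <- intersect_deg(c("g2", "g3", "g9"), de)
  expect_equal(nrow(res$de_amt), 2)
  expect_equal(res$n_up, 1)
  expect_equal(res$n_down, 1)
  expect_equal(unname(res$venn), c(1, 1, 2))  # amt_only, deg_only, both
  expect_equal(intersect_deg("gX", de)$venn[["both"]], 0)
})

test_that("planted up/down DE-AMT split is recovered end to end", {
  # plant a DEG table and AMT set mirroring a known up/down split
  set.seed(5)
  amt_genes <- sprintf("g%03d", 1:300)
  up <- sample(amt_genes, 79)
  down <- sample(setdiff(amt_genes, up), 104)
  extra <- sprintf("x%03d", 1:50)
  de <- data.frame(
    gene_id = c(up, down, extra),
    direction = c(rep("up", 79), rep("down", 104),
                  sample(c("up", "down"), 50, replace = TRUE)),
    stringsAsFactors = FALSE)
  res <- intersect_deg(amt_genes, de)
  expect_equal(res$n_up, 79)
  expect_equal(res$n_down, 104)
  expect_equal(nrow(res$de_amt), 183)
})

test_that("AMT recovery on simulated data is essentially perfect without noise", {
  cfg <- sim_config(n_genes = 80, n_observed = 320, nb_dispersion = 0)
  sim <- simulate_dataset(cfg, seed = 17)
  res <- run_pipeline(sim$observed$annotation, sim$reference$annotation,
                      sim$expression$counts)
  tg <- sim$expression$truth_gene
  det <- res$amt$amt$gene_id
  tru <- tg$gene_id[tg$amt]
  expect_gt(length(tru), 5)
  expect_gte(length(intersect(det, tru)) / length(det), 0.99)
  expect_gte(length(intersect(det, tru)) / length(tru), 0.99)
})
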