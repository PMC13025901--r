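#' Round half-up
#'
#' Decimal rounding with ties away from zero (display convention for all
#' report percentages), unlike [round()]'s banker's rounding.
#'
#' @param x numeric
#' @param digits decimal places (default 2)
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count over a total, report-rounded
#'
#' @param num,den numerator and denominator counts
#' @param digits decimal places (default 2)
#' @return `num/den * 100` rounded half-up; NA when `den` is 0.
#' @export
report_percent <- function(num, den, digits = 2) {
  out <- round_half_up(num / den * 100, digits)
  out[!is.finite(out)] <- NA_real_
  out
}

write_tsv_artifact <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full transcript-diversity pipeline
#'
#' Orchestrates the stages in dependency order — structural classification,
#' catalog summary, AS-event detection, CPM filtering, the NB Wald DE test,
#' major-transcript and AMT analysis, PAS clustering / APA / mPAS-shift
#' analysis and the poly(A)-signal hexamer scan — and renders a summary
#' report. Artifacts are returned in memory and, when `outdir` is given,
#' written as TSV files (byte-stable across reruns with the same inputs).
#'
#' @param observed annotation_set of observed transcript models (with read
#'   support).
#' @param reference annotation_set with gene ids.
#' @param counts expression_matrix of transcript-level counts with feature
#'   lengths.
#' @param genome optional DNAStringSet; enables the hexamer scan.
#' @param outdir optional directory for TSV artifacts.
#' @param params list of stage tunables: `mt_margin` (10), `mt_margin_mode`
#'   ("absolute"), `cluster_window` (24), `min_pas_support` (2), `min_cpm`
#'   (1), `min_libraries` (3), `lfc_threshold` (1), `alpha` (0.05),
#'   `high_expr_threshold` (30), `pas_window_up` (50).
#' @return list of class `txdiv_pipeline` with stage artifacts and `report`.
#' @export
run_pipeline <- function(observed, reference, counts, genome = NULL,
                         outdir = NULL, params = list()) {
  p <- utils::modifyList(list(
    mt_margin = 10, mt_margin_mode = "absolute", cluster_window = 24,
    min_pas_support = 2, min_cpm = 1, min_libraries = 3, lfc_threshold = 1,
    alpha = 0.05, high_expr_threshold = 30, pas_window_up = 50), params)

  # 1. structural classification + catalog summary
  calls <- classify_transcripts(observed, reference)
  catalog <- summarize_catalog(calls, observed)

  # observed catalog with classified gene assignments
  obs2 <- observed
  obs2$transcripts$gene_id <- calls$assigned_gene_id[
    match(obs2$transcripts$transcript_id, calls$transcript_id)]

  # 2. AS events on the classified catalog
  events <- detect_as_events(obs2)
  as_profile <- profile_as_genes(events)

  # 3. expression: filter, FPKM, DE at gene level
  tx2gene <- stats::setNames(obs2$transcripts$gene_id,
                             obs2$transcripts$transcript_id)
  kept_tx <- filter_cpm(counts, min_cpm = p$min_cpm,
                        min_libraries = p$min_libraries)
  tx_fpkm <- compute_fpkm(counts)
  gene_counts <- rollup_gene_counts(counts, tx2gene)
  kept_genes <- filter_cpm(gene_counts, min_cpm = p$min_cpm,
                           min_libraries = p$min_libraries)
  de <- nb_wald_test(subset_expression(gene_counts, kept_genes),
                     lfc_threshold = p$lfc_threshold, alpha = p$alpha)

  # 4. major transcripts and AMT
  mt_fpkm <- subset_expression(tx_fpkm, intersect(kept_tx, rownames(tx_fpkm$values)))
  mt_calls <- call_major_transcripts(mt_fpkm, tx2gene, margin = p$mt_margin,
                                     margin_mode = p$mt_margin_mode)
  amt <- detect_amt(mt_calls)
  gene_fpkm <- compute_fpkm(gene_counts)
  gene_means <- condition_means(gene_fpkm)
  change <- categorize_change(amt, gene_means)
  de_amt <- intersect_deg(amt$amt$gene_id, de)

  # 5. APA -- on transcripts whose 3' ends are full-length termini of an
  # annotated gene (FSM/ISM/NIC/NNC); genic fragments and fusion models do
  # not contribute polyadenylation evidence
  pas_tx <- calls$transcript_id[calls$category %in% c("FSM", "ISM", "NIC", "NNC")]
  pas_obs <- subset_transcripts(obs2, pas_tx)
  clusters <- cluster_pas(pas_obs, cluster_window = p$cluster_window,
                          min_support = p$min_pas_support, tx_expr = tx_fpkm)
  apa <- call_apa_genes(clusters)
  conds <- counts$conditions
  apa <- classify_mp(apa, clusters, conds)
  mpas <- call_mpas(apa, clusters, conds)
  hex <- if (!is.null(genome)) scan_pas_signal(genome, clusters,
                                               window_up = p$pas_window_up) else NULL

  # 6. diversity correlations
  gene_fpkm_mean <- rowMeans(gene_fpkm$values)
  corr <- correlate_diversity(obs2, gene_fpkm_mean,
                              high_expr_threshold = p$high_expr_threshold)

  report <- render_report(catalog, as_profile, de, amt, de_amt, apa, mpas,
                          hex, conds)
  out <- list(calls = calls, catalog = catalog, events = events,
              as_profile = as_profile, kept_tx = kept_tx,
              kept_genes = kept_genes, de = de, mt_calls = mt_calls,
              amt = amt, change = change, de_amt = de_amt,
              clusters = clusters, apa = apa, mpas = mpas, hexamers = hex,
              correlations = corr, report = report, params = p)
  class(out) <- "txdiv_pipeline"

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_artifact(calls, file.path(outdir, "structural_calls.tsv"))
    write_tsv_artifact(events, file.path(outdir, "as_events.tsv"))
    write_tsv_artifact(as_profile$profiles, file.path(outdir, "gene_as_profiles.tsv"))
    write_tsv_artifact(de, file.path(outdir, "de_calls.tsv"))
    write_tsv_artifact(mt_calls, file.path(outdir, "mt_calls.tsv"))
    write_tsv_artifact(amt$amt, file.path(outdir, "amt_genes.tsv"))
    write_tsv_artifact(change$per_gene, file.path(outdir, "change_categories.tsv"))
    write_tsv_artifact(de_amt$de_amt, file.path(outdir, "de_amt.tsv"))
    write_tsv_artifact(clusters, file.path(outdir, "pas_clusters.tsv"))
    write_tsv_artifact(apa, file.path(outdir, "apa_genes.tsv"))
    write_tsv_artifact(mpas, file.path(outdir, "mpas_shifts.tsv"))
    if (!is.null(hex))
      write_tsv_artifact(hex$table, file.path(outdir, "hexamer_table.tsv"))
    write_tsv_artifact(corr, file.path(outdir, "diversity_correlations.tsv"))
    writeLines(report$lines, file.path(outdir, "report.md"))
  }
  out
}

#' @export
print.txdiv_pipeline <- function(x, ...) {
  cat(x$report$lines, sep = "\n")
  invisible(x)
}

#' Sum transcript counts to gene level
#'
#' @param counts expression_matrix of transcript counts.
#' @param tx2gene named character vector transcript -> gene (NA dropped).
#' @return expression_matrix of gene counts; gene length is the maximum
#'   member transcript length (used only for gene-level FPKM).
#' @export
rollup_gene_counts <- function(counts, tx2gene) {
  g <- tx2gene[rownames(counts$values)]
  keep <- !is.na(g)
  m <- rowsum(counts$values[keep, , drop = FALSE], g[keep])
  glen <- NULL
  if (!is.null(counts$feature_lengths)) {
    glen <- tapply(counts$feature_lengths[keep], g[keep], max)
    glen <- stats::setNames(as.numeric(glen), names(glen))[rownames(m)]
  }
  expression_matrix(m, counts$design, unit = "counts", feature_lengths = glen)
}

#' Subset an expression matrix by feature id
#' @param m expression_matrix
#' @param ids features to keep
#' @export
subset_expression <- function(m, ids) {
  expression_matrix(m$values[ids, , drop = FALSE], m$design, unit = m$unit,
                    feature_lengths = if (is.null(m$feature_lengths)) NULL else
                      m$feature_lengths[ids])
}

#' Render the pipeline summary report
#'
#' All percentages and ratios are derived from the component counts at
#' render time (2-decimal half-up rounding), never copied, so the report is
#' internally consistent by construction.
#'
#' @param catalog catalog_summary
#' @param as_profile output of [profile_as_genes()]
#' @param de DE call table
#' @param amt output of [detect_amt()]
#' @param de_amt output of [intersect_deg()]
#' @param apa,mpas APA gene and mPAS tables
#' @param hex hexamer scan result or NULL
#' @param conds the two condition labels
#' @return list with `values` (named numerics) and `lines` (markdown).
#' @export
render_report <- function(catalog, as_profile, de, amt, de_amt, apa, mpas,
                          hex, conds) {
  v <- list()
  v$n_transcripts <- catalog$n_transcripts
  v$n_known <- catalog$n_known
  v$n_novel <- catalog$n_novel
  v$pct_known <- report_percent(catalog$n_known, catalog$n_transcripts)
  v$pct_novel <- report_percent(catalog$n_novel, catalog$n_transcripts)
  v$n_genes <- catalog$n_genes
  v$pct_annotated_genes <- report_percent(catalog$n_annotated_genes, catalog$n_genes)
  v$pct_novel_genes <- report_percent(catalog$n_novel_genes, catalog$n_genes)
  v$pct_multi_isoform <- report_percent(catalog$genes_with_multiple_isoforms,
                                        catalog$n_genes)
  v$pct_ge10_isoform <- report_percent(catalog$genes_with_ge10_isoforms,
                                       catalog$n_genes)
  cat_pct <- report_percent(catalog$category_counts, catalog$n_transcripts)
  names(cat_pct) <- paste0("pct_", catalog$category_names)
  v <- c(v, as.list(cat_pct))

  v$n_as_events <- as_profile$n_events
  v$n_as_genes <- as_profile$n_genes
  for (tp in names(as_profile$type_counts)) {
    v[[paste0("pct_", tp)]] <- report_percent(as_profile$type_counts[[tp]],
                                              as_profile$n_events)
  }
  v$pct_ge2_patterns <- report_percent(as_profile$genes_ge2_patterns,
                                       as_profile$n_genes)

  n_up <- sum(de$direction == "up"); n_down <- sum(de$direction == "down")
  v$n_deg <- n_up + n_down; v$n_up <- n_up; v$n_down <- n_down
  v$n_amt <- nrow(amt$amt)
  v$n_mt_constant <- length(amt$constant)
  v$n_de_amt <- nrow(de_amt$de_amt)
  v$n_de_amt_up <- de_amt$n_up; v$n_de_amt_down <- de_amt$n_down

  v$n_apa_genes <- nrow(apa)
  for (i in 1:2) {
    st <- apa[[paste0("mp_status_", conds[i])]]
    nM <- sum(st == "M"); nP <- sum(st == "P")
    v[[paste0("n_M_", conds[i])]] <- nM
    v[[paste0("n_P_", conds[i])]] <- nP
    v[[paste0("mp_ratio_", conds[i])]] <-
      if (nP == 0) Inf else round_half_up(nM / nP, 2)
  }
  v$n_mpas_shift <- sum(mpas$mpas_shift %in% TRUE)
  if (!is.null(hex)) {
    v$aataaa_rank <- hex$aataaa_rank
    top <- utils::head(hex$table, 10)
  } else top <- NULL

  fmt <- function(x) ifelse(is.infinite(x), "Inf (no P genes)", format(x))
  lines <- c(
    "# Transcript diversity report",
    "",
    sprintf("- Transcripts: %d (%s%% known / %s%% novel)", v$n_transcripts,
            fmt(v$pct_known), fmt(v$pct_novel)),
    sprintf("- Genes: %d (%d annotated, %d novel)", v$n_genes,
            catalog$n_annotated_genes, catalog$n_novel_genes),
    sprintf("- Genes with >1 isoform: %d (%s%%); with >=10: %d (%s%%)",
            catalog$genes_with_multiple_isoforms, fmt(v$pct_multi_isoform),
            catalog$genes_with_ge10_isoforms, fmt(v$pct_ge10_isoform)),
    sprintf("- Structural categories: %s",
            paste(sprintf("%s %d", catalog$category_names,
                          catalog$category_counts), collapse = ", ")),
    sprintf("- AS events: %d in %d genes (ES %s%%, IR %s%%, A3SS %s%%, A5SS %s%%, MEE %s%%)",
            v$n_as_events, v$n_as_genes, fmt(v$pct_ES), fmt(v$pct_IR),
            fmt(v$pct_A3SS), fmt(v$pct_A5SS), fmt(v$pct_MEE)),
    sprintf("- DEGs: %d (%d up, %d down)", v$n_deg, v$n_up, v$n_down),
    sprintf("- AMT genes: %d (MT-constant: %d); DE-AMT: %d (%d up, %d down)",
            v$n_amt, v$n_mt_constant, v$n_de_amt, v$n_de_amt_up, v$n_de_amt_down),
    sprintf("- APA genes: %d; mPAS shifts: %d", v$n_apa_genes, v$n_mpas_shift),
    sprintf("- M:P ratio %s: %s; %s: %s", conds[1],
            fmt(v[[paste0("mp_ratio_", conds[1])]]), conds[2],
            fmt(v[[paste0("mp_ratio_", conds[2])]]))
  )
  if (!is.null(top)) {
    lines <- c(lines,
               sprintf("- AATAAA rank: %s", v$aataaa_rank),
               sprintf("- Top hexamers: %s",
                       paste(sprintf("%s(%d)", top$hexamer, top$count),
                             collapse = " ")))
  }
  list(values = v, lines = lines)
}
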