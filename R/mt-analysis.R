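#' Call the major transcript of each gene in one condition
#'
#' The major transcript (MT) is the most highly expressed isoform, provided
#' it exceeds the runner-up by a margin: in `absolute` mode the difference
#' top - second must exceed `margin` (expression units, FPKM by default); in
#' `fold` mode top/second must exceed `margin` (a runner-up of zero
#' satisfies the fold rule). Single-isoform genes satisfy the margin
#' trivially. When the margin is unmet the gene has no confident MT in that
#' condition.
#'
#' @param expr named numeric vector (or 1-column matrix) of per-transcript
#'   mean expression for one gene in one condition.
#' @param margin margin threshold (default 10).
#' @param margin_mode `"absolute"` or `"fold"`.
#' @return list: mt_id (or NA), mt_level, runner_up_level, margin_satisfied.
#' @export
call_major_transcript <- function(expr, margin = 10, margin_mode = c("absolute", "fold")) {
  margin_mode <- match.arg(margin_mode)
  if (is.matrix(expr)) expr <- stats::setNames(expr[, 1], rownames(expr))
  if (any(expr < 0)) stop("negative expression")
  if (length(expr) == 0L) stop("no expressed transcripts")
  ord <- order(-expr, names(expr))
  top <- expr[ord[1]]
  second <- if (length(expr) > 1L) expr[ord[2]] else NA_real_
  ok <- if (length(expr) == 1L) TRUE
  else if (margin_mode == "absolute") (top - second) > margin
  else if (second == 0) top > 0
  else (top / second) > margin
  list(mt_id = if (ok) names(expr)[ord[1]] else NA_character_,
       mt_level = unname(top),
       runner_up_level = unname(second),
       margin_satisfied = ok)
}

#' Major-transcript calls for all genes in both conditions
#'
#' @param tx_fpkm expression_matrix of transcript-level FPKM.
#' @param tx2gene named character vector transcript_id -> gene_id.
#' @param margin,margin_mode forwarded to [call_major_transcript()].
#' @return data.frame: gene_id, condition, mt_id, mt_level, runner_up_level,
#'   margin_satisfied.
#' @export
call_major_transcripts <- function(tx_fpkm, tx2gene, margin = 10,
                                   margin_mode = "absolute") {
  cm <- condition_means(tx_fpkm)
  ids <- rownames(tx_fpkm$values)
  genes <- tx2gene[ids]
  keep <- !is.na(genes)
  rows <- list()
  for (cc in tx_fpkm$conditions) {
    v <- cm[, cc]
    sp <- split(stats::setNames(v[keep], ids[keep]), genes[keep])
    for (g in names(sp)) {
      cl <- call_major_transcript(sp[[g]], margin = margin, margin_mode = margin_mode)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, condition = cc, mt_id = cl$mt_id, mt_level = cl$mt_level,
        runner_up_level = cl$runner_up_level,
        margin_satisfied = cl$margin_satisfied, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect alternative-major-transcript (AMT) genes
#'
#' A gene is AMT iff it has a confident MT in both conditions and the two
#' identities differ. Genes lacking a confident MT in either condition are
#' reported as indeterminate and take part in neither the AMT nor the
#' MT-constant group.
#'
#' @param mt_calls output of [call_major_transcripts()] for two conditions.
#' @return list with `amt` (data.frame gene_id, mt_condition1,
#'   mt_condition2), `constant` (gene ids), `indeterminate` (gene ids) and
#'   `conditions` (the two labels, in call order).
#' @export
detect_amt <- function(mt_calls) {
  conds <- unique(mt_calls$condition)
  if (length(conds) != 2L) stop("expected MT calls for exactly two conditions")
  c1 <- mt_calls[mt_calls$condition == conds[1], ]
  c2 <- mt_calls[mt_calls$condition == conds[2], ]
  genes <- intersect(c1$gene_id, c2$gene_id)
  m1 <- c1$mt_id[match(genes, c1$gene_id)]
  m2 <- c2$mt_id[match(genes, c2$gene_id)]
  ind <- is.na(m1) | is.na(m2)
  amt <- !ind & m1 != m2
  list(
    amt = data.frame(gene_id = genes[amt], mt_condition1 = m1[amt],
                     mt_condition2 = m2[amt], stringsAsFactors = FALSE),
    constant = genes[!ind & m1 == m2],
    indeterminate = genes[ind],
    conditions = conds
  )
}

CHANGE_BINS <- c("0-50%", "50-100%", "100-200%", ">200%")

change_category <- function(ratio) {
  a <- abs(ratio)
  cut(a, breaks = c(0, 0.5, 1, 2, Inf), labels = CHANGE_BINS,
      right = FALSE, include.lowest = FALSE)
}

#' Expression-change categories for AMT vs MT-constant genes
#'
#' The relative change (E2 - E1)/E1 of gene-level expression is computed per
#' gene and its absolute value binned into 0-50%, 50-100%, 100-200% and
#' >200% (half-open bins). The two per-group distributions are compared with
#' a chi-square homogeneity test.
#'
#' @param amt_result output of [detect_amt()].
#' @param gene_expr features x 2 matrix of per-condition gene-level mean
#'   expression (column order = condition order of the AMT result).
#' @return list: `table` (bins x group counts), `per_gene` (gene, group,
#'   ratio, category), `chisq_p`, `n_excluded_zero_baseline`.
#' @export
categorize_change <- function(amt_result, gene_expr) {
  groups <- list(AMT = amt_result$amt$gene_id, constant = amt_result$constant)
  per <- list()
  excluded <- 0L
  for (gname in names(groups)) {
    g <- intersect(groups[[gname]], rownames(gene_expr))
    e1 <- gene_expr[g, 1]
    e2 <- gene_expr[g, 2]
    zero <- e1 == 0
    excluded <- excluded + sum(zero)
    g <- g[!zero]; e1 <- e1[!zero]; e2 <- e2[!zero]
    if (length(g) == 0L) next
    ratio <- (e2 - e1) / e1
    per[[gname]] <- data.frame(gene_id = g, group = gname, ratio = ratio,
                               category = change_category(ratio),
                               stringsAsFactors = FALSE)
  }
  per_gene <- do.call(rbind, per)
  rownames(per_gene) <- NULL
  tab <- table(per_gene$category, per_gene$group)
  chisq_p <- if (ncol(tab) == 2L && all(colSums(tab) > 0)) {
    suppressWarnings(stats::chisq.test(tab)$p.value)
  } else NA_real_
  list(table = tab, per_gene = per_gene, chisq_p = chisq_p,
       n_excluded_zero_baseline = excluded)
}

#' Intersect AMT genes with differential-expression calls
#'
#' @param amt_genes character vector of AMT gene ids.
#' @param de_calls data.frame from [nb_wald_test()] with columns gene_id and
#'   direction.
#' @return list: `de_amt` (data.frame gene_id, direction), `n_up`, `n_down`,
#'   `venn` (amt_only, deg_only, both).
#' @export
intersect_deg <- function(amt_genes, de_calls) {
  deg <- de_calls[de_calls$direction %in% c("up", "down"), , drop = FALSE]
  both <- intersect(amt_genes, deg$gene_id)
  de_amt <- deg[match(both, deg$gene_id), c("gene_id", "direction")]
  rownames(de_amt) <- NULL
  list(
    de_amt = de_amt,
    n_up = sum(de_amt$direction == "up"),
    n_down = sum(de_amt$direction == "down"),
    venn = c(amt_only = length(setdiff(amt_genes, deg$gene_id)),
             deg_only = length(setdiff(deg$gene_id, amt_genes)),
             both = length(both))
  )
}
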