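#!/usr/bin/env Rscript
# Stage 4: expression filtering, NB Wald differential expression, major
# transcripts, AMT switching, change categories and the DE-AMT overlap.
source("analysis/00_config.R")

obs <- read_annotation(file.path(SIM_DIR, "observed.gtf"), "observed")
calls <- utils::read.delim(file.path(OUT_DIR, "structural_calls.tsv"))
tx2gene <- stats::setNames(calls$assigned_gene_id, calls$transcript_id)
design <- unlist(yaml::read_yaml(file.path(SIM_DIR, "design.yaml")))
len <- utils::read.delim(file.path(SIM_DIR, "lengths.tsv"))
counts <- read_expression(file.path(SIM_DIR, "counts.tsv"), design,
                          feature_lengths = stats::setNames(len$length,
                                                            len$transcript_id))
truth <- utils::read.delim(file.path(SIM_DIR, "truth_genes.tsv"))

gene_counts <- rollup_gene_counts(counts, tx2gene)
kept <- filter_cpm(gene_counts)
de <- nb_wald_test(subset_expression(gene_counts, kept))
tsv(de, "de_calls.tsv")

tx_fpkm <- compute_fpkm(counts)
kept_tx <- filter_cpm(counts)
mt <- call_major_transcripts(subset_expression(tx_fpkm, kept_tx), tx2gene)
amt <- detect_amt(mt)
tsv(mt, "mt_calls.tsv")
tsv(amt$amt, "amt_genes.tsv")

gene_fpkm <- condition_means(compute_fpkm(gene_counts))
change <- categorize_change(amt, gene_fpkm)
tsv(as.data.frame.matrix(change$table), "change_categories.tsv")
dea <- intersect_deg(amt$amt$gene_id, de)
tsv(dea$de_amt, "de_amt.tsv")

tru <- truth$gene_id[truth$amt]
cat(sprintf("DEGs: %d (%d up / %d down); AMT genes: %d (recall vs truth %.2f)\n",
            sum(de$direction != "nodiff"), sum(de$direction == "up"),
            sum(de$direction == "down"), nrow(amt$amt),
            length(intersect(amt$amt$gene_id, tru)) / max(1, length(tru))))
cat(sprintf("DE-AMT: %d (%d up / %d down); change-category chi-square p = %.3g\n",
            nrow(dea$de_amt), dea$n_up, dea$n_down, change$chisq_p))
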