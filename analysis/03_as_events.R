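#!/usr/bin/env Rscript
# Stage 3: alternative-splicing events on the classified catalog, per-gene
# AS profiles, and transcript-diversity correlations.
source("analysis/00_config.R")

ref <- read_annotation(file.path(SIM_DIR, "reference.gtf"), "reference")
obs <- read_annotation(file.path(SIM_DIR, "observed.gtf"), "observed")
calls <- utils::read.delim(file.path(OUT_DIR, "structural_calls.tsv"))
obs$transcripts$gene_id <- calls$assigned_gene_id[
  match(obs$transcripts$transcript_id, calls$transcript_id)]

events <- detect_as_events(obs)
prof <- profile_as_genes(events)
tsv(events, "as_events.tsv")
tsv(prof$profiles, "gene_as_profiles.tsv")
tsv(data.frame(type = names(prof$type_counts), count = prof$type_counts,
               pct = report_percent(prof$type_counts, prof$n_events)),
    "as_summary.tsv")

design <- unlist(yaml::read_yaml(file.path(SIM_DIR, "design.yaml")))
len <- utils::read.delim(file.path(SIM_DIR, "lengths.tsv"))
counts <- read_expression(file.path(SIM_DIR, "counts.tsv"), design,
                          feature_lengths = stats::setNames(len$length,
                                                            len$transcript_id))
gene_fpkm <- compute_fpkm(rollup_gene_counts(
  counts, stats::setNames(obs$transcripts$gene_id,
                          obs$transcripts$transcript_id)))
corr <- correlate_diversity(obs, rowMeans(gene_fpkm$values))
tsv(corr, "diversity_correlations.tsv")

cat(sprintf("%d typed AS events in %d genes; ES %.1f%%, IR %.1f%%\n",
            prof$n_events, prof$n_genes, prof$type_proportions["ES"],
            prof$type_proportions["IR"]))
cat(sprintf("transcripts-vs-exons r = %.2f (n=%d)\n",
            corr$r[corr$stratum == "tx_vs_exons"],
            corr$n[corr$stratum == "tx_vs_exons"]))
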