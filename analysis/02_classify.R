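#!/usr/bin/env Rscript
# Stage 2: classify observed transcript models against the reference into
# the eight structural categories and summarise the catalog; check recovery
# against the planted labels.
source("analysis/00_config.R")

ref <- read_annotation(file.path(SIM_DIR, "reference.gtf"), "reference")
obs <- read_annotation(file.path(SIM_DIR, "observed.gtf"), "observed")
truth <- utils::read.delim(file.path(SIM_DIR, "truth_transcripts.tsv"))

calls <- classify_transcripts(obs, ref)
tsv(calls, "structural_calls.tsv")
s <- summarize_catalog(calls, obs)
tsv(data.frame(metric = c("n_transcripts", "n_known", "n_novel",
                          "pct_known", "pct_novel", "n_genes",
                          "n_novel_genes", "genes_multi_isoform"),
               value = c(s$n_transcripts, s$n_known, s$n_novel,
                         report_percent(s$n_known, s$n_transcripts),
                         report_percent(s$n_novel, s$n_transcripts),
                         s$n_genes, s$n_novel_genes,
                         s$genes_with_multiple_isoforms)),
    "catalog_summary.tsv")

rec <- mean(calls$category[match(truth$transcript_id, calls$transcript_id)] ==
              truth$category)
cat(sprintf("catalog: %d transcripts, %.2f%% novel; category recovery vs truth %.1f%%\n",
            s$n_transcripts, report_percent(s$n_novel, s$n_transcripts),
            100 * rec))
print(table(calls$category))
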