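#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-stage spleen-style dataset: a
# multi-isoform reference annotation with tandem PASs and planted AATAAA
# signals, an observed long-read catalog covering all eight structural
# categories, and NB counts for 2 conditions x 3 replicates with planted
# MT switches, DE genes and mPAS shifts.
source("analysis/00_config.R")

sim <- simulate_dataset(CFG, seed = SEED)
dir.create(SIM_DIR, recursive = TRUE, showWarnings = FALSE)

write_annotation(sim$reference$annotation, file.path(SIM_DIR, "reference.gtf"))
write_annotation(sim$observed$annotation, file.path(SIM_DIR, "observed.gtf"))
Biostrings::writeXStringSet(sim$reference$genome,
                            file.path(SIM_DIR, "genome.fa"))

counts <- sim$expression$counts
tab <- data.frame(transcript_id = rownames(counts$values), counts$values,
                  check.names = FALSE)
tsv(tab, "counts.tsv", SIM_DIR)
yaml::write_yaml(as.list(counts$design), file.path(SIM_DIR, "design.yaml"))
tsv(data.frame(transcript_id = names(counts$feature_lengths),
               length = counts$feature_lengths), "lengths.tsv", SIM_DIR)

tsv(sim$observed$truth, "truth_transcripts.tsv", SIM_DIR)
tsv(sim$expression$truth_gene, "truth_genes.tsv", SIM_DIR)
tsv(sim$expression$truth_apa, "truth_apa.tsv", SIM_DIR)
tsv(sim$reference$pas_table, "truth_pas.tsv", SIM_DIR)

cat(sprintf("simulated %d reference transcripts over %d genes; %d observed models; seed %d\n",
            n_transcripts(sim$reference$annotation), CFG$n_genes,
            n_transcripts(sim$observed$annotation), SEED))
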