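#!/usr/bin/env Rscript
# Stage 5: PAS clustering, APA gene calls, distal/proximal (M/P) status,
# major-PAS shifts, poly(A)-signal hexamers and 3'-UTR lengths.
source("analysis/00_config.R")

obs <- read_annotation(file.path(SIM_DIR, "observed.gtf"), "observed")
calls <- utils::read.delim(file.path(OUT_DIR, "structural_calls.tsv"))
obs$transcripts$gene_id <- calls$assigned_gene_id[
  match(obs$transcripts$transcript_id, calls$transcript_id)]
# read support round-trips through the truth table (GTF carries no support)
truth_tx <- utils::read.delim(file.path(SIM_DIR, "truth_transcripts.tsv"))
obs$transcripts$read_support <- truth_tx$read_support[
  match(obs$transcripts$transcript_id, truth_tx$transcript_id)]
design <- unlist(yaml::read_yaml(file.path(SIM_DIR, "design.yaml")))
len <- utils::read.delim(file.path(SIM_DIR, "lengths.tsv"))
counts <- read_expression(file.path(SIM_DIR, "counts.tsv"), design,
                          feature_lengths = stats::setNames(len$length,
                                                            len$transcript_id))
genome <- Biostrings::readDNAStringSet(file.path(SIM_DIR, "genome.fa"))
names(genome) <- sub(" .*", "", names(genome))
truth <- utils::read.delim(file.path(SIM_DIR, "truth_genes.tsv"))

keep <- calls$transcript_id[calls$category %in% c("FSM", "ISM", "NIC", "NNC")]
pas_obs <- subset_transcripts(obs, keep)
cl <- cluster_pas(pas_obs, tx_expr = compute_fpkm(counts))
apa <- call_apa_genes(cl)
conds <- unique(unname(design))
apa <- classify_mp(apa, cl, conds)
mpas <- call_mpas(apa, cl, conds)
hex <- scan_pas_signal(genome, cl)
tsv(cl, "pas_clusters.tsv")
tsv(apa, "apa_genes.tsv")
tsv(mpas, "mpas_shifts.tsv")
tsv(hex$table, "hexamer_table.tsv")
u <- utr3_length_distribution(obs, genome, ids = keep, min_aa = 150)
tsv(u$histogram, "utr3_histogram.tsv")

s <- merge(mpas, truth[, c("gene_id", "mpas_shift")], by = "gene_id")
for (i in 1:2) {
  st <- apa[[paste0("mp_status_", conds[i])]]
  cat(sprintf("%s: %d M genes, %d P genes (M:P = %.2f)\n", conds[i],
              sum(st == "M"), sum(st == "P"),
              sum(st == "M") / max(1, sum(st == "P"))))
}
cat(sprintf("APA genes: %d; mPAS shifts: %d (agreement vs truth %.2f); AATAAA rank %d\n",
            nrow(apa), sum(mpas$mpas_shift %in% TRUE),
            mean(s$mpas_shift.x == s$mpas_shift.y, na.rm = TRUE),
            hex$aataaa_rank))
cat(sprintf("3'-UTR histogram mode bin: %d bp\n", u$mode_bin))
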