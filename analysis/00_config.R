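# shared settings for the analysis drivers; run the scripts in order from
# the repository root:  Rscript analysis/01_simulate.R  etc.
suppressMessages(library(txdiversity))

SEED <- as.integer(Sys.getenv("TXDIV_SEED", "1"))
SIM_DIR <- "results/sim"
OUT_DIR <- "results"
CFG <- sim_config(n_genes = 200, n_observed = 800, rng_seed = SEED)

tsv <- function(x, name, dir = OUT_DIR) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file.path(dir, name))
}
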