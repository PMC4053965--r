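# Shared configuration for the analysis workflow.  Each numbered script
# sources this file, then reads its inputs from results/ and writes its
# outputs back there, so any stage can be rerun in isolation.

library(splicewatch)

RESULTS_DIR <- file.path("results")
DATA_DIR <- file.path(RESULTS_DIR, "data")
TABLE_DIR <- file.path(RESULTS_DIR, "tables")
dir.create(DATA_DIR, showWarnings = FALSE, recursive = TRUE)
dir.create(TABLE_DIR, showWarnings = FALSE, recursive = TRUE)

# Study-condition defaults: 101 nt reads, retention fraction 0.15,
# alternative-site offsets within +/-2..10 nt, singleton short-overhang
# decoys.  Scaled to desk size: 80 genes, 40k reads per library.
SIM <- sim_config(n_genes = 80L, library_depth = 40000L, seed = 20240101L)

CONDITIONS <- list(
  WT = list(),
  MUT = list(n_ir = 8L, n_alt5 = 6L, n_alt3 = 6L, n_skip = 6L,
             coordination_rate = 0.5))

RUN <- run_config(sim = SIM, conditions = CONDITIONS)

FILTER <- RUN$filter
IR <- RUN$ir
N_RESAMPLE <- RUN$n_resample

data_path <- function(...) file.path(DATA_DIR, ...)
table_path <- function(...) file.path(TABLE_DIR, ...)
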