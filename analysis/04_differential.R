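#!/usr/bin/env Rscript
# Stage 4 — differential splicing between the baseline (first) condition
# and each other condition: per-event and per-intron Fisher tests with the
# assigned-zero unique-event rule, plus the global per-type comparison.

source(file.path("analysis", "00_config.R"))

ann <- read_annotation_gff3(data_path("annotation.gff3"))
ev_all <- read_tsv(table_path("events.tsv"))
ir_all <- read_tsv(table_path("ir_calls.tsv"))

load_resampled <- function(cn) {
  al <- read_sam(data_path(paste0(cn, ".sam")))
  keep_ids <- read_tsv(data_path(paste0(cn, ".resampled_reads.tsv")))$read_id
  al[al$read_id %in% keep_ids, ]
}

base <- names(CONDITIONS)[1]
al_base <- load_resampled(base)
de_all <- list(); di_all <- list(); gc_all <- list()
for (cn in names(CONDITIONS)[-1]) {
  al_b <- load_resampled(cn)
  de <- test_events(ev_all[ev_all$condition == base, ],
                    ev_all[ev_all$condition == cn, ],
                    al_base, al_b, ann, alpha = RUN$alpha_as)
  de$contrast <- paste0(base, "_vs_", cn)
  de_all[[cn]] <- de
  di <- test_introns(ir_all[ir_all$condition == base, ],
                     ir_all[ir_all$condition == cn, ],
                     alpha = RUN$alpha_ir)
  di$contrast <- paste0(base, "_vs_", cn)
  di_all[[cn]] <- di
  gc_ <- global_comparison(ev_all[ev_all$condition == base, ],
                           ev_all[ev_all$condition == cn, ],
                           N_RESAMPLE, N_RESAMPLE)
  gc_$contrast <- paste0(base, "_vs_", cn)
  gc_all[[cn]] <- gc_
  message(base, " vs ", cn, ": ", sum(de$significant), "/", nrow(de),
          " events and ", sum(di$significant), "/", nrow(di),
          " introns significant")
}
write_tsv(do.call(rbind, de_all), table_path("differential_events.tsv"))
write_tsv(do.call(rbind, di_all), table_path("differential_introns.tsv"))
write_tsv(do.call(rbind, gc_all), table_path("global_comparison.tsv"))
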