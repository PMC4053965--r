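#!/usr/bin/env Rscript
# Stage 3 — alternative-splicing event classification and intron-retention
# calling per condition, on the equal-depth resamples of stage 2.

source(file.path("analysis", "00_config.R"))

ann <- read_annotation_gff3(data_path("annotation.gff3"))
jc <- read_tsv(table_path("junctions.tsv"))

events <- list(); ircalls <- list()
for (cn in names(CONDITIONS)) {
  al <- read_sam(data_path(paste0(cn, ".sam")))
  keep_ids <- read_tsv(data_path(paste0(cn, ".resampled_reads.tsv")))$read_id
  al <- al[al$read_id %in% keep_ids, ]

  kept <- jc[jc$condition == cn & jc$kept, ]
  ev <- classify_events(kept, ann)
  events[[cn]] <- tag_condition(ev, cn)

  ir <- call_intron_retention(al, ann, IR)
  ircalls[[cn]] <- tag_condition(ir, cn)
  message(cn, ": ", nrow(ev), " events (",
          paste(sprintf("%s=%d", names(table(ev$event_type)),
                        as.integer(table(ev$event_type))), collapse = ", "),
          "), ", sum(ir$called), " retained introns")
}
write_tsv(do.call(rbind, events), table_path("events.tsv"))
write_tsv(do.call(rbind, ircalls), table_path("ir_calls.tsv"))
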