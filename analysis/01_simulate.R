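#!/usr/bin/env Rscript
# Stage 1 — simulate the synthetic study: genome, annotation, per-condition
# isoform pools with planted events, read libraries and decoy reads.
# Writes FASTA / GFF3 / SAM / FASTQ plus the ground-truth ledger.

source(file.path("analysis", "00_config.R"))

ga <- make_genome_and_annotation(SIM)
write_genome_fasta(ga$genome, data_path("genome.fa"))
write_annotation_gff3(ga$annotation, data_path("annotation.gff3"))

ledgers <- list()
for (i in seq_along(CONDITIONS)) {
  cn <- names(CONDITIONS)[i]
  prof <- do.call(make_condition_profile, c(
    list(annotation = ga$annotation, config = SIM,
         seed = derive_seed(RUN$seed, 10L + i)),
    CONDITIONS[[cn]]))
  iso <- simulate_isoforms(ga$annotation, SIM, prof, condition = cn)
  rd <- simulate_reads(ga$genome, iso$pool, SIM, lib_name = cn,
                       seed = derive_seed(RUN$seed, 20L + i))
  write_sam(rd$alignments, data_path(paste0(cn, ".sam")), ga$genome, rd$reads)
  write_reads_fastq(rd$reads[, c("read_id", "seq")],
                    data_path(paste0(cn, ".fastq")))
  ledgers[[cn]] <- iso$ledger
  message(cn, ": ", length(unique(rd$reads$read_id)), " reads, ",
          nrow(iso$ledger), " planted events")
}
write_tsv(do.call(rbind, ledgers), table_path("ledger.tsv"))

decoys <- make_decoy_reads(ga$genome, ga$annotation, SIM)
write_reads_fastq(decoys$reads, data_path("decoys.fastq"))
write_tsv(decoys$truth, table_path("decoy_truth.tsv"))
message("wrote ", nrow(decoys$reads), " decoy reads")
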