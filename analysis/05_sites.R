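#!/usr/bin/env Rscript
# Stage 5 — splice-site sequence matrices, alternative-site offset
# distribution, and the skipping / alternative-site coordination test.

source(file.path("analysis", "00_config.R"))

genome <- read_genome_fasta(data_path("genome.fa"))
ann <- read_annotation_gff3(data_path("annotation.gff3"))
ev_all <- read_tsv(table_path("events.tsv"))

pfm_df <- function(p) {
  d <- as.data.frame(t(p$counts))
  cbind(position = as.integer(rownames(d)), d, row.names = NULL)
}
don <- extract_site_matrix(genome, site_table(ann, "donor"),
                           window = 10L, site_kind = "donor")
acc <- extract_site_matrix(genome, site_table(ann, "acceptor"),
                           window = 10L, site_kind = "acceptor")
write_tsv(pfm_df(don), table_path("donor_pfm.tsv"))
write_tsv(pfm_df(acc), table_path("acceptor_pfm.tsv"))
message("donor +1/+2 GT purity: ",
        (don$counts["G", "1"] + don$counts["T", "2"]) / (2 * don$n_sequences))

od <- offset_distribution(ev_all)
write_tsv(od$histogram, table_path("offsets.tsv"))
message(sprintf("offset mass within +/-10 nt: %.3f", od$prop_within_10))

coord <- coordination_test(ev_all, ann)
if (!is.null(coord)) {
  write_tsv(data.frame(observed_fraction = coord$observed_fraction,
                       background_fraction = coord$background_fraction,
                       p_value = coord$p_value),
            table_path("coordination.tsv"))
  message(sprintf(
    "alt-site rate: %.3f among skipped exons vs %.3f background (p = %.3g)",
    coord$observed_fraction, coord$background_fraction, coord$p_value))
}
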