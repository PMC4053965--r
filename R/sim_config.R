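#' Simulation configuration
#'
#' Parameters of the synthetic RNA-seq generator.  Defaults emulate the
#' study conditions the pipeline is calibrated for: fixed-length single-end
#' reads (101 nt), a wild-type condition dominated by annotated splicing,
#' and perturbed conditions with planted intron retention at a per-intron
#' retention fraction of 0.15, alternative 5'/3' splice sites offset within
#' 10 bp of the dominant sites, and exon-skipping isoforms, plus decoy
#' junction-spanning reads with short overhangs and singleton support to
#' exercise the false-positive filter.
#'
#' @param n_chromosomes number of chromosomes (>= 2 so cross-chromosome
#'   decoy junctions exist)
#' @param n_genes total genes, distributed round-robin over chromosomes
#'   with alternating strand
#' @param exons_per_gene integer range c(lo, hi)
#' @param exon_len exon length range in nt
#' @param intron_len intron length range in nt (minimum 20 so the 50%
#'   coverage rule for intron retention is meaningful on toy data)
#' @param read_length read length in nt; 101 and 85 are the library designs
#'   emulated, any value >= 30 is accepted
#' @param library_depth reads per simulated library
#' @param error_rate per-base substitution probability on raw read
#'   sequences (alignments are truth-derived and never perturbed)
#' @param ir_fraction probability that a transcript of a targeted gene
#'   retains the targeted intron
#' @param alt_ss_offset_range magnitude range of alternative splice-site
#'   offsets in nt; offsets are drawn uniformly from the signed window
#'   (-hi..-lo, lo..hi)
#' @param alt_ss_usage usage fraction of a planted alternative-splice-site
#'   isoform
#' @param skip_usage usage fraction of a planted exon-skipping isoform
#' @param decoy_read_count number of decoy junction-spanning reads
#' @param decoy_overhang_range overhang range of decoy reads (kept at or
#'   below 15 nt, and at least the 11 nt matcher anchor, so decoys register
#'   with the matcher yet fail the >20 bp filter)
#' @param decoy_singleton logical; one read per decoy junction (mimicking
#'   the dominance of single-read support among false positives)
#' @param intergenic_len range of intergenic gap lengths in nt
#' @param cds_offset transcript coordinate (0-based) of the translation
#'   start used by the frame-impact classifier
#' @param seed integer seed; all generator output is byte-reproducible
#'   under it
#' @return an object of class `sim_config` (a validated list)
#' @export
sim_config <- function(n_chromosomes = 2L,
                       n_genes = 20L,
                       exons_per_gene = c(3L, 5L),
                       exon_len = c(100L, 250L),
                       intron_len = c(60L, 150L),
                       read_length = 101L,
                       library_depth = 50000L,
                       error_rate = 0.001,
                       ir_fraction = 0.15,
                       alt_ss_offset_range = c(2L, 10L),
                       alt_ss_usage = 0.3,
                       skip_usage = 0.3,
                       decoy_read_count = 100L,
                       decoy_overhang_range = c(11L, 15L),
                       decoy_singleton = TRUE,
                       intergenic_len = c(100L, 300L),
                       cds_offset = 12L,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    n_genes = as.integer(n_genes),
    exons_per_gene = check_range(exons_per_gene, "exons_per_gene"),
    exon_len = check_range(exon_len, "exon_len"),
    intron_len = check_range(intron_len, "intron_len"),
    read_length = as.integer(read_length),
    library_depth = as.integer(library_depth),
    error_rate = stop_if_not_scalar_prob(error_rate, "error_rate"),
    ir_fraction = stop_if_not_scalar_prob(ir_fraction, "ir_fraction"),
    alt_ss_offset_range = check_range(alt_ss_offset_range, "alt_ss_offset_range"),
    alt_ss_usage = stop_if_not_scalar_prob(alt_ss_usage, "alt_ss_usage"),
    skip_usage = stop_if_not_scalar_prob(skip_usage, "skip_usage"),
    decoy_read_count = as.integer(decoy_read_count),
    decoy_overhang_range = check_range(decoy_overhang_range, "decoy_overhang_range"),
    decoy_singleton = isTRUE(decoy_singleton),
    intergenic_len = check_range(intergenic_len, "intergenic_len"),
    cds_offset = as.integer(cds_offset),
    seed = as.integer(seed)
  )
  if (cfg$read_length < 30L)
    stop("read_length must be >= 30", call. = FALSE)
  if (cfg$intron_len[1] < 20L)
    stop("intron_len minimum must be >= 20", call. = FALSE)
  if (cfg$n_chromosomes < 1L || cfg$n_genes < 1L)
    stop("n_chromosomes and n_genes must be positive", call. = FALSE)
  if (cfg$alt_ss_offset_range[1] < 1L)
    stop("alt_ss_offset_range magnitudes must be >= 1", call. = FALSE)
  class(cfg) <- c("sim_config", "list")
  cfg
}
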