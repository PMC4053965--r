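# Shared fixtures, built once per test run and cached.  Everything is
# generated in code under fixed seeds; no data files are shipped.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, builder(), envir = .fixture_cache)
  .fixture_cache[[name]]
}

# A hand-specified two-gene annotation (one gene per strand) with round
# coordinates, for arithmetic-exact unit tests.
#
# g1 (+, chrA): exons [100,200) [300,400) [500,600)
#   introns: [200,300) rank 1, [400,500) rank 2
# g2 (-, chrB): exons [1000,1100) [1200,1300) [1400,1500)
#   introns (transcribed ranks reversed): [1300,1400) rank 1, [1100,1200) rank 2
toy_annotation <- function() {
  genes <- data.frame(
    gene_id = c("g1", "g2"), chrom = c("chrA", "chrB"),
    strand = c("+", "-"), start = c(100L, 1000L), end = c(600L, 1500L),
    cds_offset = 12L, stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = rep(c("g1", "g2"), each = 3L),
    chrom = rep(c("chrA", "chrB"), each = 3L),
    strand = rep(c("+", "-"), each = 3L),
    start = c(100L, 300L, 500L, 1000L, 1200L, 1400L),
    end = c(200L, 400L, 600L, 1100L, 1300L, 1500L),
    stringsAsFactors = FALSE)
  ann <- list(genes = genes, exons = exons)
  ann$exons <- splicewatch:::exons_transcribed(ann)
  class(ann) <- c("sw_annotation", "list")
  ann
}

# Small simulated world shared by many unit tests: 12 genes, a wild-type
# library and a perturbed library with every event type planted.
small_world <- function() fixture("small_world", function() {
  cfg <- sim_config(n_genes = 12L, library_depth = 6000L, seed = 7L)
  ga <- make_genome_and_annotation(cfg)
  prof <- make_condition_profile(ga$annotation, cfg, n_ir = 2L, n_alt5 = 2L,
                                 n_alt3 = 2L, n_skip = 2L,
                                 seed = derive_seed(cfg$seed, 11L))
  iso_wt <- simulate_isoforms(ga$annotation, cfg, NULL, condition = "WT")
  iso_mut <- simulate_isoforms(ga$annotation, cfg, prof, condition = "MUT")
  rd_wt <- simulate_reads(ga$genome, iso_wt$pool, cfg, lib_name = "WT",
                          seed = derive_seed(cfg$seed, 21L))
  rd_mut <- simulate_reads(ga$genome, iso_mut$pool, cfg, lib_name = "MUT",
                           seed = derive_seed(cfg$seed, 22L))
  list(cfg = cfg, genome = ga$genome, annotation = ga$annotation,
       profile = prof, iso_wt = iso_wt, iso_mut = iso_mut,
       rd_wt = rd_wt, rd_mut = rd_mut)
})

# Independent brute-force junction-reference matcher: all-offset substring
# scanning, used as an oracle for match_reads_to_refs().
brute_force_match <- function(reads, refs, min_anchor = 11L) {
  out <- list()
  for (i in seq_len(nrow(refs))) {
    ref <- refs$sequence[i]
    flank <- refs$flank[i]
    for (r in seq_len(nrow(reads))) {
      sq <- reads$seq[r]
      if (grepl("[^ACGT]", sq)) next
      L <- nchar(sq)
      best <- NA_integer_
      for (p in 0:(nchar(ref) - L)) {
        if (substring(ref, p + 1L, p + L) != sq) next
        left <- flank - p
        right <- p + L - flank
        if (left >= min_anchor && right >= min_anchor)
          best <- max(best, min(left, right), na.rm = TRUE)
      }
      if (!is.na(best))
        out[[length(out) + 1L]] <- data.frame(
          ref_id = refs$ref_id[i], read_id = reads$read_id[r],
          overhang = best, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(ref_id = character(), read_id = character(),
               overhang = integer(), stringsAsFactors = FALSE)
}

# Independent two-sided Fisher p-value by direct enumeration of the
# hypergeometric support with lchoose (no dhyper), matching the published
# rule: sum the probabilities of all tables with the observed margins whose
# probability does not exceed the observed table's (relative tolerance
# 1e-7).
enum_fisher <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c; N <- m1 + m2
  if (m1 == 0L || m2 == 0L || k == 0L || (b + d) == 0L) return(1)
  xs <- max(0L, k - m2):min(k, m1)
  lp <- lchoose(m1, xs) + lchoose(m2, k - xs) - lchoose(N, k)
  p <- exp(lp)
  p_obs <- p[xs == a]
  sum(p[p <= p_obs * (1 + 1e-7)])
}
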