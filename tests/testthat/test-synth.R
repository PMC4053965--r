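test_that("generated introns all carry GT/AG on the transcribed strand", {
  w <- small_world()
  introns <- annotation_introns(w$annotation)
  for (r in seq_len(nrow(introns))) {
    s <- splicewatch:::genome_seq(w$genome, introns$chrom[r], introns$start[r],
                                  introns$end[r], introns$strand[r])
    expect_identical(substring(s, 1L, 2L), "GT")
    expect_identical(substring(s, nchar(s) - 1L, nchar(s)), "AG")
  }
})

test_that("genome generation is deterministic under the seed", {
  cfg <- sim_config(n_genes = 4L, seed = 99L)
  a <- make_genome_and_annotation(cfg)
  b <- make_genome_and_annotation(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$annotation$exons, b$annotation$exons)
})

test_that("exons lie inside their gene and do not overlap", {
  w <- small_world()
  ex <- w$annotation$exons
  g <- w$annotation$genes
  for (gid in g$gene_id) {
    gx <- ex[ex$gene_id == gid, ]
    gx <- gx[order(gx$start), ]
    expect_true(all(gx$start >= g$start[g$gene_id == gid]))
    expect_true(all(gx$end <= g$end[g$gene_id == gid]))
    if (nrow(gx) > 1L)
      expect_true(all(gx$start[-1L] > gx$end[-nrow(gx)]))
  }
})

test_that("isoform weights per gene sum to one and ledger matches the pool", {
  w <- small_world()
  pool <- w$iso_mut$pool
  sums <- tapply(pool$weight, pool$gene_id, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)))
  led <- w$iso_mut$ledger
  led_counts <- table(led$event_type)
  expect_identical(as.integer(led_counts[c("ALT3SS", "ALT5SS", "CASSETTE",
                                           "IR")]), rep(2L, 4L))
  # every planted isoform in the pool has a ledger row for its gene/type
  planted <- pool[pool$event_type != "annotated", ]
  expect_true(all(paste(planted$gene_id, planted$event_type) %in%
                    paste(led$gene_id, led$event_type)))
})

test_that("planted events reshape exon blocks as specified", {
  blocks <- data.frame(start = c(100L, 300L, 500L), end = c(200L, 400L, 600L))
  # intron retention on intron 1 (+): exons 1 and 2 merge over [200,300)
  ir <- splicewatch:::apply_event(blocks, "+", "IR", 1L, NA_integer_)
  expect_identical(ir$blocks$start, c(100L, 500L))
  expect_identical(ir$blocks$end, c(400L, 600L))
  expect_identical(ir$junction, c(200L, 300L))
  # ALT5SS +6 on intron 1 (+): donor moves downstream (genomic right)
  a5 <- splicewatch:::apply_event(blocks, "+", "ALT5SS", 1L, 6L)
  expect_identical(a5$junction, c(206L, 300L))
  # on the minus strand the same transcribed intron 1 is the genomic last
  # gap and downstream is genomic left
  a5m <- splicewatch:::apply_event(blocks, "-", "ALT5SS", 1L, 6L)
  expect_identical(a5m$junction, c(400L, 494L))
  # ALT3SS -4 on intron 2 (+): acceptor moves upstream
  a3 <- splicewatch:::apply_event(blocks, "+", "ALT3SS", 2L, -4L)
  expect_identical(a3$junction, c(400L, 496L))
  # cassette on transcribed exon 2 joins the flanking exons
  cs <- splicewatch:::apply_event(blocks, "+", "CASSETTE", 2L, NA_integer_)
  expect_identical(cs$junction, c(200L, 500L))
  expect_identical(nrow(cs$blocks), 2L)
  expect_error(splicewatch:::apply_event(blocks, "+", "CASSETTE", 1L, NA),
               "internal")
})

test_that("error-free reads reproduce the isoform sequence at their window", {
  cfg <- sim_config(n_genes = 6L, library_depth = 300L, error_rate = 0,
                    seed = 13L)
  ga <- make_genome_and_annotation(cfg)
  iso <- simulate_isoforms(ga$annotation, cfg, NULL)
  rd <- simulate_reads(ga$genome, iso$pool, cfg, "t")
  expect_identical(nrow(rd$reads), 300L)
  expect_true(all(nchar(rd$reads$seq) == cfg$read_length))
  # reconstruct each read from its truth alignment blocks: the spliced
  # genome sequence in transcribed orientation must equal the read
  al <- split(rd$alignments, rd$alignments$read_id)
  set.seed(1)
  for (rid in sample(names(al), 25L)) {
    a <- al[[rid]]
    a <- a[order(a$block_start), ]
    s <- splicewatch:::spliced_seq(ga$genome, a$chrom[1], a$block_start,
                                   a$block_end, a$strand[1])
    expect_identical(s, rd$reads$seq[rd$reads$read_id == rid])
  }
})

test_that("read block widths always sum to the read length", {
  w <- small_world()
  al <- w$rd_wt$alignments
  widths <- tapply(al$block_end - al$block_start, al$read_id, sum)
  expect_true(all(widths == w$cfg$read_length))
})

test_that("decoy reads join flanks from two different chromosomes", {
  w <- small_world()
  dec <- make_decoy_reads(w$genome, w$annotation, w$cfg)
  expect_identical(nrow(dec$reads), w$cfg$decoy_read_count)
  expect_true(all(dec$truth$donor_chrom != dec$truth$acceptor_chrom))
  expect_true(all(dec$truth$overhang >= w$cfg$decoy_overhang_range[1]))
  expect_true(all(dec$truth$overhang <= w$cfg$decoy_overhang_range[2]))
  # singleton mode: one read per reference
  expect_identical(anyDuplicated(dec$truth$ref_id), 0L)
})

test_that("derive_seed stays within 32-bit range and separates stages", {
  s <- vapply(0:50, function(k) derive_seed(123456L, k), integer(1))
  expect_true(all(s >= 0) && all(s < 2^31))
  expect_identical(anyDuplicated(s), 0L)
  expect_identical(derive_seed(5L, 3L), derive_seed(5L, 3L))
})
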