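test_that("equal-depth resampling is exact, without replacement, and seeded", {
  w <- small_world()
  al <- w$rd_wt$alignments
  r1 <- resample_alignments(al, 500L, seed = 4L)
  r2 <- resample_alignments(al, 500L, seed = 4L)
  r3 <- resample_alignments(al, 500L, seed = 5L)
  expect_identical(length(unique(r1$read_id)), 500L)
  expect_identical(r1, r2)
  expect_false(identical(r1$read_id, r3$read_id))
  expect_true(all(r1$read_id %in% al$read_id))
  expect_error(resample_alignments(al, nrow(al) + 1e6, seed = 1L), "exceeds")
})

test_that("the assigned-zero rule governs condition-unique events", {
  base <- data.frame(gene_id = "g", chrom = "c", intron_start = 1L,
                     intron_end = 2L, stringsAsFactors = FALSE)
  run <- function(fa, fb, ea = 100L, eb = 100L) {
    tab <- cbind(base, focal_a = fa, focal_b = fb, exon_a = ea, exon_b = eb)
    splicewatch:::fisher_differential(tab, alpha = 0.001, min_unique = 5L)
  }
  # unique to B with >= 5 reads: p assigned 0, significant, flagged
  r <- run(0L, 5L)
  expect_true(r$assigned_zero)
  expect_identical(r$p_value, 0)
  expect_true(r$significant)
  expect_identical(r$direction, "B_over")
  # unique to B with 4 reads: computed p, not auto-significant
  r <- run(0L, 4L)
  expect_false(r$assigned_zero)
  expect_gt(r$p_value, 0)
  expect_false(r$significant)
  # present in both conditions: the rule never fires even at high counts
  r <- run(1L, 50L)
  expect_false(r$assigned_zero)
  expect_identical(r$p_value, fisher_2x2(c(1L, 100L, 50L, 100L)))
})

test_that("differential significance respects the alpha threshold", {
  base <- data.frame(gene_id = "g", chrom = "c", intron_start = 1L,
                     intron_end = 2L, stringsAsFactors = FALSE)
  tab <- cbind(base, focal_a = 2L, focal_b = 30L, exon_a = 200L, exon_b = 200L)
  p <- fisher_2x2(c(2L, 200L, 30L, 200L))
  strict <- splicewatch:::fisher_differential(tab, alpha = p / 2, min_unique = 5L)
  loose <- splicewatch:::fisher_differential(tab, alpha = p * 2, min_unique = 5L)
  expect_false(strict$significant)
  expect_true(loose$significant)
  expect_equal(strict$p_value, p)
})

test_that("direction labels are antisymmetric under condition swap", {
  base <- data.frame(gene_id = "g", chrom = "c", intron_start = 1L,
                     intron_end = 2L, stringsAsFactors = FALSE)
  fwd <- splicewatch:::fisher_differential(
    cbind(base, focal_a = 20L, focal_b = 3L, exon_a = 100L, exon_b = 100L),
    alpha = 0.01, min_unique = 5L)
  rev_ <- splicewatch:::fisher_differential(
    cbind(base, focal_a = 3L, focal_b = 20L, exon_a = 100L, exon_b = 100L),
    alpha = 0.01, min_unique = 5L)
  tie <- splicewatch:::fisher_differential(
    cbind(base, focal_a = 5L, focal_b = 5L, exon_a = 100L, exon_b = 100L),
    alpha = 0.01, min_unique = 5L)
  expect_identical(fwd$direction, "A_over")
  expect_identical(rev_$direction, "B_over")
  expect_identical(tie$direction, "none")
  expect_equal(fwd$p_value, rev_$p_value)
})

test_that("flanking-exon read counting picks the nearest exons", {
  ann <- toy_annotation()
  al <- rbind(
    data.frame(read_id = c("e1", "e2"), chrom = "chrA", strand = "+",
               block_start = c(150L, 310L), block_end = c(199L, 360L),
               block_rank = 1L, stringsAsFactors = FALSE),
    data.frame(read_id = "far", chrom = "chrA", strand = "+",
               block_start = 550L, block_end = 599L, block_rank = 1L,
               stringsAsFactors = FALSE))
  iv <- data.frame(gene_id = "g1", chrom = "chrA", start = 200L, end = 300L,
                   stringsAsFactors = FALSE)
  # exons [100,200) and [300,400) flank the intron; the read in exon 3
  # does not count
  expect_identical(count_flanking_exon_reads(al, ann, iv), 2L)
})

test_that("test_introns aligns intron tables and flags planted retention", {
  w <- small_world()
  ir_wt <- call_intron_retention(w$rd_wt$alignments, w$annotation)
  ir_mut <- call_intron_retention(w$rd_mut$alignments, w$annotation)
  res <- test_introns(ir_wt, ir_mut)
  expect_identical(nrow(res), nrow(ir_wt))
  expect_identical(res$called_b, ir_mut$called)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  # planted IR introns must come out B_over and significant
  led <- w$iso_mut$ledger
  ir_led <- led[led$event_type == "IR", ]
  hit <- match(paste(ir_led$chrom, ir_led$junction_start),
               paste(res$chrom, res$intron_start))
  expect_true(all(res$significant[hit]))
  expect_true(all(res$direction[hit] == "B_over"))
})

test_that("global comparison totals junction reads per event type", {
  w <- small_world()
  jc_wt <- apply_filter(extract_junctions(w$rd_wt$alignments, w$annotation))
  jc_mut <- apply_filter(extract_junctions(w$rd_mut$alignments, w$annotation))
  ev_wt <- classify_events(jc_wt, w$annotation)
  ev_mut <- classify_events(jc_mut, w$annotation)
  g <- global_comparison(ev_wt, ev_mut, 6000L, 6000L)
  expect_setequal(g$event_type, c("ALT5SS", "ALT3SS", "CASSETTE", "MUTEX",
                                  "COORD_CASSETTE", "ALT_FIRST", "ALT_LAST"))
  for (tp in c("ALT5SS", "ALT3SS", "CASSETTE")) {
    row <- g[g$event_type == tp, ]
    expect_identical(row$reads_b,
                     sum(ev_mut$alt_count[ev_mut$event_type == tp]))
  }
  # types absent from both conditions get p = 1
  expect_true(all(g$p_value[g$reads_a + g$reads_b == 0] == 1))
})

test_that("rescue profiles normalize counts per million mapped reads", {
  counts <- matrix(c(10, 20, 40, 80), nrow = 2,
                   dimnames = list(c("ev1", "ev2"), c("WT", "MUT")))
  norm <- profile_rescue(counts, totals = c(1e6, 2e6))
  expect_equal(norm["ev1", "WT"], 10)
  expect_equal(norm["ev1", "MUT"], 20)
  expect_equal(norm["ev2", "MUT"], 40)
  expect_error(profile_rescue(counts, totals = 1e6), "one total")
  expect_error(profile_rescue(counts, totals = c(0, 1)), "positive")
})
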