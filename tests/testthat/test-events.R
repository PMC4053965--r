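# Junction catalog rows for the toy annotation, with sensible defaults.
toy_junction <- function(chrom, start, end, strand, read_count = 10L,
                         annotated = FALSE, gene_id = "g1") {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             read_count = read_count, max_overhang = 50L,
             annotated = annotated, gene_id = gene_id,
             stringsAsFactors = FALSE)
}

# toy_annotation(): g1 (+, chrA) introns [200,300) and [400,500);
# g2 (-, chrB) introns [1300,1400) (rank 1) and [1100,1200) (rank 2).
toy_catalog <- function(extra) {
  ann_rows <- rbind(
    toy_junction("chrA", 200L, 300L, "+", 100L, TRUE, "g1"),
    toy_junction("chrA", 400L, 500L, "+", 80L, TRUE, "g1"),
    toy_junction("chrB", 1300L, 1400L, "-", 90L, TRUE, "g2"),
    toy_junction("chrB", 1100L, 1200L, "-", 70L, TRUE, "g2"))
  rbind(ann_rows, extra)
}

test_that("ALT5SS and ALT3SS are detected with signed transcribed offsets", {
  ann <- toy_annotation()
  # plus strand: donor moved 5 nt downstream (genomic +5), acceptor shared
  ev <- classify_events(toy_catalog(
    toy_junction("chrA", 205L, 300L, "+")), ann)
  ev <- ev[ev$event_type != "", ]
  expect_identical(ev$event_type, "ALT5SS")
  expect_identical(ev$offset, 5L)
  expect_identical(ev$dominant_start, 200L)
  # plus strand: acceptor moved 4 nt upstream -> offset -4
  ev <- classify_events(toy_catalog(
    toy_junction("chrA", 400L, 496L, "+")), ann)
  expect_identical(ev$event_type, "ALT3SS")
  expect_identical(ev$offset, -4L)
  # minus strand: intron [1300,1400) has donor 1400, acceptor 1300.
  # a donor moved to 1394 is 6 nt downstream in transcribed orientation
  ev <- classify_events(toy_catalog(
    toy_junction("chrB", 1300L, 1394L, "-", gene_id = "g2")), ann)
  expect_identical(ev$event_type, "ALT5SS")
  expect_identical(ev$offset, 6L)
  # minus strand: acceptor moved genomically right = upstream -> negative
  ev <- classify_events(toy_catalog(
    toy_junction("chrB", 1307L, 1400L, "-", gene_id = "g2")), ann)
  expect_identical(ev$event_type, "ALT3SS")
  expect_identical(ev$offset, -7L)
})

test_that("cassette junctions join flanking exon boundaries", {
  ann <- toy_annotation()
  # skips exon 2 of g1: junction [200,500) from exon1 end to exon3 start
  ev <- classify_events(toy_catalog(
    toy_junction("chrA", 200L, 500L, "+")), ann)
  expect_identical(ev$event_type, "CASSETTE")
  # same on the minus-strand gene
  ev <- classify_events(toy_catalog(
    toy_junction("chrB", 1100L, 1400L, "-", gene_id = "g2")), ann)
  expect_identical(ev$event_type, "CASSETTE")
})

test_that("annotated junctions yield no event; others get fallback labels", {
  ann <- toy_annotation()
  ev <- classify_events(toy_catalog(NULL), ann)
  expect_identical(nrow(ev), 0L)
  # intergenic junction
  ev <- classify_events(toy_catalog(
    toy_junction("chrA", 700L, 800L, "*", gene_id = NA_character_)), ann)
  expect_identical(ev$event_type, "intergenic")
  # a junction inside a gene matching no annotated boundary
  ev <- classify_events(toy_catalog(
    toy_junction("chrA", 210L, 290L, "+")), ann)
  expect_identical(ev$event_type, "unclassified")
})

test_that("the dominant junction is the highest-count annotated counterpart", {
  ann <- toy_annotation()
  ev <- classify_events(toy_catalog(
    toy_junction("chrA", 205L, 300L, "+", read_count = 7L)), ann)
  expect_identical(ev$dominant_start, 200L)
  expect_identical(ev$dominant_end, 300L)
  expect_identical(ev$dominant_count, 100L)
  expect_identical(ev$alt_count, 7L)
})

test_that("intron retention calling enforces both thresholds exactly", {
  ann <- toy_annotation()
  # intron [200,300) of g1, length 100; build unspliced reads inside it
  unspliced <- function(n, s, e)
    do.call(rbind, lapply(seq_len(n), function(i)
      data.frame(read_id = sprintf("u%d_%d", s, i), chrom = "chrA",
                 strand = "+", block_start = s, block_end = e,
                 block_rank = 1L, stringsAsFactors = FALSE)))
  # 5 reads covering [200,250): 50% coverage -> called (both at boundary)
  al <- unspliced(5L, 200L, 250L)
  ir <- call_intron_retention(al, ann)
  row <- ir[ir$intron_start == 200L, ]
  expect_identical(row$n_unspliced_reads, 5L)
  expect_equal(row$covered_fraction, 0.5)
  expect_true(row$called)
  # 4 reads: read threshold fails
  ir <- call_intron_retention(unspliced(4L, 200L, 250L), ann)
  expect_false(ir$called[ir$intron_start == 200L])
  # 5 reads covering 49 bases: coverage threshold fails
  ir <- call_intron_retention(unspliced(5L, 200L, 249L), ann)
  expect_false(ir$called[ir$intron_start == 200L])
})

test_that("reads spliced over the intron are exon evidence, not retention", {
  ann <- toy_annotation()
  spliced <- do.call(rbind, lapply(1:6, function(i)
    data.frame(read_id = sprintf("s%d", i), chrom = "chrA", strand = "+",
               block_start = c(150L, 300L), block_end = c(200L, 350L),
               block_rank = 1:2, stringsAsFactors = FALSE)))
  ir <- call_intron_retention(spliced, ann)
  row <- ir[ir$intron_start == 200L, ]
  expect_identical(row$n_unspliced_reads, 0L)
  expect_false(row$called)
  # but the same reads do count as flanking-exon evidence
  expect_identical(row$flank_reads, 6L)
  # a read gapped over a *different* interval inside the intron is unspliced
  # evidence for this intron (its gap is not this intron)
  part <- data.frame(read_id = "p1", chrom = "chrA", strand = "+",
                     block_start = c(210L, 260L), block_end = c(240L, 290L),
                     block_rank = 1:2, stringsAsFactors = FALSE)
  ir2 <- call_intron_retention(part, ann)
  expect_identical(ir2$n_unspliced_reads[ir2$intron_start == 200L], 1L)
})

test_that("frame impact distinguishes indels, frameshifts and intronic stops", {
  # net change not divisible by 3: frameshift
  expect_identical(frame_impact(97L, kind = "alt_ss")$impact, "frameshift_PTC")
  # divisible by 3, no stop: in-frame indel with codon count
  fi <- frame_impact(-9L, kind = "alt_ss")
  expect_identical(fi$impact, "in_frame_indel")
  expect_identical(fi$codons, 3L)
  # retained intron, length divisible by 3, carrying an in-frame TAA
  fi <- frame_impact(9L, inserted_seq = "GCGTAAGCG", frame_offset = 0L,
                     kind = "ir")
  expect_identical(fi$impact, "PTC_in_retained_intron")
  # same sequence in a shifted frame has no in-frame stop
  fi <- frame_impact(9L, inserted_seq = "GCGTAAGCG", frame_offset = 2L,
                     kind = "ir")
  expect_identical(fi$impact, "in_frame_indel")
  # outside the CDS nothing is coding
  expect_identical(frame_impact(7L, in_cds = FALSE)$impact, "non_coding")
})
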