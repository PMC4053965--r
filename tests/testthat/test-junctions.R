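test_that("extract_junctions computes gap coordinates and overhangs", {
  # one read with blocks [100,140)+[200,261): gap [140,200), overhang 40
  al <- data.frame(read_id = "r1", chrom = "chrA", strand = "+",
                   block_start = c(100L, 200L), block_end = c(140L, 261L),
                   block_rank = 1:2, stringsAsFactors = FALSE)
  jc <- extract_junctions(al)
  expect_identical(nrow(jc), 1L)
  expect_identical(jc$start, 140L)
  expect_identical(jc$end, 200L)
  expect_identical(jc$read_count, 1L)
  expect_identical(jc$max_overhang, 40L)
})

test_that("junction read counts aggregate and max_overhang is the per-read max", {
  mk <- function(id, s1, e1, s2, e2)
    data.frame(read_id = id, chrom = "chrA", strand = "+",
               block_start = c(s1, s2), block_end = c(e1, e2),
               block_rank = 1:2, stringsAsFactors = FALSE)
  al <- rbind(mk("r1", 120L, 140L, 200L, 281L),   # overhang 20
              mk("r2", 110L, 140L, 200L, 271L),   # overhang 30
              mk("r3", 135L, 140L, 200L, 296L),   # overhang 5
              mk("r4", 300L, 350L, 420L, 471L))   # a different junction
  jc <- extract_junctions(al)
  expect_identical(nrow(jc), 2L)
  j1 <- jc[jc$start == 140L, ]
  expect_identical(j1$read_count, 3L)
  expect_identical(j1$max_overhang, 30L)
  expect_identical(jc$read_count[jc$start == 350L], 1L)
})

test_that("a three-block read contributes one gap per junction", {
  al <- data.frame(read_id = "r1", chrom = "chrA", strand = "+",
                   block_start = c(100L, 200L, 400L),
                   block_end = c(140L, 240L, 421L),
                   block_rank = 1:3, stringsAsFactors = FALSE)
  jc <- extract_junctions(al)
  expect_identical(jc$start, c(140L, 240L))
  expect_identical(jc$end, c(200L, 400L))
  # middle block flanks both gaps; overhangs use the adjacent block pair
  expect_identical(jc$max_overhang, c(40L, 21L))
})

test_that("annotated flag and gene assignment use the annotation", {
  ann <- toy_annotation()
  al <- rbind(
    data.frame(read_id = "r1", chrom = "chrA", strand = "+",
               block_start = c(150L, 300L), block_end = c(200L, 351L),
               block_rank = 1:2, stringsAsFactors = FALSE),   # = intron 1 of g1
    data.frame(read_id = "r2", chrom = "chrA", strand = "+",
               block_start = c(150L, 305L), block_end = c(200L, 356L),
               block_rank = 1:2, stringsAsFactors = FALSE),   # novel acceptor
    data.frame(read_id = "r3", chrom = "chrA", strand = "+",
               block_start = c(700L, 800L), block_end = c(750L, 851L),
               block_rank = 1:2, stringsAsFactors = FALSE))   # outside genes
  jc <- extract_junctions(al, ann)
  jc <- jc[order(jc$start, jc$end), ]
  expect_identical(jc$annotated[jc$end == 300L], TRUE)
  expect_identical(jc$annotated[jc$end == 305L], FALSE)
  expect_identical(jc$gene_id[1:2], c("g1", "g1"))
  expect_true(is.na(jc$gene_id[jc$start == 750L]))
  expect_identical(jc$strand[1:2], c("+", "+"))
})

test_that("malformed alignments are rejected", {
  al <- data.frame(read_id = "r1", chrom = "chrA", strand = "+",
                   block_start = c(100L, 130L), block_end = c(140L, 181L),
                   block_rank = 1:2, stringsAsFactors = FALSE)
  expect_error(extract_junctions(al), "overlap")
  al2 <- data.frame(read_id = "r1", chrom = "chrA", strand = "+",
                    block_start = 100L, block_end = 100L, block_rank = 1L,
                    stringsAsFactors = FALSE)
  expect_error(extract_junctions(al2), "width")
})

test_that("the filter applies a strict overhang cutoff and a read minimum", {
  cat_ <- data.frame(
    chrom = "chrA", start = 1:6 * 100L, end = 1:6 * 100L + 50L,
    read_count =   c(2L, 1L, 2L, 10L, 1L, 5L),
    max_overhang = c(21L, 21L, 20L, 15L, 40L, 50L),
    stringsAsFactors = FALSE)
  kept <- apply_filter(cat_, filter_config())
  # kept: overhang > 20 AND reads >= 2 -> rows 1 and 6 only
  expect_identical(kept$start, c(100L, 600L))
  # boundary: overhang exactly 20 is removed even with many reads;
  # overhang 40 with a single read is removed
  expect_false(400L %in% kept$start)
  expect_false(500L %in% kept$start)
})

test_that("annotated junctions can be exempted from the filter", {
  cat_ <- data.frame(chrom = "chrA", start = c(100L, 200L),
                     end = c(150L, 250L), read_count = c(1L, 1L),
                     max_overhang = c(10L, 10L),
                     annotated = c(TRUE, FALSE), stringsAsFactors = FALSE)
  expect_identical(nrow(apply_filter(cat_)), 0L)
  ex <- apply_filter(cat_, exempt_annotated = TRUE)
  expect_identical(ex$start, 100L)
})

test_that("junction references have fixed length and matcher agrees with brute force", {
  w <- small_world()
  flank <- w$cfg$read_length - 11L
  refs <- build_junction_refs(w$genome, w$annotation, flank, "annotated")
  expect_true(all(nchar(refs$sequence) == 2L * flank))
  expect_identical(flank, 90L)   # 101 nt reads -> 90 nt flanks, 180 nt refs
  # 20 refs x 50 reads, mixing junction-spanning and decoy reads
  refs20 <- refs[seq_len(min(20L, nrow(refs))), ]
  dec <- make_decoy_reads(w$genome, w$annotation, w$cfg)
  reads <- rbind(w$rd_wt$reads[1:30, c("read_id", "seq")],
                 dec$reads[1:20, ])
  got <- match_reads_to_refs(reads, refs20)
  want <- brute_force_match(reads, refs20)
  o <- function(d) {
    d <- d[order(d$ref_id, d$read_id), ]
    rownames(d) <- NULL
    d[, c("ref_id", "read_id", "overhang")]
  }
  expect_identical(o(as.data.frame(got)), o(want))
})

test_that("matcher requires the 11 nt anchor on both sides of the midpoint", {
  refs <- data.frame(ref_id = "ref1",
                     sequence = paste0(strrep("A", 30), strrep("C", 30)),
                     flank = 30L, origin = "annotated",
                     stringsAsFactors = FALSE)
  # 20+20 split crosses the midpoint with 20 nt on each side (kept);
  # 30+10 leaves only 10 nt past the midpoint (rejected)
  read_ok <- data.frame(read_id = "ok",
                        seq = paste0(strrep("A", 20), strrep("C", 20)),
                        stringsAsFactors = FALSE)
  read_short <- data.frame(read_id = "short",
                           seq = paste0(strrep("A", 30), strrep("C", 10)),
                           stringsAsFactors = FALSE)
  expect_identical(match_reads_to_refs(read_ok, refs)$overhang, 20L)
  expect_identical(nrow(match_reads_to_refs(read_short, refs)), 0L)
})

test_that("reads with ambiguous bases never match", {
  refs <- data.frame(ref_id = "ref1",
                     sequence = paste0(strrep("A", 30), strrep("C", 30)),
                     flank = 30L, origin = "annotated",
                     stringsAsFactors = FALSE)
  rd <- data.frame(read_id = "n1",
                   seq = paste0(strrep("A", 19), "N", strrep("C", 20)),
                   stringsAsFactors = FALSE)
  expect_identical(nrow(match_reads_to_refs(rd, refs)), 0L)
})

test_that("null characterization separates decoys from annotated junctions", {
  w <- small_world()
  flank <- w$cfg$read_length - 11L
  dec <- make_decoy_reads(w$genome, w$annotation, w$cfg)
  rnd <- match_reads_to_refs(dec$reads, dec$refs)
  ann_refs <- build_junction_refs(w$genome, w$annotation, flank, "annotated")
  ann <- match_reads_to_refs(w$rd_wt$reads[, c("read_id", "seq")], ann_refs)
  rep_ <- characterize_null(rnd, ann)
  surv <- rep_$survival
  at <- function(origin, oh, nr)
    surv$survival[surv$origin == origin & surv$min_overhang_exclusive == oh &
                    surv$min_reads == nr]
  # every decoy junction dies at the calibrated cutoffs
  expect_identical(at("random", 20L, 2L), 0)
  # but decoys do register when thresholds are trivial
  expect_gt(at("random", 0L, 1L), 0.9)
  # annotated junctions overwhelmingly survive the calibrated cutoffs
  expect_gt(at("annotated", 20L, 2L), 0.9)
})
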