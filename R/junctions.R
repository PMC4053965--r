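#' Filter configuration for the false-positive junction filter
#'
#' Defaults are the calibrated cutoffs: an overhang of more than 20 bp
#' (strict inequality, so 21 is the smallest kept) and at least two
#' supporting reads.
#'
#' @param min_overhang_exclusive junctions are kept only when max_overhang
#'   is strictly greater than this (nt)
#' @param min_reads minimum supporting read count (inclusive)
#' @return a validated list of class `filter_config`
#' @export
filter_config <- function(min_overhang_exclusive = 20L, min_reads = 2L) {
  cfg <- list(min_overhang_exclusive = as.integer(min_overhang_exclusive),
              min_reads = as.integer(min_reads))
  if (cfg$min_overhang_exclusive < 0L || cfg$min_reads < 1L)
    stop("filter thresholds out of range", call. = FALSE)
  class(cfg) <- c("filter_config", "list")
  cfg
}

#' Extract a junction catalog from spliced alignments
#'
#' One junction per distinct (chrom, intron_start, intron_end) alignment
#' gap.  A junction's read count is the number of reads whose gap equals
#' that interval; its maximum overhang is, over those reads, the largest of
#' each read's shorter gap-adjacent block.  A junction is annotated iff its
#' interval exactly equals an annotated intron.  Strand is taken from a
#' gene whose span contains the junction, else inferred from GT/AG
#' (or CT/AC) boundary dinucleotides when a genome is supplied, else "*".
#' Junction identity deliberately excludes strand: reads are unstranded.
#'
#' @param alignments long block table (read_id, chrom, block_start,
#'   block_end, block_rank)
#' @param annotation optional annotation object
#' @param genome optional named DNAStringSet for dinucleotide strand
#'   inference
#' @return data.frame: chrom, start, end (0-based half-open intron),
#'   strand, read_count, max_overhang, annotated, gene_id (NA when no
#'   containing gene)
#' @export
extract_junctions <- function(alignments, annotation = NULL, genome = NULL) {
  al <- alignments[order(alignments$read_id, alignments$block_rank), ]
  w <- al$block_end - al$block_start
  if (any(w <= 0L))
    stop("malformed alignment block (zero or negative width)", call. = FALSE)
  n <- nrow(al)
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), read_count = integer(),
                      max_overhang = integer(), annotated = logical(),
                      gene_id = character(), stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  same <- al$read_id[-n] == al$read_id[-1L]
  if (any(same & (al$block_start[-1L] < al$block_end[-n])))
    stop("malformed alignment: overlapping or unsorted blocks", call. = FALSE)
  i <- which(same)
  if (!length(i)) return(empty)
  gaps <- data.frame(chrom = al$chrom[i],
                     start = al$block_end[i], end = al$block_start[i + 1L],
                     overhang = pmin(w[i], w[i + 1L]),
                     stringsAsFactors = FALSE)
  key <- paste(gaps$chrom, gaps$start, gaps$end, sep = ":")
  agg <- data.frame(
    key = unique(key), stringsAsFactors = FALSE
  )
  cnt <- tapply(rep(1L, nrow(gaps)), key, sum)
  mx <- tapply(gaps$overhang, key, max)
  first <- !duplicated(key)
  jc <- data.frame(chrom = gaps$chrom[first], start = gaps$start[first],
                   end = gaps$end[first],
                   read_count = as.integer(cnt[key[first]]),
                   max_overhang = as.integer(mx[key[first]]),
                   stringsAsFactors = FALSE)
  jc <- jc[order(jc$chrom, jc$start, jc$end), ]
  rownames(jc) <- NULL

  jc$annotated <- FALSE
  jc$gene_id <- NA_character_
  jc$strand <- "*"
  if (!is.null(annotation)) {
    introns <- annotation_introns(annotation)
    ik <- paste(introns$chrom, introns$start, introns$end, sep = ":")
    jk <- paste(jc$chrom, jc$start, jc$end, sep = ":")
    jc$annotated <- jk %in% ik
    # containing gene (first hit; toy genes do not overlap)
    g <- annotation$genes
    for (r in seq_len(nrow(jc))) {
      hit <- which(g$chrom == jc$chrom[r] & g$start <= jc$start[r] &
                     g$end >= jc$end[r])
      if (length(hit)) {
        jc$gene_id[r] <- g$gene_id[hit[1]]
        jc$strand[r] <- g$strand[hit[1]]
      }
    }
  }
  if (!is.null(genome)) {
    need <- which(jc$strand == "*")
    for (r in need) {
      don <- genome_seq(genome, jc$chrom[r], jc$start[r], jc$start[r] + 2L)
      acc <- genome_seq(genome, jc$chrom[r], jc$end[r] - 2L, jc$end[r])
      if (don == "GT" && acc == "AG") jc$strand[r] <- "+"
      else if (don == "CT" && acc == "AC") jc$strand[r] <- "-"
    }
  }
  jc[, c("chrom", "start", "end", "strand", "read_count", "max_overhang",
         "annotated", "gene_id")]
}

#' Apply the false-positive junction filter
#'
#' A junction is kept iff its maximum overhang is strictly greater than
#' `cfg$min_overhang_exclusive` and its read count is at least
#' `cfg$min_reads`.  Annotated junctions pass through the same rule unless
#' `exempt_annotated` is set.
#'
#' @param catalog junction catalog from [extract_junctions()] (any
#'   data.frame with max_overhang and read_count columns works)
#' @param cfg a [filter_config()]
#' @param exempt_annotated keep annotated junctions regardless of support
#' @return the kept rows, fields untouched
#' @export
apply_filter <- function(catalog, cfg = filter_config(),
                         exempt_annotated = FALSE) {
  keep <- catalog$max_overhang > cfg$min_overhang_exclusive &
    catalog$read_count >= cfg$min_reads
  if (exempt_annotated && "annotated" %in% names(catalog))
    keep <- keep | catalog$annotated
  out <- catalog[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
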