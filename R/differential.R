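#' Equal-depth resampling of an alignment library
#'
#' Draws exactly `n_reads` distinct reads uniformly without replacement, so
#' libraries are compared at the same depth.  Deterministic under the seed.
#'
#' @param alignments long block table
#' @param n_reads number of reads to keep
#' @param seed integer seed
#' @return the alignment rows of the sampled reads
#' @export
resample_alignments <- function(alignments, n_reads, seed = 1L) {
  ids <- unique(alignments$read_id)
  if (n_reads > length(ids))
    stop("n_reads exceeds library size (", length(ids), ")", call. = FALSE)
  set.seed(seed)
  keep <- sample(ids, n_reads)
  out <- alignments[alignments$read_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count reads in the exons flanking a set of intervals
#'
#' The denominator of the differential splicing tests: for each interval
#' (an event junction or an intron), the number of distinct reads with at
#' least one aligned base in the annotated exon immediately left of the
#' interval start or immediately right of the interval end within the
#' interval's gene.
#'
#' @param alignments long block table
#' @param annotation annotation object
#' @param intervals data.frame with gene_id, chrom, start, end
#' @return integer vector, one count per interval row
#' @export
count_flanking_exon_reads <- function(alignments, annotation, intervals) {
  ex <- annotation$exons
  bl_gr <- GenomicRanges::GRanges(
    alignments$chrom,
    IRanges::IRanges(alignments$block_start + 1L, alignments$block_end))
  vapply(seq_len(nrow(intervals)), function(i) {
    gx <- ex[ex$gene_id == intervals$gene_id[i], , drop = FALSE]
    gx <- gx[order(gx$start), ]
    left <- gx[gx$start < intervals$start[i], , drop = FALSE]
    right <- gx[gx$end > intervals$end[i], , drop = FALSE]
    fl <- rbind(if (nrow(left)) tail(left, 1L) else NULL,
                if (nrow(right)) head(right, 1L) else NULL)
    if (is.null(fl) || !nrow(fl)) return(0L)
    fl_gr <- GenomicRanges::GRanges(fl$chrom,
                                    IRanges::IRanges(fl$start + 1L, fl$end))
    hits <- GenomicRanges::findOverlaps(bl_gr, fl_gr)
    length(unique(alignments$read_id[S4Vectors::queryHits(hits)]))
  }, integer(1))
}

# core per-row differential machinery shared by event and intron tests
fisher_differential <- function(tab, alpha, min_unique) {
  n <- nrow(tab)
  p <- numeric(n); assigned_zero <- logical(n)
  direction <- character(n); significant <- logical(n)
  for (i in seq_len(n)) {
    fa <- tab$focal_a[i]; fb <- tab$focal_b[i]
    ea <- tab$exon_a[i]; eb <- tab$exon_b[i]
    ra <- if (ea > 0) fa / ea else Inf * (fa > 0)
    rb <- if (eb > 0) fb / eb else Inf * (fb > 0)
    direction[i] <- if (isTRUE(ra > rb)) "A_over" else
      if (isTRUE(rb > ra)) "B_over" else "none"
    if (xor(fa == 0L, fb == 0L)) {
      # unique to one condition: the >=5-read rule decides
      assigned_zero[i] <- max(fa, fb) >= min_unique
      p[i] <- if (assigned_zero[i]) 0 else
        suppressWarnings(fisher_2x2(c(fa, ea, fb, eb)))
      significant[i] <- assigned_zero[i]
    } else {
      p[i] <- suppressWarnings(fisher_2x2(c(fa, ea, fb, eb)))
      significant[i] <- p[i] < alpha
    }
  }
  tab$p_value <- p
  tab$assigned_zero <- assigned_zero
  tab$direction <- direction
  tab$significant <- significant
  tab$p_adj_bh <- stats::p.adjust(ifelse(assigned_zero, 0, p), method = "BH")
  tab
}

#' Differential test of alternative-splicing events between two conditions
#'
#' Events are matched across conditions by junction coordinates and type.
#' Each event's 2x2 table is (alternative-junction reads,
#' flanking-exon reads) x (condition A, condition B), tested with
#' [fisher_2x2()]; an event is significant when p < `alpha`, or when it is
#' unique to one condition with at least `min_unique_reads` junction reads
#' (the assigned-zero rule: p reported as 0 and flagged, never silently
#' merged with computed p-values).  A Benjamini-Hochberg column is emitted
#' for convenience; the primary calls use the unadjusted threshold.
#'
#' @param events_a,events_b event tables from [classify_events()]
#' @param alignments_a,alignments_b the (equal-depth) alignment libraries
#' @param annotation annotation object
#' @param alpha significance threshold on the unadjusted p (default 0.01)
#' @param min_unique_reads support needed for the unique-event rule
#' @return data.frame: event_type, gene_id, chrom, junction_start,
#'   junction_end, focal_a, exon_a, focal_b, exon_b, p_value,
#'   assigned_zero, direction, significant, p_adj_bh
#' @export
test_events <- function(events_a, events_b, alignments_a, alignments_b,
                        annotation, alpha = 0.01, min_unique_reads = 5L) {
  use <- function(ev) ev[!ev$event_type %in% c("intergenic"), , drop = FALSE]
  ea <- use(events_a); eb <- use(events_b)
  key <- function(ev) paste(ev$event_type, ev$chrom, ev$junction_start,
                            ev$junction_end, sep = ":")
  keys <- union(key(ea), key(eb))
  ka <- match(keys, key(ea)); kb <- match(keys, key(eb))
  src <- ifelse(is.na(ka), kb + nrow(ea), ka)
  all_ev <- rbind(ea, eb)
  tab <- data.frame(
    event_type = all_ev$event_type[src], gene_id = all_ev$gene_id[src],
    chrom = all_ev$chrom[src],
    junction_start = all_ev$junction_start[src],
    junction_end = all_ev$junction_end[src],
    focal_a = ifelse(is.na(ka), 0L, ea$alt_count[ka]),
    focal_b = ifelse(is.na(kb), 0L, eb$alt_count[kb]),
    stringsAsFactors = FALSE)
  iv <- data.frame(gene_id = tab$gene_id, chrom = tab$chrom,
                   start = tab$junction_start, end = tab$junction_end,
                   stringsAsFactors = FALSE)
  tab$exon_a <- count_flanking_exon_reads(alignments_a, annotation, iv)
  tab$exon_b <- count_flanking_exon_reads(alignments_b, annotation, iv)
  fisher_differential(tab, alpha, min_unique_reads)
}

#' Differential test of intron retention between two conditions
#'
#' One 2x2 table per annotated intron: (unspliced intron reads,
#' flanking-exon reads) x (A, B), tested with [fisher_2x2()] at the
#' intron-retention threshold (default 0.001).  An intron observed in only
#' one condition is significant when supported by at least
#' `min_unique_reads` intron reads (assigned-zero rule).
#'
#' @param ir_a,ir_b intron tables from [call_intron_retention()] on the
#'   respective (equal-depth) libraries
#' @param alpha significance threshold (default 0.001)
#' @param min_unique_reads coverage needed for the unique-intron rule
#' @param only_called restrict to introns called retained in at least one
#'   condition
#' @return data.frame: gene_id, chrom, intron_start, intron_end, focal_a,
#'   exon_a, focal_b, exon_b, called_a, called_b, p_value, assigned_zero,
#'   direction, significant, p_adj_bh
#' @export
test_introns <- function(ir_a, ir_b, alpha = 0.001, min_unique_reads = 5L,
                         only_called = FALSE) {
  key <- function(x) paste(x$chrom, x$intron_start, x$intron_end, sep = ":")
  stopifnot(identical(key(ir_a), key(ir_b)))
  tab <- data.frame(
    gene_id = ir_a$gene_id, chrom = ir_a$chrom,
    intron_start = ir_a$intron_start, intron_end = ir_a$intron_end,
    focal_a = ir_a$n_unspliced_reads, focal_b = ir_b$n_unspliced_reads,
    exon_a = ir_a$flank_reads, exon_b = ir_b$flank_reads,
    called_a = ir_a$called, called_b = ir_b$called,
    stringsAsFactors = FALSE)
  if (only_called) tab <- tab[tab$called_a | tab$called_b, , drop = FALSE]
  fisher_differential(tab, alpha, min_unique_reads)
}

.JUNCTION_EVENT_TYPES <- c("ALT5SS", "ALT3SS", "CASSETTE", "MUTEX",
                           "COORD_CASSETTE", "ALT_FIRST", "ALT_LAST")

#' Global comparison of alternative splicing between two conditions
#'
#' For each junction-based event type, tallies the number of events and the
#' junction reads assigned to the type in each condition (derived from
#' equal-depth resamples), and tests the junction-read count against the
#' uniquely mapped totals with Fisher's exact test.
#'
#' @param events_a,events_b event tables from [classify_events()]
#' @param total_a,total_b uniquely mapped read totals of the two libraries
#' @return data.frame: event_type, n_events_a, n_events_b, reads_a,
#'   reads_b, p_value
#' @export
global_comparison <- function(events_a, events_b, total_a, total_b) {
  do.call(rbind, lapply(.JUNCTION_EVENT_TYPES, function(tp) {
    a <- events_a[events_a$event_type == tp, , drop = FALSE]
    b <- events_b[events_b$event_type == tp, , drop = FALSE]
    ra <- sum(a$alt_count); rb <- sum(b$alt_count)
    p <- if (ra + rb == 0L) 1 else
      suppressWarnings(fisher_2x2(c(ra, total_a, rb, total_b)))
    data.frame(event_type = tp, n_events_a = nrow(a), n_events_b = nrow(b),
               reads_a = ra, reads_b = rb, p_value = p,
               stringsAsFactors = FALSE)
  }))
}

#' Normalized junction/intron coverage across sample groups
#'
#' The rescue readout: per selected event, read coverage divided by the
#' group's uniquely mapped total (reported per million mapped reads), so a
#' mutant-elevated event returning to wild-type level in a rescue group is
#' directly visible row-wise.
#'
#' @param counts numeric matrix, events x groups, of junction or intron
#'   read counts
#' @param totals uniquely mapped totals, one per group (column)
#' @return matrix of counts per million mapped reads, same dimnames
#' @export
profile_rescue <- function(counts, totals) {
  counts <- as.matrix(counts)
  if (length(totals) != ncol(counts))
    stop("one total per group (column) required", call. = FALSE)
  if (any(totals <= 0)) stop("totals must be positive", call. = FALSE)
  sweep(counts, 2L, totals / 1e6, "/")
}
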