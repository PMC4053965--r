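#' Intron-retention calling thresholds
#'
#' Defaults: at least five unspliced reads covering at least 50% of the
#' intron.
#'
#' @param min_reads minimum distinct unspliced reads touching the intron
#' @param min_covered_fraction minimum fraction of intron bases covered >=1x
#' @return validated list of class `ir_config`
#' @export
ir_config <- function(min_reads = 5L, min_covered_fraction = 0.5) {
  cfg <- list(min_reads = as.integer(min_reads),
              min_covered_fraction = min_covered_fraction)
  if (cfg$min_reads < 1L || cfg$min_covered_fraction <= 0 ||
      cfg$min_covered_fraction > 1)
    stop("ir_config thresholds out of range", call. = FALSE)
  class(cfg) <- c("ir_config", "list")
  cfg
}

# dominant annotated counterpart among candidate annotated introns:
# highest read count in the catalog (0 when unobserved), tie broken by
# smallest interval.
pick_dominant <- function(cand, catalog) {
  key <- paste(catalog$chrom, catalog$start, catalog$end, sep = ":")
  ck <- paste(cand$chrom, cand$start, cand$end, sep = ":")
  rc <- catalog$read_count[match(ck, key)]
  rc[is.na(rc)] <- 0L
  len <- cand$end - cand$start
  cand[order(-rc, len)[1L], , drop = FALSE]
}

#' Classify alternative-splicing events from a filtered junction catalog
#'
#' Novel (unannotated) junctions are compared with the annotated introns of
#' their containing gene, after reorienting minus-strand genes so the donor
#' is always the transcribed 5' side:
#' \itemize{
#'   \item CASSETTE — both junction ends coincide with annotated exon
#'     boundaries such that exactly one internal exon is skipped;
#'     COORD_CASSETTE when two or more consecutive exons are skipped.
#'   \item ALT5SS — the junction shares its acceptor with an annotated
#'     intron but uses a different donor; ALT3SS — shares the donor,
#'     different acceptor.  The signed offset of the alternative site from
#'     the dominant site is reported in transcribed orientation
#'     (downstream positive).
#'   \item ALT_FIRST / ALT_LAST — the alternative boundary pairs with a
#'     terminal intron but lies outside the annotated terminal exon and
#'     intron, indicating an alternative first/last exon.
#'   \item MUTEX — two cassette events skipping adjacent exons whose
#'     separating annotated intron is absent from the catalog (the two
#'     exons are never observed co-included); both members are relabelled.
#' }
#' Junctions identical to annotated introns yield no event; junctions in no
#' gene are reported with type "intergenic"; unannotated junctions matching
#' no rule are reported "unclassified".  Each junction receives at most one
#' junction-based event type.
#'
#' @param junctions filtered junction catalog from [extract_junctions()] /
#'   [apply_filter()] (must carry gene_id)
#' @param annotation annotation object
#' @return data.frame: event_type, gene_id, chrom, strand, junction_start,
#'   junction_end, dominant_start, dominant_end, alt_count, dominant_count,
#'   offset (signed nt, alternative-splice-site events only)
#' @export
classify_events <- function(junctions, annotation) {
  introns <- annotation_introns(annotation)
  ex <- exons_transcribed(annotation)
  key <- function(d) paste(d$chrom, d$start, d$end, sep = ":")
  cat_key <- key(junctions)
  novel <- junctions[!junctions$annotated, , drop = FALSE]
  out <- list()
  for (r in seq_len(nrow(novel))) {
    j <- novel[r, ]
    if (is.na(j$gene_id)) {
      out[[length(out) + 1L]] <- data.frame(
        event_type = "intergenic", gene_id = NA_character_, chrom = j$chrom,
        strand = j$strand, junction_start = j$start, junction_end = j$end,
        dominant_start = NA_integer_, dominant_end = NA_integer_,
        alt_count = j$read_count, dominant_count = NA_integer_,
        offset = NA_integer_, stringsAsFactors = FALSE)
      next
    }
    gin <- introns[introns$gene_id == j$gene_id, , drop = FALSE]
    gex <- ex[ex$gene_id == j$gene_id, , drop = FALSE]
    gex <- gex[order(gex$start), ]       # genomic order
    strand <- j$strand
    donor <- if (strand == "-") j$end else j$start
    acceptor <- if (strand == "-") j$start else j$end
    n_ex <- nrow(gex)

    type <- NA_character_; dom <- NULL; offset <- NA_integer_
    # exon skipping: ends on annotated exon boundaries spanning >=1 exon
    di <- match(j$start, gex$end)        # exon whose 3' (genomic) edge = start
    ai <- match(j$end, gex$start)
    if (!is.na(di) && !is.na(ai) && ai - di >= 2L) {
      type <- if (ai - di == 2L) "CASSETTE" else "COORD_CASSETTE"
      dom <- gin[gin$start == gex$end[di] | gin$end == gex$start[ai], , drop = FALSE]
      dom <- pick_dominant(dom, junctions)
    } else {
      acc_hit <- gin[gin$acceptor == acceptor & gin$donor != donor, , drop = FALSE]
      don_hit <- gin[gin$donor == donor & gin$acceptor != acceptor, , drop = FALSE]
      first_exon <- if (strand == "+") gex[1L, ] else gex[n_ex, ]
      last_exon <- if (strand == "+") gex[n_ex, ] else gex[1L, ]
      inside <- function(pos, lo, hi) pos >= lo & pos <= hi
      if (nrow(acc_hit)) {
        dom <- pick_dominant(acc_hit, junctions)
        first_intron <- gin[gin$intron_rank == 1L, , drop = FALSE]
        in_first <- inside(donor, first_exon$start, first_exon$end) ||
          (nrow(first_intron) && inside(donor, first_intron$start, first_intron$end))
        if (nrow(first_intron) && dom$intron_rank == 1L && !in_first) {
          type <- "ALT_FIRST"
        } else {
          type <- "ALT5SS"
          offset <- if (strand == "+") donor - dom$donor else dom$donor - donor
        }
      } else if (nrow(don_hit)) {
        dom <- pick_dominant(don_hit, junctions)
        last_intron <- gin[gin$intron_rank == nrow(gin), , drop = FALSE]
        in_last <- inside(acceptor, last_exon$start, last_exon$end) ||
          (nrow(last_intron) && inside(acceptor, last_intron$start, last_intron$end))
        if (nrow(last_intron) && dom$intron_rank == nrow(gin) && !in_last) {
          type <- "ALT_LAST"
        } else {
          type <- "ALT3SS"
          offset <- if (strand == "+") acceptor - dom$acceptor else dom$acceptor - acceptor
        }
      } else {
        type <- "unclassified"
      }
    }
    dom_count <- NA_integer_
    if (!is.null(dom) && nrow(dom)) {
      hit <- match(key(dom), cat_key)
      dom_count <- if (!is.na(hit)) junctions$read_count[hit] else 0L
    }
    out[[length(out) + 1L]] <- data.frame(
      event_type = type, gene_id = j$gene_id, chrom = j$chrom,
      strand = strand, junction_start = j$start, junction_end = j$end,
      dominant_start = if (is.null(dom) || !nrow(dom)) NA_integer_ else dom$start,
      dominant_end = if (is.null(dom) || !nrow(dom)) NA_integer_ else dom$end,
      alt_count = j$read_count, dominant_count = dom_count,
      offset = offset, stringsAsFactors = FALSE)
  }
  ev <- if (length(out)) do.call(rbind, out) else data.frame(
    event_type = character(), gene_id = character(), chrom = character(),
    strand = character(), junction_start = integer(), junction_end = integer(),
    dominant_start = integer(), dominant_end = integer(),
    alt_count = integer(), dominant_count = integer(), offset = integer(),
    stringsAsFactors = FALSE)

  # MUTEX: adjacent cassette pairs whose separating intron is never spliced
  cs <- which(ev$event_type == "CASSETTE")
  if (length(cs) > 1L) {
    for (a in cs) for (b in cs) {
      if (a >= b || ev$gene_id[a] != ev$gene_id[b]) next
      gex <- ex[ex$gene_id == ev$gene_id[a], ]
      gex <- gex[order(gex$start), ]
      sk_a <- which(gex$start > ev$junction_start[a] & gex$end < ev$junction_end[a])
      sk_b <- which(gex$start > ev$junction_start[b] & gex$end < ev$junction_end[b])
      if (length(sk_a) != 1L || length(sk_b) != 1L || abs(sk_a - sk_b) != 1L)
        next
      lo <- min(sk_a, sk_b)
      sep_key <- paste(ev$chrom[a], gex$end[lo], gex$start[lo + 1L], sep = ":")
      if (!(sep_key %in% cat_key))
        ev$event_type[c(a, b)] <- "MUTEX"
    }
  }
  rownames(ev) <- NULL
  ev
}

#' Call intron retention from unspliced coverage
#'
#' For every annotated intron, counts the distinct reads with at least one
#' aligned base inside the intron and no alignment gap equal to the intron
#' (reads gapped over the intron are splicing — exon — evidence), and the
#' fraction of intron bases covered at least once by such reads.  An intron
#' is called retained iff both thresholds of `cfg` are met.  Flanking-exon
#' read counts (distinct reads overlapping either adjacent exon) are
#' returned alongside for differential testing.
#'
#' @param alignments long block table
#' @param annotation annotation object
#' @param cfg an [ir_config()]
#' @return data.frame: gene_id, chrom, strand, intron_start, intron_end,
#'   intron_rank, n_unspliced_reads, covered_fraction, flank_reads, called
#' @export
call_intron_retention <- function(alignments, annotation, cfg = ir_config()) {
  introns <- annotation_introns(annotation)
  if (any(introns$end - introns$start <= 0L))
    stop("annotation error: zero-length intron", call. = FALSE)
  ex <- exons_transcribed(annotation)
  al <- alignments

  bl_gr <- GenomicRanges::GRanges(al$chrom,
                                  IRanges::IRanges(al$block_start + 1L, al$block_end))
  in_gr <- GenomicRanges::GRanges(introns$chrom,
                                  IRanges::IRanges(introns$start + 1L, introns$end))
  hits <- GenomicRanges::findOverlaps(bl_gr, in_gr)

  # alignment gaps, keyed, to exclude spliced reads per intron
  alo <- al[order(al$read_id, al$block_rank), ]
  n <- nrow(alo)
  same <- if (n > 1L) alo$read_id[-n] == alo$read_id[-1L] else logical(0)
  gi <- which(same)
  gap_key <- paste(alo$chrom[gi], alo$block_end[gi], alo$block_start[gi + 1L],
                   alo$read_id[gi], sep = ":")

  res <- introns
  names(res)[names(res) == "start"] <- "intron_start"
  names(res)[names(res) == "end"] <- "intron_end"
  res$n_unspliced_reads <- 0L
  res$covered_fraction <- 0
  res$flank_reads <- 0L

  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  for (k in seq_len(nrow(introns))) {
    rows <- qh[sh == k]
    if (length(rows)) {
      rid <- al$read_id[rows]
      spliced <- paste(introns$chrom[k], introns$start[k], introns$end[k],
                       rid, sep = ":") %in% gap_key
      keep <- !spliced
      res$n_unspliced_reads[k] <- length(unique(rid[keep]))
      if (any(keep)) {
        s <- pmax(al$block_start[rows[keep]], introns$start[k])
        e <- pmin(al$block_end[rows[keep]], introns$end[k])
        cov <- sum(IRanges::width(IRanges::reduce(IRanges::IRanges(s + 1L, e))))
        res$covered_fraction[k] <- cov / (introns$end[k] - introns$start[k])
      }
    }
  }
  # flanking exon reads: genomic neighbours of the intron
  ex_gr <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start + 1L, ex$end))
  eh <- GenomicRanges::findOverlaps(bl_gr, ex_gr)
  eq <- S4Vectors::queryHits(eh); es <- S4Vectors::subjectHits(eh)
  for (k in seq_len(nrow(introns))) {
    fl <- which(ex$gene_id == introns$gene_id[k] &
                  (ex$end == introns$start[k] | ex$start == introns$end[k]))
    rows <- eq[es %in% fl]
    res$flank_reads[k] <- length(unique(al$read_id[rows]))
  }
  res$called <- res$n_unspliced_reads >= cfg$min_reads &
    res$covered_fraction >= cfg$min_covered_fraction
  rownames(res) <- NULL
  res
}

#' Coding-frame impact of a splicing change
#'
#' For an alternative-splice-site or exon-skipping change, `delta_nt` is
#' the net number of coding nucleotides inserted (positive) or removed
#' (negative).  A multiple of 3 with no internal stop codon in any inserted
#' sequence is an in-frame indel of `abs(delta)/3` codons; any other shift
#' is a frameshift generating a premature termination codon.  For a
#' retained intron, the intron sequence is scanned for in-frame stop codons
#' starting at the reading frame given by `frame_offset` (transcript
#' position of the insertion point minus the translation start, mod 3).
#'
#' @param delta_nt net coding-length change in nt (alternative splice
#'   sites / skipping), or the intron length for retention
#' @param inserted_seq inserted nucleotide sequence to scan for stop
#'   codons (the retained intron sequence for retention events), or NULL
#' @param frame_offset reading-frame phase (0, 1, 2) at the insertion point
#' @param in_cds FALSE when the event lies outside the coding region
#' @param kind "alt_ss" or "ir"
#' @return list with `impact` (one of "in_frame_indel", "frameshift_PTC",
#'   "PTC_in_retained_intron", "non_coding") and `codons` (codon count for
#'   in-frame indels, else NA)
#' @export
frame_impact <- function(delta_nt, inserted_seq = NULL, frame_offset = 0L,
                         in_cds = TRUE, kind = c("alt_ss", "ir")) {
  kind <- match.arg(kind)
  if (!in_cds) return(list(impact = "non_coding", codons = NA_integer_))
  if (delta_nt %% 3L != 0L)
    return(list(impact = "frameshift_PTC", codons = NA_integer_))
  has_stop <- FALSE
  if (!is.null(inserted_seq) && nchar(inserted_seq) >= 3L) {
    lead <- (3L - frame_offset %% 3L) %% 3L
    starts <- seq(lead + 1L, nchar(inserted_seq) - 2L, by = 3L)
    codons <- substring(inserted_seq, starts, starts + 2L)
    has_stop <- any(codons %in% c("TAA", "TAG", "TGA"))
  }
  if (has_stop) {
    impact <- if (kind == "ir") "PTC_in_retained_intron" else "frameshift_PTC"
    return(list(impact = impact, codons = NA_integer_))
  }
  list(impact = "in_frame_indel", codons = abs(delta_nt) %/% 3L)
}
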