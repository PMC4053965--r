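#' Site table of annotated donors or acceptors
#'
#' One row per annotated intron with the boundary genome coordinate of the
#' requested site kind, oriented by strand: the donor boundary is the
#' transcribed 5' edge of the intron, the acceptor its 3' edge.
#'
#' @param annotation annotation object
#' @param site_kind "donor" or "acceptor"
#' @return data.frame: chrom, boundary, strand, gene_id, intron_rank
#' @export
site_table <- function(annotation, site_kind = c("donor", "acceptor")) {
  site_kind <- match.arg(site_kind)
  introns <- annotation_introns(annotation)
  boundary <- if (site_kind == "donor") {
    ifelse(introns$strand == "+", introns$start, introns$end)
  } else {
    ifelse(introns$strand == "+", introns$end, introns$start)
  }
  data.frame(chrom = introns$chrom, boundary = boundary,
             strand = introns$strand, gene_id = introns$gene_id,
             intron_rank = introns$intron_rank, stringsAsFactors = FALSE)
}

#' Position frequency matrix around splice sites
#'
#' Extracts a window of `window` nt on each side of every site boundary,
#' reverse-complementing minus-strand sites so all sequences read in
#' transcribed orientation, and tallies base counts per position.  Position
#' labels are signed: for donors, +1/+2 are the first two intron bases
#' (GT for canonical sites); for acceptors, -2/-1 are the last two intron
#' bases (AG).  There is no position 0.
#'
#' @param genome named DNAStringSet
#' @param sites data.frame from [site_table()] (columns chrom, boundary,
#'   strand), or any alternative-site table with those columns
#' @param window nt on each side of the boundary
#' @param site_kind "donor" or "acceptor" (controls the position labels)
#' @return list with `counts` (4 x 2*window matrix, rows A/C/G/T, columns
#'   labelled by signed position) and `n_sequences`; sites whose window
#'   exceeds chromosome bounds are skipped with a message
#' @export
extract_site_matrix <- function(genome, sites, window = 10L,
                                site_kind = c("donor", "acceptor")) {
  site_kind <- match.arg(site_kind)
  lens <- setNames(Biostrings::width(genome), names(genome))
  lo <- sites$boundary - window
  hi <- sites$boundary + window
  ok <- lo >= 0L & hi <= lens[sites$chrom]
  if (any(!ok))
    message(sum(!ok), " site(s) skipped: window exceeds chromosome bounds")
  sites <- sites[ok, , drop = FALSE]
  if (!nrow(sites)) stop("no sites left to tally", call. = FALSE)
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(sites)), function(i)
    genome_seq(genome, sites$chrom[i], sites$boundary[i] - window,
               sites$boundary[i] + window, sites$strand[i]), character(1)))
  cm <- Biostrings::consensusMatrix(seqs)[c("A", "C", "G", "T"), , drop = FALSE]
  pos <- c(-window:-1L, 1L:window)
  # the boundary sits between columns window and window+1; for donors the
  # intron is the right half (+1 = first intron base), for acceptors the
  # left half (-1 = last intron base) -- the signed labels above encode
  # exactly that, so the same column order serves both kinds
  colnames(cm) <- pos
  list(counts = cm, n_sequences = length(seqs), site_kind = site_kind)
}

#' Offset distribution of alternative splice sites around dominant sites
#'
#' Offsets are signed in transcribed orientation (downstream positive), as
#' already computed by [classify_events()] for ALT5SS/ALT3SS events.  The
#' histogram spans a +/- `window` nt window; the mass within +/-10 nt is
#' reported separately, the resolution at which alternative sites cluster
#' around dominant sites.
#'
#' @param events event table from [classify_events()]; rows with an NA
#'   offset (non-alternative-site events) are skipped
#' @param window histogram half-width in nt
#' @return list with `offsets` (integer vector), `histogram` (data.frame
#'   offset/count over -window..window, 0 excluded), `prop_within_10`, and
#'   `n_outside_window`
#' @export
offset_distribution <- function(events, window = 50L) {
  off <- events$offset[!is.na(events$offset)]
  if (any(off == 0L)) stop("alternative site with offset 0", call. = FALSE)
  bins <- setdiff(seq(-window, window), 0L)
  counts <- vapply(bins, function(b) sum(off == b), integer(1))
  list(
    offsets = off,
    histogram = data.frame(offset = bins, count = counts),
    prop_within_10 = if (length(off)) mean(abs(off) <= 10L) else NA_real_,
    n_outside_window = sum(abs(off) > window)
  )
}

#' Co-occurrence of exon skipping and alternative splice sites
#'
#' Tests whether exons skipped by cassette events carry alternative 5'/3'
#' splice sites more often than annotated exons at large.  An exon is
#' skipped when it lies strictly inside a CASSETTE or COORD_CASSETTE
#' junction; it bears an alternative site when an ALT5SS/ALT3SS event's
#' dominant boundary coincides with one of its edges.  Counting is
#' per-exon.
#'
#' @param events event table from [classify_events()]
#' @param annotation annotation object
#' @return list with `observed_fraction` (alt-SS rate among skipped exons),
#'   `background_fraction` (rate among all annotated exons), `p_value`
#'   (Fisher, skipped vs not x alt vs not), and `table` (the 2x2 matrix);
#'   NULL when there are no skipped exons
#' @export
coordination_test <- function(events, annotation) {
  ex <- annotation$exons
  skip_ev <- events[events$event_type %in% c("CASSETTE", "COORD_CASSETTE"), ,
                    drop = FALSE]
  if (!nrow(skip_ev)) return(NULL)
  skipped <- rep(FALSE, nrow(ex))
  for (r in seq_len(nrow(skip_ev)))
    skipped <- skipped | (ex$chrom == skip_ev$chrom[r] &
                            ex$start > skip_ev$junction_start[r] &
                            ex$end < skip_ev$junction_end[r])
  alt_ev <- events[events$event_type %in% c("ALT5SS", "ALT3SS"), , drop = FALSE]
  has_alt <- rep(FALSE, nrow(ex))
  for (r in seq_len(nrow(alt_ev))) {
    # the exon whose boundary moved: donor exon for ALT5SS, acceptor exon
    # for ALT3SS, located from the dominant junction and gene strand
    if (alt_ev$event_type[r] == "ALT5SS") {
      b <- if (alt_ev$strand[r] == "+") alt_ev$dominant_start[r] else
        alt_ev$dominant_end[r]
      hit <- ex$chrom == alt_ev$chrom[r] &
        (ex$end == b | ex$start == b)
    } else {
      b <- if (alt_ev$strand[r] == "+") alt_ev$dominant_end[r] else
        alt_ev$dominant_start[r]
      hit <- ex$chrom == alt_ev$chrom[r] &
        (ex$start == b | ex$end == b)
    }
    has_alt <- has_alt | hit
  }
  tab <- matrix(c(sum(skipped & has_alt), sum(skipped & !has_alt),
                  sum(!skipped & has_alt), sum(!skipped & !has_alt)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("skipped", "not_skipped"),
                                c("alt_ss", "no_alt_ss")))
  list(observed_fraction = mean(has_alt[skipped]),
       background_fraction = mean(has_alt),
       p_value = suppressWarnings(fisher_2x2(tab)),
       table = tab)
}
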