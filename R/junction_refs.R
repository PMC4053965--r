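# spliced-context flank sequences around every annotated intron.
# Returns one row per intron with the donor-side flank (last `flank` nt of
# transcript sequence 5' of the junction) and acceptor-side flank (first
# `flank` nt 3' of it).  When a gene end leaves less context than `flank`,
# the flank is padded with N at its far end so reference length stays
# constant.
intron_flanks <- function(genome, annotation, flank) {
  introns <- annotation_introns(annotation)
  ex <- exons_transcribed(annotation)
  out <- vector("list", nrow(introns))
  for (g in unique(introns$gene_id)) {
    gx <- ex[ex$gene_id == g, ]
    gx <- gx[order(gx$exon_rank), ]
    ord <- order(gx$start)
    tseq <- spliced_seq(genome, gx$chrom[1], gx$start[ord], gx$end[ord],
                        gx$strand[1])
    # junction transcript coordinate after exon k (transcribed order)
    exw <- gx$end - gx$start
    cum <- cumsum(exw)
    tlen <- sum(exw)
    gi <- which(introns$gene_id == g)
    for (r in gi) {
      k <- introns$intron_rank[r]
      j <- cum[k]
      dstart <- max(0L, j - flank)
      donor <- substring(tseq, dstart + 1L, j)
      if (nchar(donor) < flank)
        donor <- paste0(strrep("N", flank - nchar(donor)), donor)
      aend <- min(tlen, j + flank)
      acceptor <- substring(tseq, j + 1L, aend)
      if (nchar(acceptor) < flank)
        acceptor <- paste0(acceptor, strrep("N", flank - nchar(acceptor)))
      out[[r]] <- data.frame(
        gene_id = g, chrom = gx$chrom[1], strand = gx$strand[1],
        intron_rank = k, intron_start = introns$start[r],
        intron_end = introns$end[r], donor_flank = donor,
        acceptor_flank = acceptor, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Build annotated or random junction reference sequences
#'
#' A junction reference is the concatenation of a donor-side and an
#' acceptor-side exonic flank of `flank` nt each (2 x flank total, in
#' transcribed orientation), sized so a read of length flank + 11 mapping
#' across the junction must overhang by at least 11 nt.  With the study's
#' read lengths this gives 180 nt references for 101 nt reads and 148 nt
#' for 85 nt reads.  Flanks come from the spliced transcript context, so
#' exons shorter than the flank borrow from upstream/downstream exons.
#'
#' Annotated mode emits one reference per annotated intron.  Random mode
#' emits decoy references whose donor and acceptor flanks come from introns
#' on different chromosomes — junctions that essentially never exist, used
#' as the false-positive null.
#'
#' @param genome named DNAStringSet
#' @param annotation annotation object
#' @param flank flank length in nt; conventionally read_length - 11
#' @param mode "annotated" or "random"
#' @param n_random number of random references (random mode only)
#' @param seed seed for random pairing
#' @return data.frame: ref_id, sequence, flank, origin, donor_chrom,
#'   donor_locus, acceptor_chrom, acceptor_locus
#' @export
build_junction_refs <- function(genome, annotation, flank,
                                mode = c("annotated", "random"),
                                n_random = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  fl <- intron_flanks(genome, annotation, flank)
  if (mode == "annotated") {
    return(data.frame(
      ref_id = sprintf("ann_%s_i%d", fl$gene_id, fl$intron_rank),
      sequence = paste0(fl$donor_flank, fl$acceptor_flank),
      flank = flank, origin = "annotated",
      donor_chrom = fl$chrom,
      donor_locus = ifelse(fl$strand == "+", fl$intron_start, fl$intron_end),
      acceptor_chrom = fl$chrom,
      acceptor_locus = ifelse(fl$strand == "+", fl$intron_end, fl$intron_start),
      stringsAsFactors = FALSE))
  }
  set.seed(seed)
  # full-context flanks only, so decoy reads are well-defined substrings
  don_ok <- which(!grepl("N", fl$donor_flank, fixed = TRUE))
  acc_ok <- which(!grepl("N", fl$acceptor_flank, fixed = TRUE))
  if (!length(don_ok) || !length(acc_ok))
    stop("no full-context flanks available for random references", call. = FALSE)
  # distinct (donor, acceptor) pairs on different chromosomes
  grid <- expand.grid(di = don_ok, ai = acc_ok)
  grid <- grid[fl$chrom[grid$di] != fl$chrom[grid$ai], , drop = FALSE]
  if (nrow(grid) < n_random)
    stop("n_random exceeds the ", nrow(grid),
         " available cross-chromosome pairs", call. = FALSE)
  pick <- grid[sample.int(nrow(grid), n_random), ]
  di <- pick$di; ai <- pick$ai
  data.frame(
    ref_id = sprintf("rnd_%06d", seq_len(n_random)),
    sequence = paste0(fl$donor_flank[di], fl$acceptor_flank[ai]),
    flank = flank, origin = "random",
    donor_chrom = fl$chrom[di],
    donor_locus = ifelse(fl$strand[di] == "+", fl$intron_start[di],
                         fl$intron_end[di]),
    acceptor_chrom = fl$chrom[ai],
    acceptor_locus = ifelse(fl$strand[ai] == "+", fl$intron_end[ai],
                            fl$intron_start[ai]),
    stringsAsFactors = FALSE)
}

#' Match raw reads to junction references without mismatches
#'
#' A read supports a reference iff its sequence is an exact substring of
#' the reference sequence and the placement crosses the reference midpoint
#' with at least `min_anchor` nt on both sides.  The recorded overhang is
#' the shorter side of the placement.  A read matching several references
#' is counted for each (the multiplicity is returned as an attribute); a
#' read matching one reference at several qualifying offsets is counted
#' once, at its largest overhang.
#'
#' @param reads data.frame (read_id, seq); sequences containing non-ACGT
#'   characters cannot match and are skipped
#' @param refs reference table from [build_junction_refs()]
#' @param min_anchor minimum nt on each side of the junction midpoint
#' @return data.frame of support records: ref_id, read_id, overhang; with
#'   attribute `multimatch` (read_id, n_refs) for reads matching > 1 ref
#' @export
match_reads_to_refs <- function(reads, refs, min_anchor = 11L) {
  empty <- data.frame(ref_id = character(), read_id = character(),
                      overhang = integer(), stringsAsFactors = FALSE)
  ok <- grepl("^[ACGT]+$", reads$seq)
  reads <- reads[ok, , drop = FALSE]
  if (!nrow(reads) || !nrow(refs)) {
    attr(empty, "multimatch") <- data.frame(read_id = character(),
                                            n_refs = integer())
    return(empty)
  }
  out <- list()
  for (L in unique(nchar(reads$seq))) {
    sub <- reads[nchar(reads$seq) == L, ]
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(sub$seq))
    for (i in seq_len(nrow(refs))) {
      flank <- refs$flank[i]
      m <- Biostrings::matchPDict(pd, Biostrings::DNAString(refs$sequence[i]))
      hits <- which(lengths(m) > 0L)
      for (h in hits) {
        p <- IRanges::start(m[[h]]) - 1L   # 0-based placements
        left <- flank - p
        right <- p + L - flank
        keep <- left >= min_anchor & right >= min_anchor
        if (!any(keep)) next
        out[[length(out) + 1L]] <- data.frame(
          ref_id = refs$ref_id[i], read_id = sub$read_id[h],
          overhang = max(pmin(left[keep], right[keep])),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  nref <- table(res$read_id)
  multi <- nref[nref > 1L]
  attr(res, "multimatch") <- data.frame(read_id = names(multi),
                                        n_refs = as.integer(multi),
                                        stringsAsFactors = FALSE)
  res
}

#' Summarize per-reference support
#'
#' @param support support records from [match_reads_to_refs()]
#' @return data.frame: ref_id, read_count, max_overhang
#' @export
summarize_ref_support <- function(support) {
  if (!nrow(support))
    return(data.frame(ref_id = character(), read_count = integer(),
                      max_overhang = integer(), stringsAsFactors = FALSE))
  cnt <- tapply(rep(1L, nrow(support)), support$ref_id, sum)
  mx <- tapply(support$overhang, support$ref_id, max)
  data.frame(ref_id = names(cnt), read_count = as.integer(cnt),
             max_overhang = as.integer(mx[names(cnt)]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Characterize the false-positive null against annotated junctions
#'
#' Tabulates, for random-reference (decoy) and annotated-reference support,
#' the per-junction distributions of maximum overhang and read count, and
#' the fraction of supported junctions surviving each candidate
#' (overhang, reads) threshold pair — the calibration view behind the
#' > 20 bp / >= 2 reads cutoffs.
#'
#' @param random_support support records for random references
#' @param annotated_support support records for annotated references
#' @param overhang_grid candidate exclusive overhang thresholds
#' @param reads_grid candidate minimum read counts
#' @return list with `per_ref` (origin, ref_id, read_count, max_overhang)
#'   and `survival` (origin, min_overhang_exclusive, min_reads, n_refs,
#'   n_surviving, survival); `note` flags an unexercised null
#' @export
characterize_null <- function(random_support, annotated_support,
                              overhang_grid = c(0L, 10L, 15L, 20L, 25L),
                              reads_grid = c(1L, 2L, 3L)) {
  rs <- summarize_ref_support(random_support)
  as_ <- summarize_ref_support(annotated_support)
  per_ref <- rbind(
    if (nrow(rs)) cbind(origin = "random", rs) else NULL,
    if (nrow(as_)) cbind(origin = "annotated", as_) else NULL)
  grid <- expand.grid(min_overhang_exclusive = overhang_grid,
                      min_reads = reads_grid)
  surv <- do.call(rbind, lapply(c("random", "annotated"), function(o) {
    tab <- per_ref[per_ref$origin == o, , drop = FALSE]
    do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      ns <- if (nrow(tab)) sum(tab$max_overhang > grid$min_overhang_exclusive[i] &
                                 tab$read_count >= grid$min_reads[i]) else 0L
      data.frame(origin = o,
                 min_overhang_exclusive = grid$min_overhang_exclusive[i],
                 min_reads = grid$min_reads[i],
                 n_refs = nrow(tab), n_surviving = ns,
                 survival = if (nrow(tab)) ns / nrow(tab) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  note <- if (!nrow(rs)) "null not exercised: no random-reference support" else NA_character_
  list(per_ref = per_ref, survival = surv, note = note)
}
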