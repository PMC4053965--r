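# map a transcript-coordinate window [s, s+len) through an isoform's
# genomic exon blocks (sorted by genome coordinate).  For minus-strand
# isoforms the window is first mirrored into plus-orientation transcript
# coordinates; the genome blocks a read covers are strand-symmetric.
window_to_blocks <- function(blocks, strand, s, len) {
  w <- blocks$end - blocks$start
  total <- sum(w)
  u <- if (strand == "-") total - (s + len) else s
  cum <- cumsum(c(0L, w))
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_len(nrow(blocks))) {
    a <- max(u, cum[i]); b <- min(u + len, cum[i + 1L])
    if (b > a) {
      out_s <- c(out_s, blocks$start[i] + (a - cum[i]))
      out_e <- c(out_e, blocks$start[i] + (b - cum[i]))
    }
  }
  data.frame(start = out_s, end = out_e)
}

#' Simulate reads and truth spliced alignments from an isoform pool
#'
#' Each read is a fixed-length window on one isoform (isoform drawn with
#' probability proportional to its mixture weight within a uniformly chosen
#' gene; start uniform along the isoform), emitted both as a raw sequence
#' in transcribed orientation and as its truth-derived gapped alignment in
#' genome coordinates.  Reads spanning a spliced-out intron yield
#' multi-block alignments.  Substitution errors at `error_rate` are applied
#' to the raw sequence only; alignment coordinates always reflect the truth
#' placement (no aligner is run — the pipeline's inputs begin at spliced
#' alignments).
#'
#' @param genome named DNAStringSet
#' @param pool isoform pool from [simulate_isoforms()]
#' @param config a [sim_config()]
#' @param lib_name prefix for read identifiers
#' @param n_reads number of reads; defaults to `config$library_depth`
#' @param seed integer seed; defaults to a stage seed derived from the
#'   config seed
#' @return list with `alignments` (long block table: read_id, chrom,
#'   strand, block_start, block_end, block_rank) and `reads` (read_id, seq,
#'   iso_id)
#' @export
simulate_reads <- function(genome, pool, config, lib_name = "lib",
                           n_reads = config$library_depth,
                           seed = derive_seed(config$seed, 3L)) {
  set.seed(seed)
  L <- config$read_length
  blocks_list <- lapply(pool$blocks, str_to_blocks)
  iso_len <- vapply(blocks_list, function(b) sum(b$end - b$start), integer(1))
  usable <- iso_len >= L & pool$weight > 0
  if (any(iso_len < L & pool$weight > 0))
    warning(sum(iso_len < L & pool$weight > 0),
            " isoform(s) shorter than the read length were skipped")
  if (!any(usable)) stop("no usable isoforms", call. = FALSE)
  # per-read isoform: gene uniform; within a gene, isoform probability is
  # weight x length, so per-base coverage is proportional to molar
  # abundance (a read is a window on a molecule, longer molecules offer
  # more windows)
  p <- pool$weight * iso_len * usable
  gene_tot <- tapply(p, pool$gene_id, sum)
  p <- p / as.numeric(gene_tot[pool$gene_id])
  p[is.na(p)] <- 0
  p <- p / sum(p)
  idx <- sample.int(nrow(pool), n_reads, replace = TRUE, prob = p)
  starts <- as.integer(floor(runif(n_reads) * (iso_len[idx] - L + 1L)))

  iso_seqs <- rep(NA_character_, nrow(pool))
  need <- sort(unique(idx))
  for (i in need)
    iso_seqs[i] <- spliced_seq(genome, pool$chrom[i], blocks_list[[i]]$start,
                               blocks_list[[i]]$end, pool$strand[i])

  read_id <- sprintf("%s_r%06d", lib_name, seq_len(n_reads))
  seqs <- substring(iso_seqs[idx], starts + 1L, starts + L)
  # substitution errors on the raw sequence only
  if (config$error_rate > 0) {
    n_err <- rbinom(n_reads, L, config$error_rate)
    bases <- c("A", "C", "G", "T")
    for (r in which(n_err > 0L)) {
      posn <- sample.int(L, n_err[r])
      for (pp in posn) {
        old <- substr(seqs[r], pp, pp)
        substr(seqs[r], pp, pp) <- sample1(setdiff(bases, old))
      }
    }
  }
  # truth alignments, vectorized per isoform: each read window [u, u+L)
  # in plus-orientation transcript coordinates is intersected with the
  # isoform's cumulative block layout
  aln <- vector("list", length(need))
  for (jj in seq_along(need)) {
    i <- need[jj]
    rr <- which(idx == i)
    blocks <- blocks_list[[i]]
    w <- blocks$end - blocks$start
    cum <- cumsum(c(0L, w))
    total <- sum(w)
    u <- if (pool$strand[i] == "-") total - (starts[rr] + L) else starts[rr]
    parts <- vector("list", nrow(blocks))
    for (j in seq_len(nrow(blocks))) {
      a <- pmax(u, cum[j]); b <- pmin(u + L, cum[j + 1L])
      keep <- b > a
      if (!any(keep)) next
      parts[[j]] <- data.frame(
        read_idx = rr[keep], j = j,
        block_start = blocks$start[j] + (a[keep] - cum[j]),
        block_end = blocks$start[j] + (b[keep] - cum[j]))
    }
    pa <- do.call(rbind, parts)
    pa <- pa[order(pa$read_idx, pa$j), ]
    rank <- sequence(rle(pa$read_idx)$lengths)
    aln[[jj]] <- data.frame(read_id = read_id[pa$read_idx],
                            chrom = pool$chrom[i], strand = pool$strand[i],
                            block_start = pa$block_start,
                            block_end = pa$block_end, block_rank = rank,
                            stringsAsFactors = FALSE)
  }
  aln <- do.call(rbind, aln)
  aln <- aln[order(aln$read_id, aln$block_rank), ]
  rownames(aln) <- NULL
  list(alignments = aln,
       reads = data.frame(read_id = read_id, seq = seqs,
                          iso_id = pool$iso_id[idx], stringsAsFactors = FALSE))
}

#' Generate decoy junction-spanning reads
#'
#' Decoy reads are sampled from random junction references — artificial
#' junctions joining exon flanks from two different chromosomes (see
#' [build_junction_refs()]) — so each read straddles a cross-chromosomal
#' junction that cannot arise from true splicing.  Overhangs are drawn from
#' `config$decoy_overhang_range` (short, at or above the matcher's 11 nt
#' anchor but at or below 15 nt by default) and, in singleton mode, every
#' decoy junction receives exactly one read, mimicking the short-overhang,
#' single-read profile of false-positive junctions.
#'
#' @param genome named DNAStringSet (>= 2 chromosomes)
#' @param annotation annotation object
#' @param config a [sim_config()]
#' @param refs optional precomputed random junction references; built from
#'   the config seed when NULL
#' @return list with `reads` (read_id, seq), `truth` (read_id, ref_id,
#'   overhang, donor_chrom, acceptor_chrom) and `refs` (the junction
#'   reference table used)
#' @export
make_decoy_reads <- function(genome, annotation, config, refs = NULL) {
  if (length(genome) < 2L)
    stop("decoy junctions need at least 2 chromosomes", call. = FALSE)
  set.seed(derive_seed(config$seed, 4L))
  L <- config$read_length
  flank <- L - 11L
  n <- config$decoy_read_count
  if (is.null(refs)) {
    n_refs <- if (config$decoy_singleton) n else max(1L, n %/% 3L)
    refs <- build_junction_refs(genome, annotation, flank = flank,
                                mode = "random", n_random = n_refs,
                                seed = derive_seed(config$seed, 5L))
  }
  ref_idx <- if (config$decoy_singleton) {
    if (n > nrow(refs)) stop("not enough refs for singleton decoys", call. = FALSE)
    seq_len(n)
  } else sample.int(nrow(refs), n, replace = TRUE)
  o <- sample(seq(config$decoy_overhang_range[1],
                  config$decoy_overhang_range[2]), n, replace = TRUE)
  left_short <- sample(c(TRUE, FALSE), n, replace = TRUE)
  # left flank length within the read; midpoint of ref at position `flank`
  left_len <- ifelse(left_short, o, L - o)
  start <- flank - left_len   # 0-based within ref sequence
  seqs <- substring(refs$sequence[ref_idx], start + 1L, start + L)
  read_id <- sprintf("decoy_r%06d", seq_len(n))
  list(
    reads = data.frame(read_id = read_id, seq = seqs, stringsAsFactors = FALSE),
    truth = data.frame(read_id = read_id, ref_id = refs$ref_id[ref_idx],
                       overhang = pmin(left_len, L - left_len),
                       donor_chrom = refs$donor_chrom[ref_idx],
                       acceptor_chrom = refs$acceptor_chrom[ref_idx],
                       stringsAsFactors = FALSE),
    refs = refs
  )
}
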