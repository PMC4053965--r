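#' Reads per kilobase of feature per million mapped reads
#'
#' @param read_count reads (possibly fractional) assigned to the feature
#' @param length_nt feature length in nt (> 0)
#' @param total_mapped total mapped reads in the library (> 0)
#' @return RPKM value(s); linear in read_count, inverse in total_mapped
#' @export
rpkm <- function(read_count, length_nt, total_mapped) {
  if (any(length_nt <= 0) || any(total_mapped <= 0))
    stop("length_nt and total_mapped must be positive", call. = FALSE)
  read_count / (length_nt / 1000) / (total_mapped / 1e6)
}

# fractional read counts per feature: each read contributes
# overlap / aligned-read-length to every feature it overlaps, avoiding
# double counting of boundary-spanning reads.  For introns, reads whose
# alignment gap equals the intron (junction reads) are excluded: they are
# splicing evidence, not intron expression.
count_features <- function(alignments, features, exclude_spliced = FALSE) {
  al <- alignments
  read_len <- tapply(al$block_end - al$block_start, al$read_id, sum)
  bl_gr <- GenomicRanges::GRanges(al$chrom,
                                  IRanges::IRanges(al$block_start + 1L, al$block_end))
  ft_gr <- GenomicRanges::GRanges(features$chrom,
                                  IRanges::IRanges(features$start + 1L, features$end))
  hits <- GenomicRanges::findOverlaps(bl_gr, ft_gr)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  if (exclude_spliced) {
    alo <- al[order(al$read_id, al$block_rank), ]
    n <- nrow(alo)
    same <- if (n > 1L) alo$read_id[-n] == alo$read_id[-1L] else logical(0)
    gi <- which(same)
    gap_key <- paste(alo$chrom[gi], alo$block_end[gi], alo$block_start[gi + 1L],
                     alo$read_id[gi], sep = ":")
    pair_key <- paste(features$chrom[sh], features$start[sh], features$end[sh],
                      al$read_id[qh], sep = ":")
    keep <- !(pair_key %in% gap_key)
    qh <- qh[keep]; sh <- sh[keep]
  }
  ov <- pmin(al$block_end[qh], features$end[sh]) -
    pmax(al$block_start[qh], features$start[sh])
  w <- ov / as.numeric(read_len[al$read_id[qh]])
  counts <- numeric(nrow(features))
  if (length(sh)) {
    agg <- tapply(w, sh, sum)
    counts[as.integer(names(agg))] <- as.numeric(agg)
  }
  counts
}

#' Feature-level expression table
#'
#' Fractionally counts reads over annotated exons and introns and converts
#' to RPKM.  Intron expression counts only unspliced reads; junction reads
#' gapped over an intron never contribute to it.
#'
#' @param alignments long block table
#' @param annotation annotation object
#' @param total_mapped library total of mapped reads; defaults to the
#'   number of distinct reads in `alignments`
#' @return data.frame: feature_id, feature_kind ("exon"/"intron"), gene_id,
#'   chrom, start, end, length, read_count, rpkm
#' @export
feature_expression <- function(alignments, annotation,
                               total_mapped = length(unique(alignments$read_id))) {
  ex <- exons_transcribed(annotation)
  introns <- annotation_introns(annotation)
  exf <- data.frame(
    feature_id = sprintf("%s.exon%d", ex$gene_id, ex$exon_rank),
    feature_kind = "exon", gene_id = ex$gene_id, chrom = ex$chrom,
    start = ex$start, end = ex$end, stringsAsFactors = FALSE)
  inf <- data.frame(
    feature_id = sprintf("%s.intron%d", introns$gene_id, introns$intron_rank),
    feature_kind = "intron", gene_id = introns$gene_id, chrom = introns$chrom,
    start = introns$start, end = introns$end, stringsAsFactors = FALSE)
  exf$read_count <- count_features(alignments, exf)
  inf$read_count <- count_features(alignments, inf, exclude_spliced = TRUE)
  out <- rbind(exf, inf)
  out$length <- out$end - out$start
  out$rpkm <- rpkm(out$read_count, out$length, total_mapped)
  rownames(out) <- NULL
  out
}

#' Paired intron/exon expression between two conditions
#'
#' @param expr_a,expr_b tables from [feature_expression()] on the two
#'   libraries (same annotation)
#' @return list with `paired` (feature_id, feature_kind, rpkm_a, rpkm_b)
#'   and `summary` (per feature_kind: n, median_ratio of B over A among
#'   features expressed in A)
#' @export
intron_exon_scatter <- function(expr_a, expr_b) {
  stopifnot(identical(expr_a$feature_id, expr_b$feature_id))
  paired <- data.frame(feature_id = expr_a$feature_id,
                       feature_kind = expr_a$feature_kind,
                       rpkm_a = expr_a$rpkm, rpkm_b = expr_b$rpkm,
                       stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(paired, paired$feature_kind), function(d) {
    ok <- d$rpkm_a > 0
    data.frame(feature_kind = d$feature_kind[1], n = nrow(d),
               median_ratio = if (any(ok)) median(d$rpkm_b[ok] / d$rpkm_a[ok])
               else NA_real_, stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(paired = paired, summary = summ)
}

#' Intron-retention proportion per intron
#'
#' The retained-intron share of a gene's transcripts, estimated as the
#' intron RPKM divided by the RPKM of its two flanking exons (combined
#' count over combined length).  Undefined (NA, flagged) when the flanking
#' exons are unexpressed.
#'
#' @param alignments long block table
#' @param annotation annotation object
#' @param total_mapped library total (defaults to reads in `alignments`)
#' @return data.frame: gene_id, chrom, intron_start, intron_end,
#'   intron_rank, intron_rpkm, flanking_exon_rpkm, proportion, undefined
#' @export
ir_proportion <- function(alignments, annotation,
                          total_mapped = length(unique(alignments$read_id))) {
  expr <- feature_expression(alignments, annotation, total_mapped)
  introns <- annotation_introns(annotation)
  ex <- expr[expr$feature_kind == "exon", ]
  inx <- expr[expr$feature_kind == "intron", ]
  out <- introns
  names(out)[names(out) == "start"] <- "intron_start"
  names(out)[names(out) == "end"] <- "intron_end"
  out$intron_rpkm <- NA_real_; out$flanking_exon_rpkm <- NA_real_
  for (k in seq_len(nrow(out))) {
    ik <- which(inx$gene_id == out$gene_id[k] &
                  inx$start == out$intron_start[k])
    out$intron_rpkm[k] <- inx$rpkm[ik[1]]
    fl <- ex[ex$gene_id == out$gene_id[k] &
               (ex$end == out$intron_start[k] | ex$start == out$intron_end[k]), ]
    if (nrow(fl)) {
      out$flanking_exon_rpkm[k] <- rpkm(sum(fl$read_count),
                                        sum(fl$length),
                                        total_mapped)
    }
  }
  out$undefined <- is.na(out$flanking_exon_rpkm) | out$flanking_exon_rpkm == 0
  out$proportion <- ifelse(out$undefined, NA_real_,
                           out$intron_rpkm / out$flanking_exon_rpkm)
  out[, c("gene_id", "chrom", "intron_start", "intron_end", "intron_rank",
          "intron_rpkm", "flanking_exon_rpkm", "proportion", "undefined")]
}

#' Functional-transcript expression
#'
#' Deducts the retained-intron signal from the total-transcript signal
#' (the read level of the two exons flanking the retained intron), flooring
#' at zero with a flag; functional expression never exceeds the total.
#'
#' @param total total-transcript signal (vector)
#' @param retained retained-intron signal (vector, same length/units)
#' @return data.frame: total, retained, functional, floored
#' @export
functional_expression <- function(total, retained) {
  stopifnot(length(total) == length(retained))
  raw <- total - retained
  data.frame(total = total, retained = retained,
             functional = pmax(raw, 0), floored = raw < 0)
}

#' Gene-detection saturation curve
#'
#' Reads are shuffled once under the seed and consumed as nested prefixes,
#' so detected-gene counts are monotone non-decreasing in depth by
#' construction.
#'
#' @param alignments long block table
#' @param annotation annotation object
#' @param steps read counts at which to evaluate detection; defaults to
#'   ten equal steps up to the library size
#' @param seed integer seed for the shuffle
#' @return data.frame: n_reads, genes_detected
#' @export
saturation_curve <- function(alignments, annotation, steps = NULL, seed = 1L) {
  ids <- unique(alignments$read_id)
  if (is.null(steps))
    steps <- unique(pmax(1L, round(seq_len(10L) / 10 * length(ids))))
  if (any(steps > length(ids))) stop("step exceeds library size", call. = FALSE)
  set.seed(seed)
  ids <- sample(ids)
  g <- annotation$genes
  g_gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start + 1L, g$end))
  bl_gr <- GenomicRanges::GRanges(
    alignments$chrom,
    IRanges::IRanges(alignments$block_start + 1L, alignments$block_end))
  hits <- GenomicRanges::findOverlaps(bl_gr, g_gr)
  first_gene <- tapply(S4Vectors::subjectHits(hits),
                       alignments$read_id[S4Vectors::queryHits(hits)],
                       function(x) x[1])
  gene_of <- as.integer(first_gene[ids])   # NA for intergenic-only reads
  out <- data.frame(n_reads = sort(as.integer(steps)))
  out$genes_detected <- vapply(out$n_reads, function(n)
    length(unique(gene_of[seq_len(n)][!is.na(gene_of[seq_len(n)])])),
    integer(1))
  out
}

#' Median coverage along relative transcript position
#'
#' Per gene, genome coverage is read off along the spliced transcript in
#' transcribed orientation, averaged within `n_bins` equal relative bins,
#' and the median over genes is reported per bin.  Uniform input coverage
#' yields a flat profile.
#'
#' @param alignments long block table
#' @param annotation annotation object
#' @param n_bins number of relative-position bins
#' @return data.frame: bin (1..n_bins, 5' to 3'), median_depth
#' @export
transcript_coverage_profile <- function(alignments, annotation, n_bins = 20L) {
  covs <- lapply(split(alignments, alignments$chrom), function(a)
    IRanges::coverage(IRanges::IRanges(a$block_start + 1L, a$block_end)))
  ex <- exons_transcribed(annotation)
  per_gene <- lapply(split(ex, ex$gene_id), function(g) {
    g <- g[order(g$start), ]
    cv <- covs[[g$chrom[1]]]
    if (is.null(cv)) return(rep(0, n_bins))
    depth <- unlist(lapply(seq_len(nrow(g)), function(i) {
      idx <- (g$start[i] + 1L):g$end[i]
      d <- numeric(length(idx))
      sel <- idx <= length(cv)
      if (any(sel)) d[sel] <- as.numeric(cv[idx[sel]])
      d
    }))
    if (g$strand[1] == "-") depth <- rev(depth)
    tlen <- length(depth)
    bin <- pmin(n_bins, floor((seq_len(tlen) - 1L) / tlen * n_bins) + 1L)
    as.numeric(tapply(depth, bin, mean))
  })
  mat <- do.call(rbind, per_gene)
  data.frame(bin = seq_len(n_bins), median_depth = apply(mat, 2L, median))
}

#' Mean coverage over the expressed transcriptome
#'
#' Total aligned bases divided by the summed exonic length of genes with at
#' least one overlapping read.
#'
#' @param alignments long block table
#' @param annotation annotation object
#' @return a single coverage estimate (fold)
#' @export
estimate_mean_coverage <- function(alignments, annotation) {
  total_bases <- sum(alignments$block_end - alignments$block_start)
  ex <- annotation$exons
  g <- annotation$genes
  g_gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start + 1L, g$end))
  bl_gr <- GenomicRanges::GRanges(
    alignments$chrom,
    IRanges::IRanges(alignments$block_start + 1L, alignments$block_end))
  hits <- GenomicRanges::findOverlaps(bl_gr, g_gr)
  expressed <- g$gene_id[unique(S4Vectors::subjectHits(hits))]
  tx_len <- sum(ex$end[ex$gene_id %in% expressed] -
                  ex$start[ex$gene_id %in% expressed])
  if (tx_len == 0) return(0)
  total_bases / tx_len
}
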