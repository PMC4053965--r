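#' Derive a stage seed from a global seed
#'
#' A single run-level seed fans out to per-stage seeds by a fixed affine
#' map, so each stage is independently rerunnable and all seeds stay below
#' the 32-bit integer limit.
#'
#' @param seed global integer seed
#' @param stage stage index (small non-negative integer)
#' @return an integer seed
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stage))
  as.integer((as.numeric(seed) * 2654435L + stage * 97L) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample one element of x (safe for length-1 vectors, unlike sample())
sample1 <- function(x) x[sample.int(length(x), 1L)]

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single probability in [0,1]", name), call. = FALSE)
  invisible(x)
}

check_range <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || any(is.na(x)) || x[2] < x[1])
    stop(sprintf("'%s' must be a non-empty numeric range c(lo, hi)", name), call. = FALSE)
  as.integer(x)
}

#' Intron intervals of an annotation
#'
#' Gaps between consecutive exons of each gene, with donor/acceptor genome
#' coordinates oriented by strand (donor = transcribed 5' boundary).
#'
#' @param annotation an annotation as returned by [make_genome_and_annotation()]
#'   or [read_annotation_gff3()]
#' @return data.frame with columns gene_id, chrom, strand, start, end
#'   (0-based half-open intron interval), intron_rank (transcribed order),
#'   donor, acceptor (genome coordinates of the intron boundaries; for a
#'   plus-strand intron donor = start and acceptor = end)
#' @export
annotation_introns <- function(annotation) {
  ex <- annotation$exons
  ex <- ex[order(ex$gene_id, ex$start), ]
  res <- do.call(rbind, lapply(split(ex, ex$gene_id), function(g) {
    n <- nrow(g)
    if (n < 2L) return(NULL)
    data.frame(
      gene_id = g$gene_id[1], chrom = g$chrom[1], strand = g$strand[1],
      start = g$end[-n], end = g$start[-1],
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(res)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(), end = integer(),
                      intron_rank = integer(), donor = integer(),
                      acceptor = integer(), stringsAsFactors = FALSE))
  }
  rownames(res) <- NULL
  # transcribed order: genomic order for '+', reversed for '-'
  res$intron_rank <- ave(seq_len(nrow(res)), res$gene_id, FUN = function(i) {
    k <- seq_along(i)
    if (res$strand[i[1]] == "+") k else rev(k)
  })
  res$donor <- ifelse(res$strand == "+", res$start, res$end)
  res$acceptor <- ifelse(res$strand == "+", res$end, res$start)
  res
}

#' Exon table in transcribed order
#'
#' @param annotation annotation object
#' @return the exon data.frame with exon_rank recomputed in transcribed
#'   (5' to 3') order
#' @keywords internal
exons_transcribed <- function(annotation) {
  ex <- annotation$exons
  ex <- ex[order(ex$gene_id, ex$start), ]
  ex$exon_rank <- ave(seq_len(nrow(ex)), ex$gene_id, FUN = function(i) {
    k <- seq_along(i)
    if (ex$strand[i[1]] == "+") k else rev(k)
  })
  ex
}

#' Extract a genome subsequence (0-based half-open)
#'
#' @param genome named DNAStringSet
#' @param chrom chromosome name
#' @param start,end 0-based half-open interval
#' @param strand "+" returns the forward sequence, "-" its reverse complement
#' @return character scalar
#' @keywords internal
genome_seq <- function(genome, chrom, start, end, strand = "+") {
  s <- Biostrings::subseq(genome[[chrom]], start = start + 1L, end = end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Spliced (transcript) sequence of a set of exon blocks
#'
#' @param genome named DNAStringSet
#' @param chrom chromosome
#' @param starts,ends parallel 0-based half-open block coordinates, sorted
#'   by genome position
#' @param strand transcript strand; "-" reverse-complements the concatenation
#' @return character scalar in transcribed orientation
#' @keywords internal
spliced_seq <- function(genome, chrom, starts, ends, strand = "+") {
  pieces <- vapply(seq_along(starts), function(i)
    as.character(Biostrings::subseq(genome[[chrom]], starts[i] + 1L, ends[i])),
    character(1))
  s <- paste0(pieces, collapse = "")
  if (strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}
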