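#' Write a genome to FASTA
#'
#' @param genome named DNAStringSet (or named character vector)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_genome_fasta <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, filepath = path, width = 70L)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' @param path FASTA file
#' @return named DNAStringSet; names are truncated at the first whitespace
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write reads to FASTQ with constant quality
#'
#' Per-base quality modelling is out of scope: every base gets quality "I"
#' (Phred 40).
#'
#' @param reads data.frame with columns read_id, seq
#' @param path output file
#' @return `path`, invisibly
#' @export
write_reads_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  con <- file(path, "w")
  on.exit(close(con))
  qual <- vapply(nchar(reads$seq), function(n) strrep("I", n), character(1))
  writeLines(paste0("@", reads$read_id, "\n", reads$seq, "\n+\n", qual), con)
  invisible(path)
}

#' Read a FASTQ (or FASTA) read file
#'
#' @param path input file
#' @param format "fastq" or "fasta"
#' @return data.frame with columns read_id, seq
#' @export
read_reads <- function(path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  x <- Biostrings::readDNAStringSet(path, format = format)
  data.frame(read_id = sub("\\s.*$", "", names(x)), seq = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write an annotation to GFF3
#'
#' Internal 0-based half-open exon coordinates are converted to the 1-based
#' closed GFF3 convention.  The translation-start offset is carried on the
#' gene line as a `cds_offset` attribute (transcript coordinate, 0-based).
#'
#' @param annotation annotation object (list with `genes` and `exons`)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_annotation_gff3 <- function(annotation, path) {
  genes <- annotation$genes
  exons <- exons_transcribed(annotation)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    writeLines(sprintf("%s\tsplicewatch\tgene\t%d\t%d\t.\t%s\t.\tID=%s;cds_offset=%d",
                       g$chrom, g$start + 1L, g$end, g$strand, g$gene_id,
                       g$cds_offset), con)
    ex <- exons[exons$gene_id == g$gene_id, ]
    ex <- ex[order(ex$start), ]
    writeLines(sprintf("%s\tsplicewatch\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
                       ex$chrom, ex$start + 1L, ex$end, ex$strand, g$gene_id,
                       ex$exon_rank, g$gene_id), con)
  }
  invisible(path)
}

#' Read an annotation from GFF3
#'
#' Expects gene and exon features with ID/Parent attributes (as written by
#' [write_annotation_gff3()], but any GFF3 with that structure works).
#' Coordinates are converted to the package's 0-based half-open convention.
#'
#' @param path GFF3 file
#' @return annotation object: list with data.frames `genes` (gene_id, chrom,
#'   strand, start, end, cds_offset) and `exons` (gene_id, chrom, strand,
#'   start, end, exon_rank)
#' @export
read_annotation_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(f) != 9L
  if (any(bad)) stop("malformed GFF3 line(s): ", which(bad)[1])
  m <- do.call(rbind, f)
  attr_field <- function(attrs, key) {
    val <- sub(paste0(".*(^|;)", key, "=([^;]*).*"), "\\2", attrs)
    val[!grepl(paste0("(^|;)", key, "="), attrs)] <- NA
    val
  }
  type <- m[, 3]
  gi <- type == "gene"
  genes <- data.frame(
    gene_id = attr_field(m[gi, 9], "ID"),
    chrom = m[gi, 1], strand = m[gi, 7],
    start = as.integer(m[gi, 4]) - 1L, end = as.integer(m[gi, 5]),
    cds_offset = as.integer(attr_field(m[gi, 9], "cds_offset")),
    stringsAsFactors = FALSE
  )
  ei <- type == "exon"
  exons <- data.frame(
    gene_id = attr_field(m[ei, 9], "Parent"),
    chrom = m[ei, 1], strand = m[ei, 7],
    start = as.integer(m[ei, 4]) - 1L, end = as.integer(m[ei, 5]),
    stringsAsFactors = FALSE
  )
  ann <- list(genes = genes, exons = exons)
  ann$exons <- exons_transcribed(ann)
  class(ann) <- c("sw_annotation", "list")
  ann
}

#' Write spliced alignments to SAM
#'
#' One record per read; splices are encoded as N CIGAR operations.  The
#' transcript strand is emitted as the conventional `XS:A:` tag.  All reads
#' are written unflipped (FLAG 0) with SEQ in genome-forward orientation
#' when read sequences are supplied, `*` otherwise.
#'
#' @param alignments alignment block table (see [simulate_reads()]): columns
#'   read_id, chrom, strand, block_start, block_end, block_rank
#' @param path output file
#' @param genome named DNAStringSet (for header @SQ lines)
#' @param reads optional data.frame (read_id, seq) of transcript-orientation
#'   sequences; minus-strand reads are reverse complemented into SEQ
#' @return `path`, invisibly
#' @export
write_sam <- function(alignments, path, genome, reads = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                     Biostrings::width(genome)), con)
  al <- alignments[order(alignments$read_id, alignments$block_rank), ]
  sp <- split(al, al$read_id)
  seqs <- NULL
  if (!is.null(reads)) seqs <- setNames(reads$seq, reads$read_id)
  out <- vapply(sp, function(a) {
    w <- a$block_end - a$block_start
    gaps <- if (nrow(a) > 1L) a$block_start[-1L] - a$block_end[-nrow(a)] else integer(0)
    cigar <- paste0(w[1], "M")
    if (length(gaps))
      cigar <- paste0(cigar, paste0(gaps, "N", w[-1L], "M", collapse = ""))
    sq <- "*"
    if (!is.null(seqs)) {
      sq <- seqs[[a$read_id[1]]]
      if (identical(a$strand[1], "-"))
        sq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sq)))
    }
    paste(a$read_id[1], "0", a$chrom[1], a$block_start[1] + 1L, "255", cigar,
          "*", "0", "0", sq, "*", paste0("XS:A:", a$strand[1] %||% "+"),
          sep = "\t")
  }, character(1))
  writeLines(out, con)
  invisible(path)
}

#' Read spliced alignments from SAM
#'
#' Parses mapped records; M/N (plus =/X/D/I/S) CIGAR operations are resolved
#' to aligned reference blocks with
#' [GenomicAlignments::extractAlignmentRangesOnReference()].  The `XS:A:`
#' tag, when present, supplies the transcript strand.
#'
#' @param path SAM file
#' @return alignment block table: data.frame with columns read_id, chrom,
#'   strand, block_start, block_end (0-based half-open), block_rank
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(data.frame(read_id = character(), chrom = character(),
                      strand = character(), block_start = integer(),
                      block_end = integer(), block_rank = integer(),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 11L)) stop("malformed SAM record")
  qname <- vapply(f, `[[`, "", 1L)
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  rname <- vapply(f, `[[`, "", 3L)
  pos <- as.integer(vapply(f, `[[`, "", 4L))
  cigar <- vapply(f, `[[`, "", 6L)
  keep <- !bitwAnd(flag, 4L) & rname != "*"
  xs <- vapply(f, function(x) {
    tag <- grep("^XS:A:", x[-(1:11)], value = TRUE)
    if (length(tag)) substring(tag[1], 6L) else "*"
  }, character(1))
  blocks <- GenomicAlignments::extractAlignmentRangesOnReference(
    cigar[keep], pos = pos[keep])
  n <- lengths(blocks)
  ub <- unlist(blocks)
  data.frame(
    read_id = rep(qname[keep], n),
    chrom = rep(rname[keep], n),
    strand = rep(xs[keep], n),
    block_start = IRanges::start(ub) - 1L,
    block_end = IRanges::end(ub),
    block_rank = unlist(lapply(n, seq_len)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Deterministic TSV writer
#'
#' Fixed quoting/format so identical inputs give byte-identical files
#' (required for the run-manifest checksum guarantee).
#'
#' @param x data.frame
#' @param path output file
#' @return `path`, invisibly
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path input file
#' @return data.frame
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
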