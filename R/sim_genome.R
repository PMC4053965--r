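#' Generate a toy genome and gene annotation
#'
#' Genes are laid down sequentially along each chromosome (round-robin over
#' chromosomes, alternating strand so reverse-complement handling is always
#' exercised), separated by random intergenic gaps.  Every annotated intron
#' is forced to start GT and end AG on the transcribed strand, so canonical
#' splice-site checks downstream are exercised by construction.
#'
#' @param config a [sim_config()]
#' @return list with `genome` (named DNAStringSet) and `annotation` (list
#'   of data.frames `genes` and `exons`; 0-based half-open coordinates)
#' @export
make_genome_and_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_genes < config$n_chromosomes)
    stop("infeasible geometry: fewer genes than chromosomes", call. = FALSE)
  set.seed(derive_seed(config$seed, 1L))
  bases <- c("A", "C", "G", "T")
  rand_seq <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")

  chrom_of <- rep_len(paste0("chr", seq_len(config$n_chromosomes)),
                      config$n_genes)
  strand_of <- rep_len(c("+", "-"), config$n_genes)

  chrom_seqs <- setNames(vector("list", config$n_chromosomes),
                         paste0("chr", seq_len(config$n_chromosomes)))
  offsets <- setNames(integer(config$n_chromosomes), names(chrom_seqs))
  genes <- vector("list", config$n_genes)
  exons <- vector("list", config$n_genes)

  for (i in seq_len(config$n_genes)) {
    gid <- sprintf("g%03d", i)
    chrom <- chrom_of[i]
    strand <- strand_of[i]
    n_ex <- sample1(seq(config$exons_per_gene[1], config$exons_per_gene[2]))
    ex_w <- sample(seq(config$exon_len[1], config$exon_len[2]), n_ex,
                   replace = TRUE)
    in_w <- if (n_ex > 1L)
      sample(seq(config$intron_len[1], config$intron_len[2]), n_ex - 1L,
             replace = TRUE)
    else integer(0)

    # transcribed-orientation gene sequence with GT..AG planted per intron
    glen <- sum(ex_w) + sum(in_w)
    s <- strsplit(rand_seq(glen), "")[[1]]
    # transcribed coordinates of exons within the gene
    tx_start <- cumsum(c(0L, head(ex_w, -1L) + in_w))
    tx_end <- tx_start + ex_w
    for (k in seq_len(n_ex - 1L)) {
      is0 <- tx_end[k]            # intron start (transcribed, 0-based)
      ie0 <- tx_start[k + 1L]     # intron end
      s[is0 + 1L] <- "G"; s[is0 + 2L] <- "T"
      s[ie0 - 1L] <- "A"; s[ie0] <- "G"
    }
    gene_seq <- paste(s, collapse = "")

    gap <- sample1(seq(config$intergenic_len[1], config$intergenic_len[2]))
    lead <- rand_seq(gap)
    off <- offsets[chrom] + gap
    if (strand == "-")
      gene_seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(gene_seq)))
    chrom_seqs[[chrom]] <- c(chrom_seqs[[chrom]], lead, gene_seq)
    # map transcribed exon coords to genome coords
    if (strand == "+") {
      gs <- off + tx_start
      ge <- off + tx_end
    } else {
      gs <- off + glen - tx_end
      ge <- off + glen - tx_start
    }
    ord <- order(gs)
    exons[[i]] <- data.frame(gene_id = gid, chrom = chrom, strand = strand,
                             start = gs[ord], end = ge[ord],
                             stringsAsFactors = FALSE)
    genes[[i]] <- data.frame(gene_id = gid, chrom = chrom, strand = strand,
                             start = off, end = off + glen,
                             cds_offset = config$cds_offset,
                             stringsAsFactors = FALSE)
    offsets[chrom] <- off + glen
  }
  # trailing intergenic pad per chromosome
  for (chrom in names(chrom_seqs)) {
    pad <- sample1(seq(config$intergenic_len[1], config$intergenic_len[2]))
    chrom_seqs[[chrom]] <- c(chrom_seqs[[chrom]], rand_seq(pad))
  }
  genome <- Biostrings::DNAStringSet(
    vapply(chrom_seqs, paste, character(1), collapse = ""))
  annotation <- list(genes = do.call(rbind, genes),
                     exons = do.call(rbind, exons))
  rownames(annotation$genes) <- rownames(annotation$exons) <- NULL
  annotation$exons <- exons_transcribed(annotation)
  class(annotation) <- c("sw_annotation", "list")
  list(genome = genome, annotation = annotation)
}
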