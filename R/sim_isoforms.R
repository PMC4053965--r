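#' Build a condition profile of planted splicing events
#'
#' Chooses, deterministically under a seed, which genes carry which planted
#' events and at what usage fraction.  A gene carries at most one planted
#' event so ground truth stays unambiguous; intron retention and
#' alternative splice sites target a random intron of the gene, and
#' skipping targets a random internal exon.
#'
#' @param annotation annotation object
#' @param config a [sim_config()]
#' @param n_ir,n_alt5,n_alt3,n_skip number of genes receiving each event
#'   type (0 = none planted)
#' @param coordination_rate fraction of skipped-exon genes that additionally
#'   receive an alternative splice site on a flanking intron (the
#'   coordination the skipping/alt-SS co-occurrence test measures)
#' @param seed integer seed
#' @return data.frame (the condition profile) with columns gene_id,
#'   event_type, target_index, usage, offset
#' @export
make_condition_profile <- function(annotation, config,
                                   n_ir = 0L, n_alt5 = 0L, n_alt3 = 0L,
                                   n_skip = 0L, coordination_rate = 0,
                                   seed = config$seed) {
  set.seed(derive_seed(seed, 2L))
  genes <- annotation$genes$gene_id
  ex <- exons_transcribed(annotation)
  n_exons <- table(ex$gene_id)[genes]
  eligible <- genes[n_exons >= 3L]   # need internal exons/introns
  total <- n_ir + n_alt5 + n_alt3 + n_skip
  if (total > length(eligible))
    stop("not enough eligible genes (>=3 exons) for the requested events",
         call. = FALSE)
  picked <- sample(eligible, total)
  type <- rep(c("IR", "ALT5SS", "ALT3SS", "CASSETTE"),
              c(n_ir, n_alt5, n_alt3, n_skip))
  rows <- lapply(seq_along(picked), function(i) {
    gid <- picked[i]
    nx <- as.integer(n_exons[gid])
    if (type[i] == "IR") {
      data.frame(gene_id = gid, event_type = "IR",
                 target_index = sample1(seq_len(nx - 1L)),
                 usage = config$ir_fraction, offset = NA_integer_,
                 stringsAsFactors = FALSE)
    } else if (type[i] %in% c("ALT5SS", "ALT3SS")) {
      k <- if (nx > 2L) sample1(seq_len(nx - 1L)) else 1L
      mag <- sample1(seq(config$alt_ss_offset_range[1],
                         config$alt_ss_offset_range[2]))
      data.frame(gene_id = gid, event_type = type[i], target_index = k,
                 usage = config$alt_ss_usage,
                 offset = mag * sample1(c(-1L, 1L)),
                 stringsAsFactors = FALSE)
    } else {
      k <- sample1(seq(2L, nx - 1L))
      data.frame(gene_id = gid, event_type = "CASSETTE", target_index = k,
                 usage = config$skip_usage, offset = NA_integer_,
                 stringsAsFactors = FALSE)
    }
  })
  profile <- do.call(rbind, rows)
  if (coordination_rate > 0 && n_skip > 0) {
    skip_rows <- which(profile$event_type == "CASSETTE")
    n_co <- round(coordination_rate * length(skip_rows))
    if (n_co > 0) {
      co <- skip_rows[sample.int(length(skip_rows), n_co)]
      extra <- lapply(co, function(r) {
        gid <- profile$gene_id[r]
        k <- profile$target_index[r]   # skipped exon rank
        mag <- sample1(seq(config$alt_ss_offset_range[1],
                           config$alt_ss_offset_range[2]))
        # the alternative site must sit on the skipped exon itself:
        # its 5' boundary is the acceptor of intron k-1, its 3' boundary
        # the donor of intron k (transcribed order)
        type <- sample1(c("ALT5SS", "ALT3SS"))
        data.frame(gene_id = gid, event_type = type,
                   target_index = if (type == "ALT5SS") k else k - 1L,
                   usage = config$alt_ss_usage,
                   offset = mag * sample1(c(-1L, 1L)),
                   stringsAsFactors = FALSE)
      })
      profile <- rbind(profile, do.call(rbind, extra))
    }
  }
  rownames(profile) <- NULL
  profile
}

# genomic exon blocks of a gene, sorted by genome coordinate
gene_blocks <- function(annotation, gid) {
  ex <- annotation$exons
  g <- ex[ex$gene_id == gid, ]
  g[order(g$start), c("start", "end")]
}

blocks_to_str <- function(b) paste(sprintf("%d-%d", b$start, b$end), collapse = ",")

#' Parse a block string "s-e,s-e" back to a data.frame
#' @param s block string
#' @return data.frame with columns start, end
#' @keywords internal
str_to_blocks <- function(s) {
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
  data.frame(start = as.integer(vapply(parts, `[[`, "", 1L)),
             end = as.integer(vapply(parts, `[[`, "", 2L)))
}

# apply one planted event to a gene's exon blocks (genome coords, sorted).
# Returns list(blocks, junction = c(start, end) of the novel junction /
# retained intron in genome coordinates).
apply_event <- function(blocks, strand, event_type, target_index, offset,
                        min_intron = 20L) {
  n <- nrow(blocks)
  # intron k (transcribed) = genomic gap index: '+' -> k, '-' -> n - k
  gap_index <- function(k) if (strand == "+") k else n - k
  if (event_type == "IR") {
    gi <- gap_index(target_index)
    intron <- c(blocks$end[gi], blocks$start[gi + 1L])
    merged <- blocks
    merged$end[gi] <- merged$end[gi + 1L]
    merged <- merged[-(gi + 1L), , drop = FALSE]
    return(list(blocks = merged, junction = intron))
  }
  if (event_type %in% c("ALT5SS", "ALT3SS")) {
    gi <- gap_index(target_index)
    s <- blocks$end[gi]; e <- blocks$start[gi + 1L]
    # donor/acceptor genome side depends on strand; offset signed downstream
    # in transcribed orientation
    if (event_type == "ALT5SS") {
      if (strand == "+") s <- s + offset else e <- e - offset
    } else {
      if (strand == "+") e <- e + offset else s <- s - offset
    }
    if (e - s < min_intron)
      stop("planted offset leaves intron shorter than ", min_intron, call. = FALSE)
    if (s <= blocks$start[gi] || e >= blocks$end[gi + 1L])
      stop("planted offset lands outside exon bounds", call. = FALSE)
    nb <- blocks
    nb$end[gi] <- s
    nb$start[gi + 1L] <- e
    return(list(blocks = nb, junction = c(s, e)))
  }
  if (event_type == "CASSETTE") {
    # target_index = transcribed exon rank; genomic index:
    gi <- if (strand == "+") target_index else n - target_index + 1L
    if (gi <= 1L || gi >= n)
      stop("cassette target must be an internal exon", call. = FALSE)
    junction <- c(blocks$end[gi - 1L], blocks$start[gi + 1L])
    return(list(blocks = blocks[-gi, , drop = FALSE], junction = junction))
  }
  stop("unknown event type: ", event_type, call. = FALSE)
}

#' Simulate condition-specific isoform pools with a ground-truth ledger
#'
#' For each gene the annotated isoform carries weight 1 minus the summed
#' usage of its planted events; each planted event contributes one isoform
#' at its usage fraction.  For a gene with intron retention planted at
#' fraction pi, the expected share of transcripts retaining the intron is
#' therefore exactly pi.  Alternative-splice-site isoforms shift exactly
#' one splice boundary by the profile's signed offset (downstream positive
#' in transcribed orientation); skipping isoforms omit exactly the targeted
#' exon.
#'
#' @param annotation annotation object
#' @param config a [sim_config()]
#' @param condition_profile data.frame from [make_condition_profile()] (may
#'   have zero rows: the pool then contains only annotated isoforms)
#' @param condition label recorded in the ledger
#' @return list with `pool` (data.frame: iso_id, gene_id, chrom, strand,
#'   weight, blocks, event_type) and `ledger` (data.frame: condition,
#'   event_type, gene_id, chrom, strand, junction_start, junction_end,
#'   target_index, usage, offset)
#' @export
simulate_isoforms <- function(annotation, config, condition_profile,
                              condition = "cond") {
  prof <- condition_profile
  if (is.null(prof)) prof <- data.frame()
  genes <- annotation$genes
  pool <- list(); ledger <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    strand <- genes$strand[i]
    chrom <- genes$chrom[i]
    blocks <- gene_blocks(annotation, gid)
    rows <- if (nrow(prof)) prof[prof$gene_id == gid, , drop = FALSE] else prof
    usage_sum <- if (nrow(rows)) sum(rows$usage) else 0
    if (usage_sum > 1)
      stop("total planted usage for gene ", gid, " exceeds 1", call. = FALSE)
    pool[[length(pool) + 1L]] <- data.frame(
      iso_id = paste0(gid, ".ref"), gene_id = gid, chrom = chrom,
      strand = strand, weight = 1 - usage_sum,
      blocks = blocks_to_str(blocks), event_type = "annotated",
      stringsAsFactors = FALSE)
    for (j in seq_len(nrow(rows))) {
      ev <- apply_event(blocks, strand, rows$event_type[j],
                        rows$target_index[j], rows$offset[j])
      pool[[length(pool) + 1L]] <- data.frame(
        iso_id = sprintf("%s.%s%d", gid, tolower(rows$event_type[j]), j),
        gene_id = gid, chrom = chrom, strand = strand,
        weight = rows$usage[j], blocks = blocks_to_str(ev$blocks),
        event_type = rows$event_type[j], stringsAsFactors = FALSE)
      ledger[[length(ledger) + 1L]] <- data.frame(
        condition = condition, event_type = rows$event_type[j],
        gene_id = gid, chrom = chrom, strand = strand,
        junction_start = ev$junction[1], junction_end = ev$junction[2],
        target_index = rows$target_index[j], usage = rows$usage[j],
        offset = rows$offset[j], stringsAsFactors = FALSE)
    }
  }
  ledger <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(condition = character(), event_type = character(),
               gene_id = character(), chrom = character(),
               strand = character(), junction_start = integer(),
               junction_end = integer(), target_index = integer(),
               usage = numeric(), offset = integer(),
               stringsAsFactors = FALSE)
  list(pool = do.call(rbind, pool), ledger = ledger)
}
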