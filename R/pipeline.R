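#' Run configuration for an end-to-end synthetic analysis
#'
#' Bundles the generator configuration, the planted-event design of each
#' condition, and the analysis thresholds.  All stage seeds are derived
#' from the single `seed` by a fixed map, so any stage can be rerun
#' independently and two runs with the same configuration are
#' byte-identical.
#'
#' @param sim a [sim_config()] describing genome and libraries
#' @param conditions named list; each element is a list of planted-event
#'   counts passed to [make_condition_profile()] (`n_ir`, `n_alt5`,
#'   `n_alt3`, `n_skip`, `coordination_rate`).  Two or more conditions; the
#'   first is treated as the baseline for differential contrasts.
#' @param filter a [filter_config()]
#' @param ir an [ir_config()]
#' @param n_resample equal-depth resample size per library (<= library
#'   depth)
#' @param alpha_as significance threshold for event tests
#' @param alpha_ir significance threshold for intron-retention tests
#' @param seed global seed
#' @return validated list of class `run_config`
#' @export
run_config <- function(sim = sim_config(),
                       conditions = list(
                         WT = list(),
                         MUT = list(n_ir = 4L, n_alt5 = 3L, n_alt3 = 3L,
                                    n_skip = 3L)),
                       filter = filter_config(),
                       ir = ir_config(),
                       n_resample = NULL,
                       alpha_as = 0.01,
                       alpha_ir = 0.001,
                       seed = sim$seed) {
  if (length(conditions) < 2L || is.null(names(conditions)))
    stop("at least two named conditions are required", call. = FALSE)
  n_resample <- as.integer(n_resample %||% round(0.8 * sim$library_depth))
  if (n_resample > sim$library_depth)
    stop("n_resample exceeds library depth", call. = FALSE)
  cfg <- list(sim = sim, conditions = conditions, filter = filter, ir = ir,
              n_resample = n_resample, alpha_as = alpha_as,
              alpha_ir = alpha_ir, seed = as.integer(seed))
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Read a run configuration from YAML
#'
#' Scalar fields mirror the arguments of [run_config()], [sim_config()],
#' [filter_config()] and [ir_config()]; the `conditions` block maps
#' condition names to planted-event counts.
#'
#' @param path YAML file
#' @return a `run_config`
#' @export
read_run_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(sim_config, y$sim %||% list())
  filter <- do.call(filter_config, y$filter %||% list())
  ir <- do.call(ir_config, y$ir %||% list())
  run_config(sim = sim, conditions = y$conditions,
             filter = filter, ir = ir,
             n_resample = y$n_resample %||% NULL,
             alpha_as = y$alpha_as %||% 0.01,
             alpha_ir = y$alpha_ir %||% 0.001,
             seed = y$seed %||% sim$seed)
}

#' Prepend a condition column to a stage table
#'
#' Adds `condition = cn` as the first column, handling 0-row tables (for
#' which a plain `df$condition <- cn` assignment would fail).
#'
#' @param df A data frame (possibly 0-row).
#' @param cn Condition name (length-1 character).
#' @return `df` with a leading `condition` column.
#' @export
tag_condition <- function(df, cn) {
  if (nrow(df)) return(cbind(condition = cn, df, stringsAsFactors = FALSE))
  cbind(condition = character(0), df)
}

write_stage <- function(tables, outdir) {
  manifest <- lapply(names(tables), function(nm) {
    path <- file.path(outdir, paste0(nm, ".tsv"))
    write_tsv(tables[[nm]], path)
    data.frame(file = basename(path), rows = nrow(tables[[nm]]),
               md5 = unname(tools::md5sum(path)), stringsAsFactors = FALSE)
  })
  do.call(rbind, manifest)
}

#' Run the full synthetic splicing analysis
#'
#' Executes simulate -> junctions -> filter -> events/intron retention ->
#' differential -> sites -> expression in order, writing every table as TSV
#' under `outdir` plus a JSON manifest with row counts and md5 checksums.
#' Rerunning with the same configuration reproduces every output byte for
#' byte.
#'
#' @param config a [run_config()]
#' @param outdir output directory (created if needed)
#' @return invisibly, a list with all in-memory results and the manifest
#' @export
run_all <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- config$sim
  conds <- names(config$conditions)

  ## stage 1: simulate
  ga <- make_genome_and_annotation(sim)
  write_genome_fasta(ga$genome, file.path(outdir, "genome.fa"))
  write_annotation_gff3(ga$annotation, file.path(outdir, "annotation.gff3"))
  libs <- list(); ledgers <- list()
  for (i in seq_along(conds)) {
    cn <- conds[i]
    prof <- do.call(make_condition_profile, c(
      list(annotation = ga$annotation, config = sim,
           seed = derive_seed(config$seed, 10L + i)),
      config$conditions[[cn]]))
    iso <- simulate_isoforms(ga$annotation, sim, prof, condition = cn)
    rd <- simulate_reads(ga$genome, iso$pool, sim, lib_name = cn,
                         seed = derive_seed(config$seed, 20L + i))
    write_sam(rd$alignments, file.path(outdir, paste0(cn, ".sam")),
              ga$genome, rd$reads)
    write_reads_fastq(rd$reads[, c("read_id", "seq")],
                      file.path(outdir, paste0(cn, ".fastq")))
    libs[[cn]] <- rd
    ledgers[[cn]] <- iso$ledger
  }
  ledger <- do.call(rbind, ledgers)
  decoys <- make_decoy_reads(ga$genome, ga$annotation, sim)

  ## stage 2: equal-depth resample + junction catalogs + filter
  res <- list(); catalogs <- list(); filtered <- list()
  for (i in seq_along(conds)) {
    cn <- conds[i]
    res[[cn]] <- resample_alignments(libs[[cn]]$alignments, config$n_resample,
                                     seed = derive_seed(config$seed, 30L + i))
    catalogs[[cn]] <- extract_junctions(res[[cn]], ga$annotation, ga$genome)
    filtered[[cn]] <- apply_filter(catalogs[[cn]], config$filter)
  }

  ## stage 2b: null calibration against random junction references
  flank <- sim$read_length - 11L
  ann_refs <- build_junction_refs(ga$genome, ga$annotation, flank, "annotated")
  rnd_support <- match_reads_to_refs(decoys$reads, decoys$refs)
  first_reads <- libs[[conds[1]]]$reads[, c("read_id", "seq")]
  ann_support <- match_reads_to_refs(first_reads, ann_refs)
  null_rep <- characterize_null(rnd_support, ann_support)

  ## stage 3: events + intron retention
  events <- list(); ircalls <- list()
  for (cn in conds) {
    events[[cn]] <- classify_events(filtered[[cn]], ga$annotation)
    ircalls[[cn]] <- call_intron_retention(res[[cn]], ga$annotation, config$ir)
  }

  ## stage 4: differential (baseline = first condition vs each other)
  base <- conds[1]
  diff_events <- list(); diff_introns <- list(); global <- list()
  for (cn in conds[-1]) {
    de <- test_events(events[[base]], events[[cn]], res[[base]], res[[cn]],
                      ga$annotation, alpha = config$alpha_as)
    de$contrast <- paste0(base, "_vs_", cn)
    diff_events[[cn]] <- de
    di <- test_introns(ircalls[[base]], ircalls[[cn]], alpha = config$alpha_ir)
    di$contrast <- paste0(base, "_vs_", cn)
    diff_introns[[cn]] <- di
    gc_ <- global_comparison(events[[base]], events[[cn]],
                             config$n_resample, config$n_resample)
    gc_$contrast <- paste0(base, "_vs_", cn)
    global[[cn]] <- gc_
  }

  ## stage 5: sites + expression (on the non-baseline conditions' events)
  all_events <- do.call(rbind, lapply(conds, function(cn)
    tag_condition(events[[cn]], cn)))
  alt_events <- all_events[all_events$event_type %in% c("ALT5SS", "ALT3SS"), ,
                           drop = FALSE]
  donor_pfm <- extract_site_matrix(ga$genome,
                                   site_table(ga$annotation, "donor"),
                                   window = 10L, site_kind = "donor")
  acceptor_pfm <- extract_site_matrix(ga$genome,
                                      site_table(ga$annotation, "acceptor"),
                                      window = 10L, site_kind = "acceptor")
  offsets <- offset_distribution(alt_events)
  coord <- coordination_test(all_events, ga$annotation)

  expr <- lapply(conds, function(cn)
    feature_expression(res[[cn]], ga$annotation, config$n_resample))
  names(expr) <- conds
  irp <- lapply(conds, function(cn)
    ir_proportion(res[[cn]], ga$annotation, config$n_resample))
  names(irp) <- conds

  ## write tables + manifest
  pfm_df <- function(p) {
    d <- as.data.frame(t(p$counts))
    cbind(position = as.integer(rownames(d)), d, row.names = NULL)
  }
  tables <- list(
    ledger = ledger,
    junctions = do.call(rbind, lapply(conds, function(cn) {
      cat_ <- catalogs[[cn]]
      cat_$kept <- paste(cat_$chrom, cat_$start, cat_$end) %in%
        paste(filtered[[cn]]$chrom, filtered[[cn]]$start, filtered[[cn]]$end)
      tag_condition(cat_, cn)
    })),
    null_report = null_rep$survival,
    events = all_events,
    ir_calls = do.call(rbind, lapply(conds, function(cn)
      tag_condition(ircalls[[cn]], cn))),
    differential_events = do.call(rbind, diff_events),
    differential_introns = do.call(rbind, diff_introns),
    global_comparison = do.call(rbind, global),
    donor_pfm = pfm_df(donor_pfm),
    acceptor_pfm = pfm_df(acceptor_pfm),
    offsets = offsets$histogram,
    expression = do.call(rbind, lapply(conds, function(cn)
      tag_condition(expr[[cn]], cn))),
    ir_proportion = do.call(rbind, lapply(conds, function(cn)
      tag_condition(irp[[cn]], cn)))
  )
  if (!is.null(coord))
    tables$coordination <- data.frame(
      observed_fraction = coord$observed_fraction,
      background_fraction = coord$background_fraction,
      p_value = coord$p_value)
  manifest <- write_stage(tables, outdir)
  genome_files <- c("genome.fa", "annotation.gff3",
                    paste0(conds, ".sam"), paste0(conds, ".fastq"))
  manifest <- rbind(manifest, data.frame(
    file = genome_files, rows = NA_integer_,
    md5 = unname(tools::md5sum(file.path(outdir, genome_files))),
    stringsAsFactors = FALSE))
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  jsonlite::write_json(
    list(seed = config$seed, n_resample = config$n_resample,
         conditions = as.list(names(config$conditions)),
         files = manifest),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  invisible(list(genome = ga$genome, annotation = ga$annotation,
                 ledger = ledger, libraries = libs, resampled = res,
                 catalogs = catalogs, filtered = filtered,
                 null_report = null_rep, events = events,
                 ir_calls = ircalls, differential_events = diff_events,
                 differential_introns = diff_introns, global = global,
                 donor_pfm = donor_pfm, acceptor_pfm = acceptor_pfm,
                 offsets = offsets, coordination = coord,
                 expression = expr, ir_proportion = irp,
                 manifest = manifest))
}
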