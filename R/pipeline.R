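# End-to-end orchestration over declared files: preprocess -> metrics ->
# call -> characterize -> targets. Every stage reads its inputs from, and
# writes its outputs to, plain TSV/FASTA/BED files, so any stage can be
# rerun standalone on prior outputs. All thresholds are surfaced as
# parameters; the defaults are the pipeline's operating point, never
# hard-coded downstream.

#' Pipeline parameters with their default operating point
#'
#' @param min_reads expression floor (total reads per dataset), default 20.
#' @param min_median minimum median read length (nt) of an agotron, 30.
#' @param min_5p minimum 5'-end aligned read fraction, 0.70.
#' @param tolerance 5'-offset tolerance in nt, 1.
#' @param min_datasets consensus minimum (expressed and adhering), 2.
#' @param pseudo_rpm RPM pseudocount for enrichment ratios, 1.
#' @param pseudo_fpkm FPKM pseudocount for fold changes, 0.1.
#' @param cons_cutoff conserved-site threshold on mean conservation, 0.5.
#' @param intron_min,intron_max intron universe bounds (nt), 40 and 150.
#' @param max_mismatch read-assignment substitution budget, 1.
#' @param adapter 3' adapter to trim (NULL to skip trimming).
#' @param min_len minimum post-trim read length, 18.
#' @param fold_backend folding backend for characterization.
#' @param guide_len length of the agotron 5' arm used as the target guide.
#' @return named list of parameters.
#' @export
pipeline_params <- function(min_reads = 20, min_median = 30, min_5p = 0.70,
                            tolerance = 1L, min_datasets = 2L,
                            pseudo_rpm = 1, pseudo_fpkm = 0.1,
                            cons_cutoff = 0.5, intron_min = 40L,
                            intron_max = 150L, max_mismatch = 1L,
                            adapter = "AGATCGGAAGAGC", min_len = 18L,
                            fold_backend = "builtin", guide_len = 22L) {
  as.list(environment())
}

#' Load pipeline parameters from a YAML config file
#'
#' Reads a flat YAML mapping of parameter overrides and merges it onto the
#' [pipeline_params()] defaults; every override is logged. Unknown keys
#' are an error, so typos cannot silently fall back to defaults.
#'
#' @param path YAML file of parameter overrides.
#' @return named list as from [pipeline_params()].
#' @export
read_pipeline_config <- function(path) {
  over <- yaml::read_yaml(path)
  params <- pipeline_params()
  if (length(over) == 0L) return(params)
  bad <- setdiff(names(over), names(params))
  if (length(bad)) stop("unknown pipeline parameter: ", bad[1])
  for (nm in names(over)) {
    message("config override: ", nm, " = ", over[[nm]])
    params[[nm]] <- over[[nm]]
  }
  params
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full agotron pipeline on a directory of inputs
#'
#' Expects `regions.bed`, `region_seqs.fa`, `samples.tsv` (sample_id,
#' dataset_id, condition) and one `<sample_id>.fastq` per sample; optional
#' `conservation.bedgraph` (genomic), `utrs.fa`, `expression.tsv` and
#' `utr_conservation.bedgraph` enable the conservation and target stages,
#' which are skipped gracefully when absent. Writes metrics, call,
#' feature, comparison and target TSVs plus `summary.json` under
#' `out_dir`.
#'
#' @param input_dir directory of input files.
#' @param out_dir output directory (created).
#' @param params list from [pipeline_params()].
#' @param write_assignments also write the (large) per-read assignment
#'   table, default FALSE.
#' @return invisibly, the run summary list.
#' @export
run_pipeline <- function(input_dir, out_dir, params = pipeline_params(),
                         write_assignments = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(params = params[!vapply(params, is.null, TRUE)])

  ## -- preprocess ----------------------------------------------------------
  pre <- .stage("preprocess", {
    regions <- read_regions_bed(file.path(input_dir, "regions.bed"),
                                params$intron_min, params$intron_max)
    region_seqs <- read_fasta(file.path(input_dir, "region_seqs.fa"))
    missing <- setdiff(regions$region_id, names(region_seqs))
    if (length(missing)) stop("missing sequence for region: ", missing[1])
    meta <- read_table_tsv(file.path(input_dir, "samples.tsv"))
    asn <- list(); totals <- integer()
    for (sid in meta$sample_id) {
      reads <- read_fastq(file.path(input_dir, paste0(sid, ".fastq")))
      a <- preprocess_sample(reads, region_seqs[regions$region_id],
                             adapter = params$adapter,
                             min_len = params$min_len,
                             max_mismatch = params$max_mismatch)
      a[, sample_id := sid]
      totals[sid] <- attr(a, "total_mapped_reads")
      asn[[sid]] <- a
    }
    meta <- as.data.table(meta)
    meta[, total_mapped_reads := totals[sample_id]]
    list(assignments = rbindlist(asn), meta = meta, regions = regions,
         region_seqs = region_seqs)
  })
  write_table(pre$meta, file.path(out_dir, "samples_mapped.tsv"))
  if (write_assignments) {
    write_table(pre$assignments, file.path(out_dir, "assignments.tsv"))
  }
  summary$preprocess <- list(
    n_samples = nrow(pre$meta),
    total_mapped_reads = sum(pre$meta$total_mapped_reads))

  ## -- metrics -------------------------------------------------------------
  metrics <- .stage("metrics", {
    m <- dataset_summary(pre$assignments, pre$meta,
                         min_reads = params$min_reads,
                         tolerance = params$tolerance,
                         pseudo = params$pseudo_rpm)
    merge(m, pre$regions[, c("region_id", "region_class", "is_mirtron")],
          by = "region_id")
  })
  write_table(metrics, file.path(out_dir, "metrics.tsv"))
  summary$metrics <- list(
    n_region_dataset_rows = nrow(metrics),
    n_expressed_introns = length(unique(
      metrics[expressed & region_class == "intron", region_id])))

  ## -- call ----------------------------------------------------------------
  calls <- .stage("call", {
    cm <- build_call_matrix(metrics, pre$regions, params$min_reads,
                            params$min_median, params$min_5p)
    cons <- consensus_call(cm, params$min_datasets)
    cons <- merge(cons,
                  pre$regions[, c("region_id", "is_mirtron")],
                  by = "region_id")
    stats <- rbindlist(lapply(unique(cm$dataset_id), function(ds) {
      fc <- feature_coupling_test(cm[dataset_id == ds], params$min_median,
                                  params$min_5p)
      data.table(dataset_id = ds, test = "chi2_long_x_5p",
                 statistic = fc$statistic, p_value = fc$p_value)
    }))
    list(matrix = cm, consensus = cons, stats = stats)
  })
  write_table(calls$matrix, file.path(out_dir, "calls.tsv"))
  write_table(calls$consensus, file.path(out_dir, "consensus.tsv"))
  write_table(calls$stats, file.path(out_dir, "call_stats.tsv"))
  summary$call <- list(
    n_agotrons = sum(calls$consensus$is_agotron),
    n_candidate_introns = nrow(calls$consensus))

  ## -- characterize --------------------------------------------------------
  cons_path <- file.path(input_dir, "conservation.bedgraph")
  track <- if (file.exists(cons_path)) read_conservation(cons_path) else NULL
  summary$characterize <- if (is.null(track)) list(conservation = "skipped")
    else list(conservation = "computed")
  chars <- .stage("characterize", {
    ft <- intron_features(pre$regions, pre$region_seqs, track,
                          backend = params$fold_backend)
    ago_ids <- calls$consensus[is_agotron == TRUE, region_id]
    expr_ids <- setdiff(
      calls$consensus[n_expressed_datasets >= params$min_datasets, region_id],
      ago_ids)
    all_ids <- pre$regions$region_id[pre$regions$region_class == "intron"]
    cmp <- NULL
    if (length(ago_ids) && length(expr_ids)) {
      cmp <- class_comparison(ft, list(
        agotron = ago_ids, other_expressed = expr_ids, all_introns = all_ids),
        reference = "agotron")
    }
    list(features = ft, comparison = cmp)
  })
  write_table(chars$features, file.path(out_dir, "features.tsv"))
  if (!is.null(chars$comparison)) {
    write_table(chars$comparison, file.path(out_dir, "feature_comparison.tsv"))
  }

  ## -- targets -------------------------------------------------------------
  utr_path <- file.path(input_dir, "utrs.fa")
  expr_path <- file.path(input_dir, "expression.tsv")
  if (file.exists(utr_path) && file.exists(expr_path) &&
      sum(calls$consensus$is_agotron) > 0) {
    targ <- .stage("targets", {
      guide_id <- calls$consensus[is_agotron == TRUE][1, region_id]
      guide <- substr(pre$region_seqs[[guide_id]], 1, params$guide_len)
      sites <- derive_sites(guide)
      utrs <- read_fasta(utr_path)
      utr_cons_path <- file.path(input_dir, "utr_conservation.bedgraph")
      utr_track <- if (file.exists(utr_cons_path))
        read_conservation(utr_cons_path) else NULL
      hits <- scan_utr(utrs, sites, utr_track, params$cons_cutoff)
      classes <- best_canonical_class(hits, names(utrs))
      if (!is.null(utr_track)) {
        cons_tx <- unique(hits[conserved == TRUE &
                               class_label %in% c("7mer-m8", "7mer-1A"),
                               transcript_id])
        classes[transcript_id %in% cons_tx & best_class != "none" &
                best_class != "8mer", best_class := "conserved-7mer"]
      }
      expr <- read_table_tsv(expr_path)
      shift <- stratified_shift(expr, classes, params$pseudo_fpkm)
      rip <- NULL
      if (all(c("fpkm_ip_treatment", "fpkm_input_treatment") %in% names(expr))) {
        rip <- rip_enrichment(expr, classes, params$pseudo_fpkm)
      }
      list(guide_id = guide_id, guide = guide, hits = hits,
           classes = classes, shift = shift, rip = rip)
    })
    write_table(targ$hits, file.path(out_dir, "target_hits.tsv"))
    write_table(targ$classes, file.path(out_dir, "target_classes.tsv"))
    write_table(targ$shift$stats, file.path(out_dir, "target_shift_stats.tsv"))
    write_table(targ$shift$cumulative,
                file.path(out_dir, "target_shift_cumulative.tsv"))
    if (!is.null(targ$rip)) {
      write_table(targ$rip$stats, file.path(out_dir, "target_rip_stats.tsv"))
    }
    summary$targets <- list(guide_region = targ$guide_id,
                            n_site_hits = nrow(targ$hits))
  } else {
    summary$targets <- list(status = "skipped")
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
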