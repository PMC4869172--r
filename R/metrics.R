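# Per-region read statistics defining the agotron signature: read counts,
# depth-normalized abundance (RPM), median read length, and the fraction of
# reads aligning within one nucleotide of the region 5' end.

#' Median read length of a region's reads
#' @param lengths integer vector of whole-read lengths (weight-1 reads only).
#' @return the median; even counts average the two central values.
#' @export
median_read_length <- function(lengths) {
  if (length(lengths) == 0L) stop("median read length undefined: no whole reads")
  median(as.numeric(lengths))
}

#' Fraction of reads aligned at the region 5' end
#'
#' A read qualifies when its region-local start offset is within `tolerance`
#' nucleotides of the 5' terminus (offset 0). Reads recorded at offset 0
#' with a 1-nt upstream overhang qualify by construction.
#'
#' @param offsets integer vector of region-local 0-based read starts.
#' @param tolerance maximum qualifying offset, default 1.
#' @return fraction in [0, 1].
#' @export
five_prime_fraction <- function(offsets, tolerance = 1L) {
  if (length(offsets) == 0L) stop("5' fraction undefined: no whole reads")
  mean(offsets <= tolerance)
}

#' Reads per million mapped reads
#' @param count read count (fractional weights allowed).
#' @param total_mapped total mapped reads in the sample, > 0.
#' @return count / total_mapped * 1e6.
#' @export
rpm <- function(count, total_mapped) {
  if (any(total_mapped <= 0)) stop("total_mapped must be positive")
  count / total_mapped * 1e6
}

#' Log2 enrichment of tagged-Ago over control libraries
#'
#' `log2((rpm_signal + pseudo) / (rpm_control + pseudo))`. The pseudocount
#' guards against zero-count control regions; the default of 1 RPM is small
#' relative to abundantly bound regions.
#'
#' @param rpm_flag,rpm_wt RPM in the FLAG/IP library and the WT/input
#'   control.
#' @param pseudo pseudocount in RPM units, >= 0 (both denominators must stay
#'   positive).
#' @return log2 ratio; antisymmetric under swapping the first two arguments.
#' @export
flag_enrichment <- function(rpm_flag, rpm_wt, pseudo = 1) {
  stopifnot(pseudo >= 0)
  if (any(rpm_wt + pseudo == 0) || any(rpm_flag + pseudo == 0)) {
    stop("zero ratio term: use a positive pseudocount")
  }
  log2((rpm_flag + pseudo) / (rpm_wt + pseudo))
}

#' Per-sample read counts and RPM by region
#'
#' @param assignments assignment table (from [assign_reads()]) with a
#'   `sample_id` column.
#' @param sample_meta data.table (sample_id, dataset_id, condition,
#'   total_mapped_reads).
#' @return data.table (region_id, sample_id, read_count, rpm).
#' @export
region_sample_counts <- function(assignments, sample_meta) {
  counts <- assignments[, .(read_count = sum(weight)),
                        by = .(region_id, sample_id)]
  counts <- merge(counts, sample_meta[, .(sample_id, total_mapped_reads)],
                  by = "sample_id")
  counts[, rpm := rpm(read_count, total_mapped_reads)]
  counts[, total_mapped_reads := NULL]
  counts[]
}

#' Dataset-level region summaries
#'
#' Pools each dataset's samples: the expression measure is the unweighted
#' mean of per-sample RPM across the dataset's signal samples (conditions
#' FLAG, IP or PLAIN; samples with no reads on a region contribute 0), the
#' read-shape metrics (median read length, 5'-end fraction) pool the
#' weight-1 ("whole") reads of those samples, and `total_reads` sums
#' fractional counts. WT/INPUT samples serve only as the enrichment control.
#' A region is `expressed` in a dataset when it collects at least
#' `min_reads` reads in total.
#'
#' @param assignments assignment table with `sample_id` column.
#' @param sample_meta data.table (sample_id, dataset_id, condition,
#'   total_mapped_reads); conditions among FLAG, WT, IP, INPUT, PLAIN.
#' @param min_reads expression floor (total reads), default 20.
#' @param tolerance 5'-offset tolerance in nt, default 1.
#' @param pseudo RPM pseudocount for enrichment, default 1.
#' @return data.table (region_id, dataset_id, total_reads, mean_rpm,
#'   mean_rpm_control, median_read_length, five_prime_fraction, whole_count,
#'   expressed, enrichment). Shape metrics are NA when a region has no whole
#'   reads; enrichment is NA for datasets without control samples.
#' @export
dataset_summary <- function(assignments, sample_meta, min_reads = 20,
                            tolerance = 1L, pseudo = 1) {
  stopifnot(all(sample_meta$condition %in%
                c("FLAG", "WT", "IP", "INPUT", "PLAIN")))
  if (anyDuplicated(sample_meta$sample_id)) stop("duplicate sample_id")
  signal_cond <- c("FLAG", "IP", "PLAIN")
  meta <- as.data.table(sample_meta)
  meta[, is_signal := condition %in% signal_cond]

  counts <- region_sample_counts(assignments, meta)
  counts <- merge(counts, meta[, .(sample_id, dataset_id, is_signal)],
                  by = "sample_id")
  n_samp <- meta[, .(n_signal = sum(is_signal), n_control = sum(!is_signal)),
                 by = dataset_id]

  expr <- counts[, .(
    total_reads = sum(read_count[is_signal]),
    sum_rpm_signal = sum(rpm[is_signal]),
    sum_rpm_control = sum(rpm[!is_signal])
  ), by = .(region_id, dataset_id)]
  expr <- merge(expr, n_samp, by = "dataset_id")
  expr[, mean_rpm := sum_rpm_signal / n_signal]
  expr[, mean_rpm_control := ifelse(n_control > 0,
                                    sum_rpm_control / n_control, NA_real_)]

  shape <- merge(assignments, meta[, .(sample_id, dataset_id, is_signal)],
                 by = "sample_id")
  shape <- shape[is_signal & weight == 1]
  shape <- shape[, .(
    median_read_length = median(as.numeric(length_nt)),
    five_prime_fraction = mean(offset <= tolerance),
    whole_count = .N
  ), by = .(region_id, dataset_id)]

  out <- merge(expr[, .(region_id, dataset_id, total_reads, mean_rpm,
                        mean_rpm_control)],
               shape, by = c("region_id", "dataset_id"), all.x = TRUE)
  out[is.na(whole_count), whole_count := 0L]
  out[, expressed := total_reads >= min_reads]
  out[, enrichment := ifelse(is.na(mean_rpm_control), NA_real_,
                             flag_enrichment(mean_rpm, mean_rpm_control,
                                             pseudo))]
  setorder(out, dataset_id, region_id)
  out[]
}
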