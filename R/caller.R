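# Agotron calling: per-dataset threshold classification of short introns and
# the cross-dataset consensus rule, plus the class-level statistics
# (rank-sum comparisons, the long-read x 5'-aligned contingency, boxplot
# summaries).

.CALL_STATES <- c("not_expressed", "expressed_short", "expressed_low5p",
                  "agotron")

#' Classify one intron in one dataset
#'
#' An expressed intron (>= `min_reads` total reads) is an agotron candidate
#' in a dataset when its reads are long (median >= `min_median` nt) and
#' 5'-end aligned (fraction >= `min_5p`). Expressed introns failing the
#' length test are `expressed_short` (the mirtron-like signature); long but
#' poorly 5'-anchored introns are `expressed_low5p`.
#'
#' @param total_reads,median_len,frac_5p dataset-level metrics (vectors
#'   recycled together).
#' @param min_reads,min_median,min_5p inclusive thresholds, defaults 20
#'   reads, 30 nt, 0.70.
#' @return character vector of states among `not_expressed`,
#'   `expressed_short`, `expressed_low5p`, `agotron`.
#' @export
classify_region_in_dataset <- function(total_reads, median_len, frac_5p,
                                       min_reads = 20, min_median = 30,
                                       min_5p = 0.70) {
  n <- max(length(total_reads), length(median_len), length(frac_5p))
  total_reads <- rep_len(total_reads, n)
  median_len <- rep_len(median_len, n)
  frac_5p <- rep_len(frac_5p, n)
  state <- rep("not_expressed", n)
  ex <- !is.na(total_reads) & total_reads >= min_reads
  long <- !is.na(median_len) & median_len >= min_median
  anchored <- !is.na(frac_5p) & frac_5p >= min_5p
  state[ex & !long] <- "expressed_short"
  state[ex & long & !anchored] <- "expressed_low5p"
  state[ex & long & anchored] <- "agotron"
  state
}

#' Per-dataset call matrix for intron regions
#'
#' @param summaries output of [dataset_summary()].
#' @param regions region table; only `region_class == "intron"` rows are
#'   classified (miRNA/snoRNA rows are metrics-only).
#' @inheritParams classify_region_in_dataset
#' @return long-format data.table (region_id, dataset_id, state, plus the
#'   underlying metrics) restricted to introns.
#' @export
build_call_matrix <- function(summaries, regions, min_reads = 20,
                              min_median = 30, min_5p = 0.70) {
  introns <- regions[regions$region_class == "intron", ]
  m <- as.data.table(summaries)[region_id %in% introns$region_id]
  m[, state := classify_region_in_dataset(total_reads, median_read_length,
                                          five_prime_fraction, min_reads,
                                          min_median, min_5p)]
  m[]
}

#' Consensus agotron calls across datasets
#'
#' An intron expressed (>= `min_reads` reads) in at least `min_datasets`
#' datasets is called an agotron when at least half of those expressed
#' datasets, and no fewer than `min_datasets` of them, meet the per-dataset
#' agotron definition. Datasets in which a region is not expressed neither
#' support nor oppose the call.
#'
#' @param call_matrix long-format table from [build_call_matrix()].
#' @param min_datasets minimum expressed and minimum adhering datasets,
#'   default 2.
#' @return data.table (region_id, n_expressed_datasets, n_adhering_datasets,
#'   is_agotron, supporting_datasets).
#' @export
consensus_call <- function(call_matrix, min_datasets = 2L) {
  cm <- as.data.table(call_matrix)
  out <- cm[, .(
    n_expressed_datasets = sum(state != "not_expressed"),
    n_adhering_datasets = sum(state == "agotron"),
    supporting_datasets = paste(sort(dataset_id[state == "agotron"]),
                                collapse = ",")
  ), by = region_id]
  out[, is_agotron := n_expressed_datasets >= min_datasets &
        n_adhering_datasets >= min_datasets &
        n_adhering_datasets >= n_expressed_datasets / 2]
  setorder(out, region_id)
  out[]
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided; exact enumeration for small tie-free samples (both groups
#' <= 25), otherwise the normal approximation with midrank ties and
#' continuity correction.
#'
#' @param values_a,values_b numeric vectors, each non-empty.
#' @return list(statistic, p_value, method).
#' @export
rank_sum_test <- function(values_a, values_b) {
  if (length(values_a) == 0L || length(values_b) == 0L) {
    stop("rank-sum test needs non-empty groups")
  }
  pooled <- c(values_a, values_b)
  if (all(pooled == pooled[1])) {  # fully degenerate: no evidence of a shift
    return(list(statistic = length(values_a) * length(values_b) / 2,
                p_value = 1, method = "degenerate"))
  }
  ties <- anyDuplicated(pooled) > 0L
  exact <- !ties && length(values_a) <= 25 && length(values_b) <= 25
  ht <- suppressWarnings(wilcox.test(values_a, values_b, exact = exact,
                                     correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = if (exact) "exact" else "normal")
}

#' Pearson chi-squared test of independence on a 2x2 table
#'
#' No continuity correction; applied to the long-read x 5'-aligned
#' contingency over expressed introns.
#'
#' @param tab 2x2 numeric matrix of counts with positive margins.
#' @return list(statistic, p_value).
#' @export
chi2_independence <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-squared test undefined: zero margin")
  }
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Long-read by 5'-aligned contingency over expressed introns
#'
#' Builds the 2x2 table (median length >= `min_median`) x (5' fraction >=
#' `min_5p`) over introns expressed in one dataset and tests the coupling of
#' the two defining agotron features.
#'
#' @param call_matrix table from [build_call_matrix()] (one dataset's rows).
#' @inheritParams classify_region_in_dataset
#' @return list(table, statistic, p_value).
#' @export
feature_coupling_test <- function(call_matrix, min_median = 30,
                                  min_5p = 0.70) {
  cm <- as.data.table(call_matrix)[state != "not_expressed"]
  long <- factor(cm$median_read_length >= min_median, levels = c(FALSE, TRUE),
                 labels = c("short", "long"))
  anch <- factor(cm$five_prime_fraction >= min_5p, levels = c(FALSE, TRUE),
                 labels = c("low5p", "aligned5p"))
  tab <- table(long, anch)
  res <- chi2_independence(tab)
  list(table = tab, statistic = res$statistic, p_value = res$p_value)
}

#' Boxplot-style summaries of enrichment by group
#'
#' Median, quartiles and the 5th/95th percentiles of a numeric metric per
#' group, the summary layer behind enrichment boxplots.
#'
#' @param values numeric vector.
#' @param groups grouping vector of equal length.
#' @return data.table (group, n, p05, q1, median, q3, p95).
#' @export
group_summary <- function(values, groups) {
  dt <- data.table(value = values, group = groups)
  out <- dt[!is.na(value), .(
    n = .N,
    p05 = quantile(value, 0.05, names = FALSE),
    q1 = quantile(value, 0.25, names = FALSE),
    median = median(value),
    q3 = quantile(value, 0.75, names = FALSE),
    p95 = quantile(value, 0.95, names = FALSE)
  ), by = group]
  setorder(out, group)
  out[]
}
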