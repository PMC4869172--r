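# miRNA-style seed-match target analysis driven by an agotron's 5' arm:
# derive target k-mers by class (8mer, 7mer-m8, 7mer-1A, sliding-A and
# unconstrained 8-nt windows), scan 3'-UTRs, stratify expression fold
# changes by best site class, and compute RIP ratio-of-ratios enrichment.

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Derive seed-match target site classes from a guide sequence
#'
#' Positions are 1-based along the guide 5'->3' (miRNA convention; the seed
#' spans positions 2-8). Canonical classes: 8mer = reverse complement of
#' positions 2-8 followed by an A (opposite position 1); 7mer-m8 = reverse
#' complement of positions 2-8; 7mer-1A = reverse complement of positions
#' 2-7 followed by an A. Sliding-A classes use windows i..i+6 with a
#' flanking target A (the i = 2 window coincides with the 8mer); free 8-nt
#' classes use windows i..i+7 with no flanking constraint.
#'
#' @param guide guide sequence 5'->3' (U or T spelling), length >= 11.
#' @param sliding_starts guide positions for the sliding-A windows,
#'   default 2:4.
#' @param free_starts guide positions for the unconstrained 8-nt windows,
#'   default 1..min(9, L-7).
#' @return data.table (class_label, kmer) with target k-mers in the DNA
#'   alphabet.
#' @export
derive_sites <- function(guide, sliding_starts = 2:4, free_starts = NULL) {
  g <- normalize_seq(guide)
  L <- nchar(g)
  if (L < 11L) stop("guide too short (", L, " nt); need >= 11 nt")
  if (is.null(free_starts)) free_starts <- seq_len(min(9L, L - 7L))
  sub <- function(i, j) substr(g, i, j)
  sites <- list(
    data.table(class_label = "8mer",
               kmer = paste0(revcomp(sub(2, 8)), "A")),
    data.table(class_label = "7mer-m8", kmer = revcomp(sub(2, 8))),
    data.table(class_label = "7mer-1A",
               kmer = paste0(revcomp(sub(2, 7)), "A"))
  )
  for (i in sliding_starts) {
    if (i + 6L > L) stop("sliding window ", i, "-", i + 6L, " exceeds guide")
    sites[[length(sites) + 1L]] <- data.table(
      class_label = sprintf("slidingA:%d-%dA", i, i + 6L),
      kmer = paste0(revcomp(sub(i, i + 6L)), "A"))
  }
  for (i in free_starts) {
    if (i + 7L > L) stop("free window ", i, "-", i + 7L, " exceeds guide")
    sites[[length(sites) + 1L]] <- data.table(
      class_label = sprintf("free8:%d-%d", i, i + 7L),
      kmer = revcomp(sub(i, i + 7L)))
  }
  rbindlist(sites)
}

#' Scan 3'-UTR sequences for seed-match sites
#'
#' Reports every exact (possibly overlapping) occurrence of every site
#' k-mer. With a conservation track in UTR coordinates (chrom = transcript
#' id), each hit carries a conserved flag: mean score over the site's
#' positions strictly above `cons_cutoff`.
#'
#' @param utrs named character vector of 3'-UTR sequences (5'->3', DNA).
#' @param sites site table from [derive_sites()].
#' @param track optional conservation track ([read_conservation()]).
#' @param cons_cutoff conservation threshold, default 0.5.
#' @return data.table (transcript_id, position, class_label, conserved)
#'   with 0-based leftmost positions.
#' @export
scan_utr <- function(utrs, sites, track = NULL, cons_cutoff = 0.5) {
  utrs <- normalize_seq(utrs)
  subject <- Biostrings::DNAStringSet(unname(utrs))
  hits <- list()
  for (k in seq_len(nrow(sites))) {
    m <- Biostrings::vmatchPattern(sites$kmer[k], subject)
    st <- Biostrings::startIndex(m)
    n_hit <- lengths(st)
    idx <- rep(seq_along(utrs), vapply(st, function(s) length(s %||% integer()), 0L))
    if (length(idx) == 0L) next
    hits[[length(hits) + 1L]] <- data.table(
      transcript_id = names(utrs)[idx],
      position = unlist(st[n_hit > 0]) - 1L,  # 0-based
      class_label = sites$class_label[k],
      width = nchar(sites$kmer[k])
    )
  }
  if (length(hits) == 0L) {
    return(data.table(transcript_id = character(), position = integer(),
                      class_label = character(), conserved = logical()))
  }
  out <- rbindlist(hits)
  if (is.null(track)) {
    out[, conserved := NA]
  } else {
    out[, conserved := mapply(function(tx, p, w) {
      m <- mean_conservation(tx, p, p + w, track)
      !is.na(m) && m > cons_cutoff
    }, transcript_id, position, width)]
  }
  out[, width := NULL]
  setorder(out, transcript_id, position, class_label)
  out[]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Best canonical site class per transcript
#'
#' Assigns each transcript its strongest canonical class under the priority
#' 8mer > 7mer-m8 > 7mer-1A; transcripts without any canonical site are the
#' `none` background.
#'
#' @param hits hit table from [scan_utr()].
#' @param transcript_ids all transcript ids (scanned universe).
#' @return data.table (transcript_id, best_class).
#' @export
best_canonical_class <- function(hits, transcript_ids) {
  prio <- c("8mer", "7mer-m8", "7mer-1A")
  h <- as.data.table(hits)[class_label %in% prio]
  best <- h[, .(best_class = prio[min(match(class_label, prio))]),
            by = transcript_id]
  out <- data.table(transcript_id = transcript_ids)
  out <- merge(out, best, by = "transcript_id", all.x = TRUE)
  out[is.na(best_class), best_class := "none"]
  out[]
}

log2_ratio <- function(num, den, pseudo) {
  stopifnot(pseudo > 0)
  log2((num + pseudo) / (den + pseudo))
}

#' Stratified expression shift of site-bearing transcripts
#'
#' Computes per-transcript log2 fold changes
#' `log2((fpkm_treatment + pseudo) / (fpkm_control + pseudo))` and compares
#' each site class against the no-site background with the rank-sum test.
#' Also emits a cumulative-distribution table for plotting.
#'
#' @param expr data.table (transcript_id, fpkm_control, fpkm_treatment).
#' @param classes data.table (transcript_id, best_class) from
#'   [best_canonical_class()] (or any stratification with a `none`
#'   background).
#' @param pseudo FPKM pseudocount, default 0.1.
#' @param background label of the background class, default "none".
#' @return list(stats = per-class (class, n, median_lfc, p_vs_background),
#'   lfc = per-transcript table, cumulative = plotting table).
#' @export
stratified_shift <- function(expr, classes, pseudo = 0.1,
                             background = "none") {
  e <- merge(as.data.table(expr), as.data.table(classes), by = "transcript_id")
  e[, lfc := log2_ratio(fpkm_treatment, fpkm_control, pseudo)]
  out <- .stratify_vs_background(e, background)
  list(stats = out$stats, lfc = e[], cumulative = out$cumulative)
}

# per-class medians and rank-sum p against the background stratum, plus a
# cumulative-distribution table for plotting
.stratify_vs_background <- function(e, background) {
  bg <- e[best_class == background, lfc]
  labs <- setdiff(unique(e$best_class), background)
  stats <- rbindlist(lapply(labs, function(cl) {
    v <- e[best_class == cl, lfc]
    if (length(v) == 0L || length(bg) == 0L) {
      return(data.table(class = cl, n = length(v),
                        median_lfc = if (length(v)) median(v) else NA_real_,
                        p_vs_background = NA_real_))
    }
    data.table(class = cl, n = length(v), median_lfc = median(v),
               p_vs_background = rank_sum_test(v, bg)$p_value)
  }))
  stats <- rbind(stats,
                 data.table(class = background, n = length(bg),
                            median_lfc = if (length(bg)) median(bg) else NA_real_,
                            p_vs_background = NA_real_))
  cum <- e[order(best_class, lfc),
           .(lfc = lfc, cum_fraction = seq_len(.N) / .N), by = best_class]
  list(stats = stats[], cumulative = cum[])
}

#' RIP-seq ratio-of-ratios enrichment
#'
#' Per transcript, `log2(((ip_trt + pseudo) / (input_trt + pseudo)) /
#' ((ip_ctl + pseudo) / (input_ctl + pseudo)))`: differential
#' co-immunoprecipitation of the treatment condition over the control.
#' Transcripts missing any of the four measurements are skipped with a log
#' message. The per-class stratification mirrors [stratified_shift()].
#'
#' @param expr data.table (transcript_id, fpkm_input_control,
#'   fpkm_ip_control, fpkm_input_treatment, fpkm_ip_treatment).
#' @inheritParams stratified_shift
#' @return list(stats, ror = per-transcript table, cumulative).
#' @export
rip_enrichment <- function(expr, classes, pseudo = 0.1, background = "none") {
  e <- as.data.table(expr)
  need <- c("fpkm_input_control", "fpkm_ip_control", "fpkm_input_treatment",
            "fpkm_ip_treatment")
  stopifnot(all(need %in% names(e)))
  complete <- stats::complete.cases(e[, need, with = FALSE])
  if (any(!complete)) {
    message(sum(!complete), " transcript(s) skipped: missing IP/input values")
  }
  e <- e[complete]
  e[, lfc := log2_ratio(fpkm_ip_treatment, fpkm_input_treatment, pseudo) -
        log2_ratio(fpkm_ip_control, fpkm_input_control, pseudo)]
  ee <- merge(e[, .(transcript_id, lfc)], as.data.table(classes),
              by = "transcript_id")
  out <- .stratify_vs_background(ee, background)
  list(stats = out$stats, ror = ee[], cumulative = out$cumulative)
}
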