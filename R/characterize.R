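# Physical and evolutionary characterization of called agotrons versus
# other introns: length, GC content, folding energy per nucleotide, and
# mean conservation, with rank-sum group comparisons.

#' GC fraction of a sequence
#'
#' G+C count over the non-N length; a sequence of only Ns has no defined GC
#' content and raises an error.
#'
#' @param sequence character vector of DNA/RNA sequences.
#' @return numeric vector in [0, 1].
#' @export
gc_fraction <- function(sequence) {
  s <- normalize_seq(sequence)
  gc <- nchar(gsub("[^GC]", "", s))
  denom <- nchar(gsub("N", "", s))
  if (any(denom == 0)) stop("GC fraction undefined: sequence has no unambiguous bases")
  gc / denom
}

#' Folding free-energy proxy of an RNA sequence
#'
#' The built-in backend computes the optimum over nested secondary
#' structures of a weighted base-pair score (GC -3, AU -2, GU -1, arbitrary
#' energy units; minimum hairpin loop of 3 unpaired nt) by dynamic
#' programming, a structure-propensity proxy that tracks the direction of
#' thermodynamic folding energies. An external backend
#' (`"external:<cmd>"`) pipes the sequence to a user-supplied MFE tool
#' (e.g. `RNAfold`) and parses the last parenthesized number of its output.
#' Both return values <= 0; an unstructured sequence scores 0.
#'
#' @param sequence a single sequence (U or T spelling), length >= 10.
#' @param backend `"builtin"` or `"external:<command>"`.
#' @param pair_scores named numeric vector of builtin pair weights
#'   (positive magnitudes for gc, au, gu).
#' @param min_loop minimum hairpin loop size, default 3.
#' @return delta-G (<= 0).
#' @export
fold_energy <- function(sequence, backend = "builtin",
                        pair_scores = c(gc = 3, au = 2, gu = 1),
                        min_loop = 3L) {
  stopifnot(length(sequence) == 1L, nchar(sequence) >= 10L)
  s <- normalize_seq(sequence)
  if (identical(backend, "builtin")) {
    return(nussinov_energy_cpp(s, pair_scores[["gc"]], pair_scores[["au"]],
                               pair_scores[["gu"]], as.integer(min_loop)))
  }
  if (!startsWith(backend, "external:")) {
    stop("unknown fold backend '", backend, "'; use 'builtin' or 'external:<cmd>'")
  }
  cmd <- sub("^external:", "", backend)
  exe <- strsplit(cmd, "[ \t]+")[[1]][1]
  if (Sys.which(exe) == "") {
    stop("external fold tool '", exe, "' not found on PATH; ",
         "use backend = 'builtin'")
  }
  out <- system(cmd, input = chartr("T", "U", s), intern = TRUE)
  m <- regmatches(out, gregexpr("\\(\\s*(-?[0-9]+\\.?[0-9]*)\\s*\\)", out))
  m <- unlist(m)
  if (length(m) == 0L) stop("could not parse an energy from '", cmd, "' output")
  e <- as.numeric(gsub("[()\\s]", "", m[length(m)], perl = TRUE))
  if (is.na(e)) stop("could not parse an energy from '", cmd, "' output")
  min(e, 0)
}

#' Mean conservation score over an interval
#'
#' Arithmetic mean of track scores at the interval's covered positions;
#' positions absent from the track are excluded from the mean. With no
#' covered position the result is NA (a reportable undefined state).
#'
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @param track keyed data.table from [read_conservation()].
#' @return mean score in [0, 1], or NA.
#' @export
mean_conservation <- function(chrom, start, end, track) {
  .chr <- as.character(chrom)
  .lo <- start
  .hi <- end
  sub <- track[list(.chr), nomatch = NULL][pos >= .lo & pos < .hi]
  if (nrow(sub) == 0L || all(is.na(sub$score))) return(NA_real_)
  mean(sub$score, na.rm = TRUE)
}

#' Physical/evolutionary feature table for intron regions
#'
#' @param regions region table (intron rows are used).
#' @param region_seqs named character vector of region sequences.
#' @param track optional conservation track; without one the conservation
#'   column is NA (graceful degradation for genomes lacking a track).
#' @param backend fold backend passed to [fold_energy()].
#' @return data.table (region_id, length_nt, gc, delta_g, delta_g_per_nt,
#'   mean_conservation).
#' @export
intron_features <- function(regions, region_seqs, track = NULL,
                            backend = "builtin") {
  introns <- as.data.table(regions)[region_class == "intron"]
  seqs <- region_seqs[introns$region_id]
  if (anyNA(names(seqs)) || any(!introns$region_id %in% names(region_seqs))) {
    stop("missing sequence for region: ",
         introns$region_id[!introns$region_id %in% names(region_seqs)][1])
  }
  dg <- vapply(seqs, fold_energy, 0, backend = backend)
  cons <- rep(NA_real_, nrow(introns))
  if (!is.null(track)) {
    cons <- mapply(mean_conservation, introns$chrom, introns$start,
                   introns$end, MoreArgs = list(track = track))
  }
  data.table(
    region_id = introns$region_id,
    length_nt = nchar(seqs),
    gc = gc_fraction(seqs),
    delta_g = dg,
    delta_g_per_nt = dg / nchar(seqs),
    mean_conservation = as.numeric(cons)
  )
}

#' Compare feature distributions between intron groups
#'
#' For each metric, reports group medians and the pairwise rank-sum p-value
#' of every non-reference group against the reference group (by default the
#' first), the statistics behind length / energy-per-nt / GC / conservation
#' boxplot panels.
#'
#' @param features table from [intron_features()].
#' @param groups named list mapping a group label to a character vector of
#'   region ids (e.g. agotron / other expressed intron / all introns).
#'   Every group must be non-empty.
#' @param metrics feature columns to compare.
#' @param reference label of the reference group, default the first.
#' @return data.table (metric, group, n, median, p_vs_reference).
#' @export
class_comparison <- function(features, groups,
                             metrics = c("length_nt", "gc", "delta_g_per_nt",
                                         "mean_conservation"),
                             reference = names(groups)[1]) {
  stopifnot(length(groups) >= 2, !is.null(names(groups)))
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stop("empty comparison group: ", names(groups)[sizes == 0L][1])
  ft <- as.data.table(features)
  rows <- list()
  for (metric in metrics) {
    vals <- lapply(groups, function(ids) {
      v <- ft[region_id %in% ids][[metric]]
      v[!is.na(v)]
    })
    if (all(lengths(vals) == 0L)) next  # metric undefined (e.g. no track)
    ref <- vals[[reference]]
    for (g in names(groups)) {
      v <- vals[[g]]
      p <- if (g == reference || length(v) == 0L || length(ref) == 0L) {
        NA_real_
      } else {
        rank_sum_test(v, ref)$p_value
      }
      rows[[length(rows) + 1L]] <- data.table(
        metric = metric, group = g, n = length(v),
        median = if (length(v)) median(v) else NA_real_,
        p_vs_reference = p)
    }
  }
  rbindlist(rows)
}
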