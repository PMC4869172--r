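# Read preprocessing: adapter trimming, length filtering, and assignment of
# reads to the short-region universe by Hamming matching with at most one
# substitution (no indels). The matcher is exact for the configured mismatch
# budget: it seeds on 7-mers at window positions chosen so that any valid
# placement with <= 1 mismatch leaves at least one window mismatch-free
# (pigeonhole over the read ends and midpoint), then verifies candidates by
# full comparison.

#' Trim a 3' sequencing adapter from reads
#'
#' Removes the leftmost read suffix that exactly matches a prefix of the
#' adapter, provided the overlap is at least `min_overlap` nt. Reads without
#' such a match are returned untouched.
#'
#' @param reads character vector of read sequences (names preserved).
#' @param adapter adapter sequence (non-empty).
#' @param min_overlap minimum adapter-prefix overlap, >= 3.
#' @return character vector of trimmed reads.
#' @examples
#' trim_adapter("ACGTACGTAGATCGG", "AGATCGG")  # "ACGTACGT"
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 3L) {
  stopifnot(nchar(adapter) > 0, min_overlap >= 3)
  adapter <- normalize_seq(adapter)
  out <- trim_adapter_cpp(unname(reads), adapter, as.integer(min_overlap))
  names(out) <- names(reads)
  out
}

#' Discard reads shorter than a minimum length
#'
#' @param reads character vector of (trimmed) read sequences.
#' @param min_len minimum length kept, default 18 nt.
#' @return the surviving reads; attribute `n_discarded` counts the rest.
#' @export
filter_min_length <- function(reads, min_len = 18L) {
  keep <- nchar(reads) >= min_len
  out <- reads[keep]
  attr(out, "n_discarded") <- sum(!keep)
  message(sum(!keep), " of ", length(reads), " reads below ", min_len,
          " nt discarded")
  out
}

#' Assign reads to reference regions allowing substitutions
#'
#' Each read is placed at every region position where it matches with at
#' most `max_mismatch` substitutions; a 5' overhang of up to `max_up` nt
#' (read starting just upstream of the region, accommodating the
#' single-nucleotide offset seen at decapitated intron 5' ends) and a 3'
#' overhang of up to `max_down` nt are tolerated, with overhanging bases not
#' compared. Matching is to the sense strand only; region sequences must
#' arrive strand-resolved 5'->3'. A read matching several regions is
#' assigned to the fewest-mismatch region; remaining ties are split
#' fractionally (weight 1/k to each of k regions). Within one region the
#' best placement (fewest mismatches, then least overhang, then leftmost)
#' is kept.
#'
#' @param reads named character vector of trimmed, length-filtered reads.
#' @param region_seqs named character vector of region sequences, 5'->3'.
#' @param max_mismatch substitution budget (0 or 1 supported), default 1.
#' @param max_up,max_down tolerated 5'/3' overhang in nt.
#' @param min_len reads shorter than this are never assigned.
#' @return data.table (read_id, region_id, offset, length_nt, mismatches,
#'   weight, overhang5) where `offset` is the region-local 0-based start
#'   (a 1-nt upstream start is recorded as offset 0 with `overhang5 = TRUE`);
#'   attributes `n_input`, `n_assigned`, `n_unassigned`.
#' @export
assign_reads <- function(reads, region_seqs, max_mismatch = 1L,
                         max_up = 1L, max_down = 2L, min_len = 18L) {
  stopifnot(max_mismatch %in% c(0L, 1L))
  if (is.null(names(region_seqs)) || anyDuplicated(names(region_seqs))) {
    stop("region_seqs must be uniquely named by region_id")
  }
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  n_input <- length(reads)
  eligible <- nchar(reads) >= min_len
  q <- reads[eligible]
  hits <- assign_reads_cpp(unname(q), unname(region_seqs),
                           as.integer(max_mismatch), as.integer(max_up),
                           as.integer(max_down))
  dt <- as.data.table(hits)
  if (nrow(dt) == 0L) {
    out <- data.table(read_id = character(), region_id = character(),
                      offset = integer(), length_nt = integer(),
                      mismatches = integer(), weight = numeric(),
                      overhang5 = logical())
  } else {
    dt[, weight := 1 / .N, by = read_idx]
    out <- data.table(
      read_id = names(q)[dt$read_idx],
      region_id = names(region_seqs)[dt$region_idx],
      offset = pmax(dt$start, 0L),
      length_nt = nchar(q)[dt$read_idx],
      mismatches = dt$mismatches,
      weight = dt$weight,
      overhang5 = dt$overhang5 > 0L
    )
  }
  n_assigned <- length(unique(out$read_id))
  setattr(out, "n_input", n_input)
  setattr(out, "n_assigned", n_assigned)
  setattr(out, "n_unassigned", n_input - n_assigned)
  out[]
}

#' Trim, filter and assign one read library
#'
#' Convenience wrapper running [trim_adapter()] (if an adapter is given),
#' [filter_min_length()] and [assign_reads()] for a single sample.
#'
#' @param reads named character vector of raw read sequences.
#' @param region_seqs named character vector of region sequences.
#' @param adapter optional 3' adapter to trim first.
#' @param min_len minimum post-trim read length, default 18.
#' @param max_mismatch substitution budget, default 1.
#' @return assignment table as from [assign_reads()]; attribute
#'   `total_mapped_reads` is the number of assigned reads (the RPM
#'   denominator).
#' @export
preprocess_sample <- function(reads, region_seqs, adapter = NULL,
                              min_len = 18L, max_mismatch = 1L) {
  if (!is.null(adapter)) reads <- trim_adapter(reads, adapter)
  reads <- suppressMessages(filter_min_length(reads, min_len))
  asn <- assign_reads(reads, region_seqs, max_mismatch = max_mismatch,
                      min_len = min_len)
  setattr(asn, "total_mapped_reads", attr(asn, "n_assigned"))
  asn
}
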