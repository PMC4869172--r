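# Readers and writers for the external formats the pipeline touches.
#
# Coordinate convention: 0-based half-open intervals everywhere (BED-native),
# so length = end - start and the 5' end sits at `start` on (+) and `end - 1`
# on (-). This is the only convention under which published agotron spans
# reconcile with their printed lengths, e.g. chr17:24594977-24595071 spans
# 94 nt.

.SEQ_ALPHABET <- c("A", "C", "G", "T", "U", "N")

#' Normalize a nucleotide sequence to the internal DNA alphabet
#'
#' Uppercases and converts U to T. Sequences must be over {A,C,G,T,U,N}.
#'
#' @param x character vector of sequences.
#' @return character vector over {A,C,G,T,N}.
#' @keywords internal
normalize_seq <- function(x) {
  x <- chartr("u", "U", toupper(x))
  bad <- grepl("[^ACGTUN]", x)
  if (any(bad)) {
    stop("sequence contains characters outside {A,C,G,T,U,N} (first offender: ",
         x[which(bad)[1]], ")")
  }
  chartr("U", "T", x)
}

#' Interval length under the 0-based half-open convention
#' @param start,end integer vectors, end > start.
#' @return integer vector of lengths (end - start).
#' @examples
#' interval_length(24594977, 24595071)  # 94
#' @export
interval_length <- function(start, end) {
  stopifnot(all(end > start))
  as.integer(end - start)
}

#' Genomic position of an interval's 5' end
#'
#' `start` on the plus strand, `end - 1` on the minus strand.
#' @param start,end integer vectors (0-based half-open).
#' @param strand character vector of "+"/"-".
#' @return integer vector of 0-based positions.
#' @export
five_prime_position <- function(start, end, strand) {
  stopifnot(all(strand %in% c("+", "-")))
  ifelse(strand == "+", start, end - 1L)
}

#' Read a BED6(+3) file of candidate regions
#'
#' Columns 1-6 are standard BED (0-based half-open); optional columns 7-9
#' carry the region class (`intron`, `pre_miRNA` or `snoRNA`; default
#' `intron`), a mirtron flag (0/1) and a host-gene identifier. Intron records
#' outside the 40-150 nt universe are rejected with a report (warning plus a
#' `rejected` attribute), never silently dropped; structurally malformed
#' lines abort with the offending line number.
#'
#' @param path BED file path.
#' @param intron_min,intron_max inclusive intron length bounds (nt).
#' @return data.table with columns chrom, start, end, region_id, score,
#'   strand, region_class, is_mirtron, host_gene; attribute `rejected` holds
#'   the out-of-bounds intron records.
#' @export
read_regions_bed <- function(path, intron_min = 40L, intron_max = 150L) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no records in BED file: ", path)
  fields <- strsplit(lines, "[ \t]+")
  n_col <- lengths(fields)
  if (any(n_col < 6L)) {
    stop("malformed BED line ", which(n_col < 6L)[1], ": fewer than 6 fields")
  }
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("malformed BED line ", bad[1], ": non-integer coordinates")
  bad <- which(end <= start)
  if (length(bad)) {
    stop("malformed BED line ", bad[1], ": empty or inverted interval (end <= start)")
  }
  strand <- get(6)
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) stop("malformed BED line ", bad[1], ": unknown strand '", strand[bad[1]], "'")
  region_class <- get(7)
  region_class[is.na(region_class)] <- "intron"
  bad <- which(!region_class %in% c("intron", "pre_miRNA", "snoRNA"))
  if (length(bad)) {
    stop("malformed BED line ", bad[1], ": unknown region class '", region_class[bad[1]], "'")
  }
  mirtron_raw <- get(8)
  is_mirtron <- !is.na(mirtron_raw) & mirtron_raw %in% c("1", "TRUE", "true")
  if (any(is_mirtron & region_class != "intron")) {
    stop("malformed BED line ", which(is_mirtron & region_class != "intron")[1],
         ": mirtron flag on a non-intron record")
  }
  host <- get(9)
  host[is.na(host)] <- ""
  regions <- data.table(
    chrom = get(1), start = start, end = end, region_id = get(4),
    score = get(5), strand = strand, region_class = region_class,
    is_mirtron = is_mirtron, host_gene = host
  )
  if (anyDuplicated(regions$region_id)) {
    stop("duplicate region_id: ", regions$region_id[duplicated(regions$region_id)][1])
  }
  len <- regions$end - regions$start
  oob <- regions$region_class == "intron" & (len < intron_min | len > intron_max)
  rejected <- regions[oob]
  if (nrow(rejected)) {
    warning(nrow(rejected), " intron record(s) outside the [", intron_min, ", ",
            intron_max, "] nt universe rejected: ",
            paste(head(rejected$region_id, 5), collapse = ", "),
            if (nrow(rejected) > 5) ", ..." else "")
  }
  regions <- regions[!oob]
  setattr(regions, "rejected", rejected)
  regions[]
}

#' Write regions to BED6+3
#' @param regions data.table as returned by [read_regions_bed()].
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  out <- data.table(
    regions$chrom, regions$start, regions$end, regions$region_id,
    if (is.null(regions$score)) 0L else regions$score, regions$strand,
    regions$region_class, as.integer(regions$is_mirtron),
    ifelse(nzchar(regions$host_gene), regions$host_gene, ".")
  )
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and U is normalized to T. Duplicate identifiers
#' are an error.
#' @param path FASTA file.
#' @return named character vector of DNA sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- sub("[ \t].*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  }
  setNames(normalize_seq(as.character(set)), ids)
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @param rna if TRUE, render T as U (RNA context).
#' @export
write_fasta <- function(seqs, path, rna = FALSE) {
  x <- if (rna) chartr("T", "U", seqs) else seqs
  Biostrings::writeXStringSet(Biostrings::BStringSet(setNames(x, names(seqs))), path)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#' @param path FASTQ file (may be empty; an empty vector is returned).
#' @return named character vector of read sequences, U normalized to T.
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readBStringSet(path, format = "fastq")
  ids <- sub("[ \t].*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate read id in FASTQ: ", ids[duplicated(ids)][1])
  setNames(normalize_seq(as.character(set)), ids)
}

#' Write reads to FASTQ with uniform placeholder qualities
#' @param seqs named character vector of read sequences.
#' @param path output path.
#' @export
write_fastq <- function(seqs, path) {
  if (length(seqs) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- names(seqs)
  qual <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
    paste(rep("I", n), collapse = ""), ""))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a conservation track (bedGraph or fixed-step wiggle)
#'
#' Intervals are expanded to per-position scores under the 0-based
#' convention. Scores must lie in [0, 1] (phastCons-style probabilities).
#'
#' @param path bedGraph (.bedgraph/.bg) or wiggle (.wig) file.
#' @return keyed data.table (chrom, pos, score), one row per covered position.
#' @export
read_conservation <- function(path) {
  fmt <- if (grepl("\\.wig$", path, ignore.case = TRUE)) "wig" else "bedGraph"
  gr <- rtracklayer::import(path, format = fmt)
  sc <- gr$score
  if (any(sc < 0 | sc > 1)) {
    stop("conservation score outside [0,1]: ", sc[which(sc < 0 | sc > 1)[1]])
  }
  starts <- GenomicRanges::start(gr) - 1L  # back to 0-based
  widths <- GenomicRanges::width(gr)
  track <- data.table(
    chrom = rep(as.character(GenomicRanges::seqnames(gr)), widths),
    pos = unlist(lapply(seq_along(starts), function(i)
      seq.int(starts[i], length.out = widths[i]))),
    score = rep(sc, widths)
  )
  setkey(track, chrom, pos)
  track[]
}

#' Write a per-position conservation track as bedGraph
#'
#' Runs of equal adjacent scores are merged into single intervals.
#' @param track data.table (chrom, pos, score), 0-based positions.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  tr <- as.data.table(track)
  setorder(tr, chrom, pos)
  # break runs at chromosome changes, non-adjacent positions or score changes
  brk <- c(TRUE, tr$chrom[-1] != tr$chrom[-nrow(tr)] |
                 tr$pos[-1] != tr$pos[-nrow(tr)] + 1L |
                 tr$score[-1] != tr$score[-nrow(tr)])
  run <- cumsum(brk)
  out <- tr[, .(chrom = chrom[1], start = pos[1], end = pos[.N] + 1L,
                score = score[1]), by = run][, run := NULL]
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a table as TSV with a header row
#' @param records data.frame/data.table.
#' @param path output path.
#' @export
write_table <- function(records, path) {
  fwrite(as.data.table(records), path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_table()]
#' @param path TSV path.
#' @return data.table.
#' @export
read_table_tsv <- function(path) {
  fread(path, sep = "\t", header = TRUE, na.strings = "NA")
}
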