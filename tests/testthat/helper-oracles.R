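# Independent brute-force oracles. These deliberately share no code with
# the implementation: plain character/vector scans against which the
# optimized paths are checked.

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# leftmost read suffix equal to an adapter prefix, overlap >= min_overlap
oracle_trim <- function(read, adapter, min_overlap = 3L) {
  L <- nchar(read)
  for (i in seq_len(L - min_overlap + 1L)) {
    ov <- L - i + 1L
    if (ov > nchar(adapter)) next
    if (substr(read, i, L) == substr(adapter, 1, ov)) {
      return(substr(read, 1, i - 1L))
    }
  }
  read
}

# all-positions Hamming scan mirroring the assignment conventions:
# overhanging bases are not compared; per region the best placement
# (fewest mismatches, least overhang, leftmost) is kept; across regions
# only the minimum-mismatch tier survives.
oracle_assign_one <- function(read, region_seqs, max_mm = 1L, max_up = 1L,
                              max_down = 2L) {
  L <- nchar(read)
  rv <- utf8ToInt(read)
  hits <- list()
  for (rid in names(region_seqs)) {
    sv <- utf8ToInt(region_seqs[[rid]])
    rl <- length(sv)
    if (rl - L + max_down < -max_up) next
    best <- NULL
    for (st in (-max_up):(rl - L + max_down)) {
      up <- max(0L, -st)
      down <- max(0L, st + L - rl)
      if (up > max_up || down > max_down || up + down >= L) next
      idx <- (1L + up):(L - down)
      mm <- sum(rv[idx] != sv[st + idx])
      if (mm > max_mm) next
      cand <- c(mm = mm, ov = up + down, start = st)
      if (is.null(best) ||
          mm < best["mm"] ||
          (mm == best["mm"] && (cand["ov"] < best["ov"] ||
            (cand["ov"] == best["ov"] && st < best["start"])))) {
        best <- cand
      }
    }
    if (!is.null(best)) {
      hits[[rid]] <- data.frame(region_id = rid, start = unname(best["start"]),
                                mismatches = unname(best["mm"]))
    }
  }
  if (length(hits) == 0L) return(NULL)
  all <- do.call(rbind, hits)
  all[all$mismatches == min(all$mismatches), , drop = FALSE]
}

# exhaustive enumeration of all nested structures (plain recursion, no
# memoization) maximizing the weighted pair score
oracle_fold <- function(seq, scores = c(gc = 3, au = 2, gu = 1),
                        min_loop = 3L) {
  s <- strsplit(chartr("U", "T", toupper(seq)), "")[[1]]
  pw <- function(a, b) {
    p <- paste0(a, b)
    if (p %in% c("GC", "CG")) return(scores[["gc"]])
    if (p %in% c("AT", "TA")) return(scores[["au"]])
    if (p %in% c("GT", "TG")) return(scores[["gu"]])
    -Inf
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0)
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      w <- pw(s[i], s[k])
      if (!is.finite(w)) next
      inner <- rec(i + 1L, k - 1L)
      outer <- if (k + 1L <= j) rec(k + 1L, j) else 0
      best <- max(best, w + inner + outer)
    }
    best
  }
  -rec(1L, length(s))
}

# all (possibly overlapping) 0-based occurrences of kmer in utr: a naive
# scan comparing every window against the k-mer
oracle_scan <- function(utr, kmer) {
  L <- nchar(utr); k <- nchar(kmer)
  if (L < k) return(integer(0))
  i <- 0:(L - k)
  i[substring(utr, i + 1L, i + k) == kmer]
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
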