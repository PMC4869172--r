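# Adapter trimming, the 18 nt floor, and exactness of the one-mismatch
# read-to-region matcher against an all-positions Hamming oracle.

test_that("adapter trimming removes suffix-anchored adapter prefixes", {
  expect_identical(unname(trim_adapter("ACGTACGTAGATCGG", "AGATCGG")),
                   "ACGTACGT")
  expect_identical(unname(trim_adapter("ACGTACGT", "TTTTT")), "ACGTACGT")
  # partial adapter at the read end (3 nt overlap)
  expect_identical(unname(trim_adapter("ACGTAGA", "AGATCGG")), "ACGT")
  expect_error(trim_adapter("ACGT", ""), "nchar")
  expect_error(trim_adapter("ACGT", "AGATCGG", min_overlap = 2))
})

test_that("trimming agrees with a suffix-scan oracle on random reads", {
  set.seed(11)
  adapter <- "AGATCGGAAGAGC"
  reads <- vapply(1:200, function(i) {
    r <- random_dna(sample(18:60, 1))
    if (i %% 2 == 0) {
      paste0(r, substr(adapter, 1, sample(3:nchar(adapter), 1)))
    } else r
  }, "")
  got <- trim_adapter(reads, adapter)
  want <- vapply(reads, oracle_trim, "", adapter = adapter,
                 USE.NAMES = FALSE)
  expect_identical(unname(got), want)
})

test_that("length filter keeps exactly the reads at or above the floor", {
  r <- c(a = "AAAAAAAAAAAAAAAAA",   # 17
         b = "AAAAAAAAAAAAAAAAAC",  # 18
         c = "AAAAAAAAAAAAAAAACGT") # 19
  suppressMessages(kept <- filter_min_length(r))
  expect_identical(names(kept), c("b", "c"))
  expect_identical(attr(kept, "n_discarded"), 1L)
  suppressMessages(expect_length(filter_min_length(character(0)), 0L))
  set.seed(3)
  reads <- setNames(vapply(sample(10:40, 1000, TRUE), random_dna, ""),
                    paste0("r", 1:1000))
  suppressMessages(kept <- filter_min_length(reads))
  expect_identical(names(kept), names(reads)[nchar(reads) >= 18])
})

test_that("exact reads are assigned at the correct offset with 0 mismatches", {
  set.seed(5)
  regions <- c(R1 = random_dna(100), R2 = random_dna(80))
  read <- substr(regions[["R1"]], 1, 22)
  asn <- assign_reads(c(q = read), regions)
  expect_identical(asn$region_id, "R1")
  expect_identical(asn$offset, 0L)
  expect_identical(asn$length_nt, 22L)
  expect_identical(asn$mismatches, 0L)
  expect_identical(asn$weight, 1)
})

test_that("one internal mismatch is assigned, two are not", {
  set.seed(6)
  regions <- c(R1 = random_dna(100))
  read <- substr(regions[["R1"]], 11, 40)
  mutate_at <- function(s, i) {
    b <- substr(s, i, i)
    substr(s, i, i) <- setdiff(c("A", "C", "G", "T"), b)[1]
    s
  }
  one <- mutate_at(read, 15)
  two <- mutate_at(one, 22)
  a1 <- assign_reads(c(q = one), regions)
  expect_identical(a1$mismatches, 1L)
  expect_identical(a1$offset, 10L)
  a2 <- assign_reads(c(q = two), regions)
  expect_identical(nrow(a2), 0L)
  expect_identical(attr(a2, "n_unassigned"), 1L)
})

test_that("no read shorter than 18 nt is ever assigned", {
  set.seed(8)
  regions <- c(R1 = random_dna(60))
  short <- substr(regions[["R1"]], 1, 17)
  asn <- assign_reads(c(q = short), regions)
  expect_identical(nrow(asn), 0L)
})

test_that("matcher equals the brute-force Hamming scan on random instances", {
  set.seed(13)
  regions <- setNames(vapply(sample(40:90, 50, TRUE), random_dna, ""),
                      paste0("R", 1:50))
  mutate_n <- function(s, n) {
    for (p in sample.int(nchar(s), n)) {
      b <- substr(s, p, p)
      substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }
    s
  }
  reads <- vapply(1:500, function(i) {
    if (i %% 2 == 0) return(random_dna(sample(18:40, 1)))  # mostly unmatched
    rid <- sample(names(regions), 1)
    rl <- nchar(regions[[rid]])
    len <- sample(18:min(40, rl), 1)
    st <- sample(0:(rl - len), 1)
    mutate_n(substr(regions[[rid]], st + 1, st + len), sample(0:2, 1))
  }, "")
  names(reads) <- paste0("q", seq_along(reads))
  for (mm in c(0L, 1L)) {
    got <- assign_reads(reads, regions, max_mismatch = mm)
    for (qn in names(reads)) {
      want <- oracle_assign_one(reads[[qn]], regions, max_mm = mm)
      rows <- got[got$read_id == qn]
      if (is.null(want)) {
        expect_identical(nrow(rows), 0L)
      } else {
        expect_setequal(rows$region_id, want$region_id)
        w <- want[order(want$region_id), ]
        r <- rows[order(rows$region_id)]
        expect_identical(pmax(w$start, 0L), r$offset)
        expect_identical(as.integer(w$mismatches), r$mismatches)
        expect_equal(r$weight, rep(1 / nrow(w), nrow(w)))
      }
    }
  }
})

test_that("overhanging placements are found and flagged", {
  set.seed(17)
  regions <- c(R1 = random_dna(80))
  # read starting 1 nt upstream: extra 5' base, then the region 5' arm
  up <- paste0("A", substr(regions[["R1"]], 1, 29))
  a <- assign_reads(c(q = up), regions)
  want <- oracle_assign_one(up, regions)
  expect_identical(a$offset, 0L)
  expect_true(a$overhang5)
  expect_identical(want$start, -1L)
  # read running 2 nt past the region 3' end
  down <- paste0(substr(regions[["R1"]], 61, 80), "CA")
  b <- assign_reads(c(q = down), regions)
  expect_identical(b$offset, 60L)
  expect_identical(b$mismatches, oracle_assign_one(down, regions)$mismatches)
})

test_that("assignment is deterministic and independent of read order", {
  set.seed(19)
  regions <- setNames(vapply(rep(60, 10), random_dna, ""), paste0("R", 1:10))
  reads <- setNames(vapply(1:100, function(i) {
    rid <- sample(names(regions), 1)
    substr(regions[[rid]], 1, sample(18:30, 1))
  }, ""), paste0("q", 1:100))
  a <- assign_reads(reads, regions)
  b <- assign_reads(reads, regions)
  expect_identical(a, b)
  perm <- sample(names(reads))
  cp <- assign_reads(reads[perm], regions)
  data.table::setorder(a, read_id, region_id)
  data.table::setorder(cp, read_id, region_id)
  expect_equal(as.data.frame(a), as.data.frame(cp))
})
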