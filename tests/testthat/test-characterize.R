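# GC content, the folding-energy proxy, conservation means and the group
# comparisons behind the physical characterization.

test_that("GC fraction counts G+C over unambiguous bases", {
  expect_identical(gc_fraction("GGCC"), 1)
  expect_identical(gc_fraction("ATAT"), 0)
  expect_identical(gc_fraction("ACGN"), 2 / 3)  # N excluded from the length
  expect_error(gc_fraction("NNN"), "undefined")
  set.seed(53)
  for (i in 1:1000) {
    s <- random_dna(sample(10:60, 1), gc = runif(1, 0.2, 0.8))
    ch <- strsplit(s, "")[[1]]
    expect_identical(gc_fraction(s), sum(ch %in% c("G", "C")) / length(ch))
  }
})

test_that("builtin fold energy handles unstructured and perfect-stem cases", {
  expect_identical(fold_energy("AAAAAAAAAA"), 0)
  # 4 GC pairs at -3 each; the innermost pair encloses the AAAA loop
  expect_identical(fold_energy("GGGGAAAACCCC"), -12)
  expect_error(fold_energy("ACGTACG"), "nchar")
})

test_that("builtin DP equals exhaustive structure enumeration on short sequences", {
  set.seed(59)
  for (i in 1:60) {
    s <- random_dna(sample(10:15, 1))
    expect_identical(fold_energy(s), oracle_fold(s))
  }
})

test_that("fold energy is invariant under U/T spelling", {
  set.seed(61)
  for (i in 1:20) {
    s <- random_dna(30)
    expect_identical(fold_energy(s), fold_energy(chartr("T", "U", s)))
  }
})

test_that("appending sequence never raises the fold energy", {
  set.seed(67)
  for (i in 1:30) {
    s <- random_dna(25)
    expect_lte(fold_energy(paste0(s, random_dna(10))), fold_energy(s))
    # appending the reverse complement can only extend pairing
    expect_lte(fold_energy(paste0(s, "AAAA", oracle_revcomp(s))),
               fold_energy(s) - 10)
  }
})

test_that("the external fold backend parses a tool's energy output", {
  tool <- tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh", "cat > /dev/null", "echo '....((....)) ( -7.25)'"),
             tool)
  Sys.chmod(tool, "0755")
  expect_equal(fold_energy("GGGGAAAACCCC", backend = paste0("external:", tool)),
               -7.25)
  expect_error(fold_energy("GGGGAAAACCCC",
                           backend = "external:no_such_tool_xyz"),
               "not found")
  expect_error(fold_energy("GGGGAAAACCCC", backend = "magic"), "unknown")
})

test_that("mean conservation excludes uncovered positions", {
  tr <- data.table::data.table(chrom = "c1", pos = c(0:4, 10:14),
                               score = c(rep(1, 5), rep(0.2, 5)))
  data.table::setkey(tr, chrom, pos)
  expect_identical(mean_conservation("c1", 0, 5, tr), 1)
  # half the interval covered at 1.0, half absent: absent excluded
  expect_identical(mean_conservation("c1", 0, 10, tr), 1)
  expect_identical(mean_conservation("c1", 20, 30, tr), NA_real_)
  expect_identical(mean_conservation("cX", 0, 10, tr), NA_real_)
  set.seed(71)
  for (i in 1:50) {
    pos <- sort(sample(0:99, 40))
    sc <- runif(40)
    t2 <- data.table::data.table(chrom = "c", pos = pos, score = sc)
    data.table::setkey(t2, chrom, pos)
    a <- sample(0:80, 1); b <- a + sample(1:19, 1)
    keep <- pos >= a & pos < b
    want <- if (any(keep)) mean(sc[keep]) else NA_real_
    expect_equal(mean_conservation("c", a, b, t2), want)
  }
})

test_that("identical groups compare as indistinguishable", {
  set.seed(73)
  ft <- data.table::data.table(
    region_id = paste0("r", 1:60), length_nt = rep(80, 60),
    gc = rep(runif(20), 3), delta_g = rep(-30, 60),
    delta_g_per_nt = rep(runif(20, -1, 0), 3),
    mean_conservation = NA_real_)
  cmp <- class_comparison(ft, list(a = paste0("r", 1:20),
                                   b = paste0("r", 21:40),
                                   c = paste0("r", 41:60)),
                          metrics = c("gc", "delta_g_per_nt"))
  expect_true(all(cmp$p_vs_reference > 0.9, na.rm = TRUE))
  expect_error(class_comparison(ft, list(a = character(0), b = "r1")),
               "empty")
})

test_that("a planted GC difference is detected at small group size", {
  set.seed(79)
  detect <- replicate(100, {
    small <- pmin(pmax(rnorm(12, 0.60, 0.05), 0), 1)  # shifted by 0.15
    big <- pmin(pmax(rnorm(500, 0.45, 0.05), 0), 1)
    rank_sum_test(small, big)$p_value < 0.01
  })
  expect_gte(mean(detect), 0.95)
})

test_that("agotron-class introns are more structured and GC-rich on the fixture", {
  fx <- mini_fixture()
  ref <- fx$reference
  ft <- intron_features(ref$regions, ref$region_seqs, ref$conservation)
  groups <- list(
    agotron = ref$truth[truth_class == "agotron", region_id],
    background = ref$truth[truth_class == "background_intron", region_id])
  cmp <- class_comparison(ft, groups, reference = "background")
  gc_row <- cmp[cmp$metric == "gc" & cmp$group == "agotron"]
  dg_row <- cmp[cmp$metric == "delta_g_per_nt" & cmp$group == "agotron"]
  bg_gc <- cmp[cmp$metric == "gc" & cmp$group == "background"]
  bg_dg <- cmp[cmp$metric == "delta_g_per_nt" & cmp$group == "background"]
  expect_gt(gc_row$median, bg_gc$median)
  expect_lt(dg_row$median, bg_dg$median)
  cons_row <- cmp[cmp$metric == "mean_conservation" & cmp$group == "agotron"]
  expect_gt(cons_row$median, 0.5)
})
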