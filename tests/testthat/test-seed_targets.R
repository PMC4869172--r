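# Seed-site derivation, UTR scanning, fold-change stratification and RIP
# ratio-of-ratios.

test_that("canonical site classes of let-7a match the manual construction", {
  guide <- "UGAGGUAGUAGGUUGUAUAGUU"
  s <- derive_sites(guide)
  km <- setNames(s$kmer, s$class_label)
  expect_identical(unname(km["7mer-m8"]), "CTACCTC")
  expect_identical(unname(km["8mer"]), "CTACCTCA")
  expect_identical(unname(km["7mer-1A"]), "TACCTCA")
  # the i = 2 sliding window coincides with the canonical 8mer
  expect_identical(unname(km["slidingA:2-8A"]), unname(km["8mer"]))
  expect_error(derive_sites("ACGUACGUAC"), "too short")
})

test_that("site k-mers equal brute-force reverse-complement construction", {
  set.seed(83)
  for (i in 1:100) {
    g <- random_dna(sample(15:25, 1))
    s <- derive_sites(g)
    km <- setNames(s$kmer, s$class_label)
    expect_identical(unname(km["8mer"]),
                     paste0(oracle_revcomp(substr(g, 2, 8)), "A"))
    expect_identical(unname(km["7mer-m8"]), oracle_revcomp(substr(g, 2, 8)))
    expect_identical(unname(km["7mer-1A"]),
                     paste0(oracle_revcomp(substr(g, 2, 7)), "A"))
    for (j in 2:4) {
      expect_identical(
        unname(km[sprintf("slidingA:%d-%dA", j, j + 6)]),
        paste0(oracle_revcomp(substr(g, j, j + 6)), "A"))
    }
    for (j in seq_len(min(9, nchar(g) - 7))) {
      expect_identical(unname(km[sprintf("free8:%d-%d", j, j + 7)]),
                       oracle_revcomp(substr(g, j, j + 7)))
    }
  }
})

test_that("an 8mer occurrence yields co-located hits of all canonical classes", {
  guide <- "UGAGGUAGUAGGUUGUAUAGUU"
  s <- derive_sites(guide)
  utr <- c(t1 = paste0(random_dna(30), "CTACCTCA", random_dna(30)))
  h <- scan_utr(utr, s)
  expect_identical(h[h$class_label == "8mer", position], 30L)
  expect_identical(h[h$class_label == "7mer-m8", position], 30L)
  expect_identical(h[h$class_label == "7mer-1A", position], 31L)
  bc <- best_canonical_class(h, names(utr))
  expect_identical(bc$best_class, "8mer")
})

test_that("a G-containing site never hits an all-A UTR", {
  s <- data.table::data.table(class_label = "8mer", kmer = "CTACCTCA")
  h <- scan_utr(c(t1 = strrep("A", 200)), s)
  expect_identical(nrow(h), 0L)
})

test_that("UTR scanning is position-exact against a naive substring scan", {
  set.seed(89)
  guide <- random_dna(22)
  sites <- derive_sites(guide)
  utrs <- setNames(vapply(1:300, function(i) {
    u <- random_dna(sample(60:300, 1), gc = 0.5)
    if (i %% 3 == 0) {  # plant a site to guarantee positives
      k <- sites$kmer[sample.int(nrow(sites), 1)]
      p <- sample(nchar(u) - nchar(k), 1)
      u <- paste0(substr(u, 1, p - 1), k,
                  substr(u, p + nchar(k), nchar(u)))
    }
    u
  }, ""), paste0("t", 1:300))
  got <- scan_utr(utrs, sites)
  for (cl in unique(sites$class_label)) {
    k <- sites$kmer[sites$class_label == cl][1]
    for (tx in names(utrs)) {
      want <- oracle_scan(utrs[[tx]], k)
      have <- got[got$transcript_id == tx & got$class_label == cl, position]
      expect_identical(sort(have), as.integer(want))
    }
  }
})

test_that("conserved flags follow the mean-conservation cutoff", {
  s <- data.table::data.table(class_label = "8mer", kmer = "CTACCTCA")
  utr <- c(t1 = paste0("CTACCTCA", strrep("T", 20), "CTACCTCA"))
  tr <- data.table::data.table(
    chrom = "t1", pos = c(0:7, 28:35),
    score = c(rep(0.9, 8), rep(0.3, 8)))
  data.table::setkey(tr, chrom, pos)
  h <- scan_utr(utr, s, track = tr)
  expect_identical(h[h$position == 0L, conserved], TRUE)
  expect_identical(h[h$position == 28L, conserved], FALSE)
})

test_that("unchanged expression shows no class shift", {
  set.seed(97)
  n <- 300
  expr <- data.table::data.table(
    transcript_id = paste0("t", 1:n),
    fpkm_control = rlnorm(n, 3, 1))
  expr$fpkm_treatment <- expr$fpkm_control
  classes <- data.table::data.table(
    transcript_id = expr$transcript_id,
    best_class = sample(c("8mer", "none"), n, replace = TRUE,
                        prob = c(0.2, 0.8)))
  r <- stratified_shift(expr, classes)
  expect_equal(r$stats$median_lfc, rep(0, nrow(r$stats)))
  expect_gt(r$stats[r$stats$class == "8mer", p_vs_background], 0.9)
})

test_that("class medians equal direct computation", {
  set.seed(101)
  n <- 200
  expr <- data.table::data.table(
    transcript_id = paste0("t", 1:n),
    fpkm_control = rlnorm(n, 3, 1),
    fpkm_treatment = rlnorm(n, 3, 1))
  classes <- data.table::data.table(
    transcript_id = expr$transcript_id,
    best_class = sample(c("8mer", "7mer-m8", "none"), n, replace = TRUE))
  r <- stratified_shift(expr, classes, pseudo = 0.1)
  lfc <- log2((expr$fpkm_treatment + 0.1) / (expr$fpkm_control + 0.1))
  for (cl in unique(classes$best_class)) {
    want <- median(lfc[classes$best_class == cl])
    expect_equal(r$stats[r$stats$class == cl, median_lfc], want)
  }
  # cumulative tables are proper ECDFs per class
  for (cl in unique(r$cumulative$best_class)) {
    cc <- r$cumulative[r$cumulative$best_class == cl]
    expect_true(!is.unsorted(cc$lfc))
    expect_equal(cc$cum_fraction[nrow(cc)], 1)
  }
})

test_that("label permutation rejects at about the nominal rate", {
  set.seed(103)
  n <- 600
  lfc_base <- rlnorm(n, 3, 1)
  trt <- lfc_base * rlnorm(n, 0, 0.2)
  expr <- data.table::data.table(
    transcript_id = paste0("t", 1:n), fpkm_control = lfc_base,
    fpkm_treatment = trt)
  hits <- replicate(400, {
    classes <- data.table::data.table(
      transcript_id = expr$transcript_id,
      best_class = sample(rep(c("8mer", "none"), c(60, n - 60))))
    stratified_shift(expr, classes)$stats[class == "8mer",
                                          p_vs_background] < 0.05
  })
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.09)
})

test_that("RIP ratio-of-ratios matches its arithmetic definition", {
  expr <- data.table::data.table(
    transcript_id = c("t1", "t2"),
    fpkm_input_control = c(10, 7), fpkm_ip_control = c(10, 7),
    fpkm_input_treatment = c(10, 7), fpkm_ip_treatment = c(40, 7))
  classes <- data.table::data.table(transcript_id = c("t1", "t2"),
                                    best_class = c("8mer", "none"))
  r <- rip_enrichment(expr, classes, pseudo = 1e-9)
  expect_equal(r$ror[r$ror$transcript_id == "t1", lfc], 2, tolerance = 1e-6)
  expect_equal(r$ror[r$ror$transcript_id == "t2", lfc], 0, tolerance = 1e-6)
})

test_that("transcripts with missing IP components are skipped with a log", {
  expr <- data.table::data.table(
    transcript_id = c("t1", "t2"),
    fpkm_input_control = c(10, NA), fpkm_ip_control = c(10, 7),
    fpkm_input_treatment = c(10, 7), fpkm_ip_treatment = c(40, 7))
  classes <- data.table::data.table(transcript_id = c("t1", "t2"),
                                    best_class = c("8mer", "none"))
  expect_message(r <- rip_enrichment(expr, classes), "skipped")
  expect_identical(nrow(r$ror), 1L)
})

test_that("planted IP enrichment of conserved-site transcripts is recovered", {
  cfg <- mini_config()
  ref <- simulate_reference(cfg)
  guide <- substr(ref$region_seqs[[ref$truth[truth_class == "agotron",
                                             region_id][1]]], 1, 22)
  tw <- simulate_target_world(cfg, guide)
  hits <- scan_utr(tw$utrs, tw$sites, track = tw$track)
  classes <- best_canonical_class(hits, names(tw$utrs))
  # stratify by planted conservation instead: conserved sites carry the gain
  cls <- merge(classes, tw$truth[, c("transcript_id", "conserved")],
               by = "transcript_id")
  cls[best_class != "none" & conserved == TRUE, best_class := "conserved"]
  cls[, conserved := NULL]
  r <- rip_enrichment(tw$expr, cls)
  row <- r$stats[r$stats$class == "conserved"]
  expect_gt(row$median_lfc, 0.5)
  expect_lt(row$p_vs_background, 0.01)
})
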