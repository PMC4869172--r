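# Shared simulated fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# in-memory analysis of a simulated read set: trim/filter/assign every
# sample, then dataset summaries, per-dataset calls and the consensus
analyze_simulation <- function(cfg) {
  ref <- simulate_reference(cfg)
  libs <- simulate_read_libraries(cfg, ref)
  meta <- data.table::copy(libs$sample_meta)
  asn <- list()
  totals <- integer()
  for (sid in meta$sample_id) {
    a <- preprocess_sample(libs$reads[[sid]], ref$region_seqs,
                           adapter = cfg$adapter)
    a[, sample_id := sid]
    totals[sid] <- attr(a, "total_mapped_reads")
    asn[[sid]] <- a
  }
  meta[, total_mapped_reads := totals[sample_id]]
  assignments <- data.table::rbindlist(asn)
  summaries <- dataset_summary(assignments, meta)
  cm <- build_call_matrix(summaries, ref$regions)
  cons <- consensus_call(cm)
  list(config = cfg, reference = ref, libraries = libs, meta = meta,
       assignments = assignments, summaries = summaries,
       call_matrix = cm, consensus = cons)
}

# the default study-scale fixture (seed 42, 12 agotrons, 500 background
# introns, 2 datasets x (2 FLAG + 2 WT) x 200k reads)
full_fixture <- function() {
  if (is.null(.fixture_cache$full)) {
    .fixture_cache$full <- analyze_simulation(sim_config())
  }
  .fixture_cache$full
}

# a scaled-down world for unit tests
mini_config <- function(...) {
  base <- list(
    n_agotrons = 4L, n_background_introns = 60L, n_mirtrons = 4L,
    n_mirna_loci = 8L, n_snorna_loci = 4L,
    datasets = list(
      list(dataset_id = "d1", n_flag = 1L, n_wt = 1L, depth = 8000L),
      list(dataset_id = "d2", n_flag = 1L, n_wt = 1L, depth = 8000L)),
    utr = list(n_transcripts = 300L,
               n_sites = c(`8mer` = 15L, `7mer-m8` = 15L, `7mer-1A` = 15L)))
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  do.call(sim_config, base)
}

mini_fixture <- function() {
  if (is.null(.fixture_cache$mini)) {
    .fixture_cache$mini <- analyze_simulation(mini_config())
  }
  .fixture_cache$mini
}
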