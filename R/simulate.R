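# Seeded synthetic-data generator. Emulates the empirical signatures the
# pipeline is built to detect: 5'-anchored near-full-length intron reads
# (agotron-like), ~22-nt 5'-anchored reads (miRNA/mirtron-like), diffuse
# background reads, FLAG-over-WT abundance enrichment, seed-site-bearing
# 3'-UTRs with planted repression and IP enrichment, and a conservation
# track. Every draw is governed by one integer seed; identical seeds give
# identical outputs. Planted ground truth is carried in truth tables so
# downstream callers can be scored without reference to generator
# internals.

#' Default simulation configuration
#'
#' Returns the full parameterization of the synthetic reference, read
#' libraries, UTR/expression world and conservation model. Defaults mirror
#' the study conditions the pipeline targets: 12 agotrons in the 80-100 nt
#' band, 500 background introns (40-150 nt, 8 of them mirtron-flagged),
#' 50 pre-miRNA and 30 snoRNA loci, 2 datasets of 2 FLAG + 2 WT samples at
#' 200,000 reads each, an 8-fold FLAG-over-WT abundance of planted species,
#' a 0.5% per-base substitution error rate, and a 0.3 log2-unit planted
#' target repression.
#'
#' @param ... named overrides of any top-level entry.
#' @return nested list (class `sim_config`).
#' @export
sim_config <- function(...) {
  cfg <- list(
    seed = 42L,
    n_agotrons = 12L,
    n_background_introns = 500L,
    n_mirtrons = 8L,           # mirtron-flagged subset of the background
    n_mirna_loci = 50L,
    n_snorna_loci = 30L,
    agotron_len = c(80L, 100L),
    intron_len = c(40L, 150L),
    mirna_len = c(60L, 75L),
    snorna_len = c(60L, 120L),
    gc_agotron = 0.60,
    gc_background = 0.45,
    spacer_len = 20L,
    datasets = list(
      list(dataset_id = "ds1", n_flag = 2L, n_wt = 2L, depth = 200000L),
      list(dataset_id = "ds2", n_flag = 2L, n_wt = 2L, depth = 200000L)
    ),
    read_mix = c(agotron = 0.30, mirna = 0.40, mirtron = 0.05,
                 background = 0.25),
    flag_vs_wt_fold = 8,
    p_offset = c(`-1` = 0.05, `0` = 0.90, `1` = 0.05),
    agotron_len_jitter = -3:0,
    mirna_read_len = 21:23,
    background_read_len = 18:35,
    error_rate = 0.005,
    adapter = "AGATCGGAAGAGC",
    conservation = list(high = c(0.70, 1.00), low = c(0.00, 0.30)),
    utr = list(
      n_transcripts = 2200L,
      n_sites = c(`8mer` = 60L, `7mer-m8` = 70L, `7mer-1A` = 70L),
      conserved_fraction = 0.5,
      utr_len = c(400L, 1200L),
      delta = 0.3,              # planted repression, log2 units
      delta_conserved_extra = 0.2,
      ip_gain_conserved = 1.0,  # planted RIP log2 ratio-of-ratios
      fpkm_meanlog = 3, fpkm_sdlog = 1,
      noise_sdlog = 0.15
    )
  )
  over <- list(...)
  if (length(over)) {
    stopifnot(!is.null(names(over)), all(names(over) %in% names(cfg)))
    for (nm in names(over)) {
      named <- function(x) is.list(x) && !is.null(names(x)) && all(nzchar(names(x)))
      cfg[[nm]] <- if (named(cfg[[nm]]) && named(over[[nm]])) {
        utils::modifyList(cfg[[nm]], over[[nm]])
      } else over[[nm]]
    }
  }
  stopifnot(abs(sum(cfg$read_mix) - 1) < 1e-9, all(cfg$p_offset >= 0))
  cfg$p_offset <- cfg$p_offset / sum(cfg$p_offset)
  class(cfg) <- "sim_config"
  cfg
}

.random_seq <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

.stem_loop_seq <- function(len, gc) {
  # perfect stem with a >= 4 nt loop: arm + loop + revcomp(arm)
  loop <- sample(4:8, 1)
  if (loop %% 2 != len %% 2) loop <- loop + 1L
  arm <- (len - loop) %/% 2L
  left <- .random_seq(arm, gc)
  mid <- .random_seq(len - 2L * arm, gc)
  paste0(left, mid, revcomp(left))
}

#' Generate the synthetic reference (genome, regions, sequences)
#'
#' One chromosome per region class keeps coordinate bookkeeping auditable.
#' Agotron introns are built as stem-loops (GC-rich perfect stem, loop
#' >= 4 nt) in the 80-100 nt band; background introns are uniform 40-150 nt
#' random sequence; a configured subset of background introns carries the
#' mirtron flag. Roughly half the regions are placed on the minus strand.
#'
#' @param config a [sim_config()].
#' @return list(genome = named chromosome sequences, regions = region
#'   table, region_seqs = strand-resolved 5'->3' sequences, truth =
#'   data.table(region_id, truth_class), conservation = per-position track
#'   over the intron chromosome).
#' @export
simulate_reference <- function(config = sim_config()) {
  set.seed(config$seed)
  mk_ids <- function(prefix, n) sprintf("%s_%03d", prefix, seq_len(n))

  ago_len <- sample(config$agotron_len[1]:config$agotron_len[2],
                    config$n_agotrons, replace = TRUE)
  ago_seq <- vapply(ago_len, .stem_loop_seq, "", gc = config$gc_agotron)
  bgi_len <- sample(config$intron_len[1]:config$intron_len[2],
                    config$n_background_introns, replace = TRUE)
  bgi_seq <- vapply(bgi_len, .random_seq, "", gc = config$gc_background)
  mir_len <- sample(config$mirna_len[1]:config$mirna_len[2],
                    config$n_mirna_loci, replace = TRUE)
  mir_seq <- vapply(mir_len, .random_seq, "", gc = 0.5)
  sno_len <- sample(config$snorna_len[1]:config$snorna_len[2],
                    config$n_snorna_loci, replace = TRUE)
  sno_seq <- vapply(sno_len, .random_seq, "", gc = 0.5)

  mirtron_idx <- sample.int(config$n_background_introns, config$n_mirtrons)
  regions <- rbind(
    data.table(region_id = mk_ids("ago", config$n_agotrons),
               region_class = "intron", is_mirtron = FALSE,
               truth_class = "agotron", seq = ago_seq,
               chrom = "chr_intron"),
    data.table(region_id = mk_ids("bgi", config$n_background_introns),
               region_class = "intron",
               is_mirtron = seq_len(config$n_background_introns) %in% mirtron_idx,
               truth_class = ifelse(
                 seq_len(config$n_background_introns) %in% mirtron_idx,
                 "mirtron", "background_intron"),
               seq = bgi_seq, chrom = "chr_intron"),
    data.table(region_id = mk_ids("mirna", config$n_mirna_loci),
               region_class = "pre_miRNA", is_mirtron = FALSE,
               truth_class = "pre_miRNA", seq = mir_seq,
               chrom = "chr_pre_mirna"),
    data.table(region_id = mk_ids("sno", config$n_snorna_loci),
               region_class = "snoRNA", is_mirtron = FALSE,
               truth_class = "snoRNA", seq = sno_seq, chrom = "chr_snorna")
  )
  regions[, strand := sample(c("+", "-"), .N, replace = TRUE)]
  regions[, length_nt := nchar(seq)]

  # lay regions on their chromosome with random spacers
  genome <- list()
  regions[, `:=`(start = NA_integer_, end = NA_integer_)]
  for (chr in unique(regions$chrom)) {
    idx <- which(regions$chrom == chr)
    pieces <- character(0)
    pos <- 0L
    for (i in idx) {
      spacer <- .random_seq(config$spacer_len, 0.45)
      pieces <- c(pieces, spacer)
      pos <- pos + config$spacer_len
      genomic <- if (regions$strand[i] == "+") regions$seq[i] else
        revcomp(regions$seq[i])
      pieces <- c(pieces, genomic)
      regions[i, `:=`(start = pos, end = pos + length_nt)]
      pos <- pos + regions$length_nt[i]
    }
    pieces <- c(pieces, .random_seq(config$spacer_len, 0.45))
    genome[[chr]] <- paste(pieces, collapse = "")
  }

  # conservation: high over agotron spans, low elsewhere on chr_intron
  clen <- nchar(genome[["chr_intron"]])
  score <- round(runif(clen, config$conservation$low[1],
                       config$conservation$low[2]), 3)
  for (i in which(regions$truth_class == "agotron")) {
    span <- (regions$start[i] + 1L):regions$end[i]
    score[span] <- round(runif(length(span), config$conservation$high[1],
                               config$conservation$high[2]), 3)
  }
  track <- data.table(chrom = "chr_intron", pos = seq_len(clen) - 1L,
                      score = score)
  setkey(track, chrom, pos)

  region_seqs <- setNames(regions$seq, regions$region_id)
  truth <- regions[, .(region_id, truth_class)]
  regions_out <- regions[, .(chrom, start, end, region_id, score = 0L,
                             strand, region_class, is_mirtron,
                             host_gene = paste0("gene_", region_id))]
  list(genome = setNames(unlist(genome), names(genome)),
       regions = regions_out, region_seqs = region_seqs, truth = truth,
       conservation = track)
}

.mutate_reads <- function(reads, rate) {
  if (rate <= 0) return(reads)
  bases <- c("A", "C", "G", "T")
  lens <- nchar(reads)
  n_mut <- rbinom(length(reads), lens, rate)
  # single-substitution reads (the vast majority): fully vectorized
  i1 <- which(n_mut == 1L)
  if (length(i1)) {
    pos <- ceiling(runif(length(i1)) * lens[i1])
    old <- match(substr(reads[i1], pos, pos), bases)
    new <- bases[(old + sample.int(3L, length(i1), replace = TRUE) - 1L) %% 4L + 1L]
    substr(reads[i1], pos, pos) <- new
  }
  for (i in which(n_mut > 1L)) {
    s <- strsplit(reads[i], "")[[1]]
    for (p in sample.int(lens[i], n_mut[i])) {
      s[p] <- bases[(match(s[p], bases) + sample.int(3L, 1L) - 1L) %% 4L + 1L]
    }
    reads[i] <- paste(s, collapse = "")
  }
  reads
}

#' Generate per-sample read libraries with planted signatures
#'
#' FLAG (signal) samples mix agotron-derived reads (start at the intron 5'
#' end within one nucleotide, near-full intron length), miRNA-like reads
#' (21-23 nt, 5'-anchored, on pre-miRNA loci), mirtron-like reads (21-23
#' nt, 5'-anchored, on mirtron-flagged introns) and diffuse background
#' reads (uniform starts, 18-35 nt, all regions). WT samples carry the
#' planted species at 1/fold of the FLAG per-read fraction, the remainder
#' background. Reads receive substitutions at the configured per-base
#' error rate and the 3' adapter is appended.
#'
#' @param config a [sim_config()].
#' @param reference output of [simulate_reference()].
#' @return list(reads = named list of per-sample read vectors,
#'   sample_meta = data.table(sample_id, dataset_id, condition),
#'   truth = region truth table).
#' @export
simulate_read_libraries <- function(config, reference) {
  set.seed(config$seed + 1L)
  regions <- reference$regions
  seqs <- reference$region_seqs
  rl <- nchar(seqs)
  ids_by_class <- list(
    agotron = reference$truth[truth_class == "agotron", region_id],
    mirna = reference$truth[truth_class == "pre_miRNA", region_id],
    mirtron = reference$truth[truth_class == "mirtron", region_id],
    background = reference$truth$region_id
  )
  # per-region abundance within a class (biological spread)
  abundance <- lapply(ids_by_class[c("agotron", "mirna", "mirtron")],
                      function(ids) setNames(rlnorm(length(ids), 0, 0.4), ids))

  flag_mix <- config$read_mix
  planted <- c("agotron", "mirna", "mirtron")
  wt_mix <- flag_mix
  wt_mix[planted] <- flag_mix[planted] / config$flag_vs_wt_fold
  wt_mix["background"] <- 1 - sum(wt_mix[planted])

  draw_sample <- function(sample_id, depth, mix) {
    cat_n <- as.vector(stats::rmultinom(1, depth, mix))
    names(cat_n) <- names(mix)
    reads <- character(0)
    for (cl in names(cat_n)) {
      n <- cat_n[[cl]]
      if (n == 0L) next
      if (cl == "background") {
        rid <- sample(ids_by_class$background, n, replace = TRUE)
        len <- sample(config$background_read_len, n, replace = TRUE)
        len <- pmin(len, rl[rid])
        st <- floor(runif(n) * (rl[rid] - len + 1L))
        rd <- substring(seqs[rid], st + 1L, st + len)
      } else if (cl == "agotron") {
        w <- abundance$agotron
        rid <- sample(names(w), n, replace = TRUE, prob = w)
        st <- sample(c(-1L, 0L, 1L), n, replace = TRUE, prob = config$p_offset)
        len <- rl[rid] + sample(config$agotron_len_jitter, n, replace = TRUE)
        end <- pmin(st + len - 1L, rl[rid] - 1L)
        rd <- substring(seqs[rid], pmax(st, 0L) + 1L, end + 1L)
        up <- st < 0L
        if (any(up)) {
          rd[up] <- paste0(sample(c("A", "C", "G", "T"), sum(up),
                                  replace = TRUE), rd[up])
        }
      } else {  # mirna / mirtron: short, 5'-anchored
        w <- abundance[[cl]]
        rid <- sample(names(w), n, replace = TRUE, prob = w)
        st <- sample(c(0L, 1L), n, replace = TRUE, prob = c(0.9, 0.1))
        len <- sample(config$mirna_read_len, n, replace = TRUE)
        rd <- substring(seqs[rid], st + 1L, st + len)
      }
      reads <- c(reads, rd)
    }
    if (length(reads) == 0L) return(setNames(character(0), character(0)))
    reads <- .mutate_reads(reads, config$error_rate)
    reads <- paste0(reads, config$adapter)
    names(reads) <- paste0(sample_id, "_r", seq_along(reads))
    reads[sample.int(length(reads))]  # shuffle category blocks
  }

  meta <- list(); libs <- list()
  for (ds in config$datasets) {
    for (i in seq_len(ds$n_flag)) {
      sid <- sprintf("%s_flag%d", ds$dataset_id, i)
      libs[[sid]] <- draw_sample(sid, ds$depth, flag_mix)
      meta[[length(meta) + 1L]] <- data.table(
        sample_id = sid, dataset_id = ds$dataset_id, condition = "FLAG")
    }
    for (i in seq_len(ds$n_wt)) {
      sid <- sprintf("%s_wt%d", ds$dataset_id, i)
      libs[[sid]] <- draw_sample(sid, ds$depth, wt_mix)
      meta[[length(meta) + 1L]] <- data.table(
        sample_id = sid, dataset_id = ds$dataset_id, condition = "WT")
    }
  }
  list(reads = libs, sample_meta = rbindlist(meta), truth = reference$truth)
}

.insert_at <- function(s, kmer, pos) {
  # overwrite s at 1-based pos with kmer
  paste0(substr(s, 1, pos - 1L), kmer,
         substr(s, pos + nchar(kmer), nchar(s)))
}

#' Generate the seed-target world for one agotron guide
#'
#' Builds random 3'-UTRs, plants canonical seed-match sites (8mer, 7mer-m8,
#' 7mer-1A) into designated transcripts, labels every transcript by a
#' generator-side naive substring scan (so chance sites in background UTRs
#' are owned by the truth table), and emits expression with multiplicative
#' repression 2^(-delta) of site-bearing transcripts in the treatment
#' condition, IP enrichment of conserved-site transcripts, and a
#' site-coordinate conservation track (chrom = transcript id).
#'
#' @param config a [sim_config()].
#' @param guide guide sequence (the agotron 5' arm), 5'->3'.
#' @return list(utrs, expr, track, truth, sites).
#' @export
simulate_target_world <- function(config, guide) {
  set.seed(config$seed + 2L)
  u <- config$utr
  sites <- derive_sites(guide)
  canon <- sites[class_label %in% c("8mer", "7mer-m8", "7mer-1A")]
  kmers <- setNames(canon$kmer, canon$class_label)
  g8 <- substr(normalize_seq(guide), 8, 8)
  block8 <- revcomp(g8)  # preceding this base, a 7mer-1A upgrades to 8mer

  n <- u$n_transcripts
  tx <- sprintf("tx_%04d", seq_len(n))
  utr_len <- sample(u$utr_len[1]:u$utr_len[2], n, replace = TRUE)
  utrs <- setNames(vapply(utr_len, .random_seq, "", gc = 0.45), tx)

  plant <- rep(NA_character_, n)
  k <- 0L
  for (cl in names(u$n_sites)) {
    plant[k + seq_len(u$n_sites[[cl]])] <- cl
    k <- k + u$n_sites[[cl]]
  }
  for (i in which(!is.na(plant))) {
    cl <- plant[i]
    km <- kmers[[cl]]
    pos <- sample.int(utr_len[i] - nchar(km) - 2L, 1) + 1L
    s <- .insert_at(utrs[i], km, pos)
    after <- pos + nchar(km)
    if (cl == "7mer-m8" && substr(s, after, after) == "A") {
      s <- .insert_at(s, "C", after)     # keep it from reading as an 8mer
    }
    if (cl == "7mer-1A" && substr(s, pos - 1L, pos - 1L) == block8) {
      s <- .insert_at(s, "T", pos - 1L)  # keep it from reading as an 8mer
    }
    utrs[i] <- s
  }

  # generator-side labeling: naive fixed-string scan, priority 8mer first
  actual <- rep("none", n)
  for (cl in c("7mer-1A", "7mer-m8", "8mer")) {
    actual[grepl(kmers[[cl]], utrs, fixed = TRUE)] <- cl
  }
  has_site <- actual != "none"
  conserved <- rep(FALSE, n)
  site_idx <- which(has_site)
  conserved[sample(site_idx, round(length(site_idx) * u$conserved_fraction))] <- TRUE

  # conservation track over every canonical site occurrence
  rows <- list()
  for (i in site_idx) {
    for (cl in names(kmers)) {
      mpos <- gregexpr(kmers[[cl]], utrs[i], fixed = TRUE)[[1]]
      if (mpos[1] == -1L) next
      for (p in mpos) {
        span <- (p - 1L):(p + nchar(kmers[[cl]]) - 2L)  # 0-based
        sc <- if (conserved[i]) runif(length(span), 0.8, 1.0) else
          runif(length(span), 0.0, 0.2)
        rows[[length(rows) + 1L]] <- data.table(
          chrom = tx[i], pos = span, score = round(sc, 3))
      }
    }
  }
  track <- unique(rbindlist(rows), by = c("chrom", "pos"))
  setkey(track, chrom, pos)

  delta <- ifelse(has_site, u$delta + conserved * u$delta_conserved_extra, 0)
  base <- rlnorm(n, u$fpkm_meanlog, u$fpkm_sdlog)
  noise <- function() rlnorm(n, 0, u$noise_sdlog)
  expr <- data.table(
    transcript_id = tx,
    fpkm_control = base * noise(),
    fpkm_treatment = base * 2^(-delta) * noise(),
    fpkm_input_control = base * noise(),
    fpkm_ip_control = base * noise(),
    fpkm_input_treatment = base * 2^(-delta) * noise(),
    fpkm_ip_treatment = base * 2^(-delta) *
      2^(u$ip_gain_conserved * conserved) * noise()
  )
  truth <- data.table(transcript_id = tx, best_class = actual,
                      conserved = conserved, planted_class = plant)
  list(utrs = utrs, expr = expr, track = track, truth = truth, sites = sites)
}

#' Write a full simulated input set to a directory
#'
#' Emits genome FASTA, regions BED, per-sample FASTQ files, sample metadata
#' TSV, conservation bedGraph, UTR FASTA, expression TSV, UTR-site
#' conservation bedGraph and truth tables, i.e. every file the pipeline
#' consumes.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the list of generated objects.
#' @export
write_simulation <- function(config = sim_config(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- simulate_reference(config)
  libs <- simulate_read_libraries(config, ref)
  guide <- substr(ref$region_seqs[[ref$truth[truth_class == "agotron",
                                             region_id][1]]], 1, 22)
  tw <- simulate_target_world(config, guide)

  write_fasta(ref$genome, file.path(dir, "genome.fa"))
  write_regions_bed(ref$regions, file.path(dir, "regions.bed"))
  write_fasta(ref$region_seqs, file.path(dir, "region_seqs.fa"))
  write_bedgraph(ref$conservation, file.path(dir, "conservation.bedgraph"))
  for (sid in names(libs$reads)) {
    write_fastq(libs$reads[[sid]], file.path(dir, paste0(sid, ".fastq")))
  }
  write_table(libs$sample_meta, file.path(dir, "samples.tsv"))
  write_table(libs$truth, file.path(dir, "truth_regions.tsv"))
  write_fasta(tw$utrs, file.path(dir, "utrs.fa"))
  write_table(tw$expr, file.path(dir, "expression.tsv"))
  write_bedgraph(tw$track, file.path(dir, "utr_conservation.bedgraph"))
  write_table(tw$truth, file.path(dir, "truth_targets.tsv"))
  invisible(list(reference = ref, libraries = libs, targets = tw,
                 guide = guide))
}
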