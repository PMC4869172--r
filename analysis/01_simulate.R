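#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study-scale input set.
#
# One seeded world: 12 stem-loop agotron introns (80-100 nt, GC-rich), 500
# background introns (40-150 nt, 8 mirtron-flagged), 50 pre-miRNA and 30
# snoRNA loci, plus 2 HITS-CLIP datasets of 2 FLAG + 2 WT samples at
# 200,000 reads each, a seed-target UTR world and conservation tracks.
# Raw reads land under scratch/ (large); truth tables under results/.

suppressMessages(library(agotron))

cfg <- sim_config(seed = 42L)
sim_dir <- "scratch/sim_input"
dir.create("results", showWarnings = FALSE)

sim <- write_simulation(cfg, sim_dir)

invisible(file.copy(file.path(sim_dir, c("truth_regions.tsv",
                                         "truth_targets.tsv",
                                         "samples.tsv")),
                    "results", overwrite = TRUE))

truth <- sim$libraries$truth
cat("simulated", nrow(sim$reference$regions), "regions:",
    sum(truth$truth_class == "agotron"), "agotrons,",
    sum(truth$truth_class == "mirtron"), "mirtrons,",
    sum(truth$truth_class == "background_intron"), "background introns\n")
cat("read libraries:", length(sim$libraries$reads), "samples x",
    cfg$datasets[[1]]$depth, "reads\n")
cat("target guide (", sim$guide, ") drawn from agotron",
    sim$reference$truth[truth_class == "agotron", region_id][1], "\n")
cat("inputs written to", sim_dir, "\n")
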