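#!/usr/bin/env Rscript
# Stage 5: seed-match target analysis for the top called agotron: derive
# the 8mer / 7mer-m8 / 7mer-1A (plus sliding-A and unconstrained 8-nt)
# site classes from its 5' arm, scan the 3'-UTR set, stratify expression
# fold changes by best site class, and compute RIP ratio-of-ratios
# enrichment.

suppressMessages({library(agotron); library(data.table)})

sim_dir <- "scratch/sim_input"
region_seqs <- read_fasta(file.path(sim_dir, "region_seqs.fa"))
cons <- read_table_tsv("results/consensus.tsv")

guide_id <- cons[is_agotron == TRUE, region_id][1]
guide <- substr(region_seqs[[guide_id]], 1, 22)
cat("guide:", guide_id, "5' arm", guide, "\n")

sites <- derive_sites(guide)
utrs <- read_fasta(file.path(sim_dir, "utrs.fa"))
track <- read_conservation(file.path(sim_dir, "utr_conservation.bedgraph"))
hits <- scan_utr(utrs, sites, track)
write_table(hits, "results/target_hits.tsv")

classes <- best_canonical_class(hits, names(utrs))
cons_tx <- unique(hits[conserved == TRUE &
                       class_label %in% c("7mer-m8", "7mer-1A"),
                       transcript_id])
classes[transcript_id %in% cons_tx & !best_class %in% c("none", "8mer"),
        best_class := "conserved-7mer"]

expr <- read_table_tsv(file.path(sim_dir, "expression.tsv"))
shift <- stratified_shift(expr, classes)
write_table(shift$stats, "results/target_shift_stats.tsv")
write_table(shift$cumulative, "results/target_shift_cumulative.tsv")
cat("expression shift by site class (log2 fold change vs no-site background):\n")
print(shift$stats)

rip <- rip_enrichment(expr, classes)
write_table(rip$stats, "results/target_rip_stats.tsv")
cat("RIP ratio-of-ratios by site class:\n")
print(rip$stats)
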