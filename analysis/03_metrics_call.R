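#!/usr/bin/env Rscript
# Stage 3: per-dataset region metrics (read counts, mean RPM, median read
# length, 5'-end aligned fraction, FLAG/WT enrichment), the per-dataset
# agotron classification and the cross-dataset consensus call, scored
# against the planted truth.

suppressMessages({library(agotron); library(data.table)})

sim_dir <- "scratch/sim_input"
meta <- read_table_tsv("results/samples_mapped.tsv")
regions <- read_regions_bed(file.path(sim_dir, "regions.bed"))
assignments <- rbindlist(lapply(meta$sample_id, function(sid) {
  a <- read_table_tsv(file.path("scratch/assignments", paste0(sid, ".tsv")))
  a[, sample_id := sid]
}))

metrics <- dataset_summary(assignments, meta)
metrics <- merge(metrics, regions[, .(region_id, region_class, is_mirtron)],
                 by = "region_id")
write_table(metrics, "results/metrics.tsv")

cm <- build_call_matrix(metrics, regions)
cons <- consensus_call(cm)
write_table(cm, "results/calls.tsv")
write_table(cons, "results/consensus.tsv")

truth <- read_table_tsv("results/truth_regions.tsv")
planted <- truth[truth_class == "agotron", region_id]
called <- cons[is_agotron == TRUE, region_id]
cat(sprintf("expressed introns: %d; agotrons called: %d (precision %.2f, recall %.2f)\n",
            length(unique(metrics[expressed & region_class == "intron", region_id])),
            length(called), mean(called %in% planted),
            mean(planted %in% called)))

for (ds in unique(cm$dataset_id)) {
  fc <- feature_coupling_test(cm[dataset_id == ds])
  cat(sprintf("%s: long-read x 5'-aligned coupling chi2 = %.1f, p = %.3g\n",
              ds, fc$statistic, fc$p_value))
}

# enrichment summaries by class, the boxplot layer of the report
cls <- merge(metrics[region_class == "intron"],
             cons[, .(region_id, is_agotron)], by = "region_id", all.x = TRUE)
cls[, group := fifelse(is_agotron, "agotron",
                       fifelse(is_mirtron, "mirtron", "other_intron"))]
enr <- group_summary(cls$enrichment, cls$group)
write_table(enr, "results/enrichment_by_class.tsv")
print(enr)
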