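#!/usr/bin/env Rscript
# Stage 4: physical and evolutionary characterization of the called
# agotrons versus other expressed introns and the whole intron universe:
# length, GC fraction, folding energy per nucleotide (built-in pairing
# proxy) and mean conservation.

suppressMessages({library(agotron); library(data.table)})

sim_dir <- "scratch/sim_input"
regions <- read_regions_bed(file.path(sim_dir, "regions.bed"))
region_seqs <- read_fasta(file.path(sim_dir, "region_seqs.fa"))
track <- read_conservation(file.path(sim_dir, "conservation.bedgraph"))
cons <- read_table_tsv("results/consensus.tsv")

features <- intron_features(regions, region_seqs, track)
write_table(features, "results/features.tsv")

ago <- cons[is_agotron == TRUE, region_id]
other <- setdiff(cons[n_expressed_datasets >= 2, region_id], ago)
all_introns <- regions[region_class == "intron", region_id]

cmp <- class_comparison(features,
                        list(agotron = ago, other_expressed = other,
                             all_introns = all_introns),
                        reference = "agotron")
write_table(cmp, "results/feature_comparison.tsv")
print(cmp)

med <- function(m, g) cmp[metric == m & group == g, median]
cat(sprintf("agotrons vs other expressed introns: GC %.2f vs %.2f, dG/nt %.2f vs %.2f, conservation %.2f vs %.2f\n",
            med("gc", "agotron"), med("gc", "other_expressed"),
            med("delta_g_per_nt", "agotron"),
            med("delta_g_per_nt", "other_expressed"),
            med("mean_conservation", "agotron"),
            med("mean_conservation", "other_expressed")))
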