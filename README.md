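# agotron

Discovery and characterization of **agotrons** — short (~80–100 nt),
structured, GC-rich introns that associate with Argonaute (Ago2) as
full-length, Dicer-independent RNA species — from HITS-CLIP short-read
libraries. The package is written for regulatory-genomics analysts working
with Ago CLIP data who want a self-contained, testable implementation of
the agotron calling signature and its downstream target analysis.

## What it computes

In Ago2 HITS-CLIP data an agotron shows a distinctive footprint: long
reads (median ≥ 30 nt, approaching the full intron) that pile up at the
intron 5′ end (≥ 70% of reads starting within one nucleotide of the
splice donor). The pipeline:

1. **Preprocesses** reads: 3′ adapter trimming, an 18-nt length floor,
   and assignment to a universe of short regions (introns 40–150 nt,
   pre-miRNA and snoRNA loci) allowing one substitution, with strand-aware
   matching and tolerance for a 1-nt 5′ / 2-nt 3′ overhang.
2. **Measures** each region per dataset: total reads, mean RPM
   (`count / total mapped × 10⁶` averaged over samples), median read
   length, 5′-end aligned fraction, and FLAG-over-WT enrichment
   `log2((RPM_FLAG + 1)/(RPM_WT + 1))`.
3. **Calls** agotrons: per dataset, an expressed intron (≥ 20 reads) with
   median read length ≥ 30 nt and 5′ fraction ≥ 0.70; the consensus call
   requires expression in ≥ 2 datasets and adherence in at least half of
   them and no fewer than two.
4. **Characterizes** the called class: GC fraction, folding energy per
   nucleotide (built-in weighted base-pair maximization, or an external
   MFE tool), and mean phastCons-style conservation, each compared to
   other expressed introns by Wilcoxon rank-sum.
5. **Scans targets**: from the agotron 5′ arm it derives 8mer
   (rev-comp of guide 2–8 + A), 7mer-m8 (rev-comp 2–8) and 7mer-1A
   (rev-comp 2–7 + A) sites plus sliding-A and unconstrained 8-nt
   windows, scans 3′-UTRs, stratifies expression log2 fold changes by
   best site class against the no-site background, and computes RIP
   `log2((IP/Input)_trt / (IP/Input)_ctl)` enrichment.

A seeded synthetic-data module (`sim_config()`, `write_simulation()`)
generates every input with planted ground truth, so all of the above is
exercised end to end without downloads.

## Worked example

The numbered scripts under `analysis/` run the whole study on the
simulated world (raw reads under `scratch/`, tables under `results/`):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_metrics_call.R
Rscript analysis/04_characterize.R
Rscript analysis/05_targets.R
```

Stage 3 prints the recovery of the planted class and the coupling of the
two defining read features:

```
expressed introns: 512; agotrons called: 12 (precision 1.00, recall 1.00)
ds1: long-read x 5'-aligned coupling chi2 = 302.3, p = 1.05e-67
          group     n       p05        q1    median        q3       p95
1:      agotron    24  2.115902  2.268013  2.420593  2.480923  2.662264
2:      mirtron    16  1.099691  1.236392  1.593963  1.779344  1.842645
3: other_intron   984 -2.039967 -1.916814 -1.834454 -1.742260 -1.623281
```

All 12 planted agotrons (and nothing else) pass the consensus rule; their
median FLAG enrichment is ~2.4 log2 units, versus negative enrichment for
diffuse-background introns, while mirtron-like introns sit in between —
5′-anchored but short-read, hence never called. Stage 4 recovers the
physical signature (agotrons vs other expressed introns: GC 0.63 vs 0.45;
ΔG/nt −1.25 vs −0.85; conservation 0.85 vs 0.15, rank-sum p < 1e-7), and
stage 5 the planted target repression: site-bearing transcripts shift by
−0.30 to −0.45 log2 units against background (rank-sum p ≤ 5e-10, the
conserved-7mer stratum strongest), and conserved-site transcripts show
~0.9 log2 units of RIP enrichment.

Programmatic use mirrors the scripts:

```r
library(agotron)
cfg  <- sim_config(seed = 42L)
dir  <- tempfile(); write_simulation(cfg, dir)
out  <- run_pipeline(dir, file.path(dir, "out"))
out$call$n_agotrons   # 12
```

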