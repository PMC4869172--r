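---
title: "Calling and characterizing agotrons from HITS-CLIP data: methods"
author: "Package Author"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and characterizing agotrons from HITS-CLIP data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agotron)
```

## The problem

Argonaute (Ago2) cross-linking immunoprecipitation libraries (HITS-CLIP)
footprint the RNA species bound by Ago2. Besides the expected ~22-nt
microRNAs, a distinct class of short excised introns — *agotrons* —
associates with Ago2 as essentially full-length, Dicer-independent RNAs.
Their read signature in CLIP data is characteristic: reads are long
(covering most of the intron) and pile up at the intron 5′ terminus,
within one nucleotide of the splice donor (the debranched lariat's free 5′
end sits in the Ago 5′ pocket, and a single-nucleotide offset is
consistent with decapitation-style nibbling). Mirtrons — short introns
processed into pre-miRNAs — share the 5′ anchoring but yield ~22-nt reads,
which is what separates the two classes computationally.

This package implements the full desk-side pipeline: read preprocessing
and assignment to a short-region universe, the per-region metrics that
define the agotron signature, threshold and consensus calling,
physical/evolutionary characterization, and a microRNA-style seed-match
target analysis driven by an agotron's 5′ arm. A seeded synthetic-data
module generates every input with planted ground truth, so the whole
pipeline is testable without any external download.

## Coordinates

All intervals are 0-based half-open (BED-native): `length = end − start`,
and the 5′ end is `start` on `+` and `end − 1` on `−`. Published agotron
spans reconcile with their published lengths only under this convention
(e.g. chr17:24594977–24595071 is the 94-nt *Pkd1* agotron), which is why it
is fixed globally; GFF-style 1-based input would need conversion at the
boundary. Sequences are normalized to the DNA alphabet at ingest (U → T)
and re-rendered with U only for RNA-facing output.

## Read preprocessing and assignment

Reads are adapter-trimmed by removing the leftmost read suffix that
exactly matches a prefix of the adapter (minimum overlap 3 nt), then reads
shorter than 18 nt are discarded. Surviving reads are assigned to the
region universe — annotated introns of 40–150 nt, pre-miRNA loci and
snoRNA loci, each represented by its strand-resolved 5′→3′ sequence — by
Hamming matching with at most one substitution and no indels. Matching is
to the sense strand only, as CLIP libraries are stranded.

Two boundary tolerances reflect the biology: a read may start one
nucleotide upstream of the region 5′ end (recorded as offset 0 with an
overhang flag, honouring the single-nucleotide 5′ offset of decapitated
species) and may run up to two nucleotides past the 3′ end; overhanging
bases are not compared.

The matcher is seed-and-extend and exact for the one-mismatch budget. All
7-mers of every region are hashed. For a read of length $L \ge 21$ the
query windows are the two start-anchored windows (offsets 0 and 1), the
midpoint window, and the three end-anchored windows (offsets $L-7$,
$L-8$, $L-9$); for $L \le 20$ all windows are queried. For any valid
placement — one mismatch at position $m$, upstream overhang $u \le 1$,
downstream overhang $d \le 2$ — a start window avoids $m$ whenever
$m > u + 6$, and the end window for that $d$ avoids $m$ whenever
$m < L - 9$; both can fail only when $L \le 16 < 18$, so at least one
queried window is mismatch-free and in-region, and the candidate is found
and verified by full comparison. The unit tests enforce this equivalence
against an all-positions Hamming scan.

A read matching several regions goes to the fewest-mismatch region;
remaining ties are counted fractionally ($1/k$ to each of $k$ regions) for
counts and RPM but excluded from the shape statistics (median length, 5′
fraction), which avoids arbitrary winner-picking while keeping the shape
metrics unambiguous. Within one region the best placement is the fewest
mismatches, then the least overhang, then the leftmost start — a
deterministic tie-break.

## Per-region metrics and thresholds

For each region and sample: the (possibly fractional) read count and RPM
(`count / total mapped reads × 10^6`). For each region and *dataset*: the
total read count, the unweighted mean of per-sample RPM across the
dataset's signal samples (samples with no reads on the region contribute
zero), and the shape metrics pooled over the dataset's whole (weight-1)
reads — the median read length and the fraction of reads starting within
one nucleotide of the region 5′ end.

Datasets may contain control libraries (WT littermates for FLAG-Ago2
pulldowns, input for IPs). The per-dataset expression and shape metrics
are computed over the signal samples only (FLAG/IP/plain), with the
controls entering solely through the enrichment statistic
$\log_2\!\big((\mathrm{RPM}_{signal} + c)/(\mathrm{RPM}_{control} + c)\big)$
with pseudocount $c = 1$ RPM. The source experiments define the agotron
signature on the Ago2-bound material, and a WT anti-FLAG library is a
specificity control rather than a measurement of the same quantity; the
pseudocount guards the zero-count control regions that genuinely occur.

Thresholds, all inclusive and all surfaced as parameters with these
defaults: expressed means ≥ 20 total reads; long reads means median
≥ 30 nt; 5′-anchored means fraction ≥ 0.70; the intron universe is
40–150 nt.

## Calling

Per dataset, an expressed intron is classified `agotron` (long and
5′-anchored), `expressed_short` (the mirtron-like signature),
`expressed_low5p`, or `not_expressed`. The consensus call across datasets
requires expression in at least two datasets and adherence to the agotron
definition in at least half of the expressed datasets and no fewer than
two. A dataset in which the intron is not expressed neither supports nor
opposes the call — the rule first restricts to expressed datasets, then
applies the adherence fraction. Mirtron-annotated introns are *not*
excluded from calling; the flag is carried through, since the classes
overlap in the source data.

Group comparisons use the two-sided Wilcoxon rank-sum test (exact
enumeration for tie-free groups of ≤ 25, otherwise the midrank normal
approximation with continuity correction; fully degenerate input returns
p = 1). The coupling of the two defining features over expressed introns
(long × 5′-aligned) is tested with Pearson's χ² without continuity
correction. Raw p-values are reported throughout — the comparisons are
few and confirmatory, so no multiple-testing machinery is attached.

## Physical characterization

Per intron: length, GC fraction (over unambiguous bases), a folding
energy, the energy per nucleotide, and mean conservation. The built-in
folding backend is a weighted base-pair maximization (Nussinov-style
dynamic program over nested structures; pair weights GC −3, AU −2, GU −1
in arbitrary units; minimum hairpin loop 3 nt). It is a structure
*propensity* proxy, not a thermodynamic model: absolute values are not
comparable to nearest-neighbour free energies, but the direction of
class differences is robust to the substitution, which is all the class
comparison consumes. An external MFE tool (e.g. `RNAfold`) can be plugged
in via `backend = "external:<cmd>"`; the tool's last parenthesized number
is taken as the energy. Mean conservation averages a phastCons-style
track over the covered positions of the interval, excluding uncovered
positions; a genome without a track degrades gracefully to NA.

## Seed-match target analysis

The guide is the agotron's 5′ arm (22 nt by default). Site classes follow
the microRNA convention with 1-based guide positions: the 8mer is the
reverse complement of positions 2–8 followed by an A (opposite position
1), the 7mer-m8 is the reverse complement of positions 2–8, and the
7mer-1A is the reverse complement of positions 2–7 followed by an A —
hence every 8mer occurrence contains a co-located 7mer-m8 (same start) and
7mer-1A (one base right), an invariant the tests enforce. Sliding-A
windows ($i$..$i{+}6$ with a flanking A, $i \in \{2,3,4\}$) and
unconstrained 8-nt windows ($i$..$i{+}7$, $i \in 1..9$ by default, the
start range being a parameter) mirror the extended-seed analyses.

UTRs are scanned for exact, possibly overlapping occurrences. Each
transcript is assigned its best canonical class (8mer > 7mer-m8 >
7mer-1A); a site whose mean conservation over its positions exceeds 0.5
is flagged conserved, and transcripts whose best evidence is a conserved
7mer form the `conserved-7mer` stratum. The background is the set of
transcripts with no canonical site (not "no site of any scanned class",
documented choice). Expression shifts are
$\log_2((\mathrm{FPKM}_{trt} + c)/(\mathrm{FPKM}_{ctl} + c))$ with
$c = 0.1$ FPKM (small against typical FPKM, avoids log 0), compared per
class against the background by rank-sum, with cumulative-distribution
tables emitted for plotting. RIP enrichment is the log2 ratio-of-ratios
$\big((\mathrm{IP}/\mathrm{Input})_{trt}\big) /
\big((\mathrm{IP}/\mathrm{Input})_{ctl}\big)$; transcripts missing any of
the four components are skipped with a log message.

## The synthetic-data generator

The generator is first-class, seeded code that emulates the empirical
signatures the pipeline detects. Its defaults are the study conditions
used throughout the tests:

* **Reference**: 12 agotron introns built as perfect stem-loops (arm GC
  0.60, loop ≥ 4 nt) of 80–100 nt; 500 background introns uniform on
  40–150 nt at GC 0.45, 8 of them mirtron-flagged; 50 pre-miRNA loci
  (60–75 nt) and 30 snoRNA loci. One chromosome per region class with
  20-nt spacers keeps coordinates auditable; about half the regions sit
  on the minus strand.
* **Libraries**: 2 datasets × (2 FLAG + 2 WT) samples × 200,000 reads.
  FLAG reads mix 30% agotron-derived (start −1/0/+1 with probabilities
  0.05/0.90/0.05; length = intron length − 0..3), 40% miRNA-like and 5%
  mirtron-like (21–23 nt, 5′-anchored), 25% diffuse background (uniform
  starts, 18–35 nt, all regions). WT carries each planted class at 1/8 of
  its FLAG fraction (the 8× enrichment), background absorbing the rest.
  Per-region abundances spread lognormal(0, 0.4); substitutions are
  planted at 0.5% per base to exercise the one-mismatch path; the 3′
  adapter is appended to every read.
* **Targets**: 2,200 UTRs of 400–1,200 nt; 60/70/70 transcripts receive a
  planted 8mer/7mer-m8/7mer-1A (flanks adjusted so a planted 7mer cannot
  read as an 8mer). Truth labels come from a generator-side naive scan,
  so chance sites in random UTRs are owned by the truth table and receive
  the same planted effects. Repression is multiplicative,
  $2^{-\delta}$ with $\delta = 0.3$ log2 units (+0.2 for the conserved
  half of site transcripts); conserved-site transcripts gain 1.0 log2
  units of IP enrichment; baseline FPKM is lognormal(3, 1) with
  lognormal(0, 0.15) measurement noise.
* **Conservation**: high scores (0.7–1.0) over agotron spans and
  conserved sites, low (0–0.3 genomic, 0–0.2 UTR) elsewhere.

What the generator does *not* emulate: PCR duplication, crosslink-induced
deletions/truncations, ligation bias, expression-dependent background
structure, or realistic UTR composition. Passing the recovery tests
therefore demonstrates the correctness and calibration of the pipeline's
logic under its own model assumptions — not performance on real CLIP
libraries, where duplicate collapsing and crosslink diagnostics (both
noted non-goals) would matter.

## Numerical choices and degenerate inputs

Empty read profiles raise an explicit undefined-signal error rather than
returning NaN; regions with no whole reads carry NA shape metrics and can
only be `not_expressed` or classified by count alone. The rank-sum
wrapper returns p = 1 on fully degenerate input. Conservation means over
uncovered intervals are NA, a reportable state. All randomness in the
generator flows from one integer seed (component streams at seed, seed+1,
seed+2), making every output byte-reproducible; the pipeline itself is
deterministic, so reruns produce identical files.

Problem sizes in the shipped tests: the study-scale fixture (1.6M reads,
592 regions) for recovery and directional checks; 1,000-instance oracle
sweeps for the matcher, shape metrics and UTR scanner; 200 short
sequences against exhaustive structure enumeration; 2,000 null
simulations for test calibration and 100-simulation power curves for the
planted repression — sizes chosen so the whole suite completes in a few
minutes on one CPU while keeping Monte-Carlo error well inside the
asserted margins.

## Known limitations

The folding proxy ranks but does not measure stability; conservation
handling assumes per-position scores in [0, 1]; bigWig tracks must be
converted to bedGraph/wiggle text first (noted extension point); no
gapped alignment, quality-aware trimming or duplicate collapsing; FPKM
tables are consumed, never produced. The consensus rule treats datasets
symmetrically — there is no weighting by library depth or quality.
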