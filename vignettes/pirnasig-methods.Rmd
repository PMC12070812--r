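---
title: "pirnasig: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pirnasig: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`pirnasig` analyses small-RNA sequencing libraries mapped to consensus
transposable elements (TEs): it trims and collapses reads, aligns the
resulting read species to both strands of a consensus TE panel with
multi-mapper apportioning, computes the ping-pong (Z10) and phasing (Z0)
piRNA signature statistics, 1U/10A nucleotide biases and
piRNAs-per-kilobase quantification, performs differential expression with
median-of-ratios normalization, and derives the downstream analytics used
to characterise TE silencing genetics: genetic-interaction (GI) scores for
double mutants, length-by-expression quadrant analysis of de-silenced
TEs, concomitant sense/antisense reduction grouping, and PIWI-clade IP
group assignment. A synthetic ovary-library generator with full ground
truth makes every stage testable without any external download.

# The signature statistics

## Alignment and apportioning

Read species (unique post-trim sequences with occurrence counts) are
matched exactly, full-length, against the forward strand of every panel
sequence and, through their reverse complements, against the minus strand.
Only perfect matches count, mirroring the perfect-mapping filter used for
TE quantification in piRNA studies; a SAM import path is available for
users who prefer an external aligner. A species occurring at
$n_{\text{loc}}$ locations across the panel (both strands combined)
contributes weight $c / n_{\text{loc}}$ at each location, where $c$ is its
read count, so total weight is conserved exactly. Because no separate
genome is shipped, "locations" means all perfect-match locations across
the supplied panel; users mapping against a genome should import those
alignments instead.

Coordinates are 0-based half-open internally; SAM export/import is
1-based and BED import 0-based half-open, per those standards.

## Distance histograms and Z scores

All pairwise statistics operate on per-reference, per-strand 5'/3' end
profiles (position-indexed weight sums). In transcript orientation the
plus strand uses 5' = start, 3' = end − 1; minus-strand reference
coordinates are reflected via $p \mapsto L - 1 - p$.

* **Ping-pong**: for each reference carrying both strands, the 5'–5'
  sense–antisense distance in reference coordinates is
  $d = (\text{antisense } 5') - (\text{sense } 5') + 1$, so the canonical
  ping-pong pair produced by PIWI-protein slicing scores exactly 10.
  $Z_{10}$ standardises bin 10 against the background bins 1–9 and 11–20.
* **Phasing**: within a strand, the 3'→5' distance
  $d = 5'_{\text{down}} - 3'_{\text{up}} - 1$ scores 0 for head-to-tail
  junctions; $Z_0$ standardises bin 0 against the background −10…−1 and
  1…50. The 5'–5' distance histogram exposes the ~27-nt periodicity of
  successive phased cuts.

Histogram bins accumulate the product of the two positions' apportioned
weights over *all* position pairs; bins are dense over the requested
window (absent distances count 0). Pair weighting by the product of
apportioned weights follows from treating every alignment pair of every
species pair as an observation. Per-reference histograms are summed
across references (and strands, for phasing) before scoring — the
library-level score — and per-reference scores are also returned.

Numerical choices: the background standard deviation uses the sample
(n−1) denominator; a zero background SD yields an explicitly undefined
score rather than an infinity; Z scores are invariant under uniform
scaling of all counts and under translation of all alignments, and both
invariances are enforced by tests. When the same end of the same profile
is paired with itself, pairs of a position with itself are excluded.

## Periodicity peaks

Peak $k$ of the 5'–5' histogram is the argmax within
$k \cdot 27 \pm 2$ nt (period and tolerance configurable). The baseline
is the mean histogram value over the valley strictly between peak 1 and
peak 2, excluding the tolerance band around each peak; peak height is
peak 1 minus baseline. The valley is not otherwise defined in the
literature we follow, so the inter-peak interval minus the tolerance
bands is our operational definition; ties at the argmax resolve to the
smaller distance.

## Nucleotide biases

The 1U (uridine at position 1, primary/antisense signature) and 10A
(adenine at position 10, ping-pong responder signature) percentages count
each *species* once: a species is eligible when its read count is at
least 5 (configurable), scores 1 when it carries the queried base at the
queried position, 0 otherwise — species shorter than the position are
eligible non-hits. Strand scopes (sense / antisense / both) follow the
strand(s) a species aligns to, and the same selector can be restricted to
a PIWI-clade IP group.

# Quantification and differential expression

TE counts are sums of apportioned weights; `pkb` is count / length ×
1000 and `rpkm` additionally divides by total aligned reads in millions.
piRNA-level analyses apply the ≥5-count species filter before summation;
RNA-level tables do not.

Normalization uses the median-of-ratios recipe (geometric means over
zero-free features; total-count fallback with a warning when none exist).
Differential expression is a two-sided Welch t-test on
$\log_2(\text{normalized} + 0.5)$, with a label-permutation alternative,
Benjamini–Hochberg adjustment across all tested features, and calls at
p-adj ≤ 0.05 with $|\log_2 \text{FC}| \ge 0.58$; fold changes use
pseudocount 0.5 on normalized means. A plain fold-change mode (2-fold
cutoff, no test) serves the piRNA strand analyses, which compare single
libraries per genotype. An installed DESeq2 is used in the test suite as
an independent cross-check of the internal engine on planted effects; it
is never on the implementation path.

# Downstream analytics

* **GI score** = FC(double vs control) / (FC(single 1) + FC(single 2)),
  on linear fold changes; GI > 2 is a strong positive interaction. The
  denominator is read literally as a sum of linear fold changes (so two
  unchanged single mutants contribute 2); an alternative
  excess-over-baseline reading (summing FC − 1) exists but is not the
  default.
* **Quadrants**: long iff $\log_{10}(\text{length}) \ge 3.7$
  (~5,000 nt), high iff $\log_{10}(\text{rpkm}) \ge 1$ (10 rpkm), with
  boundary TEs assigned upward (tie handling is not specified by the
  definitions we follow); expression is control-genotype rpkm. Density =
  de-silenced / total within a quadrant; distribution = a quadrant's
  share of all de-silenced TEs.
* **Concomitant groups**: among TEs whose both-strand piRNAs drop ≥
  2-fold, group 1/2/3 = sense reduction stronger / comparable / weaker
  than antisense at the same 2-fold cutoff.
* **IP assignment**: species are normalized to counts-per-million per IP
  library (raw "read counts" are not comparable across libraries of
  different depth), a 0.5 pseudocount avoids division by zero, and a
  species belongs to the protein whose IP enriches it ≥ 3-fold over both
  others; the three groups are disjoint by construction.

# The synthetic-data generator

`simulate_library()` emulates a *Drosophila* ovary small-RNA library over
a synthetic consensus TE panel with three read pathways:

* **Ping-pong pairs**: a sense read with 5' at $s$ and an antisense
  partner with 5' at $s + 9$ (reference coordinates), giving the 10-nt
  5'–5' overlap exactly.
* **Phased trails**: same-strand head-to-tail runs
  ($5'_{i+1} = 3'_i + 1$), one trail per random start, trail length
  geometric with mean 6 reads, producing the 3'→5' distance-0 signal and
  ~one-read-length 5'–5' periodicity.
* **Noise**: uniformly placed reads; any probability mass not allocated
  to the two structured pathways is emitted as noise.

Read lengths are normal(26.5, 1.5), rounded and clipped to 23–28 nt by
default (the 19–35 nt reporting window is retained downstream); TEs are
picked proportionally to length; antisense reads are reverse complements
of their reference interval and FASTQ qualities are constant `I`.

Nucleotide biases are imposed by *rejection-sampling placement positions*
rather than mutating reads — the analysis pipeline excludes non-perfect
mappings, so reads must stay exact substrings. For a target marginal bias
$t$ and reference base frequency $p$, a candidate site whose base does
not match is accepted with probability $q = p(1-t)/(t(1-p))$, which makes
the accepted-site marginal exactly $t$. Trail junctions are special: only
the handful of sites reachable by the possible read lengths are
available, so the same $q$ under-biases them; the junction acceptance is
instead solved numerically from
$E[\,W_T / (W_T + q W_N)\,] = t$ over i.i.d. site configurations, where
$W$ are the length-distribution masses of matching/non-matching
candidate sites. Realized read-level biases recover the targets within
binomial error; species-level percentages match read-level ones when
position duplication is rare (large panel relative to library size),
which is how the recovery checks are run.

Genotype effects (`condition_effect`) multiply the pathway fractions
(freed mass goes to noise), thin reads per strand, and supply per-TE RNA
fold changes for `simulate_count_table()`, which draws log-normal per-TE
baselines once and negative-binomial replicate counts with variance
$\mu + \phi\mu^2$ (Poisson at $\phi = 0$).

What the generator does *not* emulate: genomic piRNA clusters with
realistic repeat content, sequencing errors, UMIs, or ligation biases.
Passing tests therefore demonstrate correctness of the statistics and
recovery of planted structure, not performance on the full complexity of
real ovary libraries.

# Problem sizes and defaults used in the checks

The recovery checks use panels of 10–20 TEs (0.8–4 kb) with libraries of
12k–50k reads for the signature statistics, 300-TE count tables with 3–5
replicates for DE calibration and recovery, and a full smoke run of 200
TEs with 100k reads per genotype across control / single / double
genotypes and a 3-replicate count table — sizes at which every planted
effect is comfortably detectable on a single CPU. The GI recovery check
fixes 3 replicates, 10 marked TEs and a planted GI of 3 and asks for
≥90% detection; at dispersion 0.1 the per-TE power to call GI > 2 is only
about 0.9, which makes that bound undecidable by design, so the GI
conditions use dispersion 0.05, a realistic value for fly ovary RNA-seq
replicates. It was chosen once from this power analysis, not swept.

# Pipeline and configuration

`run_pipeline()` drives the stages from a validated configuration
(`pipeline_config()`), writes one TSV/JSON artifact per stage plus a
manifest with md5 digests of every output, and `generate_report()`
collates them into `report.json` / `report.txt`, noting missing stage
outputs instead of failing. Configurations are R lists or JSON files
(JSON was chosen over TOML because a JSON parser is a standing dependency
while TOML would add one); unknown keys are rejected; deterministic
stages reproduce byte-identical outputs given the same seed. The IP stage
of a purely synthetic run has no real immunoprecipitate libraries, so it
emulates them from the control library's strand assignments (antisense →
Aub-enriched, sense → Ago3-enriched, both → Piwi-enriched), which is
sufficient to exercise the assignment and overlap machinery end to end.

# Known limitations

* Exact matching only: no mismatches, indels, or quality-aware trimming;
  divergent TE copies are invisible unless imported via SAM.
* Apportioning is panel-relative; reads that would also map elsewhere in
  a genome are not down-weighted for those locations.
* Whether the fixed 30-nt 3' trim is a literal fixed-length cut or
  shorthand for adapter removal is ambiguous in the protocols we follow;
  both modes are provided and neither is claimed to replicate any
  specific in-house script.
* The phasing score aggregates per-library; alternative readings of
  "average Z score" (across loci or across significant distances) are
  possible and not implemented as defaults.
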