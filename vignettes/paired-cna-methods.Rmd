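---
title: "Methods: paired copy-number and LOH profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired copy-number and LOH profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairedCNA)
```

This vignette documents the statistical model, the tunable parameters, the
numerical choices, and the design of the built-in simulator. It makes no
empirical claims beyond what the package's test suite and
`scripts/acceptance.R` compute.

## Input model and assumptions

The unit of analysis is a paired tumor/germline experiment on a SNP
genotyping array. Per SNP the package consumes: chromosome and position, the
PCR fragment length of the amplicon carrying the SNP, a tumor and a
reference (germline) probe intensity, and a genotype call
(`AA`/`AB`/`BB`/`NoCall`) for each sample. Assumptions:

* intensities are proportional to local DNA copy number, with a sample-wide
  multiplicative scale difference between the two hybridizations;
* the germline is diploid, so the germline intensity is the per-SNP
  copy-number-2 baseline;
* the genome is mostly unaltered, so the autosomal median log2 ratio
  estimates the diploid level;
* genotype calls carry a small error rate, so single discordant calls must
  not produce LOH regions on their own.

Chromosome labels 1–22, X, Y are accepted (mitochondrial and unplaced
contigs are rejected: the arrays in scope do not tile them). The simulator
and region statistics operate on autosomes; sex chromosomes are carried
through the per-SNP computations but excluded from normalization.

## Stage-by-stage model

### Fragment-size filtering

SNPs with `fragment_length > max_frag_size` (default **600 bp**) are
removed before any computation. Whole-genome amplification of degraded DNA
(archival/FFPE material) under-amplifies long fragments, so their
intensities are unreliable; discarding them trades marker density for
signal quality. `max_frag_size = 0` disables the filter (fresh-frozen
material).

### Log2 ratios and normalization

`r = log2(tumor/reference)` per SNP, then median-centered over autosomal
SNPs. The median (rather than the mean) is robust to the altered fraction
of the genome, and autosome-only centering avoids sex-mismatch artifacts.
Raw copy number is `2 * 2^r`; the subtracted offset is retained as an
attribute for audit.

### Gaussian smoothing

Each SNP's ratio is replaced by the Gaussian-weighted mean of its
same-chromosome neighbours. The default window is **500 kb** full width
with σ = window/4 (so ±2σ spans the window), truncated at 3σ. At a weight
of `exp(-4.5) ≈ 0.011` the truncation point, contributions beyond 3σ are
negligible relative to the retained mass; the test suite bounds the
truncation error against the untruncated O(n²) direct sum at 1e-6 when the
radius covers the chromosome. The two-pointer sliding-window implementation
is O(n·k) in the number of in-window neighbours k. Smoothing never crosses
a chromosome boundary, is a convex combination of observed values (verified
by property test), and commutes with constant shifts.

### LOH calling

Only germline-heterozygous SNPs are informative: at a germline `AA` the
loss of either allele still reads `AA`. The per-SNP call is

| tumor \\ reference | `AB` | other |
|---|---|---|
| `AA`/`BB` | `LOH` | `non_informative` |
| `AB` | `retention` | `non_informative` |
| `NoCall` | `non_informative` | `non_informative` |

`NoCall` is deliberately mapped to `non_informative` rather than treated as
evidence either way: a failed genotype carries no allelic information, and
counting it as LOH would inflate LOH regions in noisy samples.

### HMM segmentation

Both tracks are segmented by exact Viterbi decoding in log space. The
transition model is distance-dependent: over a gap of `d` bp the
probability of remaining in the current state is
`max(stay_min, p₁^min(d, d_max))` with per-bp stay probability
`p₁ = 1 - 1e-7` (`hmm_stay_prob`), decay cap `d_max = 1e7` bp
(`hmm_decay_length`), and floor `stay_min = 0.1`; the leave probability is
split equally over the other states. Nearby SNPs therefore strongly share
state while SNPs across large gaps (e.g. centromeres) are nearly
decoupled, and the floor prevents log-zero transitions. The initial
distribution is uniform.

* **Copy-number model**: five states for 0–4 copies with smoothed-log2
  means (−3, −1, 0, log2(3/2), 1) and a common Gaussian emission SD of
  0.25 (`hmm_emission_sd`). The −3 mean for copy 0 stands in for the
  unbounded log2(0/2); observed homozygous-deletion ratios are bounded by
  noise, normal-cell admixture, and smoothing.
* **LOH model**: retention/loss states with Bernoulli emissions on the
  informative calls: P(read LOH | retention) = 0.05
  (`loh_miscall_rate`, the genotyping error allowance) and
  P(read LOH | loss) = 0.95 (`loh_emission`). Non-informative SNPs are
  excluded from decoding and spanned by the enclosing segments.

Ties in the Viterbi argmax break to the lower state index, which for the
LOH model means retention — the conservative call — so e.g. perfectly
alternating LOH/retention calls decode to retention throughout. Decoding
correctness is verified against exhaustive enumeration over all `K^n`
paths on hundreds of random small instances.

### Region calling

Copy-number segments become reportable regions by thresholding the segment
mean smoothed log2 ratio: gain at ≥ +0.3, loss at ≤ −0.3, homozygous
deletion at ≤ −1.5, each requiring ≥ 5 supporting SNPs
(`min_snps_per_region`). Increasing the absolute threshold values makes
detection strictly more conservative (property-tested). LOH segments
within ≤ 2 Mbp (`loh_merge_threshold`, gap measured between segment ends,
inclusive) are merged — single miscalled or non-informative SNPs otherwise
fragment long LOH tracts — with intervening retention absorbed and segment
means combined by informative-SNP weighting; merging is idempotent and
monotone in the threshold. A merged LOH area with ≥ 50% reciprocal overlap
(the minimum of the two coverage fractions) with a loss or homozygous
deletion is reported as `LOH`; otherwise as `copy_neutral_LOH` (allelic
imbalance without copy loss). Each region carries a UCSC Genome Browser
URL of the form
`http://genome.ucsc.edu/cgi-bin/hgTracks?db=<build>&position=chr<C>%3A<start>-<end>`.

**Boundary placement.** Segments span their first to last member SNP, but
the true breakpoint lies somewhere in the unobserved gap between the last
SNP of one segment and the first of the next. Reported region boundaries
are therefore extended to the floor of the inter-marker gap midpoint — the
minimax estimate, which halves the worst-case boundary error implied by
marker spacing. Outer boundaries (chromosome ends) stay at the observed
SNPs.

## The simulator

`simulation_spec()`/`simulate_paired_sample()` generate paired profiles on
a schematic hg18 autosome layout (lengths and centromeres rounded to
0.1 Mb): SNP positions uniform per chromosome with density proportional to
length; reference intensity fixed at 1000 units; tumor log2 ratio equal to
the covering truth event's expected value (gain3 → log2(3/2), gain4 → 1,
loss → −1, homdel → −3, cnloh → 0) plus Gaussian noise (default SD 0.25);
germline heterozygosity 0.3; LOH-inducing events (loss, homdel, cnloh)
turn heterozygous germline SNPs homozygous in the tumor; genotype flip
errors at 0.01 and `NoCall` dropouts at 0.02 per sample; fragment lengths
uniform on 100–1200 bp, so the default 600 bp filter removes roughly half
the markers — deliberately stressing marker sparsity. Everything is
reproducible from a single integer seed.

**Realism and limits.** The generator reproduces the signal structure the
pipeline must handle — multiplicative intensity noise, genotyping error,
marker-density loss from fragment filtering, events of different
amplitudes and sizes — but it is schematic: no probe-specific affinities,
no GC/wave artifacts, no normal-cell admixture shrinking amplitudes, no
subclonal fractions, sharp breakpoints exactly between markers, and a
uniform rather than array-specific marker distribution. Recovery results
on it are a correctness check of the implementation, not a clinical
sensitivity claim.

Two archetype truth tables (`archetype_spec()`) encode the diagnostic
glioma contrast: "oligodendroglioma" (1p loss, 1q copy-neutral LOH, 19q
loss) and "glioblastoma" (chr7 gain with a focal copy-4 amplicon, chr9
focal homozygous deletion, chr10 loss). The 1p/19q loss pair occurs in
exactly one of the two, so their reports are distinguishable.

## Determinism and reporting

All analysis stages are deterministic; only the simulator consumes a seed.
PDF reports are written with uncompressed streams and without kerning so
that the region table and links are text-searchable, and with a pinned
`timestamp` the PDF date fields are rewritten (byte-length preserving) so
reruns are byte-identical — verified by checksum in the tests. The file
pipeline writes a JSON manifest per run recording the configuration echo,
per-stage counts and timings, warnings, and output paths; on failure the
manifest names the failing stage.

## Parameter summary

| Parameter | Default | Units | Role |
|---|---|---|---|
| `max_frag_size` | 600 (0 = off) | bp | degraded-DNA fragment filter |
| `smooth_window` | 500000 | bp | Gaussian window (σ = window/4) |
| `gain_threshold` | +0.3 | log2 | gain call |
| `loss_threshold` | −0.3 | log2 | loss call |
| `homdel_threshold` | −1.5 | log2 | homozygous-deletion call |
| `loh_merge_threshold` | 2000000 | bp | LOH area merging |
| `min_snps_per_region` | 5 | SNPs | region support filter |
| `hmm_emission_sd` | 0.25 | log2 | CN emission SD |
| `hmm_stay_prob` | 1 − 1e−7 | per bp | transition stickiness |
| `hmm_decay_length` | 1e7 | bp | transition decay cap |
| `loh_miscall_rate` | 0.05 | prob. | P(LOH read given retention) |
| `loh_emission` | 0.95 | prob. | P(LOH read given loss) |

Raising `|thresholds|` or `min_snps_per_region` is strictly more
conservative; raising `hmm_stay_prob` yields fewer, longer segments (both
property-tested).
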