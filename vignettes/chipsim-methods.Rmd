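---
title: "The chipsim generative model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The chipsim generative model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipsim)
```

## Overview

`chipsim` simulates chromatin-immunoprecipitation sequencing (ChIP-seq)
experiments by modelling the four laboratory steps that shape a real
dataset — shearing, immunoprecipitation (pulldown), PCR amplification, and
sequencing — as separate stochastic modules, and it can infer every model
parameter from an existing aligned experiment. The inputs are a reference
genome (FASTA), a set of binding sites with scores interpreted as binding
probabilities in [0, 1] (BED), and a model parameter file (JSON); the
output is raw reads in FASTQ format with ground-truth origin encoded in
the read names. For histone modifications, "binding" is shorthand for
genomic localization of the modification, not literal DNA binding.

## The generative model

**Step 1 — shearing.** Each simulation round ("genome copy") shears each
chromosome into consecutive fragments whose lengths are i.i.d.
Gamma(shape $k$, scale $\theta$) draws (mean $k\theta$ bp), reflecting the
long right tail of empirical fragment-length distributions. Lengths are
drawn continuously and rounded half-up to whole base pairs (minimum 1).
The first cut in each round sits at a uniform offset in
$[0, k\theta)$ so that cut sites are decorrelated across rounds; within a
round, fragments tile the chromosome with no gaps or overlaps, and the
final fragment is cropped at the chromosome end.

**Step 2 — pulldown.** A fragment that overlaps a peak by at least 1 bp is
*bound* with probability equal to the maximum score of the peaks it
overlaps; other fragments are never bound. Antibody enrichment is
parameterized by the ratio
$$\alpha = \frac{s\,(1-f)}{(1-s)\,f},$$
the relative probability of pulling down a bound versus an unbound
fragment, where $f$ is the fraction of the genome bound by the factor and
$s$ is the fraction of pulled-down reads originating from true binding
sites (the familiar FRIP/SPOT score). $\alpha$ is never stored — it is
always recomputed from $(f, s)$, so the model file has a single source of
truth. Absolute pulldown efficiency is deliberately not modelled: after
downsampling to the requested read count only the relative ratio is
identifiable.

Pulldown is implemented as sampling *without replacement* with inclusion
probabilities proportional to weight ($\alpha$ for bound fragments, 1 for
unbound): each fragment is independently retained with probability
$w/\max(w)$, and the retained set is uniformly subsampled to the target
count. This construction makes the expected bound fraction among selected
fragments exactly $\alpha f_{pool} / (\alpha f_{pool} + 1 - f_{pool})$
regardless of how strongly the bound class is depleted. A sequential
weighted draw (Efraimidis–Špirakis) was considered and rejected: its
selection composition follows a Wallenius noncentral hypergeometric law
whose mean drifts away from the closed form precisely in the
high-enrichment regimes (transcription-factor-like $\alpha$ in the
hundreds) that matter most, unless the fragment pool is made impractically
large. Because thinning happens per simulation round, the full fragment
pool is never materialized in memory.

**Step 3 — PCR.** Each pulled-down fragment is emitted $i$ times with
$i \sim \mathrm{Geometric}(p)$ on support $\{1, 2, \dots\}$, where $p$ is
the probability a fragment has no PCR duplicates; the expected
multiplicity is $1/p$. The pipeline pulls down `numreads * p` fragments so
that the post-PCR read count is `numreads` in expectation, then truncates
(uniformly) or tops up (additional uniform draws from the retained pool,
each amplified) to hit `numreads` exactly.

**Step 4 — sequencing.** Single-end reads sequence a uniformly chosen end
of the fragment (reverse-strand reads are reverse-complemented);
paired-end mate 1 reads the 5' end forward and mate 2 the 3' end
reverse-complemented, so the insert size equals the fragment length.
Per emitted base, the events deletion / insertion / substitution /
faithful copy are mutually exclusive, selected by a single uniform draw
with probabilities `del_rate`, `ins_rate`, `sub_rate`, and the remainder:
a deletion skips a template base (and the position is redrawn), an
insertion emits a uniformly random base without consuming template, a
substitution emits a uniformly chosen *different* base. The composition
order is a documented package choice; at the per-base rates typical of
Illumina data the order is numerically immaterial. Template consumption
continues until `readlen` bases are emitted, clipped at the fragment end
and padded with N when the template is exhausted (another documented
choice — real pipelines would soft-clip, but padding keeps read length
invariant). Template N bases pass through unchanged and are never
"corrected" by the error model. Fragments shorter than the read length
are dropped (and counted) before pulldown. Qualities are a constant
Phred-30 string: the model has a base-error process, not a quality-score
process.

## Parameters

| parameter | meaning | units / range | default |
|---|---|---|---|
| `frag_shape`, `frag_scale` | gamma fragment-length law, mean `shape*scale` | >0; bp for scale | learned |
| `f` | bound fraction of the genome | (0,1) | learned from peaks |
| `s` | fraction of pulled-down reads from binding sites | (0,1) | learned (FRIP) |
| `pcr_p` | probability of no PCR duplicates | (0,1] | learned |
| `sub/ins/del_rate` | per-base sequencing error rates | [0,1), sum <1 | 0 |
| `numreads` | reads (or pairs) to emit | >=1 | 100000 |
| `readlen` | read length | bp | 36 |
| `numcopies` | simulation rounds | >=1 | 100 |

`numcopies` is loosely analogous to the number of cells processed; broad
histone-modification-like settings are well served by 25–100 rounds while
narrow transcription-factor-like settings (high $\alpha$, tiny $f$) need
on the order of 1000, because pulldown thinning discards almost all
background fragments. `suggest_numcopies()` computes the rounds needed
for a given model and read budget, and the simulator warns whenever the
retained pool falls short.

## Learning parameters from data

Given alignment records (from a BAM/SAM via `read_alignments()`, or
constructed in code) and peaks:

* **Fragment lengths** — maximum-likelihood gamma fit (with a
  method-of-moments start) to absolute template lengths of non-duplicate
  proper pairs, counted once per pair. For single-end data the package
  uses the strand cross-correlation heuristic standard in ChIP-seq QC:
  the shift maximizing the FFT cross-correlation between forward- and
  reverse-strand 5' profiles, searched above the read length (to skip the
  "phantom peak") up to 1.5 kb, sets the gamma *mean*; the shape is not
  identifiable from the peak position alone and is fixed at a
  configurable default (5), with the result flagged as approximate.
* **`f`** — the score-weighted covered fraction,
  $\sum_i \mathrm{len}_i \cdot \mathrm{score}_i / G$, over merged peaks.
* **`s`** — the fraction of non-duplicate read 5' positions inside peaks.
  This is the uncorrected FRIP convention: no adjustment is made for
  reads expected in peaks by chance, and membership uses the 5' end only
  (order-invariant and cheap). Both `f` and `s` are clipped to
  $[10^{-6}, 1-10^{-6}]$ so $\alpha$ stays finite.
* **`pcr_p`** — $1/\bar n$ with
  $\bar n = \sum_i i\,n_i / \sum_i n_i$, where $n_i$ counts fragment
  classes observed $i$ times. Without duplicate flags, classes are keyed
  on (chrom, 5' position, strand) for single-end and (chrom, leftmost
  position, template length) for paired data, matching duplicate-marker
  semantics. Position-keyed grouping can spuriously merge distinct
  fragments in very deep, narrow peaks; at the package's toy scales this
  biases $\hat p$ by well under a percentage point.
* **MAPQ** — records below MAPQ 10 are excluded from all estimators
  (configurable); the cutoff guards against multi-mapping pile-ups.
* Sequencing error rates are *not* estimated — there is no estimator for
  them in this learning flow — and default to 0.

The test suite closes the loop: models simulated over a grid of
$f \in \{0.01, 0.05\}$, $s \in \{0.2, 0.5, 0.8\}$, $p \in \{0.6, 0.9\}$,
gamma shapes 2–10 are re-learned from their own simulated output at
200k-read depth, recovering $s$ and $p$ within ±0.05 and the gamma mean
within 10%. Two effects set that tolerance and are worth knowing about:
read 5' ends of bound fragments spill just outside peak boundaries
(shrinking FRIP relative to $s$ by roughly
$\bar L / (\mathrm{peak\ length} + \bar L)$, which is why the recovery
fixtures use 5 kb peaks against 200 bp fragments), and dropping
fragments shorter than the read length truncates the gamma's left tail
(raising the fitted mean by ~5% at shape 2, less at higher shapes).

## Synthetic data

The fixture generator emulates only what the simulator consumes: i.i.d.
uniform-composition reference sequence at a chosen GC fraction, and
sorted non-overlapping peak sets with uniform lengths in a preset range —
narrow (~200 bp, "tf") or broad (1–3 kb, "hm") — and constant or uniform
scores. It deliberately does **not** emulate repeats, mappability
structure, chromatin accessibility, GC bias, or diploid variation; the
simulator never maps reads, so none of these affect the generative
process. Consequently, passing tests demonstrate the correctness and
calibration of the generative model itself, not that simulated reads are
indistinguishable from any particular real library — with real genomes,
alignment ambiguity and coverage biases will add structure this model
does not produce.

Standard problem sizes in the test suite: 1 Mb single-chromosome genomes
for unit and recovery tests, 10 Mb for the enrichment-ratio calibration
(which needs stable densities at enrichment ratios up to ~400), both
chosen as the smallest scales at which the targeted statistics are stable
at the stated tolerances.

## Numerical and design choices

* Coordinates are 0-based half-open (BED convention) everywhere
  internally; SAM positions are converted on read.
* Every stage (shearing, binding, pulldown thinning, downsampling, PCR,
  sequencing) draws from its own RNG stream derived deterministically
  from the user seed, so identical seeds replay byte-identical output and
  a change to one stage's internals does not perturb the others' draws.
* Overlap queries against merged peaks run on sorted boundary arrays via
  `findInterval` (cross-checked against IRanges in the tests); merging
  keeps the maximum score over merged intervals, and bound status under
  multi-peak overlap uses the maximum score — probability semantics, and
  after merging the alternatives differ negligibly.
* Fragments with more than 50% N bases are excluded at pulldown
  (configurable) so assembly gaps cannot dominate the output.
* The enrichment-ratio diagnostic (`enrichment_ratio()`) excludes a flank
  around peaks from the background because bound fragments spill read
  starts just past peak edges; with a flank of a few fragment lengths the
  expected peak/background density ratio equals $\alpha$ exactly for
  score-1 peaks at `pcr_p = 1` and zero error rates.
* Model JSON is written with 17 significant digits so write-then-read is
  bit-identical; unknown keys are rejected to catch typos.

## Known limitations

* No GC-content, accessibility, or cross-linking bias in pulldown; no
  locus-specific binding-energy model (peak scores are taken as given).
* No quality-score simulation, position-dependent error profiles, or
  adapter read-through.
* Whether binding probability should scale with fragment–peak overlap
  length is not specified by the model; the any-overlap rule used here is
  a documented choice.
* Peak calling, alignment and duplicate flagging of simulated reads are
  out of scope; peaks are always an input, and `sim_to_records()` stands
  in for a perfect aligner + duplicate marker when closing the
  learn-simulate loop.
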