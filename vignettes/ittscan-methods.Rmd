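---
title: "Inferring intrinsic transcription terminators from RNA-seq coverage and hairpin clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring intrinsic transcription terminators from RNA-seq coverage and hairpin clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ittscan)
```

## The inference problem

Intrinsic (rho-independent) transcription termination in bacteria is driven by
the nascent mRNA itself: a stem-loop forms behind the RNA polymerase, stalls
it, and — classically with the help of a downstream poly-U tract — releases
the transcript. Annotated terminators exist for only a handful of model
organisms, so `ittscan` infers them genome-wide from two independent signals:

1. **Coverage geometry.** Strand-specific RNA-seq depth is high and flat over
   a transcribed unit, falls sharply past its termination point, and shows a
   first sustained *rise* further into the inter-operonic region (IR). The
   position of that first positive-slope region (`pos_st`..`pos_end`) brackets
   where the transcript actually ended.
2. **Sequence structure.** Candidate stem-loop hairpins downstream of the stop
   codon, grouped into *cluster* units (adjacent hairpins separated by fewer
   than 15 nt) or *single* units.

The unit nearest the stop codon (*identified*) is the sequence-based
prediction; the unit nearest `pos_st` (*RNA-seq derived*) is the
coverage-based one. When the two co-locate (identical membership: *full*
match; span overlap: *part* match) the terminator call is corroborated; when
the identified unit sits strictly upstream and disjoint it is counted
*ahead*. The percent of derived units matched, with half-up rounding, is the
headline accuracy of the approach.

## Coverage model: sl1, sl2 and the zones

For a unit with CDS and downstream IR, let `F(i)` be the cumulative depth in
transcript orientation. The windowed slope and its difference are

```
sl1(i) = (F(i + w) - F(i)) / w          # average depth of the next w bases
sl2(i) = sl1(i + 1) - sl1(i)            # discrete second difference at lag w
```

with `w = 10` by default (supported 5..30; larger windows smooth away the
early inflection points that mark termination). The scan walks `sl2` from the
IR start, finds the first value below `-eps` (the post-stop-codon drop), then
the first later value above `+eps`: that position is `pos_st`. The region
extends while `sl2 >= -eps` and closes at the next drop (`pos_end`), or at
the IR end. The IR is then partitioned into Zone 1 (IR start to `pos_st`, the
transcript tail), Zone 2 (the positive-slope region, a buffer), and Zone 3
(the remainder, typically the next unit's upstream region); the three zones
always tile the IR exactly.

Numerical choices, made once and kept:

* **Attribution.** `sl2(i)` compares depth `w` bases apart, so its value is
  attributed to the base *entering* the sliding window (span position
  `i + w`). This keeps a drop exactly at the CDS/IR boundary inside the
  scanned support and places `pos_st` at the rise itself rather than a window
  length before it. On noise-free planted ramps the detected `pos_st` is
  within one base of the truth.
* **Sign tolerance.** `eps = 0` for integer counts; for replicate-averaged
  real-valued depth `eps = 1e-9 * max(sl1)`, so that floating-point dust is
  not read as a slope change.
* **Boundary drops.** If depth is already zero at the IR start, the drop
  happened upstream of the scanned support; a leading zero run of `sl2` is
  then accepted as the post-drop saddle. Without this rule, IRs whose
  coverage collapses exactly at the CDS boundary could never yield a
  positive-slope region.
* **Repeats.** `alternate_pos_regions()` reapplies the same detection after
  each region's closing drop, enumerating every successive rise; the first
  element always equals the primary detection.

## Read filtering and IR screening

Alignments enter the depth tracks only if they are in a proper pair (SAM
flags 83/163 or 99/147), have MAPQ ≥ 30, and have |TLEN| at least the read
length; each rejected record is tallied under its first failing criterion.
Fragment strand is the strand of the first-in-pair mate. Replicates are
averaged elementwise.

IRs are screened in two stages. Stage 1 keeps IRs with coverage fraction
strictly above 0.90 — by default on both the IR and its source CDS, the
conservative union of the two published statements of the rule. "Covered"
means depth ≥ 1 after replicate averaging (configurable; averaging can
legitimately push a base below the threshold). Stage 2 removes IRs whose mean
depth lies strictly above the upper 5% quantile of the mean-depth
distribution over survivors — an upper tail only, because the motivation is
abnormally high (amplification-inflated) coverage; with identical means
nothing is strictly above the quantile and nothing is removed.

## Hairpin model

Hairpins are enumerated as perfect inverted repeats: stem 3–20 bp (the mode
among matched terminators is 3 bp), loop 3–15 nt, Watson–Crick pairs plus G:U
wobble by default, `N` never pairs. For each loop placement the stem grows
outward from the loop-closing pair as far as pairing allows, so only the
maximal stem per apex is reported and a candidate subsumed by a larger one
with the same apex never appears. Note that shifted pairing registers over
the same repeat are distinct apexes and are reported separately; the most
stable register scores lowest. The enumerator is tested against a brute-force
enumeration over all (start, stem, loop) triples.

Stability is scored additively: the sum of nearest-neighbor-style stacking
energies over adjacent stem steps plus a loop-length penalty, in kcal/mol at
37 °C, with loops beyond the table extrapolated as
`dG(n) = dG(9) + 1.75 RT ln(n/9)`. The tables ship with the package and are
fully replaceable, and an external folding engine can be plugged in behind
the same operation contract; the score is used only as a retention threshold
(keep `dG <= +5` kcal/mol, since weakly positive short hairpins are
structurally viable) and as a descriptive statistic, so the additive model is
deliberately simple — no bulges, internal loops, pseudoknots or ensembles.
Across all screened IRs of a genome, rare (stem, loop) combinations are
rejected by a 2-D histogram rule: cells are sorted ascending by count (ties
broken lexicographically) and removed greedily while the cumulative removed
hairpins stay at or below 5% of the total.

## Termination units, matching, trails

Hairpins in one scan window (20 bases upstream of the stop-codon site through
270 downstream, clipped at the genome or the next same-strand CDS) are
reduced for subsumption — a hairpin wholly contained in an earlier, larger
one is dropped — and chained left to right: a gap (`next.start - prev.end`)
strictly below 15 nt merges, overlaps merge too. The 15 nt threshold mirrors
the nascent RNA sequestered in the RNA exit channel (~5 nt) plus the DNA-RNA
hybrid (9–10 bp) and therefore unavailable for folding. Hairpins whose span
starts upstream of the stop codon's first base lie in the CDS and are
excluded from unit selection; this also guarantees the identified unit is
never downstream of the derived one.

Distances to `pos_st` follow the unit's zone: from the last hairpin base in
Zone 1, the first in Zone 2, and `n = 0` for a unit straddling `pos_st`.
Zone 3 units are excluded from the derived-unit choice; ties at equal `n`
break toward the upstream (Zone 1) unit, since earlier termination is the
biologically preferred reading. Poly-U/A trails are searched downstream of
the identified unit's 3' end with a seed-and-extend scanner (minimum run 3,
0/1/2 interior mismatches, trimmed to in-class endpoints), taking the
nearest pattern; the search is validated against an exhaustive window scan.

## What the generator emulates — and what it does not

`simulate_genome()`/`simulate_depth()` produce the study conditions every
test runs under: units tiled on alternating strands (CDS ~900 bp, same-strand
IR ~1700 bp, matching the observed 62/38/1617 zone-length structure), a
planted terminator at a geometric offset (mean 20, max 80 bases) downstream
of each stop codon — a cluster of ≥ 2 perfect hairpins with gaps 0–14 nt in
two-thirds of units, a single hairpin otherwise, cluster sizes decaying
geometrically, with a 3–8 base U trail in half the cases — and depth with a
CDS plateau (Poisson mean 100), a sharp post-termination decay (excess depth
reaches ~1 within 5 bases), a near-zero IR floor (mean 3), a short
positive-slope bump starting 15 bases after the planted termination end, and
a 5'-UTR ascent into the next same-strand CDS that produces the alternate
positive-slope regions. The bump is placed just after the terminator, not
next to the downstream CDS, because the observed Zone 1/2 lengths put the
positive-slope region a few tens of bases into the IR with a long Zone 3
behind it. Stem bases follow the background GC so the emitted genome's
composition stays at `gc_fraction`; real terminator stems are GC-enriched,
but the detector needs complementarity, not composition.

The generator does **not** model fragment-length or GC bias of library
preparation, imperfect (bulged) stems, overlapping genes, or operon-internal
intergenic gaps. Passing the round-trip tests therefore shows the pipeline
recovers planted structure under idealized coverage geometry; it does not
certify performance on real libraries, where replicate averaging, mapping
artifacts and soft boundaries blur the slope signal. Under Poisson noise the
saddle detector fires early on plateau fluctuations in a minority of IRs
(integer counts leave `eps = 0` no room to absorb shot noise), which is the
main source of the gap between the noise-free and noisy recovery rates.

## Problem sizes and reproducibility

The test suite checks oracle equivalence on 200 random 300-mers (hairpins),
500 random interval sets (grouping), and exhaustive scans for the slope and
trail operations, and runs the full pipeline on 200-unit genomes (~260 kb)
noise-free and with Poisson noise; these sizes keep the default suite within
a few minutes on one CPU while leaving the planted-recovery thresholds
(≥ 0.95 noise-free, ≥ 0.85 noisy, spans within ±25 bases) well exercised.
Every random draw flows from one seed per simulation, recorded in the run
log; rerunning with the same seed reproduces byte-identical tables.
`scripts/acceptance.R` recomputes the benchmark accounting arithmetic and the
synthetic round-trip metrics from scratch at the same sizes.

## Known limitations

* Perfect stems only; a bulged terminator is found only via a shorter perfect
  sub-stem, which shifts its span and score.
* The additive energy model ranks hairpins sensibly but is not a folding
  engine; absolute kcal/mol values should not be compared with
  partition-function predictions.
* The saddle detector is deliberately simple (no smoothing, no likelihood
  model); it is defined by windowed differences, so `pos_st` precision
  is bounded by `w` under noise.
* Spliced features, operon prediction and alignment itself are out of scope;
  annotations and alignments (or bedGraphs) are inputs.
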