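---
title: "Probe-array HLA typing: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probe-array HLA typing: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlarray)
```

This vignette is the package's own account of the science behind its
functions: the signal model and calling algorithm, the parameters that
matter and why their defaults are what they are, what the simulator
does and does not emulate, and where the design was genuinely open.

## The typing problem

HLA class I loci (A, B, C) are the most polymorphic genes in the human
genome; each individual carries up to two alleles per locus, and allele
groups ("serotypes" in array parlance, e.g. `A*02`) contain families of
variants that may differ by a single nucleotide. An SSOP array probes a
sample's transcripts with a *complete overlapping* probe set: one probe
anchored at every position of every catalog allele. A probe hybridizes
(reads "positive") when its exact sequence occurs in the sample —
including occurrences in *other* alleles or loci. That sharing is probe
masking, and it is the method's fundamental error source: a fully
masked absent allele is indistinguishable from a present one by probe
signals alone.

## Probe design

`melting_temperature()` uses the GC-count approximation
$T_m = 64.9 + 41\,(G+C-16.4)/n$, which is linear in GC count at fixed
length (slope $41/n$ per base). `build_probe_set()` anchors a probe at
every position with at least 20 nt remaining, and `adjust_probe_length()`
extends or shortens it at the 3′ end within 20–60 nt to bring $T_m$ as
close as possible to the 64.2 °C hybridization target; ties break toward
the shorter (cheaper) probe. Anchoring at the 5′ end keeps the
convention that a probe's signal is assigned to its starting position.
In GC-balanced sequence the optimum sits near 32 nt; AT-rich stretches
push probes to the 60 nt ceiling and GC-rich stretches to the 20 nt
floor, which is why the acceptance checks exercise a catalog with a
composition wave (`gc_wave = TRUE`).

## Signal model and processing

Raw per-array fluorescence varies widely between slides, so every array
is mapped to a fixed scale: minimum 1, maximum 20,000, array-wide mean
1,000, via $S_n = \min(S - R_{min} + F,\; 20000F)/F$. The capped
formula does not pin the scaling factor $F$; the package defines $F$ as
the root of $\overline{S_n}(F) = 1000$, solved in closed form when the
cap is inactive ($F = \overline{S - R_{min}}/999$) and by bisection
otherwise. The implementation evaluates the algebraically equivalent
form $\min((S-R_{min})/F + 1, 20000)$, which hits both scale boundaries
exactly in floating point. A constant raw array is rejected: no $F$ can
satisfy the mean constraint.

Positive signals change smoothly between consecutive overlapping probes
while negative probes sit at background, so a signal that deviates from
the rolling median of its allele track by more than 3x (either
direction, window of 5 probes) is treated as a hybridization artifact
and replaced by the track consensus; `method = "discard"` drops it
instead. Tracks shorter than the window are left alone, and because a
unique probe may lie on several tracks, per-track medians are combined
into a per-probe consensus before the test. Replacement (not discard)
is the default because downstream counts assume a complete probe
universe.

Positivity thresholds are per probe. With few arrays the classic
initial rule applies: 10% of the probe's maximal observed signal. From
five arrays on, each probe's observations are split at the largest gap
on the log scale into a low and a high mode, and the threshold is the
gap's geometric midpoint; one-mode probes are classified by where the
mode sits relative to the array mean (always-positive vs
never-positive). In the initial regime the thresholds are floored at a
tenth of the pinned array mean (100 units): the 10%-of-max rule
presumes a probe has been observed positive somewhere, and without the
floor a never-positive probe's threshold would sit at 10% of
background, which noise crosses freely. Thresholds are learned only
from QC-passing arrays:
degraded or empty arrays are rescaled by the mean-1000 constraint in a
way that fills the positive/negative gap and would blur the modes.

## The three-stage calling algorithm

**Stage 1 — serotype determination.** For allele $x$, $Neg(x)$ counts
its probe placements whose unique probe is negative. Serotype scores
average the $k = \min(5, N)$ smallest $Neg(x)$ of the family's $N$
alleles. The literal alternative $k = \max(5, N)$ can never exceed the
$N$ available alleles, so it degenerates to averaging all of them; the
package implements the five-best-supported reading as the default and
keeps the literal mode selectable (`k_mode = "max"`). A locus is
homozygous when the runner-up serotype trails by $\ge 20$ average
negatives; serotypes ranked third or lower are eliminated when their
margin over the leader exceeds `MaxDifference` (pair-specific table,
global fallback 30). The stage is engineered for zero false negatives:
the top two serotypes are never eliminated, and never-distinguishable
pairs can be exempted outright.

**Stage 2 — genotype determination.** Surviving serotypes are clustered
into serogroups; each cluster yields one comparison vector — serogroup
scope when it holds two or more serotypes, serotype scope otherwise —
listing $AvgWins(x)$ and $Neg(x)$ for every in-scope allele in
canonical order. $Wins(x\,vs\,y)$ counts alignment columns where the
two alleles carry different probes and $x$'s is brighter; counting per
column rather than per probe keeps length-adjusted probes from biasing
the tally, and ties award nothing. With a populated knowledgebase the
vector is correlated against stored template vectors of the same scope
(top 5 above a 0.8 floor; candidate alleles are those present in a top
template). Otherwise the weight rule applies:
$Weight(x) = AvgWins(x) - Neg(x)$ must strictly exceed
$WeightThreshold(x)$ (global default 0; refined per allele from
knowledgebase templates as the midpoint between present and absent
weight distributions).

**Stage 3 — ambiguity removal.** If more than two candidates remain at
a locus, all legal locus genotypes (one or two alleles) are enumerated;
$Sig(G, p)$ sums the probe signals of $G$'s alleles at position $p$,
the larger sum wins the position, and each option's total wins against
all alternatives ranks it. Everything within 20 wins of the best is
reported (the call is then flagged ambiguous), with an optional
population-frequency tie-break that reorders only within that margin.
Because alignment positions partition by locus, cross-locus comparisons
decompose exactly into these per-locus tallies, which is how the
implementation enumerates: per locus first, then combined. Enumeration
is capped (default 10,000 combinations) with an instructive error.

**Template matching.** Independently of stages 2–3, a query array is
correlated against every knowledgebase template. Identity needs
$r > 0.975$, a usable match $r > 0.95$, and both require *zero*
serotype mismatches — high correlation with a serotype disagreement is
vetoed, which is what protects against coincidentally similar samples.
Correlation is Pearson on the linear normalized scale. The log scale
was considered and rejected: the min-subtraction step of the
normalization places the scale floor just below the background mode, so
log-transforming amplifies background spread and caps replicate
correlations near the identity threshold regardless of the actual noise
level, while on the linear scale the positive/negative contrast carries
the signal. `cor_arrays(log = TRUE)` retains the alternative.

**Validation flags.** Every documented typing error falls in two
classes — homozygous calls and same-serotype allele pairs — so exactly
those calls are flagged for confirmatory sequencing. Degraded arrays
(raw mean below 1/3 of a typical cohort array) are typed but flagged;
arrays below 15% are reported negative outright, because after the
mean-1000 rescale their background would read as positive signal. The
cohort reference is the *median* raw mean, robust to controls and
failed preps in the same batch.

## The simulator: what it emulates, and what it does not

`sim_config()` defaults define the study conditions used throughout the
tests: 3 loci x 8 serotypes x 4 alleles, 300 nt alleles, serotype
founders 25 substitutions from the locus root, and sibling alleles one
nucleotide apart — the documented hard regime (e.g. `C*07:01` vs
`C*07:06` differ at a single position). Three structural choices
deserve explanation:

* **Shared polymorphic hotspots.** All serotypes of a locus vary inside
  the same hotspot region, each family at its own column a few
  nucleotides apart, mirroring how class I polymorphism clusters at
  peptide-binding-groove positions across allelic lineages. Adjacent
  columns give every family essentially the same probe coverage of its
  within-serotype signal, which the fixed homozygosity margin of 20
  presupposes: with variant positions scattered across the sequence,
  local composition differences in adjusted probe length would make
  present-serotype scores heterogeneous enough to trigger spurious
  homozygosity calls. Per-family columns also make sibling variant
  probes structurally private: they carry a non-root base at a column
  where every other family is root, so with only four bases available
  no cross-family base collision can recreate them.
* **Flanked hotspots.** Each family's variant column is additionally
  flanked at ±10 nt by family-private founder substitutions, so even
  the founder allele's probes over the hotspot (which carry root bases
  at the variant column itself) differ from every other family.
  Variant columns stay one probe-length clear of the sequence ends so
  each is covered by a full complement of overlapping probes, as
  interior transcript variants are.
* **Engineered masking.** `masked_pair = TRUE` duplicates one allele's
  entire variant region into every allele of the last locus. The masked
  allele then shows zero negative probes whenever that locus is present,
  reproducing on demand the pathology where probe signals cannot
  distinguish a homozygous sample from a heterozygote with the masked
  variant; its catalog is used by the masking tests and scenarios, not
  by default, because in a 24-serotype synthetic catalog one engineered
  pair would dominate error statistics in a way the large real catalog's
  rare masked pairs do not.

Signals are lognormal around 5,000 RFU (positive) and 100 RFU
(background) with a smooth per-probe efficiency profile (sigma 0.25,
smoothed over ~15 probes) that is *reproducible across arrays* — it
models sequence-dependent hybridization efficiency, which is why
replicate arrays correlate far above distinct samples. Per-probe
replicate noise is lognormal with sigma 0.10 (~10% CV), the regime in
which replicate pairs correlate above 0.975; each array also gets a
global scale factor (sigma 0.3) that normalization removes. The
degraded scenario attenuates the whole array by 0.25; the mixed
scenario sums the noiseless signals of two genotypes before noise.

The simulator does **not** emulate: insertions/deletions (catalogs are
gap-free, so alignment columns equal positions; real HLA alignments are
supplied externally via the `msa` argument), hybridization
thermodynamics beyond the Tm formula, spatial slide artifacts, dye
chemistry, cross-hybridization of near-match (non-identical) probes, or
the absolute RFU distributions of real scanners. Passing tests
therefore demonstrate the *algorithmic* correctness and the documented
failure modes of the calling rules — not scanner-level robustness on
real slides.

## Numerical choices and degenerate inputs

* The normalization solver brackets $F$ from the closed-form uncapped
  solution downward and bisects to a relative tolerance of $10^{-9}$ on
  the scaling factor; the mean constraint is met to well under
  $10^{-6}$ relative.
* Rolling medians use `stats::runmed` with median end-rules; outlier
  correction of an already-corrected array is a no-op in practice, and
  the tests assert idempotence on simulated arrays.
* Ties: equal $|T_m - 64.2|$ chooses the shorter probe; equal serotype
  scores rank by smaller minimum allele $Neg$, then identifier; equal
  positional sums award no win; equal frequency products preserve the
  wins order (stable sort).
* Degenerate inputs fail loudly with classed conditions: constant raw
  arrays, non-positive signals, catalogs with duplicate names, anchors
  without 20 nt of sequence, genotypes with more than two alleles per
  locus, knowledgebase/probe-design fingerprint mismatches.

## Problem sizes used by the tests

The checked claims run at desk scale, chosen so the full suite and the
acceptance script each complete in minutes on one CPU: 5,000-probe
arrays for the normalization contract; 200 clean heterozygous samples
on the default 96-allele catalog for end-to-end accuracy (exact
recovery of all six alleles in every sample); 20 replicate and 50
disjoint-genotype pairs for the correlation separation; exhaustive
brute-force verification of probe-length optimality over every anchor
of a 2x2x2 composition-wave catalog; and 500 + 500 randomized
instances for the scoring-rule oracles.

## Known limitations

Within-serotype resolution rests on the hotspot probes alone, so two
samples differing only in a fully masked allele are irreducibly
ambiguous — the method's answer is the validation flag, not a forced
call. The weight rule's global threshold of 0 is conservative for
partially masked alleles; it sharpens as the knowledgebase grows.
Mixed samples are detected (via surplus surviving serotypes and flags)
but not deconvolved. The serotype-score homogeneity that the fixed
margins assume is a property of the catalog; for catalogs with very
uneven family structure the margins and `MaxNeg`/`MaxDifference` tables
should be re-derived empirically from typed templates.
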