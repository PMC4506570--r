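---
title: "Assessing capture and coverage adequacy of a clinical gene panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing capture and coverage adequacy of a clinical gene panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelcov)
library(dplyr)
```

## The problem

When exome sequencing is used as a diagnostic test for a condition with
many candidate genes — here the prototype is a curated 103-gene panel for
pediatric sudden cardiac arrest/death (SCA/D) — a pathogenic variant can be
missed for reasons that have nothing to do with interpretation:

1. the exon harbouring it was never targeted by the exome capture design;
2. the position was targeted but sequenced at inadequate depth;
3. the variant class (large insertions/deletions without a reported genomic
   coordinate) is invisible to short-read exome analysis altogether.

panelcov quantifies each of these failure modes for a given panel, capture
design, per-sample depth tables, and variant catalogue, and triages
case-level findings into the standard positive / uncertain / negative
verdicts. It deliberately starts *downstream* of alignment and variant
calling: its depth input is a per-base (or per-locus) depth table of the
kind produced by GATK DepthOfCoverage, and any base- or mapping-quality
filtering is assumed to have been applied by whatever produced that table.
Pathogenicity labels are carried verbatim; the package performs no variant
classification of its own.

## The model and its conventions

**Coordinates.** Exons and capture targets are 0-based half-open (the BED
convention); variant and locus positions are 1-based (the VCF/HGMD
convention). Conversion happens in exactly two places —
`position_in_exon()` and `depth_at()` — so off-by-one bugs cannot diffuse
through the code. Chromosome names are taken verbatim from the input files;
no `chr`-prefix harmonisation is attempted, because silent renaming turns
into silent zero-overlaps.

**Capture.** An exon counts as *captured* when its total overlap with the
merged design targets reaches `min_overlap` bases; the default of 1 base is
the least-assuming reading of "targeted by the kit", and the knob is
exposed because design-level truth is rarely available. A catalogued
position lying in several exons counts as captured if *any* containing exon
is captured (captured-dominates): detectability is a property of the base
being targeted in at least one context.

**Coverage.** A base is adequately sequenced when its depth `d` satisfies
`d >= D` with `D = 20` reads by default ("20x", inclusive). For an exon of
`L` bases with `n` adequate bases, the covered fraction `f = n/L` is
classified into five tiers:

| tier   | condition        |
|--------|------------------|
| FULL   | `n == L` (exact integer test) |
| WELL   | `0.90 <= f < 1`  |
| MOSTLY | `0.70 <= f < 0.90` |
| LIGHT  | `0.40 <= f < 0.70` |
| NONE   | `f < 0.40`       |

FULL is decided by the integer comparison, never by `f >= 1 - eps`: "every
base adequate" is an exact condition and floating point should not be
allowed near it. The three interior boundaries partition `[0, 1]` exactly,
so each fraction belongs to exactly one tier.

Per-sample tier proportions are computed over **captured exons only** by
default (`denominator = "captured"`), because non-captured exons fail for a
different reason and are already reported by the capture stage; the
`"all"` mode is available for a whole-panel denominator. Cross-sample
summaries are unweighted arithmetic means — every sample counts equally.
A catalogued position enters a sample's "no coverage" count only when
*every* captured exon containing it is tier NONE in that sample, mirroring
the captured-dominates rule. The median over an even number of samples is
the mean of the two central order statistics.

**Detectability.** Positional catalogue records are deduplicated to unique
(chromosome, position) pairs for position-level statistics — a position
with good depth is covered regardless of which base change is reported
there — while per-record rows are also emitted. Each position's per-sample
depths are summarised by the arithmetic mean rounded *down* to an integer
(median available via `summary = "median"`; the choice is exposed because a
published single-integer depth per variant does not identify the
statistic), and binned:
ADEQUATE (`d >= D`), MID (`10 <= d < D`), LOW (`5 <= d < 10`), VERY_LOW
(`d < 5`). Coordinate-free large indels are never binned; they appear in a
dedicated "not assessable by this method" table, since locating them is
beyond short-read exome analysis regardless of depth.

**Triage.** A case is *positive* if any panel-gene finding is pathogenic or
likely pathogenic, else *uncertain* if any finding is a VUS, else
*negative*. "Suspected pathogenic" wording in negative-rule definitions is
mapped to the likely-pathogenic tier, so the positive and negative rules
use the same tier set. Yield percentages are displayed as half-up integers
with the exact fractions retained; all other report percentages are half-up
at 1 decimal (counts are always primary, the percentages are display).

## The synthetic-data generator

The generator exists so that every stage can be verified against planted
ground truth without patient data. Its defaults emulate the study
conditions the pipeline is designed for:

* 103 genes (the bundled SCA/D symbols), 2,190 exons, one synthetic
  chromosome per gene (`chrS1`, `chrS2`, ...; no real-genome coordinates
  are imitated, to prevent accidental conflation with real annotation);
* capture dropout probability 0.024 per exon (the observed 2.4% of
  untargeted exons), with an optional edge trim;
* 72 samples at a 20x adequacy threshold with planted tier mixture
  81 / 5.04 / 4.91 / 3.39 / 5.66 % (FULL / WELL / MOSTLY / LIGHT / NONE);
* an 11,452-record catalogue, 16.6% coordinate-free large indels, 11.4% of
  unique positions multiallelic with exactly two records each (the
  published counts imply exactly two records per multiallelic position on
  average);
* a 30-case diagnostic cohort with planted verdict mixture
  17 / 53 / 30 %.

Quantities the source study does not state were fixed once at
field-realistic values and not revisited: exon lengths uniform on 60–300 bp
(the bulk of human coding exons), inter-exon gaps 100–2,000 bp, a
pathogenicity mixture of 0.5 / 0.2 / 0.2 / 0.1 over pathogenic / likely
pathogenic / VUS / unknown, and an on-target mean depth of 100x (typical of
clinical exomes and matching the platform average the panel was evaluated
at).

**Exact-fraction mode** plants a tier literally: for each (sample, exon)
the number of adequate bases is drawn uniformly from the tier's admissible
*integer* range (e.g. `ceiling(0.9 L) .. L-1` for WELL), the first `n`
bases get depth `5 D` and the rest `D - 1`. Drawing the integer count
directly — rather than a real-valued fraction that is then multiplied by
`L` and ceiled — guarantees the realized fraction lies inside the planted
tier for every exon length, so the classifier must recover the planted
assignment *exactly*; this mode is what the deterministic recovery tests
use. The `D - 1` filler also exercises the inclusive-threshold boundary on
every exon.

**Stochastic mode** aims at distributional realism instead: the tier's
target fraction of the exon (1.0 / 0.95 / 0.80 / 0.55 / 0.15) forms a
well-captured core with negative-binomial depth (mean 100), and the
remaining bases fall off at the two exon edges (mean 2), mimicking the
capture-efficiency decay at target boundaries. The negative-binomial size
is 50 for FULL exons and 8 otherwise: the tighter FULL noise keeps the
probability that any core base of a 300 bp exon dips below 20x negligible,
while the overdispersed interior of the other tiers still concentrates the
realized fraction well inside its tier. An independent-per-base model with
depth calibrated to hit the target fraction was rejected: for a 60 bp exon
the binomial noise of 60 independent bases is wider than the WELL tier
itself, which would make tier recovery systematically biased rather than
merely noisy. With the core/edge model the cross-sample mean of recovered
tier proportions matches the planted mixture within Monte-Carlo error,
which is exactly what the stochastic acceptance test asserts (tolerance
three standard errors of the mean, estimated from the run itself).

Every generator emits machine-readable ground truth (dropped exon ids,
per-sample planted tiers, the realized catalogue partition, planted
verdicts), and all output is a deterministic function of the configuration
and seed: each stage derives its RNG stream from the base seed plus a fixed
stage offset, so regenerating a dataset is byte-identical.

What passing these tests shows — and what it does not: the recovery tests
verify the *logic* of every stage (interval algebra, thresholding,
classification, partitioning, triage) on data whose structure is known.
They do not show that real exome coverage looks like the generator's output:
real data has GC- and mappability-driven coverage structure, correlated
failures across samples, duplicate reads, and capture-kit batch effects,
none of which are modelled. Conclusions about a real platform require real
depth tables, which the pipeline consumes in the same formats.

## Numerical and degenerate-input choices

* Depth profiles are carried run-length encoded over the panel footprint;
  bases absent from the source table are depth 0 by construction, and a
  fully empty depth file is a valid all-zero profile.
* Interval merging treats bookended intervals (`end == next start`) as one
  run; merging is idempotent and conserves the covered base count.
* An empty capture design is valid (nothing captured); an empty panel is an
  error.
* Zero-length exons are impossible by the interval invariant
  `start < end`.
* Positions falling in no panel exon are excluded from both sides of every
  partition and reported separately, never silently dropped.
* Half-up rounding (`round_half_up()`) is used for all display percentages
  because the conventional clinical-report style rounds 16.67% to 17%, not
  to R's round-half-even 17 (which agrees here) or 2.5 to 2 (which would
  not).

## Problem sizes used in the tests

The deterministic recovery tests run the generator at the full emulated
scale (103 genes / 2,190 exons / 72 samples / 11,452 catalogue records) in
exact-fraction mode, where the run-length representation keeps the whole
cohort to a few hundred thousand rows. The stochastic-mode check runs at
the same scale with per-base depth draws (~28 million); the brute-force
oracle comparisons use randomized fixtures of at most a few thousand bases
and a thousand records, where exhaustive per-base enumeration is
practical. These sizes are the package's test design; the pipeline itself
has no built-in scale assumptions beyond memory.

## Known limitations

* Capture is binary at the exon level; probe-level efficiency and
  continuous capture models are out of scope.
* Detectability is depth-only: genotype quality, allele balance, indel
  realignment, and CNV calling are not modelled, so an ADEQUATE bin is
  necessary but not sufficient for a confident call.
* The published per-variant depths that the detectability worked example
  reproduces are single integers per variant; whether they were means,
  medians, or a representative sample is not identifiable, and the
  package's default (floored mean) is a documented choice, not a claim
  about the source data.
* Whether published tier proportions used all panel exons or captured
  exons as denominator is likewise not identifiable; both modes are
  supported and `"captured"` is the documented default.
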