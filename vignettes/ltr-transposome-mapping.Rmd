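---
title: "Mapping endogenous retroviral LTR integration sites across a cohort"
author: "ltrmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping endogenous retroviral LTR integration sites across a cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltrmap)
```

## The problem

Endogenous retroviruses (ERVs) leave long terminal repeats (LTRs) scattered
through host genomes — often as solo-LTRs after recombination deletes the
proviral interior. Because each LTR carries promoter and enhancer sequence,
the individual-specific map of LTR insertions (the *transposome*) is a
candidate modifier of host gene expression. In the domestic cat, endogenous
feline leukemia virus (enFeLV) LTRs are numerous and polymorphic between
animals, and linker-mediated PCR gives a cheap way to enrich sequencing
libraries for LTR/genome junctions: sheared DNA is ligated to a synthetic
linker and amplified between the linker and an LTR-specific primer, so every
informative fragment has one end anchored at the 5′-LTR junction.

`ltrmap` implements the downstream computation: calling integration sites
from aligned enrichment reads, unifying them across individuals, comparing
populations, annotating gene proximity, and overlaying expression data. The
upstream steps (trimming, alignment) are deliberately out of scope — the
package consumes aligned genomic intervals (BED6 or a minimal SAM dialect)
and its simulator emits them directly.

## The enrichment geometry and the simulator

The assay's signature is geometric. All enriched fragments share the
LTR-primer end, so at a true junction the aligned footprints form a stack
that begins *exactly* at the junction (a blunt coverage edge) and decays
into flanking sequence following the fragment-length distribution. The
simulator reproduces that signature:

* **Fragment lengths** are truncated normal with mean 400 bp (the
  sonication target) and sd 80 bp, truncated to `[1, 3 × mean]`. Only the
  mean is assay-determined; the sd is a free parameter of this package.
* **Footprint cap** (`read_length`, default 500 bp). With 2×250 bp paired
  sequencing of ~400 bp fragments, the mates overlap and tile the whole
  fragment, so the aligned footprint is the fragment itself capped at
  R1+R2 = 500 bp. A 250 bp single-read cap would make every junction stack
  rectangular and its orientation undecidable; the 500 bp default preserves
  both the blunt edge and the decaying tail that orientation inference
  relies on.
* **Per-site read counts** are Poisson(`target_junction_depth`, default
  200), honouring the count noise a pooled amplicon library shows while
  keeping expected depth controllable.
* **Env loci emit the same junction signature.** The LTR primer also
  captures the 3′-LTR flanking the reference-fixed endogenous *env* genes,
  so the simulator plants those stacks deliberately — the env-exclusion
  stage must have real signal to remove.
* **Background** is uniform off-target coverage at
  `background_read_rate` = 100 reads/Mbp (0.1 reads/kbp).

The default cohort models three populations of differing relatedness (7, 6
and 7 individuals) with a heritable pool of 40 sites per population, each
site carried with probability 0.5, plus Poisson(10) private sites per
animal, on a toy genome of 4 × 2.5 Mbp chromosomes with one fixed env locus
per chromosome. Sites are placed uniformly with a rejection rule: no site
may fall within `min_site_spacing` = 2000 bp (twice the env-exclusion
window) of an env locus or of another site of the same individual, so a
planted site can never be env-flagged or merged into a neighbour by
construction. These are desk-scale conditions — per-animal site counts in
the tens rather than the hundreds — chosen so a full 20-animal cohort
simulates and calls in seconds; all acceptance measurements in this package
use 20 replicate cohorts of this size.

What the simulator does *not* model: base-level sequence, sequencing error,
PCR duplicates, mapping ambiguity, copy-number variation at the LTR itself,
or the solo-LTR vs full-length provirus distinction (undecidable from
junction data alone). Passing the recovery tests therefore demonstrates the
pipeline's interval logic, not robustness to alignment artefacts in real
libraries.

## Site calling

Per individual: exact pileup → candidate intervals → filters → orientation
→ within-individual merge → env exclusion.

* **Pileup** is exact and collapsed to constant-depth runs (the
  `genomecov -bg` layout); `sum(run length × depth)` equals the summed read
  lengths, an invariant asserted on every test run.
* **Candidate intervals** are maximal runs with depth ≥ `coverage_floor`
  (default 1, i.e. faithful to the bedGraph convention; raise it to
  suppress background-chained intervals in noisier data).
* **Filters are strict inequalities**: length must exceed 100 bp and stay
  below 1000 bp, and the *peak* per-base depth must exceed 100×. Boundary
  values are rejected. "Depth" is read as peak rather than mean because
  junction-anchored enrichment concentrates its depth at the junction; a
  mean reading would conflate site strength with tail length.
* **Orientation (polarity).** An edge is *blunt* when depth rises from zero
  to at least `blunt_fraction` (0.5) of the peak within `blunt_tolerance`
  (10 bp) of the interval boundary. Exactly one blunt edge orients the
  site: blunt left edge = `+` (LTR to the left of its flank), blunt right
  edge = `-`; the junction is that boundary. Neither or both edges blunt
  gives `ambiguous`. The two blunt parameters are not assay-determined;
  they are chosen to tolerate single-read ragged ends and are exposed in
  the configuration.
* **Ambiguous junction placement.** For ambiguous intervals the junction is
  placed at the sharpest single-step depth change inside the interval
  (leftmost on ties) rather than at an interval boundary. This choice is
  load-bearing: a single background read overlapping the blunt side of a
  true stack shelves the interval edge by up to one footprint, and an
  edge-based junction would then be hundreds of bp off. The sharpest step
  recovers the true junction in exactly that failure mode, and on a clean
  rectangular plateau it degrades to the left edge.
* **Within-individual merge** collapses candidates whose junctions lie
  within 200 bp (the same tolerance used across individuals) to the deepest
  one, before env exclusion.
* **Env exclusion** flags any site whose interval extended by `env_window`
  (1000 bp) touches a reference env locus. Flagged sites are reported in a
  secondary table, never silently dropped.

## Unifying sites across individuals

Two calls are "the same insertion" when their junctions differ by less than
200 bp. That pairwise rule is not transitive, so the package uses greedy
leader clustering: per chromosome, calls are scanned in junction order; a
call joins the open cluster iff it lies within the tolerance of the
cluster's *leader* (its leftmost member), otherwise it founds a new
cluster. Leader anchoring makes the result deterministic and bounds a
cluster's span at one tolerance; the cost is that a chain like
1000/1150/1320 splits as {1000, 1150}, {1320} even though 1150 and 1320 are
within tolerance of each other. Distances are measured between inferred
junctions (not interval starts) — the junction is the biologically anchored
coordinate — and the tolerance is configurable.

Prevalence classes follow the field's reading: *singletons* are clusters
seen in exactly one individual across the whole cohort (not per
population), *fixed* clusters appear in every individual, and `n ≥ k`
thresholds are configurable. The partition invariant — cluster prevalences
sum to the number of unified calls — is exact and checked. Pairwise sharing
is the co-membership count matrix, symmetric with per-individual totals on
the diagonal.

Population comparison uses a Kruskal–Wallis rank test implemented from the
rank formula (mid-ranks, tie correction, chi-square approximation with
k − 1 df), cross-checked in the test suite against an independent
implementation to 1e−10. The all-ties degenerate case returns H = 0, p = 1.
The summary can be repeated with one named individual excluded — the manual
outlier-reanalysis pattern — by removing exactly that individual's
membership rows (its singleton clusters vanish; shared clusters lose one
member) rather than re-clustering.

## Gene proximity

Each unified junction is annotated with two windows: a *promoter* set
(genes whose TSS lies within 1 kb of the junction) and an *enhancer* set
(genes whose body lies within 1 Mb). Distance is measured from the junction
to the nearest gene boundary, zero when overlapping. "Downstream" for the
promoter rule is interpreted relative to LTR polarity by default — an LTR
promoter drives transcription off its 3′ end — with an unoriented fallback
used automatically for ambiguous clusters and available globally via
`promoter_oriented = FALSE`, since many real calls are unoriented. The
promoter set is a subset of the enhancer set by construction, and a site
with an empty enhancer set is an *orphan*. The interval-indexed
implementation is verified against a brute-force all-pairs scan.

## Expression overlay

The overlay asks whether genes near an LTR are differentially expressed
between carriers and non-carriers of that LTR. Counts are CPM-normalized
(`counts / library size × 1e6`); genes are retained when they reach ≥ 1 CPM
in at least 25% of samples (ceiling). The per-gene statistic is the
absolute log2 fold change of group-mean CPM, with a 0.5-raw-count
equivalent pseudo-CPM added to each group mean before the log.
Significance is assessed by label permutation (group sizes preserved,
`p = (1 + #exceedances) / (1 + n_permutations)`, default 10,000
permutations under a fixed seed), BH-adjusted, and a gene is called
significant only when `q ≤ 0.05` *and* `|logFC| ≥ 1`. This self-contained
permutation test is the package's declared replacement for a
negative-binomial GLM likelihood-ratio test: it is calibrated under the
null (verified empirically in the acceptance suite) and expresses a null
result faithfully, at the cost of power at small sample sizes — with 4 vs 4
samples the attainable p floor is 2/70, so multiplicity correction across
large gene panels is intentionally conservative.

Presence contrasts run only for clusters with at least 3 carrier and 3
non-carrier expression samples, separately for the promoter- and
enhancer-window gene sets. Presence is coded per *individual*: an
expression sample carries a cluster when its animal does, regardless of the
tissue the RNA came from.

## Reproducibility

Every stochastic stage derives its own substream from the single master
seed, so per-individual simulation does not depend on call order and an
identical configuration reproduces byte-identical outputs. `run_pipeline()`
writes a JSON manifest with the seed, all parameter values, per-stage
record counts and the conservation checks, alongside the per-stage TSV
tables.

## Known limitations

* The leader-clustering rule is one defensible resolution of an
  intransitive merge criterion; dense insertion regions near the tolerance
  will split differently under other rules.
* Orientation is undecidable for rectangular coverage profiles; such calls
  are retained as `ambiguous` and the annotation falls back to unoriented
  promoter windows.
* The simulator's background is uniform; real off-target coverage is
  structured (repeats, mapping artefacts), so real-data precision will be
  lower than the synthetic estimates.
* The permutation overlay trades power for calibration; it is a screen,
  not a substitute for a replicated designed expression study.
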