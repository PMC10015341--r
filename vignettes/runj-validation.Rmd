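---
title: "Validating predicted splice-altering mutations with RUNJ"
author: "spliceRUNJ"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating predicted splice-altering mutations with RUNJ}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Splice-site predictors assign each variant four delta scores — the
probability that it causes an acceptor loss (AL), donor loss (DL),
acceptor gain (AG) or donor gain (DG) — together with a signed offset
locating each predicted site relative to the variant. A score, however
well calibrated, is a prediction about DNA; the observable consequence
lives in RNA. This package tests the prediction directly in matched
RNA-seq: if a donor is lost, reads should run through the old exon–intron
boundary (intron retention) or use a substitute site; if a site is
gained, reads should splice at a coordinate no annotated transcript uses.

The test statistic is the Relative Usage of the Novel Junction:

$$\mathrm{RUNJ} = \frac{\#M_a}{\#M_a + \#M_n} - \frac{\#C_a}{\#C_a + \#C_n}$$

the abnormal-read fraction at the event position in the mutated sample
minus the pooled abnormal fraction in a control panel. Subtracting the
control fraction removes background from mapping artifacts, annotation
gaps and physiological intron retention at that locus. Two panels are
used: a panel of normals (PON, non-tumor samples) and a panel of tumors
(POT, tumors unmutated at the locus), the latter controlling for
tumor-specific expression and isoform effects that are not caused by the
mutation under test.

A prediction is validated iff all three criteria hold:

1. at least `minReads = 2` abnormal reads in the mutated sample;
2. RUNJ against the PON reaches `minRunj = 0.01` in direct **or** all
   mode;
3. RUNJ against the POT reaches 0.01 in direct **or** all mode, **or**
   the POT is not applicable (no eligible tumor, or no informative POT
   coverage at the position).

## Read classification

For every event an *evaluation position* `p` is fixed: the first intronic
base of the lost site for DL/AL (so every crossing read is forced to show
either the canonical junction or retention), and the novel site itself
for DG/AG. Reads crossing `p` with MapQ ≥ `minMapq = 20` — including
reads whose N-gap splices over `p` — are retrieved from the BAM;
duplicates and secondary/supplementary alignments are dropped.

Each read is then called in one of two modes.

* **direct** — abnormal only for the event's most direct consequence:
  aligned bases on both sides of the lost boundary (retention) for
  DL/AL, or a junction whose splice edge sits exactly at the novel site
  for DG/AG. Normal means the canonical junction at the boundary (or,
  for gains, contiguous alignment through the novel site). Reads showing
  *other* non-canonical patterns are uninformative in this mode: the
  direct score deliberately measures one mechanism.
* **all** — abnormal for *any* non-canonical pattern at the boundary:
  the direct consequence, a junction absent from the canonical junction
  set whose intron overlaps the boundary (cryptic-site usage, exon
  skipping), or retention across the canonical boundary. This catches
  the common situation where a donor loss is resolved through a cryptic
  donor rather than retention.

The published partition of crossing reads is binary
(normal/abnormal). We add an explicit third bucket, **uninformative**,
excluded from both numerator and denominator: reads soft-clipped within
`clipWindow = 3` bp of the decision point (the aligner gave up exactly
where the evidence is), and reads that neither span the decision point
with aligned bases nor carry a junction bearing on it. Forcing such
reads into either class would inject noise with no information content;
the deviation is deliberate and configurable only through the clip
window. Counting is fragment-level: mates sharing a read name are merged
and a fragment is abnormal if either informative mate is, so a junction
on one mate cannot be outvoted by its partner.

Junction matching against the canonical set is exact-coordinate. A
tolerance window would absorb genuine novel junctions a few bases from
an annotated one — precisely the events of interest — whereas alignment
slop at spliced anchors is already absorbed by the uninformative
clip rule.

## Parameters and conventions

| parameter | default | meaning |
|---|---|---|
| delta-score threshold | 0.5 | minimum score for a significant event (inclusive) |
| `minReads` | 2 | abnormal read support, criterion (i), from the all-mode count |
| `minRunj` | 0.01 | RUNJ threshold, criteria (ii)/(iii), applied to the signed value |
| `minMapq` | 20 | minimum mapping quality |
| panel size | 5 | PON/POT samples pooled by summing counts |
| `clipWindow` | 3 bp | clip-based uninformative window |

Decisions the published procedure leaves open, and the choices made here:

* **Ties on the maximal delta score** are broken by the fixed order
  AL > DL > AG > DG, for determinism.
* **Zero denominators**: no informative tumor coverage gives `NA` (the
  event is untestable); zero control coverage sets the control fraction
  to 0 and raises a `low_control_coverage` flag, so sparsely covered
  loci remain assessable but auditable. Criterion (iii) treats a
  zero-coverage POT as not applicable.
* **Criterion (i)** uses the all-mode abnormal count, the superset of
  direct; this is configurable via the returned per-mode counts.
* **Signed RUNJ**: the 0.01 threshold is applied to the signed value as
  written; a control excess (negative RUNJ) can therefore never
  validate.
* **Position conventions** (strand-aware, transcript orientation):
  donor-relative coordinates put 0 on the last exonic base and +k on the
  k-th intronic base; acceptor-relative coordinates use −k for the k-th
  intronic base upstream and +k for the k-th exonic base, with no 0.
* **Overlapping transcripts**: boundaries come from the transcript
  flagged canonical in the annotation, else the transcript with the
  largest summed exon width.
* Intervals are handled 1-based inclusive end to end (the native
  convention of VCF, GTF and Bioconductor ranges); junctions are stored
  as intron intervals derived from N CIGAR operations only — deletions
  never create junctions.

## Signature attribution

Mutations are classified into the 96 SBS trinucleotide contexts
(pyrimidine-strand convention). Given per-sample signature exposures
$e_{j,s}$ (taken as input — extraction is out of scope) and a catalog of
context profiles $f_s(c)$, each mutation is attributed by

$$P(s \mid m) = \frac{e_{j,s}\, f_s(c_m)}{\sum_{s'} e_{j,s'}\, f_{s'}(c_m)},$$

a row-stochastic matrix. The contribution of a signature to a mutation
set is $\sum_{m \in S} P(m,s)$, so splice and non-splice contributions
add exactly to the total. Enrichment of a signature in splice mutations
(essential splice annotations plus cryptic events with delta score
≥ 0.5) is tested with a two-sided Wilcoxon rank-sum test on the pooled
per-mutation $P(m,s)$ values, as the comparison is stated — an
alternative would aggregate per sample first; the pooled form is what we
implement and report. Raw p-values are reported, with a
Benjamini–Hochberg column alongside for convenience.

## What the simulator emulates — and what it does not

The simulator builds a three-exon gene (exons 501–1000, 1201–1700,
1901–2400 on a 3000 bp contig, either strand) and emits pre-aligned
reads with analytically constructed CIGARs: canonical junction reads,
retention reads, cryptic-site junctions at configurable offsets
(including the donor positions 0 and +5), exon-skipping reads, and
boundary-clipped reads. Reads carry per-read truth labels assigned at
construction time, independently of the classifier, so classification
accuracy is measured against ground truth rather than self-consistency.
Abnormal reads appear with a controllable fraction `f`; panels are
simulated per sample with seeds derived from a master seed, and
identical seeds reproduce byte-identical SAM output.

Deliberately absent: sequencing errors and base-quality variation,
alignment (reads are never passed through an aligner, so aligner-induced
soft-clip rescue and multi-mapping are not exercised), expression-level
realism, overlapping genes, and multi-isoform loci beyond the canonical
junction set. Passing tests therefore demonstrate that the counting and
decision machinery is correct on unambiguous evidence and that ambiguous
(clipped) evidence is excluded — not that any particular aligner's
output is handled optimally.

## Problem sizes used in the checks

The test suite and the acceptance script run entirely on simulated data:
1000 random count quadruples for the RUNJ formula oracle; all 8
criteria combinations plus the POT-not-applicable branch; 200 reads per
class × 5 classes × 4 event types for classification accuracy;
abnormal-fraction recovery at f ∈ {0.05, 0.12, 0.30, 0.80}, depth 200,
20 seeds each against clean 5-sample panels (within 3 binomial standard
errors, ≥ 19/20 seeds); 2000 mutations for the 0.7/0.3 signature-mixture
recovery; and 200 replicates for the Wilcoxon null calibration. These
sizes keep the full suite under a minute of simulation-heavy work per
module while leaving the statistical checks well-powered.

## Known limitations

* RUNJ is a fixed-threshold decision rule, not a significance test; no
  per-event p-value is attached, and power at low coverage is limited by
  criterion (i) rather than by an explicit error model.
* Exact junction matching means an annotation missing a genuine minor
  isoform will count its junction as abnormal; the POT criterion is the
  intended guard against such locus-specific background.
* The attribution model assumes the exposure vector is correct for the
  sample and that contexts are independent given the signature; it
  redistributes, but cannot repair, a misspecified catalog.
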