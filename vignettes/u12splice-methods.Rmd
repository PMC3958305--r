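---
title: "Detecting minor-spliceosome splicing deficiency from RNA-seq"
author: "u12splice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting minor-spliceosome splicing deficiency from RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(u12splice)
```

## Background

U12-type introns are a rare intron class (fewer than 0.5% of human introns,
roughly 900 introns in about 700 genes) excised by the minor spliceosome.
They almost always co-occur with ordinary U2-type introns in the same gene,
which makes the gene its own control: when minor-spliceosome function is
impaired -- for example by mutations in one of its protein components --
U12-type introns are spliced less efficiently and retained more often,
while the U2-type introns of the same transcript are processed normally.
Failed U12 splicing also provokes aberrant rescue processing: activation of
nearby cryptic U2-type donor or acceptor sites inside the U12 intron, and
skipping of the exon adjacent to it.

`u12splice` implements this comparison as a reusable pipeline over aligned
RNA-seq: per-gene splicing-efficiency and intron-retention metrics, a
case-versus-control outlier ranking, and detection and classification of
aberrant processing events. Because the patient data motivating this class
of analysis are generally not publicly deposited, the package ships a
seeded spliced-read simulator with a complete per-molecule truth table, and
its entire test suite runs against that known ground truth.

## The four metrics

For each gene with an annotated U12-type intron, two U2-type *reference*
introns of the same (canonical) transcript are selected -- the introns
immediately upstream and downstream of the U12 intron in transcript order,
falling back to the two nearest U2 introns on one side when the U12 intron
has no U2 neighbour on the other. Genes that cannot provide two U2
references are excluded with a reason code.

Per sample, with $J$ a split-read (junction) count, $D$ a mean intron-body
read depth and $F$ the gene's FPKM:

* splicing efficiency
  $\;r_{U12/U2} = \dfrac{J_{U12}}{\tfrac12 (J_{U2a}+J_{U2b}) + c}$ and
  $\;r_{U12/F} = \dfrac{J_{U12}}{F + c}$,
* intron retention
  $\;IR_{U2} = \dfrac{D_{U12}}{\tfrac12 (D_{U2a}+D_{U2b}) + c}$ and
  $\;IR_{F} = \dfrac{D_{U12}}{F + c}$,

where $c$ is a pseudocount (default 0.5) applied to denominators only:
numerator zeros are biologically meaningful (no expression, or complete
splicing failure with full retention), while zero denominators are
measurement artifacts at low coverage. Genes with several U12-type introns
are averaged arithmetically across introns.

A split read supports a junction only when one of its skip (CIGAR `N`)
operations matches the intron span exactly and carries at least
`min_anchor` (default 6 bp) aligned bases immediately on both sides; reads
skipping a superset region (e.g. exon-skipping reads) are counted as
events, not as canonical junction support. Intron-body depth is mean
per-base coverage by aligned segments over the body trimmed by `edge_trim`
(default 10 bp) at each end, so that alignment wobble at exon boundaries
does not leak into the retention signal. FPKM is computed internally as
reads whose leftmost position falls in the canonical exon union, per kb of
exonic length, per million mapped fragments; it is used only as a within-sample
per-gene normalizer, so any monotone proxy of expression would serve.

## Cohort comparison

Genes must first be *detected*: FPKM at least `min_fpkm` (default 1) and
the two reference junctions together carrying at least
`min_ref_junction_reads` (default 10) split reads, in **every** sample.
Genes whose control samples are too variable are then discarded: for each
metric the coefficient of variation across control samples is computed and
the gene is dropped if any metric exceeds `cv_max` (default 0.5). This
operationalizes "high variability in controls"; the threshold is exposed
because no canonical value exists.

For each remaining gene and metric,

$$z = \frac{\bar x_{case} - \bar x_{control}}{\max(s_{control},\; s_{floor})}$$

with the sample standard deviation over controls and a small floor
(`sd_floor`, default 1e-6) preventing division by zero when controls are
identical. A metric is flagged when $z \le -2$ for the two efficiency
metrics or $z \ge +2$ for the two retention metrics -- deficiency is
directional: efficiency falls, retention rises -- and a gene is flagged
when at least `min_metrics` (default 2) of the four metrics are flagged.
A two-sided mode is available. Flagged genes are ranked by their largest
flagged $|z|$, ties broken by gene id so the ranking is deterministic. No
multiple-testing correction is applied: the procedure is an
SD-threshold rank, not a hypothesis test, and should be read as a
prioritization, not as calibrated significance.

By default the case statistic is the mean over case samples, matching a
small-cohort group comparison (two cases against four controls). The
alternative `case_aggregation = "all"` scores each case sample separately
and reports the least extreme one, so a flag requires every case to exceed
the threshold.

## Aberrant event detection

All skip spans within a gene's extent that match no annotated intron (any
transcript) are collected under the same anchor rule, and kept with at
least `min_support` (default 3) reads. Each novel junction is classified
against the gene's U12-type intron, strand-aware:

* shares the U12 donor, acceptor within `window` (default 100 bp) of the
  U12 acceptor: cryptic acceptor activation (`cryptic_3p`);
* the mirror case: cryptic donor activation (`cryptic_5p`);
* runs from an annotated donor to a non-adjacent annotated acceptor across
  the U12 intron: `exon_skip`;
* anything else: `other`.

Event abundance is reported as `support / (support + canonical)` -- the
fraction of junction-spanning transcripts using the aberrant junction
rather than canonical U12 splicing -- per sample and pooled by condition.
Events with pooled control fraction below 1% and pooled case fraction
above 5% are marked case-exclusive. The fraction is read-level; at equal
isoform lengths it estimates the transcript-level fraction, and the
residual length bias is below a few percent for cryptic events (which
change isoform length by at most ~90 bp) but can be larger for exon
skipping (see Limitations).

## The simulator

`simulate_gene_set()` draws gene structures of 4--8 exons (80--300 bp)
separated by introns of 200--2000 bp, placed without overlap on synthetic
chromosomes with random strand. 90% of genes carry exactly one U12-type
intron at an internal position (so both flanking U2 references and exon
skipping are always defined); the rest are all-U2 negative controls. Each
U12-bearing gene is assigned once, as a property of its sequence, an
aberrant mode: a cryptic donor or acceptor 30--90 bp inside the U12 intron,
or skipping of the exon on the intron's 5' side. Affected
(splicing-deficient) genes are drawn once per simulation and shared by all
case samples.

Per sample and gene, the fragment count is negative binomial around the
gene's expression level; each molecule is assigned a class at the U12
intron *hierarchically*: retained with probability $r$, otherwise aberrant
with probability $q$, otherwise canonical. The hierarchy makes the
aberrant share a fraction of **spliced** molecules, so the read-level
event fraction estimates $q$ directly. U2-type introns are retained
independently at the baseline rate in every sample and condition. One
100-bp single-end read per molecule is placed uniformly along the
molecule's isoform and projected to genomic match/skip operations; output
is coordinate-sorted SAM with deterministic seeded bases. Paired-end
simulation is deliberately omitted: junction counting and depth are
read-level, so mates add coverage but no new structure.

Default study conditions, chosen once:

| parameter | default | rationale |
|---|---|---|
| `read_length` | 100 | typical short-read RNA-seq |
| `n_case_samples` / `n_control_samples` | 2 / 4 | small patient-vs-control cohort |
| `mean_fragments_per_gene` | 2000 | depth of a moderately expressed gene in a ~30M-fragment library |
| `expression_spread` (lognormal sdlog) | 0.5 | between-gene spread of the detected, moderately expressed gene set |
| `expression_dispersion` (NB size) | 20 | ~22% biological CV between samples |
| `baseline_retention` | 0.02 | low but nonzero background intron retention |
| `baseline_cryptic` | 0 | cryptic sites silent under normal splicing |
| `case_retention`, `case_cryptic` | 0.3 | strong deficiency; upper end of the <5--30% aberrant range |
| `affected_gene_fraction` | 0.04 | 20 deficient genes among 500 |

RNG discipline: one master seed; each sample derives a sub-seed from the
seed and the sample id, and within a sample each gene re-seeds its own
substream. Matched designs (same seed, one parameter varied) therefore
stay matched gene by gene, and every fixed-seed run is byte-identical.

## Numerical and design choices

* **Coordinates.** All internal tables are 1-based inclusive, the native
  convention of GTF, SAM and the R interval stack used for counting and
  coverage; conversions happen only at I/O boundaries (which, for these
  formats, are identity).
* **Intron typing** comes only from the annotation table; introns of
  unknown type are ineligible as U2 references, and genes that cannot
  obtain two references are excluded with a logged reason rather than an
  error.
* **Canonical transcript**: largest exonic length, ties by smallest
  transcript id -- deterministic and independent of input order. The
  intron chain of that transcript defines intron indices and reference
  selection.
* **Degenerate inputs**: a sample with zero mapped reads is rejected with
  a clear message; introns shorter than twice the edge trim yield `NA`
  depth with a reason code; an empty annotation table leaves all introns
  unknown and the quantifiable set empty.
* **Problem sizes.** The test suite exercises cohorts of 500 genes
  (about 6 million reads across 6 samples) for the discrimination and
  null-calibration checks, 10,000-molecule genes for parameter-recovery
  checks, and ~20k-read cohorts for exact oracle-equivalence checks
  against brute-force recomputation.

## Limitations

* The simulator emulates the statistical structure the analysis relies on
  -- expression variation, class mixtures, junction and body coverage --
  but not alignment artifacts: no sequencing error, no mappability gaps,
  no multi-mapping, no soft-clipping, one isoform backbone per gene.
  Passing tests demonstrate correctness of the quantification and ranking
  given faithful alignments, not robustness to aligner failure modes.
* Read-level event fractions are biased for exon skipping when the
  skipped exon is a large share of the transcript (the shorter isoform
  yields proportionally more junction-spanning reads per molecule); the
  bias is bounded by the isoform length ratio.
* The control-variability filter trades recall for specificity: genes
  whose U12 intron is short accumulate few intron-body reads in controls,
  their retention CV estimate is count-noise limited, and truly affected
  genes can be discarded before ranking. At the default study conditions
  this is the dominant cause of missed deficient genes.
* With four controls, the control SD is itself noisy; directional 2-SD
  flags on two correlated metric pairs yield a few percent false flags
  under the null, and the flagged fraction should be read accordingly.
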