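---
title: "Quantifying alternative-promoter usage from splice junctions: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying alternative-promoter usage from splice junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promusage)
library(dplyr)
```

## The problem

Genes with many alternative first exons — *TCF4* is the motivating case,
with at least 18 N-terminally distinct protein isoforms — cannot be usefully
summarised by a single expression value. Which promoter fired matters: in
*TCF4*, a CTG trinucleotide-repeat tract sits in the intron between internal
exons 3 and 4, immediately upstream (in transcript orientation) of the 5′
exons 4a, 4b and 4c, and its expansion causes Fuchs' endothelial corneal
dystrophy. The analytically useful signal is therefore *per-5′-exon* usage,
and the natural evidence for a 5′ exon is the splice junction that joins it
to its internal acceptor exon: a read spanning that junction is unambiguous
proof that this particular first exon was used.

This package implements that junction-centric quantification and the
statistics for comparing it between a disease and a control cohort across
two independent experiments, plus two companions: classification of
promoters as focused vs dispersed from transcription-start-site (TSS)
positions, and the repeated-measures statistics for dual-luciferase
promoter-reporter series.

## Quantification model

### Filtering

Junction support is the count of uniquely mapped junction-spanning reads
(multimappers excluded). Two filter stages, both with "at least" (≥ keeps)
semantics so a row exactly at a threshold survives:

* **dataset level** (`filter_config()`): drop mitochondrial junctions
  (`chrM`/`MT`), non-canonical intron motifs, and junctions with fewer than
  6 reads summed over the whole dataset. "Dataset" means one experiment's
  samples; the two cohorts are filtered independently.
* **gene level**: inside the gene region only, drop junctions with fewer
  than 4 dataset-wide reads. Junctions outside the region are untouched.

The defaults (6 and 4) are the conventional support floors for
junction-level quantification at these sequencing depths; both are
parameters.

### Normalization

Per-sample values are junctions per million spliced reads (jpm):
`count / total × 10⁶`, where the total is the sample's genome-wide sum of
junction reads. The denominator is fixed **after dataset-level filtering
but before gene-level filtering**. The ordering had to be pinned down to be
testable; this choice reads the denominator as "the library's spliced
depth after quality filtering", so that dropping a handful of weak in-gene
junctions cannot change every other value in the gene. Because the gene
filter removes only a vanishing fraction of a multi-million-read
denominator, the alternative ordering differs negligibly in practice; the
denominator population is an explicit argument (`normalize_jpm(jx,
totals)`) for anyone who wants the other convention.

### Extended exons

Some 5′ exons are *extended exons*: transcription starts upstream of an
internal exon and reads straight into it, so there is no junction to count.
These are quantified as reads *crossing* a 2-bp window immediately
transcript-upstream of the internal exon. Two conventions, both
deliberate:

* "upstream" is resolved in transcript orientation — on a minus-strand gene
  the window is `[exon_end, exon_end + 2)` in genomic coordinates;
* "crossing" requires one aligned block to cover **both** window bases. A
  spliced read whose intron gap spans the window is evidence of splicing,
  not of exon extension, and must not count; neither does a block touching
  only one of the two bases.

Window counts are normalized with the same per-sample denominator and enter
the event table as ordinary rows, so they ride the same statistics and the
same plots as junction events.

### Aggregation

Events are labelled `"<5′exon>-<acceptor>"` (`"4aI-4"`, `"3b-3"`) and
internal-exon junctions `"N-M"` (`"6-7"`). Event-level usage is the sum of
the member junctions' jpm values; isoform-group usage sums events that
encode the same protein isoform (rows labelled `none` are excluded at the
isoform level). Aggregation is linear in the input, which the tests exploit
as an invariant.

## Differential statistics

### Tier 1: within-experiment Mann–Whitney

Per event and experiment, CTRL vs FECD jpm values are compared with a
two-sided Mann–Whitney U test. With 6–9 samples per group the exact null
distribution is both feasible and preferable: the implementation uses the
exact p whenever `min(n) ≤ 8` and the pooled values are tie-free, and the
normal approximation with tie and continuity corrections otherwise.
Normalized continuous values are effectively always tie-free, so at the
study's group sizes the exact branch is the operative one. p-values are BH-
adjusted across the members of a *test family* — the set of events shown
together (one aggregation level) — within each experiment.

### Tier 2: combined Gamma GLM

Pooling both experiments, each event's values are fitted with

```
jpm + 0.01  ~  Experiment + Disease + Experiment:Disease,   Gamma family
```

and the Disease coefficient is tested with a two-sided Wald test, BH-
adjusted across the family. Design choices worth stating:

* **Shift.** The +0.01 is applied at fit time only — jpm values can be
  exactly zero, which the Gamma support excludes. The Mann–Whitney tier
  sees unshifted values (a monotone shift would not change it anyway).
* **Link.** The inverse link, the canonical Gamma GLM default, is used;
  `link = "log"` is available. With the fully crossed 2×2 factor design
  the fitted cell means are identical under either link; only the
  coefficient scale and its Wald standard error differ.
* **Tested coefficient.** With the interaction in the model and treatment
  coding, the Disease main effect is the disease effect *at the reference
  experiment* (alphabetically first). This is the literal reading of
  "test Disease in Experiment + Disease + Experiment:Disease"; a joint
  test of Disease plus interaction would answer a different question and
  is not what a single disease-state p-value per event implies.
* **Degenerate inputs.** A design missing an experiment, a disease level
  or a whole cell is refused with an error. A constant response (zero
  dispersion) returns coefficient 0 with p = 1 — no evidence, not a crash.
  Non-convergence returns a flagged result with `p = NA`.

Directions (`up`/`down`/`flat`) are the sign of the FECD-minus-CTRL median
difference, per experiment and pooled.

## TSS dispersal and repeat positioning

A *dispersed* promoter initiates transcription over a region on the order
of 100 nucleotides rather than at one focused start. The literature gives
the ~100-bp figure but no formal rule, so the package fixes one:
dispersed ⇔ spread (max − min position) ≥ 100 bp **and** ≥ 3 distinct
TSSs. The second clause is this package's convention: two isolated starts,
however far apart, are two focused starts, not a spread initiation region.
The rule is monotone — adding a TSS can never flip dispersed back to
focused — which the tests check property-style.

`repeat_in_any_utr()` asks whether any TSS lies transcript-upstream of the
repeat tract's far edge, i.e. whether any transcript would carry the repeat
in its 5′ UTR. A TSS exactly at the repeat boundary does *not* place the
repeat in the UTR (strict inequality) — a deterministic tie-break, flagged
as a convention rather than biology.

## Reporter statistics

Dual-luciferase measurements are normalized twice: firefly/Renilla within
the well (transfection-efficiency control), then to the 11-repeat
construct's ratio within the same promoter panel and independent
experiment. The 11-repeat rows are therefore exactly 1, and any
experiment-wide rescaling cancels.

The repeat-length series is tested with one-way repeated-measures ANOVA
using the independent experiments as subjects — the only repeated unit in
the design — with the Greenhouse–Geisser ε estimated from the
double-centered condition covariance matrix. ε is clipped to its
theoretical range `[1/(k−1), 1]` and equals 1 exactly at k = 2. F and ε
are computed from textbook sums-of-squares formulas; an independent
`stats::aov`-based oracle in the test-suite confirms both to 1e-8.

Dunnett's many-to-one comparisons against the 11-repeat control use the
pooled within-subject mean square with `(n−1)(k−1)` degrees of freedom and
the equicoordinate multivariate-t adjustment (equicorrelation 1/2 for equal
group sizes). The multivariate-t probability has no closed form; it is
evaluated numerically to an absolute tolerance of 1e-4 (a fixed internal
substream keeps the quadrature reproducible). With one comparison the
adjusted p reduces analytically to the paired t-test, which the tests
assert. The two promoter panels are analysed independently — they are
separate constructs answering separate questions, so no cross-panel
multiplicity is imposed.

## What the simulator does and does not emulate

`simulate_dataset()` reproduces the *structure* of the motivating study:
two experiments of 6/8 and 9/6 CTRL/FECD samples; negative-binomial
(Gamma-Poisson) junction counts, size parameter 10 by default — a standard
overdispersed RNA-seq count model whose normalized values the Gamma GLM
approximates well; per-sample library sizes uniform on 1–3 million spliced
reads (baseline event means are expressed as expected counts at a 2-million
reference depth and scale linearly with depth); and a disease profile with
the reported direction pattern — events immediately downstream of the
repeat and 5′ exons spliced directly to exon 4 at fold 0.3, the extended
exon 4c, exon-3-spliced and distal 5′ exons and the internal 10–16 chain at
fold 3, and a few events flat. Baseline magnitudes are order-of-magnitude
choices (tens to low hundreds of reads per junction), since only relative
changes are identifiable from the published figures; they were fixed once
and are not calibrated further. Background is one aggregate pseudo-junction
carrying the bulk of the library plus 50 decoys (mitochondrial,
non-canonical, low-count, and clean) so every filter branch is exercised by
generated data. One master seed drives everything; per-sample streams are
derived by stable hashing of the sample id, so output is independent of
generation order and byte-identical across runs.

`simulate_reporter()` needs effects at every repeat length, but only the
144-repeat reductions (to 0.30 and 0.25 of control for the two promoters)
are anchored; the intermediate lengths use a monotone dose response
(1, 0.95, 0.9, ~0.6, ~0.5 → 144) chosen once as the qualitative pattern of
a length-dependent repressive element. Signal noise is multiplicative
log-normal at 10% CV per luminescence reading.

What passing tests therefore *do* show: the pipeline computes its stated
definitions exactly, controls its error rates under a true null at the
study's sample sizes, and recovers planted effects of the study's
magnitude. What they do *not* show: robustness to features real corneal
RNA-seq has and the simulator lacks — batch structure beyond the experiment
factor, GC/length biases, correlated junction usage within transcripts,
mapping artefacts, or outlier samples.

## Problem sizes and numerical conventions

The test-suite runs the oracle-equivalence checks on 100 random ≤20×6
matrices, the exact Mann–Whitney enumeration over all group sizes with
n₁+n₂ ≤ 12, 1,000 random BH vectors, 200 null-calibration and 50
effect-recovery pipeline replicates at the full 29-sample design, 500 GLM
bias replicates at 50 samples per cell, and 200 reporter replicates —
sizes at which the Monte-Carlo bounds quoted in the tests are sharp enough
to be meaningful while the whole suite stays fast. Other conventions:
coordinates are 0-based half-open internally with conversion at every file
boundary; junction identity is the exact (chrom, donor start, acceptor
end, strand) 4-tuple with no fuzzy matching, mirroring how curated
junction annotations are constructed; jpm conservation is asserted to
1e-6 relative; the RM-ANOVA oracle agreement to 1e-8; the Dunnett
multivariate-t to 1e-4.

## Known limitations

* Junction evidence cannot see promoters whose first exon splices to the
  same acceptor at identical coordinates as another; such events need the
  extended-exon window mechanism or external TSS data.
* The Gamma GLM treats samples as independent within experiments; no
  random effects, no shrinkage across events.
* The Mann–Whitney exact/asymptotic switch follows sample size and ties
  only; heavily tied data at small n fall back to the corrected normal
  approximation.
* The simulator's flat-profile calibration bounds are Monte-Carlo
  statements, not proofs; they carry the quoted MC error.
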