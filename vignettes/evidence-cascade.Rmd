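---
title: "The evidence-integration cascade: model, nulls and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The evidence-integration cascade: model, nulls and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmjcascade)
```

## The problem

During muscle regeneration, proliferating primary myoblasts run a
transcriptional program in which the transcription factor Runx1 cooperates
with MyoD and c-Jun at a shared set of regulatory regions. Identifying
which genes this program actually controls requires combining several
noisy genome-wide assays, none of which is conclusive alone: a
differential-expression contrast (Runx1-deficient vs wild type), ChIP-seq
peak sets for the three factors, histone-mark ChIP-seq (H3K4me1, H3K27ac)
delineating active enhancers, and ATAC-seq marking nucleosome-free open
chromatin. `rmjcascade` implements the staged intersection of these
evidence layers as a tested, reusable pipeline, together with the
significance machinery for each intersection and a synthetic-data
generator that makes the whole cascade verifiable against planted ground
truth at desk scale.

## The cascade

`run_cascade()` executes four nested selection stages plus an optional
in-vivo cross:

1. **Responsive genes.** From a gene-level table of log2 fold changes and
   BH-adjusted q-values, keep genes with `qvalue < q_max` and linear fold
   change strictly above `fc_min` (defaults 0.1 and 1.5; the in-vivo
   contrast uses 0.05 and 1.7). Both inequalities are strict, matching how
   such thresholds are conventionally printed ("q < 0.1, > 1.5-fold").
2. **Regulated genes.** Responsive genes with at least one Runx1 peak
   anchor within 200 kb of their TSS (window inclusive at exactly
   200,000 bp).
3. **RMJ-regulated genes.** Stage-2 genes near a region co-occupied by all
   three factors. Co-occupancy is region-level: the union of the three
   peak sets is collapsed into merged clusters and a cluster counts as
   RMJ when each factor contributes at least one interval
   (`rmj_regions()`). The enrichment of the intersection is scored with
   the exact hypergeometric tail over the full annotation.
4. **High-confidence genes.** Stage-3 genes with a supporting RMJ region
   that is both an active enhancer (overlaps H3K4me1 *and* H3K27ac) and
   open chromatin (overlaps ATAC). A Monte Carlo set test provides the
   empirical significance of the final intersection.

The optional in-vivo stage intersects the RMJ-regulated set with a second,
independently thresholded expression contrast (e.g. a dystrophic-muscle
model), recording both parents in the result's provenance.

Nesting (`high_confidence ⊆ rmj_regulated ⊆ regulated ⊆ responsive`, and
`in_vivo ⊆ rmj_regulated`) is asserted on every run. Because stage 3 is
defined on merged-cluster anchors while stage 2 uses Runx1 peak anchors, a
cluster midpoint could in principle sit marginally inside the window while
every Runx1 summit sits marginally outside; `run_cascade()` therefore
computes stage 3 as a refinement of stage 2 (genes co-occupied by all
three factors are in particular Runx1-bound), which makes the nesting
guarantee structural rather than approximate.

### Two deliberately open readings, and the defaults chosen

* **Gene assignment for stage 3** defaults to the triple-overlap-cluster
  reading (`rmj_mode = "cluster"`): the three factors must share one
  merged region. The alternative (`"independent"`) — a gene separately
  within 200 kb of a peak of each factor — is available behind the config
  switch, because the region-level conjunction is the stricter and more
  mechanistically interpretable reading.
* **Chromatin support for stage 4** defaults to region-level conjunction
  (`conjunction = "region"`): one and the same RMJ region must carry both
  the histone marks and the ATAC signal. The `"independent"` switch lets
  the marked region and the open region be different RMJ regions near the
  same gene. The stricter reading is the default for the same reason.

## Peak-to-gene logic

Every distance is measured from a single-bp **anchor**: the narrowPeak
summit when present, else the interval midpoint
`floor((start + end) / 2)`. The summit is the best point estimate of the
binding site; the midpoint is the determinate fallback. `bound_genes()`
also accepts `anchor = "edge"` (whole-interval overlap with the window)
for the edge reading of "within 200 kb".

Distances are unsigned — the distance classes are symmetric around the
TSS: promoter (`d ≤ 1 kb`), proximal (1–10 kb), distal (10–100 kb), gene
desert (> 100 kb), each bin closed on its right edge. Ties between
equidistant genes resolve to the lexicographically smallest `gene_id`, so
assignments are deterministic. Peaks on chromosomes absent from the
annotation are reported as unassigned, never silently dropped, and
chromosome names are taken literally: a naming mismatch between inputs is
an error rather than a silent empty join.

## Resampling nulls and empirical p-values

**Bootstrap overlap test.** The null for region-set overlap relocates
every subject interval independently and uniformly within its own
chromosome, preserving interval lengths and per-chromosome counts;
relocated intervals may overlap each other. This is the simplest
well-calibrated genomic null; alternatives (gap-preserving shuffles,
exclusion masks, covariate matching) deliberately live outside this
package and can be slotted in behind the same operation. The statistic is
the number of query regions overlapped.

**Monte Carlo set test.** The null for a gene-set intersection draws two
sets of the observed sizes uniformly without replacement from the
universe, independently per iteration; the statistic is the intersection
size, whose null mean is `|A||B|/N`. The universe is all genes in the
supplied annotation — the only defensible default when no background list
is given.

Both tests report the add-one empirical p-value
`(1 + #{null ≥ observed}) / (1 + n_iter)`. It is never exactly zero, and
the smallest reportable value is `1/(n_iter + 1)`; claiming `p < 1e-4`
therefore requires `n_iter ≥ 10,000`, which is the cascade default. Both
nulls are reproduced bit-identically under a fixed seed, and the null
statistics can be dumped for audit (`write_null_distribution()`).

Overlap itself requires at least one shared base pair under the half-open
convention, so book-ended regions do not overlap; `merge_regions()`, in
contrast, does merge book-ended intervals, matching common interval-tool
semantics. Both conventions are pinned by tests.

## Motif scanning and modules

Motifs are IUPAC consensus strings scanned exactly (`scan_consensus()`),
on both strands, with overlapping matches reported; `N` in a sequence
never satisfies a non-`N` motif position. The default library holds
conventional literature consensi — RUNX `TGYGGTY`, MyoD E-box `CAGCTG`,
AP-1 `TGASTCA` — and is user-extensible through a TSV table. This
consensus-scanning stand-in makes module logic exactly testable; it is
explicitly not a reimplementation of de-novo discovery or commercial
module-mining tools, and its rankings are not claimed to reproduce
theirs.

A region contains an (anchor, partner) **module** when some partner-match
midpoint lies within ±50 bp (configurable) of some anchor-match midpoint.
Significance comes from a per-region mononucleotide shuffle preserving
each region's exact base composition — the simplest seed-stable sequence
null; the shuffler is a separate function so a dinucleotide-preserving
variant can replace it. Fold enrichment is the observed module-region
count over the null mean.

## The synthetic generator

`generate_dataset()` builds, from one seed: a toy genome (default
2 × 10 Mb); 500 genes with TSSs placed uniformly at ≥ 20 kb spacing (so
the distance classes are populated non-degenerately); 1000 Runx1 peaks
with truncated-normal lengths (200 ± 50 bp, min 50); MyoD and c-Jun peaks
co-planted at Runx1 peaks with probabilities 0.46 and 0.47 (the
co-occupancy rates reported for primary myoblasts) plus 500 independent
background peaks each; both histone marks planted together at 70% of
peaks and ATAC at 25%, plus 200 background regions per track; an i.i.d.
uniform-ACGT genome in which a concrete RUNX instance (`TGTGGTT`) is
written at 95% of peak centers and an E-box partner within the ±50 bp
module window at 60% of anchor-bearing peaks (instances are written
exactly, without degeneracy sampling, so scanner tests are unambiguous);
and two expression tables.

Expression is simulated through z-statistics rather than by stamping
q-values: every gene draws `z ~ N(0,1)`; responsive genes — chosen with
probability 0.30 if a Runx1 anchor lies within 200 kb of the TSS and 0.05
otherwise — have the z shifted by `effect_size / lfc_se` (defaults
1.5 / 0.25 = 6) with a sign set by the direction bias (0.75 up for the
culture-like table, 0.87 for the in-vivo-like one, the directional splits
reported for the two contrasts). The emitted `log2fc` is `z · lfc_se` and
the emitted `qvalue` is the BH adjustment of the two-sided normal
p-values, so the q-value column has realistic rank structure and is
exactly coupled to the fold changes. The BH step belongs to the
generator, not the pipeline, which consumes q-values as given.

Ground truth (per-peak co-planting, mark and openness labels; per-gene
bound/responsive/direction labels; planted motif positions) is emitted
alongside, and `recovery_report()` scores every cascade stage against it.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: read-level noise and peak-calling artifacts,
fragment-size effects, GC and mappability biases, correlated placement of
peaks with gene density, dinucleotide structure of real sequence, and
inter-gene expression correlation. The generator validates the *logic and
calibration* of the cascade, not the biology of any particular dataset.

Two emergent properties of the toy conditions are worth knowing. First,
at the default peak density (1 peak per ~20 kb) a ±200 kb window
saturates: essentially every gene has some Runx1 peak nearby, so the
bound fraction of responsive genes approaches 1 and the stage-3/stage-4
set tests are not expected to be significant — enrichment reappears as
soon as windows are narrowed or peak density lowered, and the planted
binding–expression *link* is still fully visible to `recovery_report()`.
Second, measured fractions sit slightly above their planted probabilities
because background features can also hit a peak by chance (about +1% for
co-occupancy, less for motifs); the recovery tests use 3-SD binomial
bands, which absorb this.

The **zero-signal configuration** (`zero_signal_config()`) used for
calibration sets every co-planting, mark, openness and motif probability
to 0 and makes the responsive rate identical for bound and unbound genes.
Taken literally, "all probabilities zero" would also empty the responsive
set and make calibration unfalsifiable (the observed intersection is
always 0 and p always 1); zero *signal* — no planted dependence between
any two evidence layers, with each layer still populated — is the
property the calibration needs.

## Problem sizes used in validation

The test suite validates at sizes chosen to make the statistics
informative while the whole suite stays quick on one core: oracle
equivalence on 200 randomized instances per operation (hypergeometric
enumeration at `N ≤ 12`); the single-interval bootstrap toy at
`n_iter = 10,000` against the enumerated 19/91 overlap probability;
calibration over 500 zero-signal replicates (1 × 100 kb, 40 + 40 peaks,
200 genes, `n_iter = 199`), with the replicate sizes picked so the
discrete null statistics have enough spread for attained test levels to
sit near nominal; parameter recovery and cascade recovery on the default
conditions with 2000 Runx1 peaks. Perfect-signal configurations (all
probabilities 0 or 1) must be recovered exactly; default configurations
require stage sensitivity ≥ 0.9 against brute-force-recomputed truth.

## Numerical and representation choices

Intervals are 0-based half-open in every file format this package reads
and writes (BED, narrowPeak) and in every user-facing coordinate (anchors,
TSSs, motif offsets). Internally, region sets are `GRanges` objects, whose
native convention is 1-based closed; the conversion happens exactly once
on read and once on write, so no other code path can introduce off-by-one
drift. GTF input (1-based inclusive) is converted at ingestion, taking the
5′-most transcript start per gene on its strand as the TSS. Genes,
expression tables and gene sets are plain data frames / small S3 objects
with sorted unique ids; every derived gene set carries a provenance list
(stage, parameters, parents) sufficient to recompute it.

Degenerate inputs have pinned behaviour: empty region files parse to
empty sets; an empty query makes a co-occupancy fraction an error rather
than `NaN`; a missing anchor motif yields `p = 1` with a zero count; a
zero-positive truth stage is flagged `degenerate` with `NA` sensitivity
rather than crashing; infeasible gene packing aborts generation before
anything is written.

## Limitations

The bootstrap null ignores assembly gaps, blacklists and covariates — on
real genomes it is anti-conservative near excluded regions. Peak-to-gene
assignment is distance-based only; no looping or expression-weighted
assignment. Consensus scanning has no position-weight scoring. The
Monte Carlo set test reports a single empirical p per intersection and
performs no multiplicity adjustment across candidate subsets. These are
scope boundaries, not accidents; each sits behind a single operation so a
richer implementation can replace it without touching the cascade.
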