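# rmjcascade

Staged multi-evidence integration for regulatory gene discovery in
myoblasts: given ChIP-seq peak sets for Runx1, MyoD and c-Jun, histone
marks (H3K4me1, H3K27ac), ATAC-seq open chromatin, a gene annotation and
gene-level differential-expression tables, `rmjcascade` derives nested
gene subsets — responsive → regulated → RMJ-regulated → high-confidence —
with a significance test for every intersection, and validates the whole
cascade against planted ground truth from its own synthetic-data
generator.

## The method

Four selection stages, each a refinement of the last:

1. **Responsive**: genes with FDR q-value `< q_max` and linear fold change
   `> fc_min` (defaults `q < 0.1`, `> 1.5`-fold; the optional in-vivo
   contrast uses `q < 0.05`, `> 1.7`-fold). Up- and down-regulated sets are
   kept separately.
2. **Regulated**: responsive genes with a Runx1 peak anchor (summit, else
   midpoint) within 200 kb of the TSS, boundary inclusive.
3. **RMJ-regulated**: stage-2 genes near a merged region receiving peaks
   from all three factors (the ABC class of the three-way region Venn),
   scored with the exact hypergeometric tail
   P(X ≥ k) for k = |responsive ∩ near-RMJ| over the annotation universe.
4. **High-confidence**: stage-3 genes whose supporting RMJ region is an
   active enhancer (H3K4me1 ∧ H3K27ac) *and* open chromatin (ATAC), scored
   with a Monte Carlo set test (null: uniform same-size draws,
   E[|A∩B|] = |A||B|/N).

Region-overlap significance uses a bootstrap relocation null (subject
intervals relocated uniformly within their chromosomes, lengths
preserved); all resampling p-values are add-one empirical,
`p = (1 + #{null ≥ obs}) / (1 + n_iter)`, never exactly zero. Bound
regions can additionally be screened for IUPAC consensus motifs (RUNX
`TGYGGTY`, E-box `CAGCTG`, AP-1 `TGASTCA` by default) and RUNX-anchored
motif modules (partner motif within ±50 bp), against a
composition-preserving shuffle null.

See `vignettes/evidence-cascade.Rmd` for the full account of the model,
nulls, defaults and design choices.

## Worked example

Generate the default synthetic study conditions (2 × 10 Mb genome,
500 genes, 2000 Runx1 peaks, co-occupancy planted at 0.46/0.47, marks at
0.70, ATAC at 0.25) and run the cascade:

```r
library(rmjcascade)

cfg <- synthetic_config(seed = 42, n_runx1_peaks = 2000)
ds <- generate_dataset(cfg)

report <- run_cascade(list(
  runx1 = ds$regions$runx1, myod = ds$regions$myod, cjun = ds$regions$cjun,
  h3k4me1 = ds$regions$h3k4me1, h3k27ac = ds$regions$h3k27ac,
  atac = ds$regions$atac, genes = ds$genes,
  expression = ds$expression, expression_in_vivo = ds$expression_in_vivo,
  chrom_sizes = ds$chrom_sizes,
  n_iter_bootstrap = 10000, n_iter_monte_carlo = 10000, seed = 43,
  dataset_id = ds$dataset_id))
print(report)
#> Evidence-integration cascade report
#>   annotation genes: 500
#>   responsive           144
#>   up                   109
#>   down                 35
#>   runx1_bound          500
#>   regulated            144
#>   rmj_regulated        144
#>   high_confidence      130
#>   in_vivo_responsive   155
#>   in_vivo              50
#>   RMJ regions: 459 of 2889 merged clusters
#>   bootstrap p (Runx1 x MyoD overlap): 0.0001
#>   hypergeometric p (RMJ x responsive): 1
#>   Monte Carlo p (high confidence): 0.45
```

144 of 500 genes pass the expression thresholds (109 up, 35 down); all of
them are Runx1-bound — at the default density of one peak per ~20 kb a
±200 kb window covers every gene, which also explains the non-significant
set-test p-values on these toy conditions (there is no *enrichment* to
find when the bound set is the whole annotation; the planted
binding–expression link is still fully recovered, see below). 459 of 2889
merged region clusters are triple-occupied, and the Runx1×MyoD overlap is
far beyond its relocation null (p = 1e-4, the smallest value reportable at
10,000 iterations). Scoring against the generator's ground truth:

```r
recovery_report(ds$truth, report)[, c("stage", "n_true", "n_predicted",
                                      "sensitivity", "specificity")]
#>             stage n_true n_predicted sensitivity specificity
#> 1      responsive    137         144           1   0.9807163
#> 2       regulated    137         144           1   0.9807163
#> 3   rmj_regulated    137         144           1   0.9807163
#> 4 high_confidence    121         130           1   0.9762533
```

Every planted gene is recovered at every stage; the handful of extra
calls are background genes that cross the q-value threshold by chance.

The same pipeline runs from files (`read_regions()`, `read_genes()`,
`read_expression_table()`) or from the command line via the wrapper in
`inst/cli/`: `rmjcascade simulate <cfg> <outdir>`,
`rmjcascade integrate <cfg>`, `rmjcascade report <report.json>`.

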