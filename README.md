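# tcrpair

Data-driven pairing of T cell receptors with their cognate peptide–MHC
from DNA-barcoded single-cell screens.

## The problem

Droplet-based single-cell immune profiling captures, per droplet (GEM), a
T cell's paired TCRα/β transcripts together with DNA barcodes reporting
which peptide–MHC (pMHC) multimers were bound to the cell, each quantified
by UMI counts. Raw data are noisy: ambient multimer reagents contaminate
droplets, chains drop out, droplets capture doublets, and most GEMs
therefore report several pMHCs. `tcrpair` is for immunologists and
computational biologists who need reliable TCR–pMHC pairs out of such
screens without a ground truth to filter against.

## The method

1. **Clonotyping.** Contigs are filtered to full-length, productive
   transcripts; clonotypes with identical VJ-CDR3αβ are merged and
   unassigned GEMs imputed; per locus the highest-UMI chain represents the
   TCR.
2. **Hashing demultiplexing.** CLR-normalized hashing counts are clustered
   by k-medoids into `n_samples + 1` clusters; per barcode, a negative
   binomial fitted to the background pool sets a 0.99-quantile threshold;
   GEMs are singlets, doublets or negatives.
3. **Expected binders.** For each clonotype with ≥ 10 GEMs, the two pMHCs
   with the highest mean UMI (0 when undetected) are compared with a
   one-sided Wilcoxon signed-rank test (exact, tie-aware); at p < 0.05 the
   top pMHC is the clonotype's expected target. Accuracy = fraction of
   GEMs whose most abundant pMHC matches their clonotype's target.
4. **Threshold optimization.** Per GEM and feature class (pMHC, TRA, TRB),
   UMI<sub>ratio</sub> = UMI<sub>max</sub> / (UMI<sub>sec</sub> + 0.25).
   An exhaustive grid search over six thresholds (count ≥, ratio >)
   maximizes the objective *o* = (2·acc + f) / 3 against binder labels
   fixed on the unfiltered data, where *f* is the retained GEM fraction.
5. **Filter cascade.** Composable, order-aware filters: UMI thresholds,
   HLA haplotype match (top pMHC's allele must be in the hashed donor's
   haplotype), hashing singlets, complete TCRs, specificity multiplets
   (each clonotype–pMHC pair seen in ≥ 2 GEMs), vendor cell flags,
   viable cells (200–2500 genes, ≤ 0.2 mitochondrial fraction).
6. **Evaluation.** Annotation accuracy, GEM-weighted binding concordance,
   and a BLOSUM62 string-kernel CDR3 similarity converted to a ROC-AUC
   (intra-specificity comparisons as positives), plus comparison with
   fluorescent multimer staining (MCC, recall, precision, log–log
   regression of GEM counts on adjusted sorted-cell counts).

A seeded synthetic-data generator (`simulate_dataset()`) plants ground
truth (targets, donors, clone sizes) under the realistic noise processes —
ambient contamination, dropout, doublets, hashing background — so the full
pipeline is testable offline.

## Worked example

```r
library(tcrpair)

sim <- simulate_dataset(simulation_params(seed = 42, n_clonotypes = 100,
                                          n_samples = 3))
ds <- collapse_and_impute_clonotypes(select_dominant_chains(sim$dataset))
ds <- demultiplex_hashing(ds, seed = 1)
ds
#> <gem_dataset>
#>   GEMs:       525
#>   contigs:    1018
#>   pMHC panel: 10 barcodes; 2394 nonzero (gem, pMHC) counts
#>   samples:    3 hashed; 1388 nonzero (gem, hash) counts
#>   clonotypes: 108
#>   hashing:    514 singlets / 11 doublets / 0 negatives

expected <- expected_binders(ds)
annotation_accuracy(ds, expected)
#> [1] 0.9464

grid <- grid_search_thresholds(ds, expected)
grid
#> <grid_search_result>
#> <umi_thresholds> min count: pmhc=0 tra=0 trb=0 | min ratio: pmhc=1 tra=0 trb=0
#>   acc = 0.9785  f = 0.9619  o = 0.9729  (505 GEMs retained)

res <- apply_filter_chain(ds, filter_config(
  steps = c("umi_thresholds", "hla_match"),
  thresholds = grid$thresholds
), expected = expected)
res$report[, 1:6]
#>            stage n_gems n_clonotypes retained_fraction accuracy avg_concordance
#> 1          total    525          108             1.000    0.946           0.967
#> 2 umi_thresholds    505          106             0.962    0.978           0.967
#> 3      hla_match    503          106             0.958    0.978           0.971
```

Reading the output: on this simulated screen the raw per-GEM annotations
already match their clonotypes' expected binders for 94.6% of eligible
GEMs. The grid search finds that a pMHC UMI-ratio threshold of 1 — which
removes GEMs where two pMHCs are equally abundant — raises accuracy to
97.9% while keeping 96.2% of GEMs, and no TCR-side threshold helps.
Adding the HLA haplotype match removes the few remaining
haplotype-inconsistent GEMs and lifts average binding concordance to
97.1%.

`run_pipeline()` wraps all stages, reading the raw vendor formats
(contig annotation CSV, Matrix Market feature matrix, panel/sample
configs) and writing per-stage GEM tables, reports and a JSON manifest;
`inst/cli/tcrpair.R` exposes it from the shell (`simulate`, `run`,
`gridsearch` subcommands).

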