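---
title: "Denoising barcoded single-cell TCR–pMHC screens: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoising barcoded single-cell TCR–pMHC screens: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrpair)
```

## The problem

Droplet-based single-cell immune profiling can read out, from the same
droplet (GEM, gel-bead in emulsion), the paired TCRα/β transcripts of a T
cell and the DNA barcodes of the peptide–MHC (pMHC) multimers bound to its
surface, each quantified by a UMI count. In principle every GEM yields a
TCR–pMHC pair. In practice the raw data are heavily contaminated: ambient
multimer reagents partition into droplets independently of binding, chains
drop out, droplets capture two cells, and hashing antibodies cross-stain.
Most GEMs therefore contain several pMHC barcodes, and naive per-GEM
annotation (take the most abundant barcode) produces contradictory pairings
within one clonotype.

`tcrpair` denoises such data with a fully data-driven cascade: it pools
evidence across the GEMs of a clonotype to call an *expected binder*,
optimizes UMI filtering thresholds against those calls, applies composable
filters (HLA haplotype match, hashing singlets, complete TCRs, specificity
multiplets, cell viability), and evaluates each configuration by annotation
accuracy, binding concordance, and a sequence-similarity ROC-AUC.

## Clonotypes

A clonotype is the set of GEMs sharing identical V gene, J gene and CDR3 on
both chains ("VJ-CDR3αβ"). Vendor clonotypes with identical keys are merged
(the vendor calls them apart when nucleotide-level differences exist);
GEMs left unannotated by the vendor are imputed against the
duplicate-reduced clonotype set, and novel combinations found new
clonotypes. Three design points were genuinely open:

* **Merge key.** Amino-acid CDR3 plus V and J gene names; the C gene is
  ignored. Whether imputation should match at nucleotide level instead is
  exposed as `use_nt` in `collapse_and_impute_clonotypes()`; amino-acid is
  the default because the merge is defined on functional identity.
* **Single-chain GEMs.** A GEM carrying only an α (or only a β) joins an
  existing clonotype only when exactly one clonotype matches that chain's
  triple. Ambiguous matches found a separate single-chain clonotype:
  conservative assignment avoids false merges that no downstream step could
  undo.
* **Dominant chains.** Per locus the highest-UMI contig represents the
  TCR, selected after clonotype definition. UMI ties are broken toward the
  lexicographically smallest CDR3 nucleotide sequence purely for
  determinism, and tied GEMs are flagged `chain_ambiguous` so the
  complete-TCR filter can drop them; the original multiplicity (`n_tra`,
  `n_trb`) is what that filter tests, since a dual-chain cell remains
  dual-chain no matter which contig represents it.

## Expected binders

For each clonotype with at least `min_gems = 10` members, the per-pMHC UMI
distributions over member GEMs are compared, counting 0 UMIs where a pMHC
is not detected. The two pMHCs with the highest mean are tested one-sided
(top > runner-up) at `alpha = 0.05`; a significant top pMHC becomes the
clonotype's expected target, and GEMs whose most abundant pMHC equals the
target are "true" annotations. Accuracy is the fraction of true
annotations among GEMs of clonotypes with a target.

Both candidate pMHCs are measured in the *same* GEMs, so the default test
is the paired Wilcoxon signed-rank over per-GEM differences; the unpaired
rank-sum is available via `method = "ranksum"` since the original
description names only "Wilcoxon". UMI differences are small integers with
heavy ties, where the tabulated tie-free null is wrong, so the package
computes the exact sign-flip null with midranks by a generating-function
sweep for up to 25 nonzero differences (`signed_rank_test()`), and a
normal approximation with continuity and tie correction beyond. Zero
differences are discarded (classic zero handling). Two degenerate cases
are defined explicitly: clonotypes under the size floor are not tested,
and a large clonotype observing a single pMHC is assigned that pMHC with
an undefined p-value.

**Binding concordance** is the fraction of a clonotype's GEMs supporting a
given pMHC, computed over GEMs with an unambiguous top pMHC; tied GEMs are
excluded from both numerator and denominator and reported separately. The
"average binding concordance" of a dataset is GEM-weighted by default
(each unambiguous GEM contributes its clonotype's fraction for its own top
pMHC), paralleling the GEM-wise accuracy; a clonotype-weighted variant is
available because the averaging weight is genuinely ambiguous.

## UMI thresholds and the grid search

Within a GEM and feature class (pMHC, TRA, TRB) the UMI ratio is

$$\mathrm{UMI}_{ratio} = \frac{\mathrm{UMI}_{max}}{\mathrm{UMI}_{sec} + 0.25},$$

where 0.25 avoids division by zero; equal top counts score below 1, so a
ratio threshold of 1 removes low-count ties. Thresholds (a minimum count,
compared with `>=`, and a minimum ratio, compared strictly) are selected by
exhaustive grid search maximizing

$$o = \frac{2 \cdot acc + f}{3},$$

the weighted average of accuracy over surviving training GEMs and the
retained fraction of all GEMs. The expected-binder labels are fixed once,
on the unfiltered data, before the search: the training set definition
precedes thresholding, and re-deriving labels per grid point would let the
filter chase its own tail.

Grid construction follows "0 up to the median": integer count thresholds
up to the per-class median of per-GEM top counts, and a ratio ladder
`0, 1, 1.5, 2, 3, 4, 5` continued with roughly 1.5× geometric steps up to
the per-class median ratio. The step beyond 5 is the package's choice: UMI
discreteness forces integer counts, while the geometric ladder keeps the
full six-dimensional grid tractable without excluding the informative
low-ratio region. Ties in `o` prefer the higher retained fraction, then
lower thresholds component-wise, so "no filtering" wins whenever filtering
buys nothing. The search is exact: the pass indicator factorizes over the
three feature classes, so every grid point is evaluated (as weighted
matrix cross-products), none is skipped, and the full evaluation can be
written out for audit (`audit = TRUE`).

## Hashing demultiplexing

Hashing counts are CLR-normalized across barcodes within each GEM (the
convention of the cell-hashing literature; the transform is not named in
the source description) and clustered by k-medoids into
`k = n_samples + 1` clusters. Clustering uses all barcodes jointly; the
partitioning-around-medoids build step is deterministic and the seed
covers any stochastic refinement. Per barcode, a negative binomial is
fitted by maximum likelihood to the raw counts of the background pool, and
a GEM is positive when its raw count strictly exceeds the fitted 0.99
quantile; one positive barcode is a singlet, several a doublet, none a
negative. When the pool is under-dispersed or the ML fit fails, a Poisson
quantile substitutes.

One robustness choice departs from the literal description: the background
pool excludes *every* cluster whose mean expression of the barcode exceeds
the mean of cluster means, not only the single highest cluster. With
`k = n_samples + 1` and few genuinely negative droplets, k-medoids can
split one positive population across two clusters; excluding only one of
them leaves signal in the pool and inflates the threshold severalfold.
The rule reduces to the literal one whenever exactly one cluster is
positive.

## The filter cascade

Filters are independently applicable, composable and only ever remove
GEMs. `apply_filter_chain()` runs them in order (cumulative mode) or each
against the full data (individual mode) and reports GEM count, clonotype
count, accuracy and average concordance after each step. Order sensitivity
is confined to the specificity-multiplet filter, which recounts
(clonotype, top pMHC) pairs on the current set — a pair reduced to one GEM
by earlier steps loses its survivor too. HLA matching uses the union of
implicated donor haplotypes for hashing doublets (flagged, so doublets can
still be excluded separately) and removes hashing negatives, which have no
donor. The `is_cell` flags are vendor-provided pass-through predicates,
never recomputed; viability bounds are 200–2500 detected genes and at most
0.2 mitochondrial fraction.

## Similarity evaluation

Filtering quality is evaluated without ground truth through the hypothesis
that TCRs binding the same pMHC are more sequence-similar than TCRs
binding different pMHCs. CDR3 similarity uses a BLOSUM62 string kernel:
the raw kernel sums, over all k and all k-mer pairs, position-wise
products of $m(a,b) = \exp\{\beta\,(B_{ab} - \max B)\} \in (0,1]$ with
$\beta = 0.11387$, and is normalized by
$K(s,t)/\sqrt{K(s,s)\,K(t,t)}$ so identical sequences score exactly 1.
The kernel is computed by a suffix-product recursion (quadratic in
sequence length, equivalent to exhaustive k-mer enumeration). Both the
matrix scaling and β are configurable; no flank trimming is applied by
default, with a `trim_flanks` switch. A TCR-pair score is the sum of the α
and β chain similarities (range 0–2); GEMs missing a chain are excluded.

Each both-chain clonotype carries one label — its expected target, else
its highest-concordance pMHC — so cross-reactive clonotypes cannot appear
on both sides of a comparison. The intra-score is the maximum similarity
to same-label clonotypes; the inter-score the maximum over a seeded,
equal-sized, without-replacement sample of other-label clonotypes.
Pooled intra (positive) and inter (negative) scores yield a rank AUC, and
a one-sided paired signed-rank test asks whether intra exceeds inter.
Pooling is of the per-clonotype max-scores across peptides, the natural
reading when per-peptide counts are small.

## Synthetic data: what it emulates and what it does not

`simulate_dataset()` generates GEM-level data with planted truth:
clonotypes with unique VJ-CDR3αβ identities (lengths 10–18, fixed
"CA…F"/"CASS…F" flanks), power-law clone sizes (exponent 1.5, capped at
50), one planted target per clonotype consistent with its donor's
haplotype, negative binomial signal UMIs (mean 8, dispersion 5) for target
pMHC and chains, Poisson(0.5) ambient counts per non-target pMHC, chain
dropout (α 0.1, β 0.05), 5% droplet doublets merging full GEM contents,
hashing counts NB(80, 10) on the true sample versus NB(2, 5) background,
and per-GEM gene-count/mitochondrial scalars for the viability filter.
These defaults are the package's standing study conditions; the test suite
and the acceptance script evaluate recovery under them (300 clonotypes,
10 pMHC over 5 alleles, 4 donors — roughly 1500 GEMs, small enough for the
full pipeline including the grid search to run in about a minute).

What the generator does **not** emulate: real CDR3 sequence structure
(sequences are random, so intra-specificity clonotypes share no genuine
similarity and the similarity AUC on synthetic data hovers near chance —
the AUC machinery is validated against enumeration oracles, not against
planted sequence signal), transcriptome-wide expression, index-hopping, or
UMI saturation. Passing recovery tests on synthetic data therefore
demonstrates the statistical machinery, not performance on any particular
real screen; thresholds found by the grid search are data-specific by
design and must be refitted per experiment.

## Numerical and degenerate-input choices

* Exact signed-rank null enumerated up to 25 nonzero differences (the
  doubled-midrank polynomial has at most 651 coefficients there); normal
  approximation with continuity and tie-corrected variance beyond.
* Mean-UMI ties when choosing a clonotype's top two pMHCs break toward the
  pMHC observed in more GEMs, then lexicographically.
* Grid points where no eligible training GEM survives score an accuracy
  contribution of 0 and are flagged rather than erroring.
* A GEM with no pMHC counts cannot enter the dataset (assembly requires
  both a TCR and a pMHC observation); a clonotype whose GEMs are all tied
  yields an empty concordance with a warning; an empty intra or inter
  class yields an undefined AUC with a warning.
* Zero-count feature entries are never materialized; absence means 0 and
  the 0 is imputed at computation time (expected-binder matrices, top-pMHC
  summaries).
* HLA alleles are canonicalized to the two-field `A*03:01` form from any
  of the common notations before matching.

## Known limitations

* The expected-binder call needs ≥10 GEMs; rare clonotypes are never
  tested and inherit only concordance-based labels.
* The grid search optimizes a single global objective; per-donor or
  per-pMHC thresholds are out of scope.
* Cross-reactivity is surfaced via concordance, never called explicitly;
  the filters treat divergent annotations as noise.
* The multimer comparison consumes response frequencies from a table; no
  flow-cytometry file processing is provided.
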