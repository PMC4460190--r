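# scMolO

Resolving functional heterogeneity in sorted stem-cell populations by
integrating single-cell gene expression, index-sort phenotypes and
single-cell functional assays.

## The problem

The most refined hematopoietic stem cell (HSC) sorting strategies isolate
populations that are only ~50% functionally pure, and different strategies
select overlapping but non-identical cell sets. Because repopulation assays
are retrospective and destroy the assayed cell, the molecular profile of a
*functional* HSC cannot be read out directly. `scMolO` implements a
computational route around this: if every strategy contains true HSCs, the
true HSCs should form a **molecularly overlapping (MolO)** subpopulation
shared across strategies, mixed in proportion to each strategy's published
repopulation probability.

## The method

1. **qPCR panel** — single-cell Ct tables are housekeeper-normalized
   (ΔCt\[i,g\] = Ct\[i,g\] − mean Ct\[i, HK\]), failed assays are excluded,
   and cells are Ward-clustered on Spearman correlation distance.
2. **MolO search** — cells are embedded in 2D by t-SNE. For each HSC cell
   the strategy composition `c_i` of its `k` nearest HSC neighbors is
   compared with the repopulation-weighted target
   `w_s = p_s / Σ p_s` by Jensen–Shannon divergence
   `d_i = JSD(c_i, w)` (nats). A permutation null (strategy labels shuffled
   over the fixed neighbor geometry) converts `d_i` into a per-cell
   p-value; cells at or below the `α`-quantile of their null are MolO, the
   remaining HSC-gated cells NoMO. Per-gene Wilcoxon/BH tables and
   index-marker enrichments characterize the partition.
3. **Score transfer** — a random forest trained on per-platform z-scored
   expression of the genes shared between the qPCR panel and the RNA-seq
   variable-gene set produces a per-cell **MolO score** (fraction of trees
   voting MolO), validated by stratified 10-fold cross-validation and
   applied to scRNA-seq profiles.
4. **scRNA-seq** — median-of-ratios size factors; technical noise fitted on
   ERCC spike-ins as `CV²(μ) = a1/μ + a0` (gamma GLM, identity link);
   variable genes called by a chi-square exceedance test with BH
   correction; PCA; transcriptome-wide Spearman ranking of genes against
   the MolO (or SuMO) score.
5. **Function linkage** — sequenced and transplanted cells are embedded
   jointly on their z-scored index-sort channels; the **SuMO score** is the
   projection onto the first total-least-squares axis, oriented so it
   correlates non-negatively with the MolO score. Transplant outcomes are
   called from donor chimerism (repopulated ⇔ donor WBC ≥ 1% at week 16
   and/or 24, inclusive), subtyped by the myeloid/lymphoid ratio
   (α: ρ > 2, β: 0.25 ≤ ρ ≤ 2, γ: ρ < 0.25), and HSC frequency is
   estimated by single-hit Poisson limiting dilution with a
   likelihood-ratio 95% CI. A mammary colony-assay pipeline (per-patient
   z-scoring, pooled embedding, Ward cut, colony-forming-efficiency fold)
   generalizes the approach.

A synthetic-data generator (`SimSpec`, `simulateQPCR`, `simulateCounts`,
`simulateIndexAndFunction`) emulates all five input kinds with a planted
MolO subpopulation, so the full pipeline is testable end to end without
external data.

## Worked example

```r
library(scMolO)

spec <- SimSpec(seed = 11L)          # 5 strategies x 210 cells, 48 assays
sim  <- simulateQPCR(spec)
dct  <- applyGeneExclusions(
    deltaCtNormalize(sim$ct, housekeepers = c("Ubc", "Polr2a")),
    c("Cdkn2a", "Egfl7"))
dct
#> DeltaCtExperiment: 43 genes x 1050 cells
#>   excluded assays: 5 (Ubc, Polr2a, Actb, Cdkn2a, Egfl7)

emb    <- embedTSNE(t(dctValues(dct)), seed = 3L)
assign <- identifyMolo(emb,
    labels  = setNames(sim$truth$strategy, sim$truth$cell_id),
    weights = setNames(spec@repop_prob, paste0("HSC", 1:5)),
    n_perm = 999, seed = 4L)
assign
#> MolOAssignment: 1050 cells — MolO: 500, NoMO: 550, non-HSC: 0
#>   k = 50 , alpha = 0.05 , permutations = 999
```

The 43 genes are the 48-assay panel minus three housekeepers and two
excluded assays. Against the generator's planted truth this assignment
scores F1 = 0.97 (the counts vary a little by seed). Downstream:

```r
tab <- moloDifferentialGenes(dct, assign, fdr = 0.05)   # per-gene Wilcoxon+BH
limitingDilution(10, 5, 1)
#> LDAResult: f = 0.1609 (1 in 6.21), 95% CI [0.04649, 0.4372]
```

The same stages are scriptable as a shell pipeline
(`inst/cli/molo-pipeline.R`):

```sh
Rscript inst/cli/molo-pipeline.R simulate --seed 5 --out-dir run1
Rscript inst/cli/molo-pipeline.R qpcr     --seed 5 --out-dir run1
# ... embed molo classify hvg signature sumo transplant mammary
```

Each stage writes delimited tables plus a JSON manifest; identical seed and
config reproduce every output byte for byte.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "scMolO",
                               load_package = "installed")'
```

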