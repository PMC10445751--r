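# ngcdev

Resolving neurogliaform-cell (NGC) subtype identity across development from
single-cell RNA-seq and patch-seq data.

Cortical neurogliaform cells — *Htr3a*⁺, preoptic-area-born GABAergic
interneurons — split into two transcriptional subtypes (*Dock5*⁺ and
*Lsp1*⁺) with distinct laminar positions and electrophysiological profiles.
Establishing that kind of result takes a chain of computational steps:
per-platform quality control, transferring reference-atlas labels onto query
cells, extracting age-conserved marker signatures, ordering cells on
developmental maturation, assigning patch-seq cells to subtypes from their
transcriptomes, quantifying membrane physiology from current-clamp traces,
and testing laminar distributions and gene-set enrichments. `ngcdev`
implements that chain as a tested, reusable R pipeline, together with
seed-controlled synthetic-data generators that plant known ground truth so
every stage can be validated end-to-end.

## What the package computes

* **Consensus label transfer.** Reference and query cells are embedded in a
  common space (per-dataset standardized joint PCA, approximating
  canonical-correlation integration). A k-nearest-neighbour classifier on the
  embedding and a one-vs-rest linear SVM on expression each predict a label;
  agreement gives the consensus, disagreement is `INCONCLUSIVE`, and a
  consensus that contradicts the cell's fluorescence-reporter lineage demotes
  it from the "core" set.
* **Conserved signatures.** Cell age is regressed out of log-normalized
  expression (per-gene OLS), a deliberately overfit linear SVM is trained on
  all cells, and the top 150 genes per class by signed weight form the
  signature, with log1p-RPM fold changes rescaled onto \[−0.5, 0.5\] for
  display. A cumulative-logit (proportional-odds) model with an L2 penalty,
  cross-validated over the penalty, scores postnatal maturation.
* **Embryonic trajectory.** PCA keeping components that explain ≥ 3% of
  variance, a Hastie–Stuetzle principal curve, orientation by *Nes* (early)
  versus *Dcx* (late) expression, min–max scaling of arc length to a \[0, 1\]
  maturation score, and a mitotic-to-postmitotic transition at the point
  where a loess fit (span 0.25, degree 1) of the S-G2/M score falls below
  half its average. A per-cell "pseudogene" score (mean conserved-marker
  expression divided by the number of genes expressed) thresholded at the
  80th percentile assigns embryonic cells to the lineage.
* **Electrophysiology.** From current-clamp sweeps: input resistance
  R = ΔV/ΔI on the −40 pA step, membrane time constant by monoexponential
  fit to the first 100 ms, sag ratio (V\_min − V\_end)/V\_min on the −200 pA
  step, spike detection at dV/dt ≥ 20 mV/ms, first-AP latency/threshold/AHP
  and the subthreshold depolarizing bump (STDB) from the rheobase ramp, and
  spike frequency from the +300 pA step. Feature-level PCA, gene–feature
  Pearson correlations, depth correlates with χ² Pearson residuals, and
  Welch t-tests compare the subtypes.
* **Spatial statistics.** Landmark-normalized depths (pia = 0), two-sided
  Kolmogorov–Smirnov comparisons, kernel density profiles, layer fractions,
  and one-sided hypergeometric gene-set enrichment with optional ancestor
  propagation over a term DAG.

## Worked example

Label transfer on a synthetic cohort with three planted classes:

```r
library(ngcdev)

cfg   <- sim_config(seed = 1, n_cells_per_group = 100)
atlas <- generate_reference_atlas(cfg)
query <- generate_query_cohort(cfg)

emb        <- embed_joint(atlas, query)
ref_labels <- setNames(atlas$cells$true_class, atlas$cells$cell_id)
assignments <- consensus_assign(
  knn_classify(emb, ref_labels, k = 15),
  predict(train_linear_svm(atlas, ref_labels), query),
  fluorescence  = query$cells[, c("cell_id", "tdtom")],
  tdtom_classes = c("Dock5", "Lsp1"))
summarize_assignments(assignments)
#> # A tibble: 4 × 3
#>   label            n   pct
#>   <chr>        <int> <dbl>
#> 1 Dock5          198 33
#> 2 Lsp1           197 32.8
#> 3 Other          197 32.8
#> 4 INCONCLUSIVE     8  1.33
```

Of 600 query cells (200 per class), the consensus recovers the planted
class for 98.5% of all cells; 1.3% are inconclusive because the two
classifiers disagree.

Embryonic maturation reconstruction with a planted transition at 0.4:

```r
embryo <- generate_embryonic_continuum(sim_config(seed = 1, n_cells_per_group = 500))
pt <- reconstruct_maturation(embryo)
pt
#> <ngc_pseudotime> 500 cells, 1 PCs kept, transition at 0.407
glance(pt)
#> # A tibble: 1 × 5
#>   n_cells n_pcs_kept transition pct_mitotic converged
#> 1     500          1      0.407        37.8 TRUE
```

The maturation score correlates with the planted truth at Spearman ρ ≈ 0.99
and the detected mitotic transition (0.407) sits within 0.01 of the planted
value. `autoplot(pt)` draws the S-G2/M-versus-maturation diagnostic;
`tidy(pt)` returns the per-cell table.

The whole chain — simulation, QC, transfer, signatures, trajectory,
patch-seq features and subtype tests, spatial statistics — runs as one call:

```r
res <- run_pipeline(pipeline_config(seed = 1), out_dir = "run1")
```

which writes per-stage TSV/JSON artifacts and a manifest under `run1/`.

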