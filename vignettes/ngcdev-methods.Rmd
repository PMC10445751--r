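---
title: "Models and methods behind ngcdev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ngcdev}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ngcdev)
```

`ngcdev` reconstructs the identity and developmental history of
neurogliaform cells (NGCs) from single-cell transcriptomes, patch-seq
recordings and histological positions. This vignette explains the models
each stage implements, the tunable parameters and their defaults, what the
synthetic-data generators emulate (and do not), and the numerical choices
made where the design was genuinely open.

## Quality control

Each sequencing platform has its own exclusion rules, applied as strict
inequalities so a cell exactly at a bound is kept:

| platform | rule set |
|---|---|
| `postnatal_c1` | `< 1000` genes, `< 100,000` UMIs, `< 50,000` mapped reads, `> 20%` mitochondrial |
| `embryonic_c1` | same, but `> 15%` mitochondrial |
| `droplet` | `< 1000` genes, `> 15%` mitochondrial (UMI/read rules inactive) |
| `patchseq` | `≥ 10,000` reads, `≥ 25%` exonically mapped, `< 15%` mitochondrial, confirmed fluorescence |

The droplet preset deliberately leaves the UMI and read rules inactive —
droplet libraries are far shallower per cell and the genes + mitochondrial
pair is the appropriate filter there. Contaminating populations
(glutamatergic, vascular, immune, ...) are removed by clustering on the top
2000 variable genes and flagging clusters whose marker-panel score exceeds
the global mean score by a configurable factor (default 2). The default
clustering is seeded k-means on the leading principal components: fully
deterministic under the seed and dependency-free; graph-based clustering
gives comparable flags on well-separated contaminants, which is the regime
the rule is designed for (the populations it removes are transcriptionally
distant from interneurons). The factor rule presumes the contaminant is a
minority; a panel whose cells are half the dataset would raise the global
mean past the flagging point.

## Consensus label transfer

Two independent classifiers must agree before a query cell receives a
reference label.

* **Embedding + kNN.** The default `cca_like` embedding standardizes the
  shared variable genes within each dataset (removing dataset-specific
  location and scale — the property that canonical-correlation integration
  exploits) and fits one PCA on the concatenated cells; `pca_project` fits
  the PCA on the reference alone and projects the query. The standardized
  variant is the default because it is robust to expression programs present
  in only one dataset (e.g. maturation programs in young query cells that an
  adult reference lacks). `k = 15` neighbours by Euclidean distance; ties
  are resolved by the single nearest neighbour's label. kNN runs on the
  full `n_dims = 20` embedding rather than on a 2-D stochastic map: the 2-D
  map distorts distances and injects a second seed dependency for no gain in
  accuracy.
* **Linear SVM.** One-vs-rest soft-margin machines (cost `C = 1`) on
  log-normalized expression (scale factor 1e4). The winning one-vs-rest
  margin is the reported decision value. Classification operates at the 1e4
  log-normalization scale throughout the package; the 1e6 (log1p-RPM) scale
  is reserved for fold changes, where it is the conventional reporting unit.
  At the RPM scale the gap between a dropout zero and a detected transcript
  dominates the margin geometry and measurably degrades generalization.

Disagreement yields `INCONCLUSIVE`; agreement that contradicts the
fluorescence-implied lineage (a tdTOM⁻ cell labeled as a tdTOM-lineage
subtype, or vice versa) keeps the label but clears the `core` flag, so
downstream signature training can restrict itself to cells whose molecular
and genetic evidence concur.

## Conserved signatures and maturation scoring

To find markers stable across ages, cell age is first regressed out of each
gene (ordinary least squares on the age index, gene means restored). A
linear SVM is then trained on **all** cells with a high cost (default 100) —
deliberately overfit, because the object of interest is the ranked weight
vector, not held-out accuracy. The top 150 genes per class by signed weight
form the signature; each carries its log1p-RPM fold change, linearly
min-max rescaled onto \[−0.5, 0.5\] (a display convention: the rescaled
value hits ±0.5 at the extreme fold changes and preserves zero only for
symmetric fold-change vectors).

Postnatal maturation is scored with a proportional-odds (cumulative-logit)
model over the union of per-timepoint variable genes, with an L2 penalty on
the gene weights selected by 10-fold cross-validated classification
accuracy. The exposed quantity is the linear predictor — a continuum that
orders cells within and across timepoints. The penalized likelihood is
maximized directly (BFGS with analytic gradients; thresholds parameterized
as a first cut plus log-increments to keep them ordered). The contract is
the *ordering*, not the coefficients of any particular solver; the test
suite cross-checks the ordering against an unpenalized proportional-odds
reference fit on low-dimensional data.

## Embryonic trajectory

The embryonic pipeline is: log-normalize; residualize every gene against
the number of genes expressed (removing sequencing-depth bias); z-scale;
PCA keeping components with variance ratio ≥ 3% (at least one); fit a
principal curve; orient; scale; locate the mitotic transition.

The principal curve is the Hastie–Stuetzle iteration: initialize with the
first principal component, then alternate projecting points onto the
current curve (exact polyline projection) and smoothing each coordinate
against arc length with a cubic smoothing spline, until the mean squared
projection distance changes by less than 1e-4 (relative) or 50 iterations.
Exact duplicate points are collapsed into weighted unique points before
smoothing, so the fitted curve depends on the empirical distribution, not
on multiplicity. Orientation is chosen so the maturation score correlates
more with the late marker (*Dcx*-like) mean than the early (*Nes*-like)
mean, and arc length is min–max scaled to \[0, 1\].

The mitotic-to-postmitotic transition is the smallest maturation at which a
loess fit (span 0.25, degree 1, evaluated on a 200-point grid) of the
S-G2/M score drops below half the mean score *and stays below through the
next grid point* — the sustained-crossing rule guards against
local-regression wiggle near the decision level. If the curve never
crosses, the transition is clamped to 0 or 1 with a warning. The S-G2/M
score itself is the unweighted mean of log-normalized expression over a
user-supplied cell-cycle gene list; an unweighted mean keeps the score's
scale interpretable and makes the half-average rule scale-invariant.

The pseudogene score divides the mean conserved-marker expression by the
raw count of genes the cell expresses (the simplest complexity measure; a
scaled variant would only change the score by a monotone factor and leave
the percentile assignment untouched). The assignment threshold is the
upper-tail nearest-rank percentile: the smallest score such that at least
`ceiling(n × (1 − p/100))` cells sit at or above it. With distinct scores
this assigns exactly the top `1 − p/100` fraction; ties at the threshold
are all assigned.

## Electrophysiology

The membrane features follow their textbook definitions, with the
operational windows fixed as package conventions: baseline = mean before
step onset; steady state = mean over the last 20% of the step; sag
V\_end = mean of the last 5 ms; AHP window = 50 ms after the spike; spike
upstroke threshold 20 mV/ms with a 2 ms merge window. Sag V\_min and
V\_end are baseline-subtracted deflections by default, which makes the
ratio positive for sagging cells and exactly zero without sag; an
absolute-voltage mode is available. V\_min is located on a 5 ms
moving-average of the trace — the single-sweep analogue of measuring on
averaged repeat sweeps, since a raw minimum over thousands of noisy
samples is biased by the noise extreme. Spike frequency divides the spike
count by the actual step duration, so 500 ms and 1000 ms protocol variants
are handled identically. Capacitance is amplifier metadata, not derived
from traces.

Patch-seq subtype assignment applies the trained signature with three
published filters: signature genes must be detected in ≥ 10% of patched
cells; cells expressing < 20% of the kept genes are discarded; and the
assignment requires an absolute SVM decision value above 0.2. Because the
decision is evaluated on the kept gene subset, the omitted genes'
contributions are imputed at their training means — otherwise the decision
midpoint would drift with whichever genes happened to be filtered.

Welch's t-test is the default subtype comparison (the pooled-variance test
is available); the gene–feature correlation matrix carries
Benjamini–Hochberg q-values across all pairs.

## Spatial statistics and enrichment

Depth is distance from the recorded landmark (pia surface, or ventricle
for embryonic tissue), zero at the landmark; the orthogonal axis is
replaced by seeded uniform jitter within the region limits and flagged as
a display coordinate. The KS comparison uses the exact two-sided p-value
when `n_a × n_b ≤ 1e4` and the asymptotic approximation otherwise (package
defaults for the exact/asymptotic switch vary between versions, so the
rule is pinned here). Density profiles renormalize the kernel estimate to
integrate to one over the \[0, max depth\] grid. Hypergeometric enrichment
is one-sided over-representation, `P[X ≥ k]`, with optional transitive
closure of each gene's terms over the parent DAG before counting
(propagation can only grow a term's gene set, never shrink it), and BH
correction across terms. Hypergeometric p-values are discrete and
therefore super-uniform under the null; calibration checks assert the
absence of anti-conservative deviation and the nominal false-positive
rate, not exact uniformity.

## The synthetic-data generators

Every generator is driven by one `sim_config()` and draws from a named
substream of the root seed (the seed initializes a polynomial hash of the
stream name), so identical configurations are bit-reproducible and adding
a stage never perturbs another stage's draws.

Counts follow a negative binomial (variance μ + φμ²; default dispersion
φ = 0.5) around per-cell expected profiles: a log-normal per-cell library
size (mean 20,000), a shared log-normal gene baseline, and planted
structure on top — class markers shifted by `marker_log_fc` (default 1.5,
natural-log scale), then independent Bernoulli dropout (default 10%). In
the noise-free limit (`noise_dispersion = 0`) the expected values
themselves are returned and the library size is fixed, giving exact
oracles for arithmetic tests. QC metadata (reads, UMIs, detected genes)
are reported at the scale of a real library, since the simulated matrix
covers only a gene subsample.

The embryonic continuum plants four programs along a uniform maturation
`t ∈ [0, 1]`: a cell-cycle block whose logistic decay **completes** at the
configured transition (expression is ~0 beyond `t*`, matching how the
half-average detection rule reads a decay); an early block falling and a
late block rising log-linearly; and 150 "wave" genes that switch on or off
around random midpoints — sequential waves of expression are what makes
the manifold a well-spread one-dimensional curve, as in real
differentiation data. The age-regulated block in the postnatal generator
is modeled as low-baseline, age-induced transcripts: their information
lives in the age covariate, and their residual variance after age
regression is small. That choice is what makes "age regression never
selects an age-only gene" a property of the method rather than a coin
flip — with age genes noise-matched to the rest of the transcriptome,
ranking chance alone would pull several of 50 such genes into a 300-gene
signature.

The patch-seq generator synthesizes traces from a single-compartment RC
model: deflections `ΔV = I·R·(1 − e^{−t/τ})`, a sag term that engages
after the charging peak and relaxes with a 50 ms time constant (applied on
the −200 pA step only, where hyperpolarization-activated current is
engaged — so the −40 pA step recovers the planted resistance exactly), and
spikes pasted as stereotyped waveforms whose 20 mV/ms upstroke crossing
defines the reference frame for threshold, latency and AHP. Subtype
presets (AHP −14.6 ± 1.0 vs −23.4 ± 0.9 mV; latency 50.3 ± 5.4 vs
205.3 ± 25.4 ms; STDB 3.2 ± 0.4 vs 0.8 ± 0.4 mV; n = 20/27) plant the
published subtype statistics as per-cell means and SDs; depth modulates
latency (increasing with depth for both subtypes) and sag linearly.
Positions come from two normal depth distributions separated by a
configurable shift, with per-image landmark offsets so normalization is
exercised; annotation maps plant one enriched term inside random gene–term
assignments whose parent map is acyclic by construction.

What the generators do **not** emulate: transcriptome-wide gene–gene
correlation beyond the planted programs, ambient RNA and doublets, batch
chemistry differences, conductance-level biophysics (the trace model is
waveform-level by design, because every extracted feature is
waveform-level), or branching trajectories. Passing tests therefore
demonstrate that the algorithms recover what they claim under a faithful
noise model — not that any particular biological dataset will behave as
cleanly.

## Problem sizes and determinism

The test suite and the acceptance script run cohorts of 100–500 cells per
group with 400–2000 genes, 100-seed replicates for the stochastic
recovery checks, and a full pipeline pass at the default configuration
(120 cells per class-age, 1500 genes, 400 embryonic cells, 47 patch-seq
cells at a 15 pA ramp increment) — sizes at which every planted effect is
comfortably detectable yet a complete run stays in the tens of seconds.
All randomness flows from explicit seeds; reruns are byte-identical.

## Known limitations

* The consensus guarantee degrades gracefully, not sharply: with marker
  effects below ~1 natural-log unit or classes under ~50 cells the
  inconclusive rate grows before the accuracy falls.
* The proportional-odds score is calibrated per fitted model; scores from
  different fits are comparable in order but not in scale.
* The principal curve is single-branch; bifurcating differentiation would
  need a different backbone.
* `DISCARDED` patch-seq cells (gene-detection filter) are reported but not
  rescued; in real data they would warrant re-sequencing rather than
  imputation.
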