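# thyrotrace

Tissues respond to thyroid hormones only through the cells that can hear
them: cells expressing the receptor genes *Thra* or *Thrb*, supplied with
hormone by the transporters *Slc16a2*, *Slc16a10* and *Slco1c1* and the
deiodinases *Dio2*/*Dio3*. Bulk RNA-seq sees the tissue average;
single-cell RNA-seq lets us ask *which cell types and subtypes* are
competent to respond. `thyrotrace` implements that tracing workflow for R
users working with single-cell count atlases and treated/control bulk
experiments.

## What it computes

**Expressing-cell fractions.** The central statistic is, for gene $g$ and
cell type $t$,

$$f_{g,t} = \frac{\#\{\text{cells of } t \text{ with count}_g \ge 1\}}{\#\{\text{cells of } t\}},$$

computed on raw counts after platform-specific cell QC (full-length
libraries: keep cells with ≥ 5,000 counts and ≥ 500 detected genes;
UMI libraries: ≥ 2,500 UMIs and ≥ 500 genes) and an abundance filter
(≥ 20 cells per type).

**Co-expression.** Whether receptor and transporter/deiodinase are
detected in the *same* cells is tested per cell type with the exact
hypergeometric upper tail: with $n$ cells, $m$ expressing gene A, $k$
expressing gene B and $x$ expressing both,

$$p = P(X \ge x), \qquad X \sim \mathrm{Hypergeom}(n, m, k),$$

computed in log space with compensated summation; a pair is testable
only when $m \ge 10$ and $k \ge 10$.

**Subtype discovery.** Cell types with low receptor fractions
(< 0.2) but ≥ 500 cells and > 50 expressing cells are re-clustered
(log-normalisation at scale factor 10,000 → mean/variance-plot variable
genes → PCA on 15 components → shared-nearest-neighbour graph → Louvain
at resolution 0.5). Cluster pairs whose receptor fractions differ more
than five-fold are flagged, and cluster markers are screened with a
Wilcoxon rank-sum test (≥ 2-fold change, ≥ 20% detection in one group,
Bonferroni-adjusted p ≤ 0.05).

**Bulk DEG decomposition.** Differentially expressed gene lists from a
treated/control bulk experiment are mapped to their fraction profiles
over a ten-cell-type liver microenvironment (pancreatic stellate cells
standing in for hepatic stellate cells) and grouped by Ward.D2
hierarchical clustering on Euclidean distances, isolating e.g. the
hepatocyte-specific component of the response; groups can be tested
against GMT gene sets with the same hypergeometric tail.

A synthetic-data module generates atlases and bulk experiments with
planted ground truth (detection probabilities, subtype structure,
pairwise gene dependence, up/down-regulated genes), so the whole chain
is testable without downloads.

## Worked example

The `analysis/` directory is a numbered workflow over synthetic data
(`01_simulate.R` … `05_deg_decomposition.R`). Step 4 discovers planted
subtypes inside a low-expressing "myeloid cell" type:

```r
library(thyrotrace)
atlas <- generate_atlas(subtype_benchmark_config(seed = 1))
res <- run_subtype_analysis(atlas$matrix, atlas$annotation,
                            "myeloid cell", "Thra", seed = 1)
```

Running `Rscript analysis/01_simulate.R` then
`Rscript analysis/04_subtypes.R` prints:

```
found 2 clusters among 800 cells (165 variable genes)
Thra fraction per cluster: 0: 0.220, 1: 0.022
divergent pair: cluster 0 (0.220) vs cluster 1 (0.022), fold 9.8
median depths of the pair: 2614 vs 2621 (comparable depths)
markers retained at Bonferroni-adjusted p <= 0.05: 122
```

The two clusters recover the planted subtypes (receptor detection 0.20
vs 0.02 — a ten-fold sensitivity gap invisible to the whole-type
fraction of 0.11), the fold change clears the five-fold rule, the
matched sequencing depths show the gap is not a depth artifact, and the
122 retained markers are the planted subtype programs. Step 3 flags a
planted co-detection dependence (marginals 0.3/0.3, joint 0.25, 300
cells) at `p = 2.1e-50`, and step 5 isolates the hepatocyte-specific
up-regulated genes into their own Ward.D2 group with the
`hepatocyte_program` gene set significant after Bonferroni.

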