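# cladosig

Topology-only phylogenetic signal analysis for landmark shape data.

Supertrees for fossil-rich clades — the motivating case is the bears,
Ursidae, and the shape of their basicranium — usually carry a trustworthy
topology and no trustworthy branch lengths. `cladosig` tests whether
continuous tip traits (shape principal components, centroid size, or any
tip-level variable) carry phylogenetic signal using the cladogram topology
alone, and surrounds the tests with the full working pipeline: landmark
input, Procrustes superimposition, shape PCA, ancestral reconstruction,
habitat-character parsimony, and skull-proportion group tests.

## What it computes

**Orthogram (orthonormal decomposition).** The topology of a rooted tree
with *n* tips defines *n−1* orthonormal contrast vectors (Helmert contrasts
per internal node; polytomies contribute out-degree − 1 columns). A
standardized trait *x* decomposes as R²ₖ = (bₖᵀxₛ)² with ΣR²ₖ = 1, one bar
per node from root-like to tip-like (decreasing node complexity np). Four
statistics are permutation-tested: R2Max = max R²ₖ, SkR2k = Σ k·R²ₖ
(root-vs-tip skew, two-sided), Dmax = maxₘ |Cₘ − m/B| (KS-type), and
SCE = Σₘ (Cₘ − m/B)². Pointwise permutation envelopes attribute signal to
specific nodes.

**Abouheif's C-mean.** Proximity wᵢⱼ = Π 1/dd(v) over the internal nodes on
the i↔j path (MRCA included), diagonal filled so rows sum to one; the
statistic is C = zᵀWz / zᵀz on the centered trait, permutation-tested
upper-tailed.

**Everything around them.** TPS reading/writing, centroid size, generalized
Procrustes analysis, covariance shape PCA, squared-change parsimony for
ancestral landmark configurations (exact Laplacian solve; optional linear
criterion), Hartigan/Fitch parsimony for binary characters, Kruskal–Wallis
and Holm-adjusted pairwise Wilcoxon tests for bsL/stL skull ratios, and a
synthetic-data generator (Yule topologies, Brownian vs white-noise traits
and landmark sets) with known ground truth.

## Worked example

```r
library(cladosig)

tree <- read_topology("(((A,B),(C,D)),((E,F),(G,H)));")
x <- simulate_trait(tree, "brownian", sigma = 1, seed = 42)
orthogram_test(x, tree, n_perm = 999, seed = 1)
```

```
Orthonormal decomposition of trait variance (topology-only)
  8 tips, 7 basis columns, 999 permutations, seed 1
  R2Max  =   0.8075   p = 0.0200 (upper)
  SkR2k  =   1.8183   p = 0.0420 (two-sided)
  Dmax   =   0.6647   p = 0.0110 (upper)
  SCE    =   1.0123   p = 0.0220 (upper)
  nodes above the upper envelope: 9 (np=8, R2=0.808)
```

Read: 81% of trait variance sits on the root contrast (node 9, np = 8), far
above its 95% permutation envelope; SkR2k is near its minimum of 1, meaning
the variance is skewed to the base of the tree, and the cumulative curve
departs significantly from uniformity (Dmax, SCE). All four statistics
agree: strong, basally concentrated signal — exactly what Brownian
evolution on this tree produces. The companion test concurs:

```r
c_mean_test(x, tree, n_perm = 999, seed = 2)
#> Abouheif C-mean = 0.5526, p = 0.0290 (999 permutations, upper tail)
```

## The analysis workflow

Numbered scripts under `analysis/` run a complete synthetic study (the real
specimens are not redistributable; the stand-in cladogram and habitat
codings under `inst/extdata/` are labelled synthetic):

1. `01_simulate.R` — 16-tip ursid-style cladogram; Brownian basicranium
   landmarks (TPS); shuffled centroid sizes; specimen measurement table.
2. `02_signal_screen.R` — GPA → shape PCA → screen PC1–PC5 and CS with both
   tests. Expected and observed: "signal" for PC1–PC2 with basal nodes
   flagged, "no signal" for PC3–PC5 and CS.
3. `03_ancestral.R` — squared-change shapes at all internal nodes (tree
   score reported), Fitch optimization of open/closed habitat.
4. `04_ratios.R` — Kruskal–Wallis + pairwise Wilcoxon on bsL/stL ratios
   across subfamilies.
5. `05_calibration.R` — type-I error and power of all five statistics on
   32-tip Yule trees.

Each stage prints what it found and writes tables under `results/`.

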