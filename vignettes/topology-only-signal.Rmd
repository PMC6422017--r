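---
title: "Topology-only phylogenetic signal: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology-only phylogenetic signal: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladosig)
```

## The problem

Phylogenetic signal is the tendency of closely related species to resemble
each other more than distant relatives. Testing for it usually requires
branch lengths, but composite phylogenies (supertrees) for clades rich in
fossils — such as the bears, Ursidae — often carry trustworthy topology and
no trustworthy branch lengths at all. `cladosig` implements two signal tests
that consume *only* the topology of a rooted cladogram, together with the
geometric-morphometric quantification that typically feeds them (landmark
shapes of the basicranium, centroid size) and two topology-only
reconstruction tools (squared-change parsimony for ancestral landmark
shapes, Fitch parsimony for binary ecological characters).

## The orthogram: orthonormal decomposition of trait variance

For a rooted tree with $n$ tips, each internal node $v$ with children
$c_1,\dots,c_m$ contributes $m-1$ Helmert-style contrast columns: column $j$
($2 \le j \le m$) opposes the pooled tips of $c_1,\dots,c_{j-1}$ (value $a$)
to the tips of $c_j$ (value $b$), zero elsewhere, with $a, b$ fixed by
centering and unit norm:

$$a = \sqrt{\frac{n_2}{n_1 (n_1+n_2)}}, \qquad
  b = -\sqrt{\frac{n_1}{n_2 (n_1+n_2)}},$$

where $n_1, n_2$ are the tip counts of the pooled and the opposed part.
Columns of one node are orthogonal by the Helmert construction; columns of
different nodes are orthogonal because the deeper node's column sums to zero
inside any clade on which the shallower one is constant. The resulting
matrix $B$ ($n \times (n-1)$) satisfies $B^\top B = I$ and $B^\top
\mathbf{1} = 0$ exactly, so together with the constant vector it is an
orthonormal basis: standardizing a trait $x$ (centered, unit norm, uniform
tip weights) and projecting gives squared coefficients $R^2_k = (b_k^\top
x_s)^2$ with $\sum_k R^2_k = 1$ (Parseval).

Columns are indexed by decreasing node complexity `np` (descendant tip
count), ties broken by preorder rank, so the orthogram reads from root-like
to tip-like nodes, and the ordering statistic below is well defined. For
polytomies the individual columns of a node are a convention (any
orthonormal rotation of a node's block spans the same subspace), but the
*per-node* sum of $R^2_k$ is rotation-invariant — node attribution does not
depend on the convention, which the test suite verifies directly.

Four summaries of the ordered $R^2$ sequence are tested:

* **R2Max** $= \max_k R^2_k$ — dependence concentrated at a single node;
* **SkR2k** $= \sum_k k\,R^2_k$ — skew of variance toward the root (small)
  or the tips (large);
* **Dmax** $= \max_m |C_m - m/B|$, with $C_m$ the cumulative sum and $B =
  n-1$ — a Kolmogorov–Smirnov-type deviation from uniformity;
* **SCE** $= \sum_m (C_m - m/B)^2$ — the accumulated squared deviation.

Significance comes from Monte Carlo permutation of the trait across tips
(the exact null under exchangeability), with the add-one estimate
$p = (1 + \#\{T^{perm} \ge T^{obs}\})/(n_{perm}+1)$. R2Max, Dmax and SCE are
upper-tailed; SkR2k is two-sided (doubled smaller tail, capped at 1),
because variance may skew either toward the root or toward the tips and the
direction is not prescribed a priori. Dmax uses the absolute deviation, the
two-sided KS convention. Pointwise permutation envelopes (upper $1-\alpha$
quantile per bar; $\alpha/2, 1-\alpha/2$ per cumulative position) support
node attribution: bars above the envelope mark nodes carrying significantly
concentrated variance.

## Abouheif's C-mean

The proximity between distinct tips $i,j$ is
$$w_{ij} = \prod_{v \in P(i,j)} \frac{1}{\mathrm{dd}(v)},$$
the product over internal nodes on the tree path between them (most recent
common ancestor included) of inverse direct-descendant counts; the diagonal
is filled so each row sums to one, making the symmetric matrix
bistochastic — the "non-null diagonal" construction. The statistic is the
Moran-type form $C = z^\top W z / z^\top z$ with $z$ the centered trait: zero
in expectation without structure (exactly zero on a star tree, where $W$ is
constant), positive when proximate tips agree. The permutation test is
upper-tailed, since phylogenetic signal is positive autocorrelation.

## Upstream morphometrics

Landmark input is the plain-text TPS dialect (`LM=`, coordinate lines,
`ID=`/`IMAGE=`/`SCALE=`). Centroid size is
$\mathrm{CS} = \sqrt{\sum_l \lVert p_l - \bar p\rVert^2}$. Generalized
Procrustes analysis translates each configuration to centroid origin, scales
to unit CS, and iteratively rotates to the running mean shape (orthogonal
Procrustes via SVD, reflections excluded by forcing the rotation determinant
to $+1$), until the mean changes by less than `tol` (default `1e-10`
Frobenius, `max_iter` 100). Full GPA with unit-size scaling is used, not
partial Procrustes, because size is analysed separately as CS. Shape PCA is
a covariance PCA of the flattened aligned coordinates — the shape-analysis
convention, since all coordinates share units. Translation and scale are
removed exactly, so two or three eigenvalues are machine zero; the rotation
constraint is nonlinear, leaving second-order (noise-variance-squared)
crumbs in the rotation direction rather than an exact zero. Multi-specimen
species are mapped onto tree tips by per-species means of scores and CS.

## Ancestral reconstruction

Squared-change parsimony minimizes $\sum_{(a,d)} \lVert X_a - X_d
\rVert_F^2$ over branches with equal weights (there are no branch lengths to
weight by). The optimum is the unique solution of a Laplacian linear system
in which every internal node is the mean of its tree neighbours; it is
solved exactly, one dense solve for all coordinates at once, and doubles as
the Brownian-motion best linear predictor under unit edges. A `linear`
criterion (sum of unsquared Frobenius distances, closer to spatial-parsimony
tree scores) is available via Weiszfeld iterations started from the squared
solution, with a `1e-12` distance floor guarding degenerate steps and
convergence on score change below `tol`. The criterion used is recorded in
the result. Binary characters are optimized with two-pass Fitch parsimony
using Hartigan-style majority counts at each node, which is exact on
polytomies where naive pairwise folding undercounts; ambiguous nodes adopt
the parent's state in the top-down pass.

## Rank tests for skull proportions

The basicranium/skull length ratio is compared across subfamilies with
`stats::kruskal.test` (tie-corrected H, chi-square reference) and
`stats::pairwise.wilcox.test` (exact small-sample null when possible,
normal approximation with tie correction otherwise). The pairwise adjustment
defaults to Holm's step-down — a choice recorded in the output, since the
convenience function's default is the natural reading of "pairwise Wilcoxon
tests" in an R workflow. Specimens are the unit of analysis for the group
tests; species means are reported separately.

## The synthetic-data generator

Because the study specimens behind the motivating analysis are not
redistributable, the package carries a generator that reproduces the
*structure* of such a dataset with known ground truth:

* **Trees**: Yule topologies (repeated uniform tip splitting), binary,
  labels assigned exchangeably; no branch lengths, matching the analysis
  regime. A polytomy-injecting variant (random collapse of internal edges)
  exercises multifurcation handling.
* **Traits**: Brownian motion with unit-length edges and per-edge step sd
  `sigma` (high signal), versus i.i.d. Gaussian white noise (no signal, the
  exact permutation null).
* **Landmarks**: independent per-coordinate Brownian motion from a base
  shape, or white-noise perturbations of it, written as TPS.
* **Measurements**: specimens nested in species nested in groups with
  group-specific mean ratios, lognormal skull lengths, and a missing-data
  fraction emulating incomplete fossils.

Default experiment scale is 32 tips, 500 replicate datasets, `sigma` 1.0 and
999 permutations — enough for rejection-rate estimates with binomial
standard error about 1%, and minutes-scale runs on one core. The end-to-end
landmark runs use 8 landmarks with step sd 0.1 on a unit-radius base shape,
25 signal and 100 null replicates. What these simulations do **not** emulate:
correlated evolution among landmarks, non-ultrametric fossil sampling,
measurement error, and within-species shape variance. Passing tests
therefore demonstrate the statistical machinery is correct and calibrated
under the stated models, not that any particular empirical dataset carries
signal.

## Numerical and design choices

* `n_perm` defaults to 999; add-one p-values avoid exact zeros; all
  permutation engines take an explicit seed and record it, making runs
  bit-reproducible.
* Orthonormality and completeness hold to better than `1e-10` by
  construction (verified to ~`1e-15` in practice); the decomposition refuses
  constant traits.
* Branch lengths found in input Newick are dropped with a warning rather
  than an error: topology-only analysis is the package's contract.
* A basal trifurcation (unrooted-style Newick) is accepted as a rooted
  polytomy at the root; no rerooting is attempted.
* The screen verdict calls "signal" when at least two of the four orthogram
  statistics are significant at `alpha`, or the C-mean is. A single
  significant statistic among four is weak evidence once their correlation
  is considered; requiring two formalizes the "diffuse dependence" reading
  in which several statistics must depart from the null together. All
  per-statistic p-values are reported so users can apply stricter or looser
  rules.
* Tip-label reconciliation between tree and trait table is strict by
  default; an explicit `policy = "prune"` drops tree tips absent from the
  table, with a logged list.
* Which cladogram to analyse (where several competing topologies exist) is
  simply the tree handed in; the package makes no equivalence claim across
  topologies — run the screen per cladogram and compare.

## Limitations

Topology-only tests discard real information when reliable branch lengths
exist; branch-length-aware statistics (Pagel's lambda, Blomberg's K) are
deliberately out of scope. The squared-change reconstruction assumes
superimposed inputs and equal branch weights; it does not re-run GPA and
does not model landmark covariance. The linear criterion's optimum may be
non-unique on symmetric configurations. Exact Wilcoxon p-values are
unavailable with ties, where the normal approximation is used. P-value
granularity is `1/(n_perm+1)`; published permutation p-values can only be
matched to within Monte Carlo error.
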