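---
title: "Distances between extension spaces of phylogenetic trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distances between extension spaces of phylogenetic trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(extspace)
```

## The problem

Phylogenetic trees estimated from different genes rarely carry identical
leaf sets: gene gain, loss and transfer mean that even closely related
organisms share only part of their gene content. The
Billera--Holmes--Vogtmann (BHV) space gives trees on a *common* leaf set a
complete geodesic metric that accounts for both topology and branch
lengths, but it says nothing about trees whose leaf sets differ.

`extspace` implements a dissimilarity for that situation. A tree $T$ on
leaves $\mathcal{L} \subseteq \mathcal{N}$ is represented in the larger BHV
space $\mathcal{T}_\mathcal{N}$ by its *extension space*
$E_T^\mathcal{N}$: every tree on $\mathcal{N}$ whose restriction to
$\mathcal{L}$ (pruning the other leaves and merging the resulting
degree-2 vertices by summing branch lengths — the tree dimensionality
reduction, or TDR, map $\Psi_\mathcal{L}$) equals $T$. The distance between
two trees $T_1, T_2$ with leaf sets
$\mathcal{L}_1, \mathcal{L}_2 \subseteq \mathcal{N}$ is then

$$ d(E_{T_1}^\mathcal{N}, E_{T_2}^\mathcal{N})
   = \inf_{(t_1, t_2) \in E_{T_1}^\mathcal{N} \times E_{T_2}^\mathcal{N}}
     d(t_1, t_2), $$

the shortest BHV distance between the two extension spaces. A pair
achieving the infimum is an *optimal pair*; the midpoint of the geodesic
joining an optimal pair is a natural candidate "supertree" that averages
the two phylogenies.

This quantity is a dissimilarity, not a metric: distinct trees can have
intersecting extension spaces (distance zero), and the triangle inequality
can fail. When $\mathcal{L}_1 = \mathcal{L}_2 = \mathcal{N}$ it reduces
exactly to the BHV distance.

## Structure of the computation

**Geodesics.** Within the BHV space, the unique geodesic between two trees
is characterized by its *proper support*: ordered partitions
$(A_1, \dots, A_k)$ and $(B_1, \dots, B_k)$ of the two trees' uncommon
internal splits with nondecreasing norm ratios
$\lVert A_i \rVert / \lVert B_i \rVert$ and a minimum-weight vertex-cover
condition on each pair's bipartite incompatibility graph (vertex weights
$|a|^2 / \lVert A_i \rVert^2$ and $|b|^2 / \lVert B_i \rVert^2$). The
squared length is
$\sum_i (\lVert A_i \rVert + \lVert B_i \rVert)^2 +
 \sum_{s \in K} (|s|_{T_1} - |s|_{T_2})^2$,
where $K$ collects the common internal splits and all external edges. The
engine refines the support from the single all-uncommon pair, splitting any
pair whose minimum cover weighs less than one (strict comparison with
tolerance $10^{-12}$). Covers are found exactly: by subset enumeration
over the smaller side when it has at most 14 vertices, and by an s--t
minimum cut (maximum flow, via igraph) beyond that. At the sizes where the
orthant-pair search is tractable the enumeration path is always taken; the
flow path keeps the engine correct for larger single-geodesic queries.

**Extension spaces, one orthant at a time.** Restricted to one maximal
orthant $O$ of the connection cluster (enumerated by attaching missing
leaves to every edge in a fixed order — with a fixed order the attachment
sequences biject onto the $(2n-5)!!/(2l-5)!!$ cluster orthants, so no
deduplication pass is needed), the extension space is the affine slice
$M_\mathcal{L}^O x = v_T$, $x \ge 0$, where the 0/1 matrix
$M_\mathcal{L}^O$ records which orthant edge projects onto which tree
edge. Edges in no path between retained leaves project to nothing: these
*inconsequential* edges are free in the extension space but do affect the
distance to the other tree. For an orthant pair, the *mutually restricted*
space pins every inconsequential edge — copied from the tree where the
edge is consequential when the edge is shared, zero otherwise — which
provably contains a minimizing pair and makes the feasible set convex and
compact.

**Per-pair optimization.** On each orthant pair the squared distance
$\delta(\dot x)$ is convex in the consequential edge lengths $\dot x$, and
the constraints form the block system
$\operatorname{diag}(\ddot M_1, \ddot M_2) \dot x = (v_{T_1}, v_{T_2})$
with one unit entry per column. The reduced gradient method classifies
variables as dependent (one per constraint row; the unit-column structure
makes the dependent block a permutation, so no linear solves are needed),
free, or null (pinned at zero), descends along the projected steepest
descent direction with an exact line search, and on termination evaluates
the multiplier vector $\bar\mu$ over the null variables; a nonnegative
$\bar\mu$ certifies the global optimum of the convex program, otherwise
the flagged variables are released and descent resumes.

**Global search.** The per-pair minima over all
$\Omega = (2n-5)!!^2 / ((2l_1-5)!!\,(2l_2-5)!!)$ orthant pairs are reduced
by a plain minimum; ties within a relative tolerance of $10^{-6}$ are
collected as distinct optimal pairs (deduplicated as trees with edge-length
tolerance $10^{-7}$), and geodesic midpoints of the optimal pairs are
reported as candidate supertrees. Per-pair computations are pure functions
of their inputs, so the loop parallelizes trivially; the package runs them
sequentially, which is adequate at the problem sizes it targets.

## Numerical choices

- **Gradient of $\delta$.** Each variable contributes to exactly one
  quadratic term of $\delta$: $2\dot x_p (1 + \lVert B_i \rVert /
  \lVert A_i \rVert)$ for a dropped split $p \in A_i$ (symmetrically for
  added splits), and $2(\dot x_s^1 - \dot x_s^2)$ for a common split
  consequential in both trees. Where a support leg has zero norm the
  derivative does not exist; `gradient_delta()` flags those entries and
  returns zero for them (a subgradient choice). Inside the optimizer the
  flagged entries are instead replaced by a forward-difference estimate of
  the one-sided directional derivative, which exists by convexity. This
  matters: the zero placeholder systematically underestimates the cost of
  growing an edge whose support leg is empty, and with it the descent
  direction can stall at non-stationary boundary points, while the
  one-sided estimate lets the certificate classify such variables
  correctly.
- **Line search.** The restriction of $\delta$ to a ray is convex and
  piecewise smooth, so its slope is nondecreasing; the step is found by
  root-finding on the analytic slope (Brent's method on
  $\varphi'(\tau)$), falling back to the boundary step when the slope
  stays negative. Slope root-finding rather than function-value
  minimization is what makes gradient norms of $10^{-8}$ reachable: near
  the optimum, objective *differences* fall below double-precision
  resolution while the slope remains well determined.
- **Tolerances.** Reduced-gradient stopping tolerance $10^{-8}$;
  feasibility $10^{-9}$ per constraint row (absolute, appropriate because
  the targets are sums of input branch lengths); certificate release
  threshold equal to the gradient tolerance; iteration cap 500 per orthant
  pair. Tree equality in tests uses absolute length tolerance $10^{-9}$
  with an absent split counting as length zero, so zero-length edges
  compare equal to collapsed ones.
- **Degenerate inputs.** Zero-length uncommon splits sit in support legs
  with zero contribution; zero-norm leg sides collapse onto the
  common-edge treatment (their squared lengths add independently), which
  keeps the length formula continuous at orthant boundaries. A
  rooted Newick input has its degree-2 root suppressed and the two
  incident lengths summed; `keep_root = TRUE` instead retains the root as
  a pseudo-leaf `__root__`, the standard rooted-to-unrooted equivalence.
- **Tie-breaks.** When several variables reach zero in one step, the one
  with the most negative gradient entry is reclassified (any choice is
  admissible); when a dependent variable must leave the basis, the free
  variable with the largest current value in the same row replaces it,
  keeping the dependent block a well-conditioned permutation.

## The synthetic-data generator

`random_binary_tree()` draws a uniformly random binary topology by
sequential attachment (each of the $2m-3$ edges of the growing $m$-leaf
tree equally likely) with i.i.d. branch lengths. Two length regimes are
provided: a unimodal lognormal with mean 5 and variance 1, and a
long-branch mixture of lognormals with means 5 and 60 (variances 1 and 10)
in proportions 75/25. "Mean 5, variance 1" is interpreted as the moments
of the lognormal variable itself, with $\mu, \sigma^2$ back-solved from
them; `parameterization = "underlying"` switches to reading them as the
moments of the underlying normal, since the phrasing is ambiguous in parts
of the literature. `make_scenario_pair()` exposes the six named size
presets (a)--(f) with leaf-count triples $(7,6,4)$, $(7,6,4)$, $(7,5,4)$,
$(10,9,8)$, $(10,8,8)$ and $(10,8,7)$, drawing the two leaf subsets so
their overlap is exactly $l_1 + l_2 - n$.

The generator emulates the *sizes and length scales* of realistic gene
trees, not their phylogenetic signal: the two trees of a pair are
independent, whereas real gene trees are correlated through the species
history, and real branch lengths are neither i.i.d. nor
topology-independent. Tests passing on these fixtures therefore establish
the correctness of the geometry and optimization, not calibration against
biological data.

## What the tests compute

The suite checks every layer against an independent oracle at sizes where
exhaustion is exact: geodesic lengths against brute-force enumeration of
all ratio-ordered valid supports on 5-leaf trees; per-orthant-pair minima
against a dense zooming-grid search over the feasible polytope on systems
with at most 4 free dimensions (5--6 leaves); cluster enumerations against
the double-factorial closed form for all $3 \le l \le n \le 7$ plus the
2145- and 195-orthant enumerations at 7 and 8 of 10 leaves; the full
search against per-pair brute force at 5 leaves; analytic gradients
against central finite differences at 500 random interior feasible
points; and zero-distance witnesses built by projecting one tree to two
overlapping leaf subsets. These sizes keep the default test run in the
minutes range while leaving every code path exercised; the acceptance
script (`scripts/acceptance.R`) recomputes the counting quantities from
scratch at the application scale (7--11 leaves).

## Limitations

- The orthant-pair count $\Omega$ grows super-exponentially in the number
  of missing leaves; the sequential search is practical to roughly
  $|\mathcal{N}| \approx 10$ with a few unshared leaves per tree.
  Pruning provably suboptimal orthant pairs is the natural next step and
  is out of scope here.
- Input trees must be binary (extension spaces of multifurcating trees
  would require unioning the clusters of all resolutions, which the
  mutual-restriction theory does not cover); zero-length edges are
  accepted.
- The dissimilarity is not a metric — zero distance does not imply equal
  trees, and the triangle inequality can fail — so downstream methods
  that assume metric axioms should be applied with care.
- Whether the distance is invariant to enlarging $\mathcal{N}$ beyond
  $\mathcal{L}_1 \cup \mathcal{L}_2$ is open; the package tests monotone
  non-increase empirically on small instances and makes no stronger claim.
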