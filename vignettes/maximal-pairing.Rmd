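---
title: "Maximal pairing on phylogenetic trees: models, algorithms, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximal pairing on phylogenetic trees: models, algorithms, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytarget)
```

## The problem

Pairwise comparative analyses — matched-pair tests of trait associations,
targeted sequencing of contrast pairs — are statistically independent only
if no branch of the phylogeny contributes to two comparisons. Modelling a
comparison between taxa $x$ and $y$ as the unique tree path $\pi_{xy}$,
independence becomes **edge-disjointness**: two paths may meet at a vertex
(which is what makes polytomies useful) but may not share an edge. A
*path-system* is a set of leaf pairs with pairwise edge-disjoint paths, no
leaf used twice. Given a symmetric, non-negative pair weight
$\omega_{xy}$ — informativeness, trait contrast, feasibility — the maximal
pairing problem (MPP) asks for a path-system of maximum total weight.

Weights enter as an explicit table (`load_weight_table`), or as one of the
structural modes: `unit_weights` (maximize the number of pairs),
`path_length_weights` (maximize the number of edges covered), or
`edge_sum_weights` (sum arbitrary non-negative per-edge weights along each
path; branch lengths by default). Negative weights are rejected in every
mode: the matching construction below needs $\omega \ge 0$, and one
contract is simpler than two. Estimating $\omega$ from character data is
out of scope; the package starts where a weight table exists.

## Binary trees: dynamic programming

Two arrays drive the solver. $S_u$ is the optimal score on the subtree
$T[u]$; $R_{ux}$ is the optimal score on $T[u]$ over systems edge-disjoint
with the path from $u$ to the leaf $x \in T[u]$ — the situation that
arises when a path through $u$'s parent has already claimed the edges down
to $x$. At a leaf, $S_x = R_{xx} = 0$. With children $v, w$ of $u$ and
$u_x$ the child towards $x$ (the navigation table `build_nav_table`):

$$R_{ux} = S_{\mathrm{sib}(u_x)} + R_{u_x x}, \qquad
S_u = \max\Big( S_v + S_w,\; \max_{x \in L(v),\, y \in L(w)}
\omega_{xy} + R_{vx} + R_{wy} \Big).$$

The argmax (or "no crossing pair") is recorded at each node; backtracing
walks these records from the root, decomposing $R$ along each emitted
path's spine. Each leaf pair is examined exactly once, at its last common
ancestor, so the forward pass is $O(n^3)$ in the worst case ($O(n^2)$
pairs, $O(n)$ spine work) with $O(n^2)$ table space.

**Tie-breaking.** Among equal-score alternatives the solver prefers *no*
crossing pair (fewer, cheaper-to-audit pairs), then the lexicographically
smallest pair by leaf label. This makes output byte-identical across runs
and platforms; the tests rely on it.

## Multifurcating trees: matchings at polytomies

At a polytomy with children $C$, more than one path can cross the node,
and the choice of which child subtrees to connect is a matching problem.
For each child pair $(v', v'')$ the best single crossing path contributes
$\hat\omega_{v'v''} = \max \omega_{xy} + R_{v'x} + R_{v''y}$
(`compute_pair_score_hat`). The *auxiliary graph* (`build_aux_graph`) has
two copies of each child; pair edges carry $\hat\omega$, and each self
edge $(v, v^*)$ carries $S_v$. A maximum-weight matching in which every
child vertex is covered corresponds exactly to a path-system on $T[u]$:
matched pairs become crossing paths, self-matched children contribute
their independent optimum. Since $S_v \ge 0$, covering an exposed child
with its self edge never costs anything, so the covered optimum equals
the unconstrained matching optimum (`max_weight_matching` applies this
post-processing).

For backtracing, the matching for $S_u$ and, for each child $k$, the
matching on $C \setminus \{k\}$ (the value $Q_{u,k}$, needed when a path
from above enters through $k$) are tabulated. $Q$ is stored per child,
not per leaf: the value depends only on which child the pending path
uses.

**The matcher.** No exact general-graph (non-bipartite) maximum-weight
matching routine is available among this package's dependencies, so it
ships its own: an exact dynamic program over vertex subsets
(`mwm_exact`), with the pendant starred copies contracted first so the
DP runs on $|C|$ vertices with reduced edge weights
$\hat\omega - S_{v'} - S_{v''}$. This is exponential in the polytomy
degree and exact for what it accepts; polytomies with more than 18
children are rejected with a clear error. That bound is far above the
polytomy degrees of practical consensus trees; a blossom-type algorithm
would lift it without changing any contract, and could be swapped in
behind `max_weight_matching`. Edges of non-positive reduced weight are
never taken, which realizes the fewer-pairs tie-break at polytomies too.

## Constrained variants (binary trees)

**At most $\kappa$ pairs.** Tables gain a budget index:
$S_{u,k}$ and $R_{ux,k}$ are the optima using at most $k$ pairs, with
$S_{u,0} = 0$, $R_{xx,l} = 0$, convolution over the split of the budget
between the two sides, and one unit spent on a crossing pair. "At most"
rather than "exactly" is the deliberate contract: with $\omega \ge 0$
the optimum is non-decreasing in $\kappa$, every prefix budget is
meaningful, and degenerate "must waste pairs" cases cannot arise. The
answer is $S_{\mathrm{root},\kappa}$; backtracing recomputes each max and
follows the first achieving decomposition (no-new-pair splits first, then
pairs in label order), reproducing the forward tie-breaks exactly because
identical sums of identical doubles are identical.

**Required taxa.** To force a set $Z$ of taxa into the solution the leaf
initialization changes to $S_x = -\infty$ for $x \in Z$ (a required leaf
left to its own subtree's system is a failure), while $R_{xx} = 0$
remains (a pending path through $x$ covers it). The $-\infty$ sentinel —
IEEE $-\infty$, which propagates correctly through `max` and `+` in R —
then absorbs every decomposition that strands a required leaf, and the
same recurrences, records and backtracing apply unchanged.
$S_{\mathrm{root}} = -\infty$ means infeasible; the parity fact that a
subtree whose leaves are all required and odd in number is infeasible
falls out automatically, and the tests assert it.

**Prescribed pairs.** A set of already-committed pairs is handled by
preprocessing, valid on any tree: their endpoints' pendant edges are on
their paths, so blocking every pair whose path shares an edge with a
prescribed path (weight set to the $-\infty$ sentinel) both removes the
endpoints and protects the claimed edges. The residual problem is an
ordinary MPP; adding back the prescribed weight gives the best extension.
The solvers treat a $-\infty$ weight as "pair unavailable"; since some
finite alternative ($S_v + S_w \ge 0$) always exists, sentinels never
reach a reported score.

Bounded-count and required-taxa versions for *multifurcating* trees would
need matchings with a fixed edge count or forced vertices; those are not
provided, and such inputs raise an `mpp_unsupported_variant` error rather
than silently brute-forcing.

## The Boltzmann ensemble (binary trees)

Replacing max by sum turns the optimizer into a partition function: every
path-system $\Upsilon$ gets weight $e^{\beta\,\omega(\Upsilon)}$,

$$Z_u = Z_v Z_w + \sum_{x \in L(v),\, y \in L(w)}
e^{\beta \omega_{xy}}\, ZR_{vx}\, ZR_{wy}, \qquad
ZR_{ux} = Z_{\mathrm{sib}(u_x)}\, ZR_{u_x x},$$

with $Z = 1$ at leaves (the empty system counts). The **sign
convention** is $e^{+\beta\,\mathrm{score}}$ — equivalently, energy
$=-\mathrm{score}$ — because the MPP *maximizes*: larger $\beta$ must
emphasize optimal systems, and does. At $\beta = 0$, $Z$ is the number of
valid path-systems.

The probability that a pair $(x, y)$ appears in a system drawn with
probability proportional to its Boltzmann weight is
$P_{xy} = Z(\pi_{xy})/Z$, where the restricted partition function
$Z(\pi_{xy})$ starts at the pair's last common ancestor $k$ as
$e^{\beta\omega_{xy}} ZR_{vx} ZR_{wy}$ and is propagated to the root.
The key structural fact: the path through $k$ occupies both of $k$'s
child edges, so no other path can leave $T[k]$; at each ancestor, only
pairs avoiding $T[k]$ can cross, and the hanging subtree containing $k$
contributes its restricted value in place of its free one. One pair costs
$O(n^2)$ here; `ensemble_expected_pairs` sums all pairs.

**Numerics.** All accumulation is in the log domain with log-sum-exp, so
$\beta\,\mathrm{score}$ products in the hundreds (e.g. $\beta = 50$ on
integer weights) lose no precision and cannot overflow; the identity
tests against exhaustively enumerated Boltzmann sums hold to $10^{-9}$
relative and pass at machine precision.

**Degenerate optima.** The zero-temperature limit is
$\tfrac1\beta \log Z \to S_{\mathrm{root}} + \tfrac{\log m}{\beta}$ with
$m$ the number of *tied* optimal systems, and tied optima split the
probability mass: on the quartet fixture with two score-3 optima,
$P(a,c) \to 1/2$, not 1. The tests assert the degeneracy-corrected
limit; ignoring $m$ is only valid when the optimum is unique.

## Oracle, generators, and what the tests show

`enumerate_path_systems` builds every valid path-system (up to 12 leaves)
by extending partial pairings in leaf order, pruning on edge conflicts —
so only valid systems are ever touched. It is deliberately independent
of the DP machinery: same definitions, different algorithm. Every solver
in the package is tested for exact agreement with it on hundreds of
seeded instances, and the constrained and ensemble variants against its
filtered maxima and Boltzmann sums.

The generators emulate the *combinatorial* conditions of the problem:
uniform sequential-attachment binary topologies, recursive-partition
multifurcating topologies with a degree cap (default studies use degree
≤ 5), and i.i.d. symmetric integer weights in $0..9$ — chosen to
exercise ties, zeros and polytomies hard. Test instances use 2–10 leaves
(within the oracle's reach, with all topology shapes represented), 2–12
for the unit-weight pairing law, and a 200-leaf multifurcating instance
as a timing check (it solves in well under a second). What passing shows:
the implementation realizes its definitions exactly, at every size the
oracle can verify, and the DP's structure makes no size-dependent
approximations — so agreement at small $n$ is evidence for all $n$. What
it does not show: anything about the *statistical* merit of a weight
scheme on real data — phylogenetically realistic (birth–death,
coalescent) topologies and empirically estimated weights are explicitly
not modelled.

## Degenerate inputs and small contracts

* Single-leaf trees: score 0, empty system (ape cannot represent them;
  the Newick parser special-cases them).
* Unary chains in Newick input are collapsed with branch lengths summed,
  with a warning — common in exported trees, and the algorithms assume
  them away.
* Rooting: scores are invariant to root placement (paths do not depend
  on the root); `root_unrooted` places a root deterministically on the
  edge to the first child so runs are reproducible, and the tests check
  score invariance across all placements.
* Scores are doubles; integer-weight comparisons in tests are exact,
  float comparisons use $10^{-9}$ absolute tolerance; the backtrace
  defensively re-scores its output and refuses to return on mismatch.

## Known limitations

Polytomies above degree 18 (matcher bound); no bounded-count or
required-taxa variants and no partition function on multifurcating trees;
no sampling of path-systems from the ensemble (probabilities only); the
oracle stops at 12 leaves by design. The all-pairs probability mode costs
$O(n^4)$ and is meant for the modest trees where per-pair support is
interpretable at a glance.
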