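# phytarget

Exact solvers for the **maximal pairing problem (MPP)** on rooted
phylogenetic trees: given a tree `T` with leaf set `L` and a symmetric,
non-negative weight `ω(x, y)` on leaf pairs, find a set of leaf pairs whose
connecting paths are pairwise **edge-disjoint** and whose total weight
`Σ ω(x, y)` is maximal.

This is the combinatorial core of *phylogenetic targeting*: choosing pairs
of taxa for expensive downstream data collection so that the pairwise
comparisons are phylogenetically independent. Edge-disjointness of the
leaf-to-leaf paths is exactly the independence requirement of pairwise
comparative methods — no branch of the tree contributes to two
comparisons — while the weights encode how informative each candidate pair
would be (trait contrast, data availability, cost, ...). The package is
for comparative biologists planning taxon sampling, and for anyone needing
exact maximum-weight edge-disjoint path packings on trees.

## What it computes

* **Binary trees** — a post-order dynamic program over two score arrays:
  `S(u)`, the optimal path-system weight in the subtree `T[u]`, and
  `R(u, x)`, the optimum in `T[u]` among systems edge-disjoint with the
  pending path from `u` down to leaf `x` (`S(x) = R(x, x) = 0` at leaves).
  At a node with children `v, w`, either the child optima combine, or one
  path is spent on the best crossing pair:

  ```
  S(u) = max( S(v) + S(w),
              max_{x ∈ L(v), y ∈ L(w)}  ω(x, y) + R(v, x) + R(w, y) )
  ```

  O(n³) time, O(n²) space, with backtracing from recorded argmax pairs.
* **Multifurcating trees** — at a polytomy with children `C`, the optimal
  combination of child subtrees is an exact **maximum-weight matching** on
  an auxiliary graph with two copies of each child: pair edges carry the
  best crossing-path contribution `ω̂(v′, v″)`, self edges `(v, v*)` carry
  the subtree optimum `S(v)`. Because weights are non-negative, every
  child can be covered without loss, and matchings correspond exactly to
  path-systems. Matchings are tabulated per node (and per excluded child)
  for backtracing.
* **Constrained variants (binary trees)** — at most `κ` pairs
  (`solve_binary_kappa`); required taxa that must appear in the solution
  (`solve_binary_required`, with infeasibility detection); extension of an
  already-chosen pair set (`solve_with_prescribed`, any tree).
* **Boltzmann ensemble (binary trees)** — the partition function
  `Z = Σ_Υ exp(β · ω(Υ))` over *all* valid path-systems `Υ` and per-pair
  selection probabilities `P(x, y)` (`partition_function`,
  `path_probability`), computed in the log domain. At `β = 0`, `Z` counts
  the valid path-systems; as `β → ∞` the ensemble concentrates on the
  optima.
* **Brute-force oracle** (`enumerate_path_systems`, ≤ 12 leaves) and
  seeded random generators (`random_binary_tree`,
  `random_multifurcating_tree`, `random_weights`) used throughout the
  tests — and available to you for verification (`selfcheck()`).

## Worked example

A quartet `((a,b)u,(c,d)v)r;` with weights favouring the two cross pairs
(`ω(a,c) = ω(b,d) = 3`, cherries 1, the rest 0). The two "crossing"
perfect pairings `{(a,c),(b,d)}` and `{(a,d),(b,c)}` are invalid — their
paths share the two root edges — so the optimum is a single cross pair:

```r
library(phytarget)
tree <- read_newick(system.file("extdata", "quartet.nwk", package = "phytarget"))
w <- load_weight_table(system.file("extdata", "quartet_weights.tsv",
                                   package = "phytarget"), tree)
(sol <- solve_mpp(tree, w))
#> Maximal pairing solution (score 3)
#> Path-system: 1 pair, score 3
#>  leaf1 leaf2 weight
#>      a     c      3

validate_path_system(tree, w, sol$system)$valid
#> [1] TRUE

partition_function(tree, w, beta = 0)$Z   # number of valid path-systems
#> [1] 8
ens <- partition_function(tree, w, beta = 1)
path_probability(ens, "a", "c")           # ensemble support for (a,c)
#> [1] 0.3586915
ensemble_expected_pairs(ens)
#> [1] 1.1141
```

The score 3 beats the two-cherry system `{(a,b),(c,d)}` (score 2); the
ensemble at `β = 1` puts probability 0.36 on the pair `(a, c)` (its tied
mirror `(b, d)` gets the same), and a system drawn from the ensemble
contains 1.11 pairs on average.

The same run from the shell, with the path of every chosen pair spelled
out as node labels so edge-disjointness can be audited, and the
brute-force oracle cross-checking the score:

```sh
$ Rscript "$(Rscript -e 'cat(system.file("cli","targeting.R",package="phytarget"))')" \
    --tree inst/extdata/quartet.nwk --weights inst/extdata/quartet_weights.tsv --oracle
# score	3
# leaves	4	interior	3	multifurcations	0	oracle_systems	8
leaf1	leaf2	weight	path
a	c	3	a,u,r,v,c
```

Flags: `--unit | --path-length | --edge-weights FILE | --weights FILE`
(weight modes), `--kappa K`, `--require FILE`, `--prescribed FILE`
(variants), `--probabilities --beta B [--all-pairs | --pairs FILE]`
(ensemble), `--format tsv|json`, `--oracle`. Exit codes: 0 success, 2
infeasible, 3 input error, 4 unsupported variant.

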