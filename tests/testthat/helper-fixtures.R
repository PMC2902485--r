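## Worked fixtures used across the suite.

## Nested binary quartet: two cherries (a,b) and (c,d) under the root.
## The two "crossing" perfect pairings share the root edges and are
## invalid, leaving 8 valid path-systems; the optimum is the single pair
## (a,c) (tied with (b,d), broken lexicographically) with score 3.
fixture_nested <- function() {
  tree <- parse_newick("((a,b)u,(c,d)v)r;")
  m <- matrix(c(0, 1, 3, 0,
                1, 0, 0, 3,
                3, 0, 0, 1,
                0, 3, 1, 0), 4, 4,
              dimnames = list(c("a", "b", "c", "d"), c("a", "b", "c", "d")))
  list(tree = tree, w = weights_from_matrix(m, tree))
}

## Star over four leaves: all three perfect pairings are edge-disjoint
## (paths meet only at the root); optimum {(a,c),(b,d)} with score 8.
fixture_star <- function() {
  tree <- parse_newick("(a,b,c,d)r;")
  m <- matrix(c(0, 5, 4, 1,
                5, 0, 1, 4,
                4, 1, 0, 1,
                1, 4, 1, 0), 4, 4,
              dimnames = list(c("a", "b", "c", "d"), c("a", "b", "c", "d")))
  list(tree = tree, w = weights_from_matrix(m, tree))
}

## Three-leaf ensemble fixture: 4 valid path-systems (empty + each pair).
fixture_cherry3 <- function() {
  tree <- parse_newick("((a,b)u,c)r;")
  m <- matrix(c(0, 2, 1,
                2, 0, 1,
                1, 1, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  list(tree = tree, w = weights_from_matrix(m, tree))
}

random_instance <- function(i, n = NULL, multifurcating = FALSE,
                            max_degree = 5L) {
  if (is.null(n)) n <- 2L + (i %% 9L)
  tree <- if (multifurcating)
    random_multifurcating_tree(n, max_degree, 1000L + i)
  else random_binary_tree(n, 1000L + i)
  list(tree = tree, w = random_weights(tree, "integer", 2000L + i))
}

## Extract the subtree below node u as a standalone tree (labels kept).
subtree_as_tree <- function(tree, u) {
  nk <- function(v) {
    if (v <= tree$ntip) return(tree$tip_label[v])
    paste0("(",
           paste(vapply(tree$children[[v]], nk, character(1)),
                 collapse = ","), ")")
  }
  parse_newick(paste0(nk(u), ";"))
}

pairs_of <- function(sol) {
  paste(sol$system$pairs$leaf1, sol$system$pairs$leaf2, sep = "-")
}
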