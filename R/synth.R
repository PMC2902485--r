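## Seeded random instance generators. One integer seed drives everything
## through withr::with_seed, so the same configuration always yields the
## same tree and weights and no global random state is touched.

#' Random binary tree by sequential leaf attachment
#'
#' Starts from a two-leaf tree and attaches each further leaf to a
#' uniformly chosen edge, which can produce every binary topology. Leaves
#' are labelled `L1..Ln`. No branch lengths are assigned.
#'
#' @param n number of leaves, `>= 1`.
#' @param seed integer seed; the same `(n, seed)` yields the same tree.
#' @return a [rooted_tree].
#' @export
random_binary_tree <- function(n, seed) {
  stopifnot(n >= 1L)
  labels <- paste0("L", seq_len(n))
  if (n == 1L)
    return(rooted_tree(NA_integer_, list(integer(0)), labels))
  withr::with_seed(as.integer(seed), {
    nnode <- 2L * n - 1L
    parent <- rep(NA_integer_, nnode)
    children <- rep(list(integer(0)), nnode)
    ## tips 1..n, internals n+1..2n-1; start with root joining L1, L2
    root <- n + 1L
    parent[1L] <- root; parent[2L] <- root
    children[[root]] <- c(1L, 2L)
    nodes_in <- c(1L, 2L)              # non-root nodes, i.e. existing edges
    for (i in seq_len(n - 2L)) {
      tip <- 2L + i
      m <- n + 1L + i                  # new interior node
      v <- nodes_in[sample.int(length(nodes_in), 1L)]
      p <- parent[v]
      children[[p]][children[[p]] == v] <- m
      parent[m] <- p
      parent[v] <- m
      parent[tip] <- m
      children[[m]] <- c(v, tip)
      nodes_in <- c(nodes_in, tip, m)
    }
    rooted_tree(parent, children, labels)
  })
}

#' Random multifurcating tree
#'
#' Recursively splits the leaf set: each interior node receives a degree
#' drawn uniformly from `2..max_degree` (capped by the number of leaves
#' remaining) and its leaves are distributed over the children with every
#' child non-empty, so no unary nodes arise. With `max_degree = 2` the
#' result is binary.
#'
#' @param n number of leaves, `>= 1`.
#' @param max_degree maximum number of children per node, `>= 2`.
#' @param seed integer seed.
#' @return a [rooted_tree].
#' @export
random_multifurcating_tree <- function(n, max_degree, seed) {
  stopifnot(n >= 1L, max_degree >= 2L)
  labels <- paste0("L", seq_len(n))
  if (n == 1L)
    return(rooted_tree(NA_integer_, list(integer(0)), labels))
  withr::with_seed(as.integer(seed), {
    parent <- rep(NA_integer_, n)
    children <- rep(list(integer(0)), n)
    nxt <- n                            # last allocated node id
    new_node <- function() {
      nxt <<- nxt + 1L
      parent[nxt] <<- NA_integer_
      children[nxt] <<- list(integer(0))
      nxt
    }
    build <- function(tips) {
      if (length(tips) == 1L) return(tips)
      u <- new_node()
      dmax <- min(max_degree, length(tips))
      d <- if (dmax == 2L) 2L else sample(2:dmax, 1L)
      ## one tip per group first, remainder at random
      grp <- integer(length(tips))
      grp[sample.int(length(tips), d)] <- seq_len(d)
      rest <- which(grp == 0L)
      if (length(rest))
        grp[rest] <- sample.int(d, length(rest), replace = TRUE)
      for (g in seq_len(d)) {
        child <- build(tips[grp == g])
        parent[child] <<- u
        children[[u]] <<- c(children[[u]], child)
      }
      u
    }
    build(seq_len(n))
    rooted_tree(parent[seq_len(nxt)], children[seq_len(nxt)], labels)
  })
}

#' Random symmetric leaf-pair weights
#'
#' @param tree a [rooted_tree].
#' @param regime `"unit"` (all ones), `"integer"` (uniform integers in
#'   `0..w_max`), or `"uniform"` (continuous in `[0, w_max]`).
#' @param seed integer seed.
#' @param w_max upper bound for the random regimes.
#' @return an `mpp_weights` model.
#' @export
random_weights <- function(tree, regime = c("integer", "unit", "uniform"),
                           seed = 1L, w_max = 9) {
  regime <- match.arg(regime)
  n <- tree$ntip
  if (regime == "unit") return(unit_weights(tree))
  withr::with_seed(as.integer(seed), {
    m <- matrix(0, n, n, dimnames = list(tree$tip_label, tree$tip_label))
    np <- n * (n - 1L) / 2L
    vals <- if (regime == "integer")
      sample.int(w_max + 1L, np, replace = TRUE) - 1L
    else runif(np, 0, w_max)
    m[upper.tri(m)] <- vals
    m <- m + t(m)
    new_weight_model(m, "table")
  })
}
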