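## Exact maximum-weight matching for the small general graphs that arise at
## multifurcations. The auxiliary graph of a polytomy has two copies of each
## child; the starred copies are pendant, so the matcher contracts them and
## runs an exact subset DP over the child vertices only. Exponential in the
## child count, which is what bounds the supported polytomy degree.

MAX_MATCH_VERTICES <- 18L

#' Exact maximum-weight matching on a small general graph
#'
#' Dynamic program over vertex subsets: exact on arbitrary (non-bipartite)
#' graphs, exponential in the vertex count, so restricted to at most 18
#' vertices. Matchings need not be perfect; edges of non-positive weight are
#' never used (leaving a vertex exposed is always at least as good), which
#' also makes ties resolve toward fewer matched pairs.
#'
#' @param nv number of vertices (numbered `1..nv`).
#' @param edges a data frame or list with integer columns `i`, `j` and
#'   numeric `w`.
#' @return a list with `weight` (the exact optimum) and `matching`, a
#'   two-column matrix of matched vertex pairs.
#' @export
mwm_exact <- function(nv, edges) {
  nv <- as.integer(nv)
  if (nv > MAX_MATCH_VERTICES)
    stop("exact matcher supports at most ", MAX_MATCH_VERTICES,
         " vertices (got ", nv, ")", call. = FALSE)
  ei <- as.integer(edges$i); ej <- as.integer(edges$j)
  ew <- as.numeric(edges$w)
  if (any(is.na(ew)) ) stop("NA edge weight", call. = FALSE)
  keep <- which(is.finite(ew) & ew > 0)
  if (nv == 0L || length(keep) == 0L)
    return(list(weight = 0, matching = matrix(integer(0), 0L, 2L)))
  ei <- ei[keep]; ej <- ej[keep]; ew <- ew[keep]
  bit <- bitwShiftL(1L, seq_len(nv) - 1L)
  ## adjacency: for each vertex, incident edges with the partner vertex
  adj_j <- vector("list", nv); adj_w <- vector("list", nv)
  adj_id <- vector("list", nv)
  for (e in seq_along(ei)) {
    a <- ei[e]; b <- ej[e]
    adj_j[[a]] <- c(adj_j[[a]], b); adj_w[[a]] <- c(adj_w[[a]], ew[e])
    adj_id[[a]] <- c(adj_id[[a]], e)
    adj_j[[b]] <- c(adj_j[[b]], a); adj_w[[b]] <- c(adj_w[[b]], ew[e])
    adj_id[[b]] <- c(adj_id[[b]], e)
  }
  nm <- bitwShiftL(1L, nv)
  f <- numeric(nm)                    # f[mask+1]: best matching inside mask
  choice <- integer(nm)               # 0: lowest vertex left exposed
  for (mask in seq_len(nm - 1L)) {
    low <- bitwAnd(mask, -mask)
    i <- 1L + as.integer(round(log2(low)))
    best <- f[mask - low + 1L]        # leave i exposed
    pick <- 0L
    js <- adj_j[[i]]
    if (!is.null(js)) {
      inm <- bitwAnd(mask, bit[js]) != 0L
      if (any(inm)) {
        js2 <- js[inm]
        vals <- f[mask - low - bit[js2] + 1L] + adj_w[[i]][inm]
        bi <- which.max(vals)
        if (vals[bi] > best) {        # strict: ties prefer exposing i
          best <- vals[bi]
          pick <- adj_id[[i]][inm][bi]
        }
      }
    }
    f[mask + 1L] <- best
    choice[mask + 1L] <- pick
  }
  ## reconstruct
  mask <- nm - 1L
  mi <- integer(0); mj <- integer(0)
  while (mask > 0L) {
    low <- bitwAnd(mask, -mask)
    e <- choice[mask + 1L]
    if (e == 0L) {
      mask <- mask - low
    } else {
      mi <- c(mi, ei[e]); mj <- c(mj, ej[e])
      mask <- mask - bit[ei[e]] - bit[ej[e]]
    }
  }
  list(weight = f[nm], matching = cbind(mi, mj, deparse.level = 0L))
}

#' Auxiliary matching graph of a polytomy
#'
#' For an interior node `u` and a subset `C` of its children, builds the
#' graph with vertex set `{v, v* : v in C}`: a "pair" edge between every two
#' children `v', v''` weighted by the best score of a single path crossing
#' from one subtree to the other (plus the optimal remainders on both
#' sides), and a "self" edge `(v, v*)` weighted by the unconstrained subtree
#' optimum `S(v)`. A matching on this graph in which every `v` is covered
#' corresponds exactly to a path-system on the subtrees of `C`: matched
#' child pairs contribute one crossing path each, self-matched children
#' contribute their independent subtree optimum.
#'
#' @param children integer ids of the children in `C` (at least 2).
#' @param S named-by-position numeric: subtree optima `S(v)` for `C`.
#' @param what symmetric matrix of cross-pair scores for `C` (the best
#'   single-path contribution between each pair of child subtrees); `-Inf`
#'   where no admissible pair exists.
#' @param pair_rec list-matrix of the leaf pairs realizing `what`.
#' @return an object of class `mpp_aux_graph`.
#' @export
build_aux_graph <- function(children, S, what, pair_rec = NULL) {
  d <- length(children)
  stopifnot(d >= 2L, length(S) == d, nrow(what) == d)
  e_i <- integer(0); e_j <- integer(0); e_w <- numeric(0)
  for (a in seq_len(d - 1L)) for (b in seq(a + 1L, d)) {
    e_i <- c(e_i, a); e_j <- c(e_j, b); e_w <- c(e_w, what[a, b])
  }
  structure(list(
    children = children, d = d, S = as.numeric(S),
    what = what, pair_rec = pair_rec,
    pair_edges = list(i = e_i, j = e_j, w = e_w)
  ), class = "mpp_aux_graph")
}

#' @export
print.mpp_aux_graph <- function(x, ...) {
  cat("Auxiliary matching graph: ", 2L * x$d, " vertices (", x$d,
      " children + starred copies), ",
      x$d * (x$d - 1L) / 2L + x$d, " edges\n", sep = "")
  invisible(x)
}

#' Exact maximum-weight matching on an auxiliary graph
#'
#' Solves the matching exactly and post-processes it so that every child
#' vertex `v` is covered: any `v` left exposed is matched to its starred
#' copy via the self edge `(v, v*)`, which carries the non-negative weight
#' `S(v)` and therefore never decreases the matching weight. Internally the
#' pendant starred copies are contracted: a matching of the auxiliary graph
#' restricted to the child vertices has weight
#' `sum(S) + sum over matched pairs of (what - S_v' - S_v'')`, so the subset
#' DP runs on the children only with those reduced edge weights.
#'
#' @param aux an `mpp_aux_graph` from [build_aux_graph()].
#' @return a list with `weight` (covered-matching optimum), and `matching`,
#'   a list of entries `list(type = "pair", i, j)` (children `i`, `j` of `C`
#'   matched by a crossing path) or `list(type = "self", i)` (child matched
#'   to its starred copy).
#' @export
max_weight_matching <- function(aux) {
  stopifnot(inherits(aux, "mpp_aux_graph"))
  if (any(aux$S < 0))
    stop("self-edge weights S(v) must be non-negative", call. = FALSE)
  if (any(is.finite(aux$pair_edges$w) & aux$pair_edges$w < 0))
    stop("pair-edge weights must be non-negative", call. = FALSE)
  d <- aux$d
  ## reduced weights on the child vertices
  red <- aux$pair_edges
  red$w <- red$w - aux$S[red$i] - aux$S[red$j]
  res <- mwm_exact(d, red)
  covered <- rep(FALSE, d)
  matching <- list()
  if (nrow(res$matching)) {
    for (r in seq_len(nrow(res$matching))) {
      a <- res$matching[r, 1L]; b <- res$matching[r, 2L]
      covered[c(a, b)] <- TRUE
      matching[[length(matching) + 1L]] <- list(type = "pair", i = a, j = b)
    }
  }
  for (v in which(!covered))
    matching[[length(matching) + 1L]] <- list(type = "self", i = v)
  list(weight = sum(aux$S) + res$weight, matching = matching)
}
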