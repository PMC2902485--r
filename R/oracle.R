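## Brute-force reference implementation: enumerate every valid path-system
## on a small tree by extending partial leaf pairings, pruning on edge
## conflicts as pairs are added. Exact but exponential; the arbiter of
## correctness for every solver in the package.

ORACLE_MAX_LEAVES <- 12L

#' Enumerate all valid path-systems on a small tree
#'
#' Recursively pairs leaves in label order — each leaf is either left
#' unpaired or paired with a later available leaf whose connecting path is
#' edge-disjoint with everything chosen so far — so only valid systems are
#' ever produced. The empty system is included. Refuses trees with more
#' than 12 leaves.
#'
#' @param tree a [rooted_tree] with at most 12 leaves.
#' @param w optional `mpp_weights`; if supplied, per-system scores are
#'   computed.
#' @return an object of class `system_enumeration`: `systems` (list of
#'   two-column tip-id matrices), `scores` (numeric, if `w` given),
#'   `npairs`, and `count`.
#' @export
enumerate_path_systems <- function(tree, w = NULL) {
  n <- tree$ntip
  if (n > ORACLE_MAX_LEAVES)
    stop("oracle enumeration is limited to ", ORACLE_MAX_LEAVES,
         " leaves (got ", n, ")", call. = FALSE)
  ## path edge sets per pair, as node-id vectors
  pedges <- vector("list", n * n)
  if (n >= 2L) {
    for (x in seq_len(n - 1L)) for (y in seq(x + 1L, n)) {
      pedges[[(x - 1L) * n + y]] <- path_between(tree, x, y)$edges
    }
  }
  systems <- list()
  add <- function(m) systems[[length(systems) + 1L]] <<- m
  used <- logical(tree$nnode)
  cur1 <- integer(0); cur2 <- integer(0)
  rec <- function(avail) {
    if (!length(avail)) {
      add(cbind(cur1, cur2, deparse.level = 0L))
      return(invisible())
    }
    x <- avail[1L]
    rest <- avail[-1L]
    ## leave x unpaired
    rec(rest)
    for (y in rest) {
      e <- pedges[[(x - 1L) * n + y]]
      if (!any(used[e])) {
        used[e] <<- TRUE
        cur1 <<- c(cur1, x); cur2 <<- c(cur2, y)
        rec(setdiff(rest, y))
        cur1 <<- cur1[-length(cur1)]; cur2 <<- cur2[-length(cur2)]
        used[e] <<- FALSE
      }
    }
  }
  rec(seq_len(n))
  scores <- if (!is.null(w)) {
    vapply(systems, function(m)
      if (nrow(m)) sum(w$mat[cbind(m[, 1L], m[, 2L])]) else 0,
      numeric(1))
  } else NULL
  structure(list(systems = systems, scores = scores,
                 npairs = vapply(systems, nrow, integer(1)),
                 count = length(systems), tree = tree),
            class = "system_enumeration")
}

#' @export
print.system_enumeration <- function(x, ...) {
  cat("Enumeration: ", x$count, " valid path-systems on ",
      x$tree$ntip, " leaves\n", sep = "")
  invisible(x)
}

#' Exact constrained/unconstrained optimum by enumeration
#'
#' Filters the enumerated systems by the optional constraints (at most
#' `kappa` pairs; every taxon in `Z` covered) and maximizes the score.
#'
#' @param enum a `system_enumeration` built with weights.
#' @param kappa optional bound on the number of pairs.
#' @param Z optional character vector of required taxon labels.
#' @return a list with `score` (`-Inf` if no system satisfies the
#'   constraints), `best` (list of optimal systems, as label matrices),
#'   and `n_optima`.
#' @export
oracle_max <- function(enum, kappa = NULL, Z = NULL) {
  stopifnot(inherits(enum, "system_enumeration"), !is.null(enum$scores))
  keep <- rep(TRUE, enum$count)
  if (!is.null(kappa)) keep <- keep & enum$npairs <= kappa
  if (!is.null(Z) && length(Z)) {
    zi <- tip_id(enum$tree, Z)
    keep <- keep & vapply(enum$systems, function(m)
      all(zi %in% c(m[, 1L], m[, 2L])), logical(1))
  }
  if (!any(keep))
    return(list(score = -Inf, best = list(), n_optima = 0L))
  sc <- enum$scores
  mx <- max(sc[keep])
  opt <- which(keep & sc == mx)
  labs <- enum$tree$tip_label
  best <- lapply(enum$systems[opt], function(m) {
    if (!nrow(m)) return(matrix(character(0), 0L, 2L))
    l1 <- labs[m[, 1L]]; l2 <- labs[m[, 2L]]
    mm <- cbind(pmin(l1, l2), pmax(l1, l2))
    mm[order(mm[, 1L], mm[, 2L]), , drop = FALSE]
  })
  list(score = mx, best = best, n_optima = length(opt))
}

#' Oracle Boltzmann sums over the enumerated ensemble
#'
#' Log partition function `log sum exp(beta * score)` over all enumerated
#' systems, and optionally the restricted sum over systems containing a
#' given pair — the independent reference for [partition_function()] and
#' [path_probability()].
#'
#' @param enum a `system_enumeration` built with weights.
#' @param beta inverse temperature.
#' @param pair optional length-2 character vector of leaf labels.
#' @return a list with `logZ` and, when `pair` is given, `logZ_pair` and
#'   `probability`.
#' @export
oracle_partition <- function(enum, beta, pair = NULL) {
  stopifnot(inherits(enum, "system_enumeration"), !is.null(enum$scores))
  lz <- logsumexp(beta * enum$scores)
  out <- list(logZ = lz)
  if (!is.null(pair)) {
    pi_ <- tip_id(enum$tree, pair)
    has <- vapply(enum$systems, function(m)
      any((m[, 1L] == pi_[1L] & m[, 2L] == pi_[2L]) |
            (m[, 1L] == pi_[2L] & m[, 2L] == pi_[1L])), logical(1))
    lzp <- if (any(has)) logsumexp(beta * enum$scores[has]) else -Inf
    out$logZ_pair <- lzp
    out$probability <- exp(lzp - lz)
  }
  out
}
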