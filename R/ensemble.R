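## Boltzmann ensemble over path-systems on binary trees. Every valid
## path-system Y receives weight exp(beta * score(Y)); the partition
## function Z sums these over all systems, and P(x,y) is the probability
## that the pair (x,y) is selected when systems are drawn proportionally
## to their Boltzmann weight. All accumulation is done in the log domain so
## large beta * score products cannot overflow.

logsumexp <- function(v) {
  v <- v[!is.na(v)]
  if (!length(v)) return(-Inf)
  m <- max(v)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(v - m)))
}

#' Partition function over path-systems (binary trees)
#'
#' The optimizing recurrences of [solve_binary()] with max replaced by sum
#' and scores by Boltzmann factors `exp(beta * omega)`: `Z(leaf) = 1` (the
#' empty system), and at an interior node the systems either do not cross
#' the node (product of the child partition functions) or spend one
#' crossing path on a leaf pair, weighting each choice by its factor and
#' the pending-path analogues `ZR`. At `beta = 0` every system counts 1, so
#' `Z(root)` is the number of valid path-systems; as `beta` grows the
#' ensemble concentrates on the optimal systems.
#'
#' @param tree a binary [rooted_tree].
#' @param w an `mpp_weights` model.
#' @param beta inverse temperature, `>= 0`.
#' @return an object of class `mpp_ensemble` with `beta`, `logZ` (per-node
#'   log partition functions), `logZR` (pending-path analogue), `Z` (the
#'   root partition function, `Inf` if it overflows), and the tree/weights.
#' @export
partition_function <- function(tree, w, beta) {
  if (!is_binary(tree))
    stop_unsupported(paste0("partition functions are only available for ",
                            "binary trees"))
  check_weights(tree, w)
  stopifnot(is.numeric(beta), length(beta) == 1L, beta >= 0)
  ntip <- tree$ntip; nnode <- tree$nnode
  nav <- build_nav_table(tree)
  lZ <- numeric(nnode)                     # leaves: log 1 = 0
  lZR <- matrix(-Inf, nnode, ntip)
  lZR[cbind(seq_len(ntip), seq_len(ntip))] <- 0
  interior <- tree$postorder[tree$postorder > ntip]
  wm <- w$mat
  for (u in interior) {
    ch <- tree$children[[u]]
    v <- ch[1L]; s <- ch[2L]
    Lv <- tree$leafset[[v]]; Ls <- tree$leafset[[s]]
    lZR[u, Lv] <- lZ[s] + lZR[v, Lv]
    lZR[u, Ls] <- lZ[v] + lZR[s, Ls]
    cross <- beta * wm[Lv, Ls, drop = FALSE] +
      outer(lZR[v, Lv], lZR[s, Ls], "+")
    lZ[u] <- logsumexp(c(lZ[v] + lZ[s], cross))
  }
  structure(list(beta = beta, logZ = lZ, logZR = lZR, nav = nav,
                 Z = exp(lZ[tree$root]), tree = tree, w = w),
            class = "mpp_ensemble")
}

#' @export
print.mpp_ensemble <- function(x, ...) {
  cat("Path-system ensemble: beta = ", format(x$beta),
      ", log Z = ", format(x$logZ[x$tree$root]), "\n", sep = "")
  invisible(x)
}

#' Ensemble probability that a leaf pair is selected
#'
#' `P(x, y) = Z(restricted to systems containing the x-y path) / Z`. The
#' restricted partition function starts at the pair's last common ancestor
#' `k` — every system on `T[k]` containing the path contributes
#' `exp(beta*omega(x,y)) * ZR(v,x) * ZR(w,y)` — and is propagated ancestor
#' by ancestor to the root. Because the path through `k` occupies both of
#' `k`'s child edges, no other path can leave `T[k]`, so at each ancestor
#' only leaf pairs avoiding `T[k]` (and the already-restricted side) can
#' cross; the hanging subtree containing `k` contributes its restricted
#' value in place of its free one.
#'
#' @param ens an `mpp_ensemble` from [partition_function()].
#' @param x,y distinct leaf labels.
#' @return the selection probability, in `[0, 1]`.
#' @export
path_probability <- function(ens, x, y) {
  stopifnot(inherits(ens, "mpp_ensemble"))
  tree <- ens$tree; wm <- ens$w$mat; beta <- ens$beta
  xi <- tip_id(tree, x); yi <- tip_id(tree, y)
  if (xi == yi) stop("pair endpoints must be distinct leaves", call. = FALSE)
  lZ <- ens$logZ; lZR <- ens$logZR; nav <- ens$nav
  k <- lca_of(tree, xi, yi)
  v <- nav[k, xi]; s <- nav[k, yi]
  lZp <- beta * wm[xi, yi] + lZR[v, xi] + lZR[s, yi]
  ## restricted pending-path values over leaves outside T[k]
  lZRp <- rep(-Inf, tree$ntip)
  Lk <- tree$leafset[[k]]
  a <- tree$parent[k]; cbelow <- k
  while (!is.na(a)) {
    ch <- tree$children[[a]]
    d <- ch[ch != cbelow]
    Ld <- tree$leafset[[d]]
    Lc_free <- setdiff(tree$leafset[[cbelow]], Lk)
    terms <- lZp + lZ[d]
    if (length(Lc_free)) {
      cross <- beta * wm[Lc_free, Ld, drop = FALSE] +
        outer(lZRp[Lc_free], lZR[d, Ld], "+")
      terms <- c(terms, cross)
    }
    new_lZRp <- lZRp
    new_lZRp[Ld] <- lZp + lZR[d, Ld]
    if (length(Lc_free)) new_lZRp[Lc_free] <- lZRp[Lc_free] + lZ[d]
    lZRp <- new_lZRp
    lZp <- logsumexp(terms)
    cbelow <- a
    a <- tree$parent[a]
  }
  exp(lZp - lZ[tree$root])
}

#' Expected number of selected pairs under the ensemble
#'
#' Sums `P(x, y)` over all unordered leaf pairs: the expected number of
#' paths in a system drawn from the Boltzmann distribution. As `beta` grows
#' this converges to the number of pairs in the optimal system(s).
#'
#' @param ens an `mpp_ensemble`.
#' @return a non-negative number.
#' @export
ensemble_expected_pairs <- function(ens) {
  n <- ens$tree$ntip
  if (n < 2L) return(0)
  tot <- 0
  for (x in seq_len(n - 1L)) for (y in seq(x + 1L, n))
    tot <- tot + path_probability(ens, x, y)
  tot
}
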