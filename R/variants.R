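## Constrained variants on binary trees: at most kappa pairs, required
## taxa, and prescribed already-chosen pairs. The multifurcating analogues
## would need matchings with a fixed edge count or forced vertices, which
## this package does not attempt; those inputs raise a clear error.

stop_unsupported <- function(msg) {
  stop(errorCondition(msg, class = c("mpp_unsupported_variant", "error")))
}

check_binary_variant <- function(tree, what) {
  if (!is_binary(tree))
    stop_unsupported(paste0(what, " is only available for binary trees; ",
                            "the multifurcating analogue is not supported"))
}

#' Maximal pairing with a bounded number of pairs
#'
#' Solves the binary-tree problem restricted to path-systems with at most
#' `kappa` pairs. The score tables gain one index for the number of pairs
#' spent; with non-negative weights the constrained optimum is
#' non-decreasing in `kappa` and reaches the unconstrained optimum at
#' `kappa = floor(n/2)`.
#'
#' @param tree a binary [rooted_tree].
#' @param w an `mpp_weights` model.
#' @param kappa non-negative integer bound on the number of pairs.
#' @return a list of class `mpp_solution` with `score`, `system` (at most
#'   `kappa` pairs) and `tables` (`Sk`: node x budget score matrix).
#' @export
solve_binary_kappa <- function(tree, w, kappa) {
  check_binary_variant(tree, "the bounded-pair-count variant")
  check_weights(tree, w)
  kappa <- as.integer(kappa)
  stopifnot(kappa >= 0L)
  ntip <- tree$ntip; nnode <- tree$nnode
  nav <- build_nav_table(tree)
  K <- kappa + 1L                       # column k+1 holds "at most k pairs"
  Sk <- matrix(0, nnode, K)
  Rk <- array(NA_real_, c(nnode, ntip, K))
  Rk[cbind(seq_len(ntip), seq_len(ntip), rep(seq_len(K), each = ntip))] <- 0
  interior <- tree$postorder[tree$postorder > ntip]
  wm <- w$mat
  for (u in interior) {
    ch <- tree$children[[u]]
    v <- ch[1L]; s <- ch[2L]
    Lv <- tree$leafset[[v]]; Ls <- tree$leafset[[s]]
    for (k in 0:kappa) {
      js <- 0:k
      best <- max(Sk[v, js + 1L] + Sk[s, k - js + 1L])
      if (k >= 1L) {
        for (j in 0:(k - 1L)) {
          l <- k - 1L - j
          M <- wm[Lv, Ls, drop = FALSE] +
            outer(Rk[v, Lv, j + 1L], Rk[s, Ls, l + 1L], "+")
          m <- max(M)
          if (m > best) best <- m
        }
      }
      Sk[u, k + 1L] <- best
      ## R tables for this budget
      for (cidx in 1:2) {
        cc <- ch[cidx]; sib <- ch[3L - cidx]
        lx <- tree$leafset[[cc]]
        cand <- Sk[sib, 1L] + Rk[cc, lx, k + 1L]
        if (k >= 1L) for (j in 1:k) {
          cand <- pmax(cand, Sk[sib, j + 1L] + Rk[cc, lx, k - j + 1L])
        }
        Rk[u, lx, k + 1L] <- cand
      }
    }
  }
  pairs <- kappa_backtrace(tree, wm, nav, Sk, Rk, tree$root, kappa)
  df <- canonical_pairs_df(tree, w, pairs)
  sys <- new_path_system(df, sum(df$weight))
  if (abs(sys$score - Sk[tree$root, kappa + 1L]) > 1e-9)
    stop("internal error: kappa backtrace mismatch", call. = FALSE)
  structure(list(score = Sk[tree$root, kappa + 1L], system = sys,
                 tables = list(Sk = Sk, Rk = Rk)),
            class = "mpp_solution")
}

## Backtracing by recomputation: at each node find the first decomposition
## achieving the stored value (no-new-pair splits first, then crossing
## pairs in lexicographic order), which reproduces the forward tie-breaks.
kappa_backtrace <- function(tree, wm, nav, Sk, Rk, root, kappa) {
  p1 <- integer(0); p2 <- integer(0)
  labels <- tree$tip_label
  bt_S <- function(u, k) {
    if (u <= tree$ntip) return(invisible())
    ch <- tree$children[[u]]
    v <- ch[1L]; s <- ch[2L]
    target <- Sk[u, k + 1L]
    for (j in 0:k) {
      if (Sk[v, j + 1L] + Sk[s, k - j + 1L] == target) {
        bt_S(v, j); bt_S(s, k - j)
        return(invisible())
      }
    }
    Lv <- tree$leafset[[v]]; Ls <- tree$leafset[[s]]
    for (j in 0:(k - 1L)) {
      l <- k - 1L - j
      M <- wm[Lv, Ls, drop = FALSE] +
        outer(Rk[v, Lv, j + 1L], Rk[s, Ls, l + 1L], "+")
      hit <- which(M == target, arr.ind = TRUE, useNames = FALSE)
      if (nrow(hit)) {
        if (nrow(hit) > 1L) {
          l1 <- labels[Lv[hit[, 1L]]]; l2 <- labels[Ls[hit[, 2L]]]
          hit <- hit[order(pmin(l1, l2), pmax(l1, l2))[1L], , drop = FALSE]
        }
        x <- Lv[hit[1L, 1L]]; y <- Ls[hit[1L, 2L]]
        p1 <<- c(p1, x); p2 <<- c(p2, y)
        bt_R(v, x, j); bt_R(s, y, l)
        return(invisible())
      }
    }
    stop("internal error: no achieving decomposition", call. = FALSE)
  }
  bt_R <- function(u, x, k) {
    while (u != x) {
      cc <- nav[u, x]
      ch <- tree$children[[u]]
      sib <- ch[ch != cc]
      target <- Rk[u, x, k + 1L]
      done <- FALSE
      for (j in 0:k) {
        if (Sk[sib, j + 1L] + Rk[cc, x, k - j + 1L] == target) {
          bt_S(sib, j)
          u <- cc; k <- k - j
          done <- TRUE
          break
        }
      }
      if (!done) stop("internal error: no achieving R decomposition",
                      call. = FALSE)
    }
  }
  bt_S(root, kappa)
  cbind(p1, p2, deparse.level = 0L)
}

#' Maximal pairing covering a required taxon set
#'
#' Finds the best path-system in which every taxon in `Z` is the endpoint
#' of some path, or reports infeasibility. Implemented by score
#' propagation with a `-Inf` sentinel: a required leaf that would be left
#' uncovered inside its own subtree scores `-Inf`, which then absorbs every
#' decomposition that strands it; the pending-path tables keep score 0 at
#' the leaf itself because the path through it covers it. An odd subtree
#' whose leaves are all required is automatically infeasible this way.
#'
#' @param tree a binary [rooted_tree].
#' @param w an `mpp_weights` model.
#' @param Z character vector of required taxon labels (may be empty).
#' @return an `mpp_solution` with additionally `feasible = TRUE`, or, when
#'   no covering path-system exists, a list with `feasible = FALSE` and
#'   `score = -Inf`.
#' @export
solve_binary_required <- function(tree, w, Z) {
  check_binary_variant(tree, "the required-taxa variant")
  zi <- tip_id(tree, Z)
  leaf_score <- numeric(tree$ntip)
  leaf_score[zi] <- -Inf
  tables <- mpp_forward(tree, w, binary_only = TRUE,
                        leaf_score = leaf_score)
  if (!is.finite(tables$S[tree$root])) {
    return(structure(list(score = -Inf, system = NULL, tables = tables,
                          feasible = FALSE), class = "mpp_solution"))
  }
  sys <- backtrace(tree, w, tables)
  covered <- unique(c(sys$pairs$leaf1, sys$pairs$leaf2))
  if (!all(tree$tip_label[zi] %in% covered))
    stop("internal error: required taxon left uncovered", call. = FALSE)
  structure(list(score = tables$S[tree$root], system = sys,
                 tables = tables, feasible = TRUE),
            class = "mpp_solution")
}

#' Preprocess prescribed (already selected) pairs
#'
#' Given a set of pairs already committed to, blocks every pair whose path
#' shares an edge with a prescribed path by setting its weight to the
#' `-Inf` sentinel (a leaf that is a prescribed endpoint is blocked
#' automatically, since every path to it uses its pendant edge). Solving
#' the residual problem with the returned model and adding `offset` gives
#' the best extension of the prescribed set. Works on arbitrary trees:
#' this is preprocessing, not a new recursion.
#'
#' @param tree a [rooted_tree].
#' @param w an `mpp_weights` model.
#' @param prescribed a two-column matrix/data frame of leaf labels, or a
#'   `path_system`; must itself be a valid path-system.
#' @return a list with `weights` (modified `mpp_weights`; blocked entries
#'   are `-Inf`), `offset` (total weight of the prescribed pairs), and
#'   `prescribed` (canonical data frame of the prescribed pairs).
#' @export
apply_prescribed_pairs <- function(tree, w, prescribed) {
  chk <- validate_path_system(tree, w, prescribed)
  if (!chk$valid)
    stop("prescribed pairs are not a valid path-system: ", chk$reason,
         call. = FALSE)
  pairs <- if (inherits(prescribed, "path_system")) prescribed$pairs else
    as.data.frame(prescribed, stringsAsFactors = FALSE)
  m <- w$mat
  if (nrow(pairs)) {
    i <- tip_id(tree, as.character(pairs[[1L]]))
    j <- tip_id(tree, as.character(pairs[[2L]]))
    used <- logical(tree$nnode)
    for (r in seq_along(i))
      used[path_between(tree, i[r], j[r])$edges] <- TRUE
    n <- tree$ntip
    for (x in seq_len(n - 1L)) for (y in seq(x + 1L, n)) {
      if (any(used[path_between(tree, x, y)$edges]))
        m[x, y] <- m[y, x] <- -Inf
    }
  }
  offset <- if (nrow(pairs)) sum(w$mat[cbind(tip_id(tree, pairs[[1L]]),
                                             tip_id(tree, pairs[[2L]]))]) else 0
  df <- canonical_pairs_df(tree, w,
                           if (nrow(pairs))
                             cbind(tip_id(tree, pairs[[1L]]),
                                   tip_id(tree, pairs[[2L]]))
                           else NULL)
  list(weights = new_weight_model(m, w$mode), offset = offset,
       prescribed = df)
}

#' Best extension of a prescribed pair set
#'
#' Convenience wrapper: applies [apply_prescribed_pairs()], solves the
#' residual problem with [solve_mpp()], and returns the combined
#' path-system (prescribed plus residual pairs) with the total score.
#'
#' @inheritParams apply_prescribed_pairs
#' @return an `mpp_solution` whose system contains the prescribed pairs.
#' @export
solve_with_prescribed <- function(tree, w, prescribed) {
  pre <- apply_prescribed_pairs(tree, w, prescribed)
  res <- solve_mpp(tree, pre$weights)
  df <- rbind(pre$prescribed, res$system$pairs)
  df <- df[order(df$leaf1, df$leaf2), , drop = FALSE]
  total <- pre$offset + res$score
  structure(list(score = total,
                 system = new_path_system(df, total),
                 tables = res$tables), class = "mpp_solution")
}
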