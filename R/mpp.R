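## Exact maximal-pairing solvers. One post-order engine serves both the
## binary recurrences and the multifurcating generalization; backtracing
## reconstructs an optimal path-system from the recorded argmax pairs and
## tabulated matchings.

new_path_system <- function(pairs_df, score) {
  rownames(pairs_df) <- NULL
  structure(list(pairs = pairs_df, score = score), class = "path_system")
}

#' @export
print.path_system <- function(x, ...) {
  cat("Path-system: ", nrow(x$pairs), " pair",
      if (nrow(x$pairs) != 1L) "s", ", score ",
      format(x$score), "\n", sep = "")
  if (nrow(x$pairs)) print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' @export
print.mpp_solution <- function(x, ...) {
  cat("Maximal pairing solution (score ", format(x$score), ")\n", sep = "")
  print(x$system)
  invisible(x)
}

empty_pairs_df <- function() {
  data.frame(leaf1 = character(0), leaf2 = character(0),
             weight = numeric(0), stringsAsFactors = FALSE)
}

canonical_pairs_df <- function(tree, w, pairs) {
  ## pairs: 2-column matrix of tip ids -> sorted data frame with weights
  if (is.null(pairs) || nrow(pairs) == 0L) return(empty_pairs_df())
  l1 <- tree$tip_label[pairs[, 1L]]
  l2 <- tree$tip_label[pairs[, 2L]]
  a <- pmin(l1, l2); b <- pmax(l1, l2)
  df <- data.frame(leaf1 = a, leaf2 = b,
                   weight = w$mat[cbind(pairs[, 1L], pairs[, 2L])],
                   stringsAsFactors = FALSE)
  df[order(df$leaf1, df$leaf2), , drop = FALSE]
}

## Best leaf pair across two child subtrees: max over x in Lv, y in Lw of
## omega(x,y) + Rv[x] + Rw[y]; ties broken by lexicographically smallest
## (label, label) pair so that runs are reproducible.
best_cross_pair <- function(wmat, labels, Lv, Lw, Rv, Rw) {
  M <- wmat[Lv, Lw, drop = FALSE] + outer(Rv, Rw, "+")
  m <- max(M)
  if (m == -Inf) return(list(w = -Inf, pair = NULL))
  idx <- which(M == m, arr.ind = TRUE, useNames = FALSE)
  if (nrow(idx) > 1L) {
    l1 <- labels[Lv[idx[, 1L]]]; l2 <- labels[Lw[idx[, 2L]]]
    o <- order(pmin(l1, l2), pmax(l1, l2))[1L]
    idx <- idx[o, , drop = FALSE]
  }
  list(w = m, pair = c(Lv[idx[1L, 1L]], Lw[idx[1L, 2L]]))
}

#' Best crossing-path score for a pair of children
#'
#' For two distinct children `v'`, `v''` of an interior node, computes the
#' best possible contribution of a single path with one endpoint in each
#' child subtree: the pair weight plus the optimal remainders on both sides
#' that stay edge-disjoint with the crossing path. The realizing leaf pair
#' is returned alongside (ties broken lexicographically by label).
#'
#' @param tree a [rooted_tree].
#' @param w an `mpp_weights` model.
#' @param tables DP tables from [solve_mpp()] or [solve_binary()].
#' @param v1,v2 two distinct children of a common interior node (node ids or
#'   node labels).
#' @return a list with `what` (the score) and `pair` (leaf labels).
#' @export
compute_pair_score_hat <- function(tree, w, tables, v1, v2) {
  if (is.character(v1)) v1 <- match(v1, tree$node_label)
  if (is.character(v2)) v2 <- match(v2, tree$node_label)
  stopifnot(v1 != v2, tree$parent[v1] == tree$parent[v2])
  Lv <- tree$leafset[[v1]]; Lw <- tree$leafset[[v2]]
  bp <- best_cross_pair(w$mat, tree$tip_label, Lv, Lw,
                        tables$R[v1, Lv], tables$R[v2, Lw])
  list(what = bp$w,
       pair = if (is.null(bp$pair)) NULL else tree$tip_label[bp$pair])
}

## Core post-order engine. leaf_score: per-tip initial S (0 unconstrained;
## -Inf marks a taxon that must not be left uncovered, used by the
## required-taxa variant). Returns the full DP table set.
mpp_forward <- function(tree, w, binary_only = FALSE, leaf_score = NULL) {
  check_weights(tree, w)
  ntip <- tree$ntip; nnode <- tree$nnode
  nav <- build_nav_table(tree)
  S <- numeric(nnode)
  if (!is.null(leaf_score)) S[seq_len(ntip)] <- leaf_score
  R <- matrix(NA_real_, nnode, ntip)
  R[cbind(seq_len(ntip), seq_len(ntip))] <- 0
  Fpair <- vector("list", nnode)      # binary nodes: argmax pair or NULL
  Qval <- vector("list", nnode)       # per child: score of T[u] minus T[child]
  Smatch <- vector("list", nnode)     # multifurcating: tabulated S-matching
  Qmatch <- vector("list", nnode)     # multifurcating: per-child Q-matchings
  Wrec <- vector("list", nnode)       # what matrix + realizing pairs
  interior <- tree$postorder[tree$postorder > ntip]
  for (u in interior) {
    ch <- tree$children[[u]]
    d <- length(ch)
    if (binary_only && d != 2L)
      stop("tree is multifurcating (node ", tree$node_label[u],
           " has ", d, " children); use solve_mpp()", call. = FALSE)
    what <- matrix(-Inf, d, d)
    prec <- vector("list", d * d)
    dim(prec) <- c(d, d)
    for (a in seq_len(d - 1L)) for (b in seq(a + 1L, d)) {
      La <- tree$leafset[[ch[a]]]; Lb <- tree$leafset[[ch[b]]]
      bp <- best_cross_pair(w$mat, tree$tip_label, La, Lb,
                            R[ch[a], La], R[ch[b], Lb])
      what[a, b] <- what[b, a] <- bp$w
      prec[a, b] <- prec[b, a] <- list(bp$pair)
    }
    Wrec[[u]] <- list(what = what, pairs = prec)
    if (d == 2L) {
      nopair <- S[ch[1L]] + S[ch[2L]]
      if (what[1L, 2L] > nopair) {    # strict: ties prefer no extra pair
        S[u] <- what[1L, 2L]
        Fpair[[u]] <- prec[[1L, 2L]]
      } else {
        S[u] <- nopair
      }
      Qval[[u]] <- c(S[ch[2L]], S[ch[1L]])
    } else {
      aux <- build_aux_graph(ch, S[ch], what, prec)
      mm <- max_weight_matching(aux)
      S[u] <- mm$weight
      Smatch[[u]] <- mm$matching
      Qv <- numeric(d); Qm <- vector("list", d)
      for (k in seq_len(d)) {
        sel <- setdiff(seq_len(d), k)
        auxk <- build_aux_graph(ch[sel], S[ch[sel]],
                                what[sel, sel, drop = FALSE],
                                prec[sel, sel, drop = FALSE])
        mk <- max_weight_matching(auxk)
        Qv[k] <- mk$weight
        ## re-express matching in terms of positions in ch
        Qm[[k]] <- lapply(mk$matching, function(e) {
          if (e$type == "pair") list(type = "pair", i = sel[e$i], j = sel[e$j])
          else list(type = "self", i = sel[e$i])
        })
      }
      Qval[[u]] <- Qv
      Qmatch[[u]] <- Qm
    }
    for (k in seq_len(d)) {
      lx <- tree$leafset[[ch[k]]]
      R[u, lx] <- Qval[[u]][k] + R[ch[k], lx]
    }
  }
  structure(list(S = S, R = R, Fpair = Fpair, Qval = Qval,
                 Smatch = Smatch, Qmatch = Qmatch, Wrec = Wrec,
                 nav = nav), class = "mpp_tables")
}

## Backtracing: reconstruct one optimal path-system from the tables.
mpp_backtrace_pairs <- function(tree, tables) {
  acc <- new.env(parent = emptyenv())
  acc$p1 <- integer(0); acc$p2 <- integer(0)
  emit <- function(x, y) {
    acc$p1 <- c(acc$p1, x); acc$p2 <- c(acc$p2, y)
  }
  bt_S <- function(u) {
    if (u <= tree$ntip) return(invisible())
    ch <- tree$children[[u]]
    if (length(ch) == 2L) {
      fp <- tables$Fpair[[u]]
      if (is.null(fp)) {
        bt_S(ch[1L]); bt_S(ch[2L])
      } else {
        emit(fp[1L], fp[2L])
        bt_R(if (tables$nav[u, fp[1L]] == ch[1L]) ch[1L] else ch[2L], fp[1L])
        bt_R(if (tables$nav[u, fp[2L]] == ch[1L]) ch[1L] else ch[2L], fp[2L])
      }
    } else {
      apply_matching(u, tables$Smatch[[u]])
    }
  }
  apply_matching <- function(u, matching) {
    ch <- tree$children[[u]]
    for (e in matching) {
      if (e$type == "self") {
        bt_S(ch[e$i])
      } else {
        pr <- tables$Wrec[[u]]$pairs[[e$i, e$j]]
        if (is.null(pr)) stop("inconsistent DP tables", call. = FALSE)
        emit(pr[1L], pr[2L])
        bt_R(ch[e$i], pr[1L])
        bt_R(ch[e$j], pr[2L])
      }
    }
  }
  bt_R <- function(u, x) {
    ## optimal remainder on T[u] edge-disjoint with the pending path to x
    while (u != x) {
      k <- tables$nav[u, x]
      ch <- tree$children[[u]]
      if (length(ch) == 2L) {
        bt_S(ch[ch != k])
      } else {
        apply_matching(u, tables$Qmatch[[u]][[which(ch == k)]])
      }
      u <- k
    }
  }
  bt_S(tree$root)
  cbind(acc$p1, acc$p2, deparse.level = 0L)
}

#' Reconstruct an optimal path-system from DP tables
#'
#' Walks the recorded argmax pairs (binary nodes) and tabulated matchings
#' (multifurcations) from the root down, decomposing the remainder along
#' each emitted path's spine. The recomputed score of the returned system
#' equals the forward optimum exactly (defensively checked).
#'
#' @param tree a [rooted_tree].
#' @param w an `mpp_weights` model.
#' @param tables an `mpp_tables` object from [solve_mpp()]/[solve_binary()].
#' @return a `path_system`.
#' @export
backtrace <- function(tree, w, tables) {
  stopifnot(inherits(tables, "mpp_tables"))
  prs <- mpp_backtrace_pairs(tree, tables)
  df <- canonical_pairs_df(tree, w, prs)
  sc <- sum(df$weight)
  target <- tables$S[tree$root]
  if (is.finite(target) && abs(sc - target) > 1e-9 * max(1, abs(target)))
    stop("internal error: backtraced score ", sc,
         " does not match forward optimum ", target, call. = FALSE)
  new_path_system(df, sc)
}

#' Solve the maximal pairing problem on a binary tree
#'
#' Post-order dynamic program for strictly binary trees. At each interior
#' node `u` with children `v`, `w` it considers either joining the two
#' optimal child systems, or spending one path across `u` on the best leaf
#' pair `(x, y)` with `x` below `v` and `y` below `w`, adding the optimal
#' remainders that avoid the path on both sides. Runs in O(n^3) time and
#' O(n^2) space. Ties prefer no extra pair, then the lexicographically
#' smallest leaf pair.
#'
#' @param tree a binary [rooted_tree].
#' @param w an `mpp_weights` model (symmetric, non-negative).
#' @return a list of class `mpp_solution`: `score`, `system` (a
#'   `path_system`), and `tables` (the DP arrays, reusable by [backtrace()]
#'   and [compute_pair_score_hat()]).
#' @export
solve_binary <- function(tree, w) {
  tables <- mpp_forward(tree, w, binary_only = TRUE)
  sys <- backtrace(tree, w, tables)
  structure(list(score = tables$S[tree$root], system = sys,
                 tables = tables), class = "mpp_solution")
}

#' Solve the maximal pairing problem on an arbitrary rooted tree
#'
#' Binary nodes are handled by the binary recurrences; at a multifurcation
#' the optimal combination of child subtrees is found as an exact
#' maximum-weight matching on the auxiliary graph over the node's children
#' (see [build_aux_graph()]), with one matching tabulated per node and one
#' per excluded child for backtracing.
#'
#' @inheritParams solve_binary
#' @param tree a [rooted_tree] (binary or multifurcating).
#' @return an `mpp_solution` (see [solve_binary()]).
#' @export
solve_mpp <- function(tree, w) {
  tables <- mpp_forward(tree, w, binary_only = FALSE)
  sys <- backtrace(tree, w, tables)
  structure(list(score = tables$S[tree$root], system = sys,
                 tables = tables), class = "mpp_solution")
}

#' Validate a path-system and recompute its score
#'
#' Checks the two defining conditions: every pair connects two distinct
#' leaves and no leaf is used twice, and the connecting paths of distinct
#' pairs share no edge (sharing vertices is allowed, which is what makes
#' multifurcations useful). The score is recomputed from the weight model.
#'
#' @param tree a [rooted_tree].
#' @param w an `mpp_weights` model.
#' @param system a `path_system`, or a two-column matrix/data frame of leaf
#'   labels.
#' @return a list with `valid` (logical), `score` (sum of pair weights; `NA`
#'   if invalid), and `reason` (`""` if valid).
#' @export
validate_path_system <- function(tree, w, system) {
  pairs <- if (inherits(system, "path_system")) system$pairs else
    as.data.frame(system, stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) return(list(valid = TRUE, score = 0, reason = ""))
  i <- tip_id(tree, as.character(pairs[[1L]]))
  j <- tip_id(tree, as.character(pairs[[2L]]))
  if (any(i == j))
    return(list(valid = FALSE, score = NA_real_,
                reason = "pair endpoints must be distinct leaves"))
  ends <- c(i, j)
  if (anyDuplicated(ends))
    return(list(valid = FALSE, score = NA_real_,
                reason = "a leaf appears in more than one pair"))
  used <- logical(tree$nnode)
  for (r in seq_along(i)) {
    e <- path_between(tree, i[r], j[r])$edges
    if (any(used[e]))
      return(list(valid = FALSE, score = NA_real_,
                  reason = "paths are not edge-disjoint"))
    used[e] <- TRUE
  }
  list(valid = TRUE, score = sum(w$mat[cbind(i, j)]), reason = "")
}
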