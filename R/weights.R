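## Leaf-pair weight models. A weight model is a dense symmetric ntip x ntip
## matrix with leaf labels as dimnames plus a mode tag. Entries are >= 0;
## the sentinel -Inf marks a forbidden pair (used only by the prescribed-pair
## preprocessing) and is absorbed by every max in the solvers.

new_weight_model <- function(mat, mode) {
  structure(list(mat = mat, mode = mode), class = "mpp_weights")
}

#' @export
print.mpp_weights <- function(x, ...) {
  cat("Leaf-pair weight model (mode: ", x$mode, ", ",
      nrow(x$mat), " leaves)\n", sep = "")
  invisible(x)
}

check_weights <- function(tree, w) {
  stopifnot(inherits(w, "mpp_weights"))
  m <- w$mat
  if (nrow(m) != tree$ntip || !identical(rownames(m), tree$tip_label))
    stop("weight model does not match the tree's leaves", call. = FALSE)
  if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE)))
    stop("weight matrix must be symmetric", call. = FALSE)
  bad <- is.finite(m) & m < 0
  if (any(bad))
    stop("negative pair weights are not allowed", call. = FALSE)
  if (any(is.na(m[row(m) != col(m)])))
    stop("weight model leaves some pairs unspecified", call. = FALSE)
  invisible(TRUE)
}

#' Look up the weight of a leaf pair
#'
#' @param w an `mpp_weights` model.
#' @param x,y leaf labels.
#' @return the (symmetric, non-negative) pair weight.
#' @export
weight_of <- function(w, x, y) {
  w$mat[x, y]
}

#' Unit pair weights
#'
#' Every distinct leaf pair weighs 1, so the optimal path-system simply
#' maximizes the number of edge-disjoint pairs.
#'
#' @param tree a [rooted_tree].
#' @return an `mpp_weights` model.
#' @export
unit_weights <- function(tree) {
  n <- tree$ntip
  m <- matrix(1, n, n, dimnames = list(tree$tip_label, tree$tip_label))
  diag(m) <- 0
  new_weight_model(m, "unit")
}

#' Path-length pair weights
#'
#' The weight of a pair is the number of edges on its connecting path
#' (every edge counted as unit length), so maximizing the total weight
#' maximizes the number of tree edges covered by the path-system.
#'
#' @param tree a [rooted_tree].
#' @return an `mpp_weights` model.
#' @export
path_length_weights <- function(tree) {
  edge_sum_weights(tree, rep(1, tree$nnode), mode = "path_length")
}

#' Edge-weight-sum pair weights
#'
#' The weight of a pair is the sum of non-negative per-edge weights along
#' its path. With all edge weights 1 this reduces to [path_length_weights()];
#' by default the tree's branch lengths are used (absent lengths count as 1).
#'
#' @param tree a [rooted_tree].
#' @param edge_weight per-edge weights, one per node (the weight of the edge
#'   above that node; the root entry is ignored). Either a numeric vector of
#'   length `nnode`, or a numeric vector named by node label, or `NULL` to
#'   use branch lengths.
#' @param mode internal mode tag.
#' @return an `mpp_weights` model.
#' @export
edge_sum_weights <- function(tree, edge_weight = NULL, mode = "edge_sum") {
  n <- tree$ntip
  if (is.null(edge_weight)) {
    ew <- tree$edge_length
    ew[is.na(ew)] <- 1
  } else if (!is.null(names(edge_weight))) {
    i <- match(names(edge_weight), tree$node_label)
    if (anyNA(i))
      stop("unknown node label in edge weights: ",
           paste(names(edge_weight)[is.na(i)], collapse = ", "),
           call. = FALSE)
    ew <- rep(NA_real_, tree$nnode)
    ew[i] <- edge_weight
    ew[tree$root] <- 0
    if (anyNA(ew))
      stop("missing edge weight for: ",
           paste(tree$node_label[is.na(ew)], collapse = ", "), call. = FALSE)
  } else {
    stopifnot(length(edge_weight) == tree$nnode)
    ew <- as.numeric(edge_weight)
  }
  if (any(ew < 0, na.rm = TRUE))
    stop("edge weights must be non-negative", call. = FALSE)
  ## distance from root to every node, then w(x,y) = D x + D y - 2 D lca
  d <- numeric(tree$nnode)
  for (v in rev(tree$postorder)) {
    p <- tree$parent[v]
    if (!is.na(p)) d[v] <- d[p] + ew[v]
  }
  m <- matrix(0, n, n, dimnames = list(tree$tip_label, tree$tip_label))
  for (x in seq_len(n)) for (y in seq_len(n)) {
    if (x < y) {
      k <- lca_of(tree, x, y)
      m[x, y] <- m[y, x] <- d[x] + d[y] - 2 * d[k]
    }
  }
  new_weight_model(m, mode)
}

#' Load a pair-weight table
#'
#' Reads a whitespace/tab-separated table with columns `leaf1 leaf2 weight`
#' (`#` comments allowed) and closes it symmetrically. A pair listed twice
#' with conflicting values, a self-pair, an unknown label or a negative
#' weight is an error. Pairs absent from the table are an error unless
#' `default_weight` is supplied; silent zero-filling would hide data errors.
#'
#' @param x path to a TSV file, or a data frame with three columns.
#' @param tree a [rooted_tree] supplying the leaf label set.
#' @param default_weight optional non-negative weight for unlisted pairs.
#' @return an `mpp_weights` model.
#' @export
load_weight_table <- function(x, tree, default_weight = NULL) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("weight file not found: ", x, call. = FALSE)
    x <- read.table(x, header = FALSE, comment.char = "#",
                    col.names = c("leaf1", "leaf2", "weight"),
                    colClasses = c("character", "character", "numeric"))
  }
  stopifnot(is.data.frame(x), ncol(x) >= 3L)
  labs <- tree$tip_label
  i <- match(as.character(x[[1L]]), labs)
  j <- match(as.character(x[[2L]]), labs)
  if (anyNA(i) || anyNA(j)) {
    bad <- unique(c(as.character(x[[1L]])[is.na(i)],
                    as.character(x[[2L]])[is.na(j)]))
    stop("unknown leaf label in weight table: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  wv <- as.numeric(x[[3L]])
  if (anyNA(wv)) stop("non-numeric weight in table", call. = FALSE)
  if (any(wv < 0)) stop("negative weights are not allowed", call. = FALSE)
  if (any(i == j)) stop("self-pairs are not allowed in a weight table",
                        call. = FALSE)
  n <- tree$ntip
  m <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
  for (r in seq_along(i)) {
    a <- i[r]; b <- j[r]
    if (!is.na(m[a, b]) && m[a, b] != wv[r])
      stop("conflicting weights for pair (", labs[a], ", ", labs[b], ")",
           call. = FALSE)
    m[a, b] <- m[b, a] <- wv[r]
  }
  miss <- is.na(m) & row(m) != col(m)
  if (any(miss)) {
    if (is.null(default_weight))
      stop("weight table leaves ", sum(miss) / 2,
           " pair(s) unspecified; supply default_weight to fill them",
           call. = FALSE)
    if (default_weight < 0)
      stop("default_weight must be non-negative", call. = FALSE)
    m[miss] <- default_weight
  }
  diag(m) <- 0
  new_weight_model(m, "table")
}

#' Build a weight model from a full symmetric matrix
#'
#' @param mat symmetric non-negative numeric matrix with leaf labels as
#'   dimnames (or unnamed, in tip order).
#' @param tree a [rooted_tree].
#' @return an `mpp_weights` model.
#' @export
weights_from_matrix <- function(mat, tree) {
  n <- tree$ntip
  stopifnot(is.matrix(mat), nrow(mat) == n, ncol(mat) == n)
  if (is.null(rownames(mat))) {
    dimnames(mat) <- list(tree$tip_label, tree$tip_label)
  } else {
    mat <- mat[tree$tip_label, tree$tip_label]
  }
  diag(mat) <- 0
  w <- new_weight_model(mat, "table")
  check_weights(tree, w)
  w
}
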