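#' @importFrom stats setNames runif
#' @importFrom utils head read.table write.table
NULL

## Internal node numbering follows ape: tips are 1..ntip, interior nodes
## ntip+1..nnode. All algorithms address nodes by these integer ids; leaf
## labels are the external interface.

#' Construct a rooted tree from parent/child maps
#'
#' Low-level constructor used by the Newick parser and the random tree
#' generators. Tips must be numbered `1..ntip` and carry unique non-empty
#' labels; interior nodes follow. Unary nodes (exactly one child) are not
#' permitted.
#'
#' @param parent integer vector of length `nnode`; `parent[v]` is the parent
#'   of node `v`, `NA` for the root.
#' @param children list of integer vectors; `children[[v]]` are the children
#'   of `v` in order, `integer(0)` for tips.
#' @param tip_label character vector of leaf labels for tips `1..ntip`.
#' @param edge_length optional numeric vector of length `nnode`; the length of
#'   the edge above each node (`NA` where absent, ignored at the root).
#' @param node_label optional character labels for interior nodes
#'   (`nnode - ntip` values); missing labels are auto-filled as `"N<id>"`.
#' @return an object of class `rooted_tree`.
#' @export
rooted_tree <- function(parent, children, tip_label,
                        edge_length = NULL, node_label = NULL) {
  ntip <- length(tip_label)
  nnode <- length(parent)
  stopifnot(length(children) == nnode, ntip >= 1L, nnode >= ntip)
  if (anyNA(tip_label) || any(!nzchar(tip_label)))
    stop("leaf labels must be non-empty", call. = FALSE)
  if (anyDuplicated(tip_label))
    stop("duplicate leaf labels: ",
         paste(unique(tip_label[duplicated(tip_label)]), collapse = ", "),
         call. = FALSE)
  roots <- which(is.na(parent))
  if (length(roots) != 1L)
    stop("tree must have exactly one root", call. = FALSE)
  ndeg <- lengths(children)
  if (any(ndeg == 1L))
    stop("unary nodes (exactly one child) are not allowed", call. = FALSE)
  if (any(ndeg[seq_len(ntip)] != 0L))
    stop("tips must have no children", call. = FALSE)
  if (is.null(edge_length)) edge_length <- rep(NA_real_, nnode)
  if (any(edge_length < 0, na.rm = TRUE))
    stop("edge lengths must be non-negative", call. = FALSE)
  nint <- nnode - ntip
  lab <- character(nnode)
  lab[seq_len(ntip)] <- tip_label
  auto <- paste0("N", seq_len(nnode))
  if (nint > 0L) {
    il <- if (is.null(node_label)) rep(NA_character_, nint) else node_label
    il[is.na(il) | !nzchar(il)] <- auto[ntip + which(is.na(il) | !nzchar(il))]
    lab[ntip + seq_len(nint)] <- il
  }

  po <- integer(nnode)
  depth <- integer(nnode)
  leafset <- vector("list", nnode)
  root <- roots
  ## iterative post-order (children before parents) + depths + leaf sets
  stack <- root
  order_rev <- integer(0)
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    order_rev <- c(order_rev, v)
    stack <- c(stack, children[[v]])
  }
  po <- rev(order_rev)
  if (length(po) != nnode)
    stop("tree is not connected", call. = FALSE)
  depth[root] <- 0L
  for (v in order_rev) {
    for (w in children[[v]]) depth[w] <- depth[v] + 1L
  }
  for (v in po) {
    leafset[[v]] <- if (v <= ntip) v else
      sort(unlist(leafset[children[[v]]], use.names = FALSE))
  }
  structure(list(
    ntip = ntip, nnode = nnode, root = root,
    parent = as.integer(parent), children = children,
    tip_label = tip_label, node_label = lab,
    edge_length = as.numeric(edge_length),
    postorder = po, depth = depth, leafset = leafset
  ), class = "rooted_tree")
}

#' @export
print.rooted_tree <- function(x, ...) {
  nint <- x$nnode - x$ntip
  poly <- sum(lengths(x$children) > 2L)
  cat("Rooted tree: ", x$ntip, " leaves, ", nint, " interior node",
      if (nint != 1L) "s", if (poly) paste0(" (", poly, " multifurcating)"),
      "\n", sep = "")
  cat("  leaves: ", paste(head(x$tip_label, 8L), collapse = ", "),
      if (x$ntip > 8L) ", ...", "\n", sep = "")
  invisible(x)
}

is_binary <- function(tree) {
  all(lengths(tree$children)[-seq_len(tree$ntip)] == 2L)
}

#' Parse a Newick string into a rooted tree
#'
#' Multifurcations, branch lengths and quoted labels are supported. Chains of
#' unary nodes (a single child) are collapsed with their branch lengths
#' summed, with a warning; the result satisfies the structural assumption
#' that no node has exactly one child.
#'
#' @param text a Newick string (must end with `;`).
#' @return a [rooted_tree].
#' @seealso [read_newick()] to read from a file, [write_newick()].
#' @export
parse_newick <- function(text) {
  text <- trimws(text)
  if (!nzchar(text)) stop("empty Newick string", call. = FALSE)
  if (!grepl("\\(", text)) {
    ## single-leaf tree, e.g. "a;" -- ape mangles this case
    lab <- sub(";\\s*$", "", text)
    lab2 <- sub(":[0-9eE.+-]+$", "", lab)
    if (!nzchar(lab2)) stop("malformed Newick string", call. = FALSE)
    return(rooted_tree(parent = NA_integer_, children = list(integer(0)),
                       tip_label = lab2))
  }
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop("malformed Newick string", call. = FALSE)
  if (ape::has.singles(phy)) {
    warning("unary nodes collapsed (branch lengths summed)", call. = FALSE)
    phy <- ape::collapse.singles(phy)
  }
  as_rooted_tree(phy)
}

#' Read a Newick tree from a file
#'
#' @param path file containing one Newick tree.
#' @return a [rooted_tree].
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path, call. = FALSE)
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Convert an ape "phylo" object to a rooted_tree
#'
#' @param phy a `phylo` object.
#' @return a [rooted_tree].
#' @export
as_rooted_tree <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  parent <- rep(NA_integer_, nnode)
  children <- rep(list(integer(0)), nnode)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]; v <- phy$edge[i, 2L]
    parent[v] <- p
    children[[p]] <- c(children[[p]], v)
  }
  el <- rep(NA_real_, nnode)
  if (!is.null(phy$edge.length)) el[phy$edge[, 2L]] <- phy$edge.length
  nl <- if (!is.null(phy$node.label)) phy$node.label else NULL
  rooted_tree(parent, children, phy$tip.label, edge_length = el,
              node_label = nl)
}

#' Convert a rooted_tree to an ape "phylo" object
#'
#' @param tree a [rooted_tree] with at least two leaves.
#' @return a `phylo` object.
#' @export
as_phylo <- function(tree) {
  stopifnot(inherits(tree, "rooted_tree"))
  if (tree$ntip < 2L)
    stop("ape cannot represent single-leaf trees", call. = FALSE)
  edge <- cbind(tree$parent, seq_len(tree$nnode))
  edge <- edge[!is.na(edge[, 1L]), , drop = FALSE]
  ## ape expects cladewise-ish order; preorder by parent works
  edge <- edge[order(tree$depth[edge[, 2L]], edge[, 1L]), , drop = FALSE]
  phy <- list(edge = edge, Nnode = tree$nnode - tree$ntip,
              tip.label = tree$tip_label,
              node.label = tree$node_label[-seq_len(tree$ntip)])
  if (any(!is.na(tree$edge_length))) {
    el <- tree$edge_length[edge[, 2L]]
    el[is.na(el)] <- 0
    phy$edge.length <- el
  }
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Write a rooted_tree as Newick
#'
#' @param tree a [rooted_tree].
#' @param path optional file; if `NULL` the Newick string is returned.
#' @return the Newick string, invisibly if written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  if (tree$ntip < 2L) {
    s <- paste0(tree$tip_label, ";")
  } else {
    s <- ape::write.tree(as_phylo(tree))
  }
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Re-root an effectively unrooted tree by subdividing an edge
#'
#' A tree whose root is a polytomy (a basal trifurcation is the usual Newick
#' encoding of an unrooted tree) is rooted by placing a new root in the
#' middle of the edge leading to one of the root's children. The optimal
#' pairing score is invariant to this choice, since edge-disjointness of
#' leaf paths does not depend on the root; the default rule (first child in
#' input order) simply makes runs reproducible. A tree whose root already
#' has two children is returned unchanged.
#'
#' @param tree a [rooted_tree].
#' @param edge_choice index (into the root's child list) of the edge to
#'   subdivide; default 1.
#' @return a [rooted_tree] whose root has two children.
#' @export
root_unrooted <- function(tree, edge_choice = 1L) {
  stopifnot(inherits(tree, "rooted_tree"))
  ch <- tree$children[[tree$root]]
  if (length(ch) == 2L) return(tree)
  if (edge_choice < 1L || edge_choice > length(ch))
    stop("edge_choice out of range", call. = FALSE)
  pick <- ch[edge_choice]
  nnode <- tree$nnode
  newroot <- nnode + 1L
  parent <- c(tree$parent, NA_integer_)
  children <- c(tree$children, list(integer(0)))
  parent[tree$root] <- newroot
  parent[pick] <- newroot
  children[[tree$root]] <- setdiff(ch, pick)
  children[[newroot]] <- c(pick, tree$root)
  el <- c(tree$edge_length, NA_real_)
  if (!is.na(el[pick])) {
    half <- el[pick] / 2
    el[pick] <- half
    el[tree$root] <- half
  }
  rooted_tree(parent, children, tree$tip_label, edge_length = el,
              node_label = c(tree$node_label[-seq_len(tree$ntip)], NA))
}

#' Leaf navigation table
#'
#' For every interior node `u` and every leaf `x` in the subtree below `u`,
#' `nav[u, x]` is the child of `u` on the unique path from `u` to `x`. This
#' is the workhorse lookup for all the dynamic programs: it identifies, at
#' each node, which child subtree a leaf hangs in.
#'
#' @param tree a [rooted_tree].
#' @return an `nnode x ntip` integer matrix; `NA` where `x` is not below `u`
#'   or `u` is itself a tip.
#' @export
build_nav_table <- function(tree) {
  nav <- matrix(NA_integer_, tree$nnode, tree$ntip)
  for (x in seq_len(tree$ntip)) {
    prev <- x
    a <- tree$parent[x]
    while (!is.na(a)) {
      nav[a, x] <- prev
      prev <- a
      a <- tree$parent[a]
    }
  }
  nav
}

tip_id <- function(tree, x) {
  if (is.character(x)) {
    i <- match(x, tree$tip_label)
    if (anyNA(i)) stop("unknown leaf label: ",
                       paste(x[is.na(i)], collapse = ", "), call. = FALSE)
    i
  } else as.integer(x)
}

lca_of <- function(tree, a, b) {
  while (a != b) {
    if (tree$depth[a] >= tree$depth[b]) a <- tree$parent[a]
    else b <- tree$parent[b]
  }
  a
}

#' Path between two leaves
#'
#' Returns the unique path connecting two distinct leaves, through their
#' last common ancestor. Each edge is identified by its lower (child-side)
#' node, a convention used throughout for edge-disjointness checks.
#'
#' @param tree a [rooted_tree].
#' @param x,y leaf labels (or internal tip ids); must be distinct.
#' @return a list with `nodes` (node id sequence from `x` to `y`), `edges`
#'   (ids of the child-side nodes of the traversed edges) and `labels`
#'   (node labels along the path).
#' @export
path_between <- function(tree, x, y) {
  xi <- tip_id(tree, x); yi <- tip_id(tree, y)
  if (xi == yi) stop("path endpoints must be distinct leaves", call. = FALSE)
  k <- lca_of(tree, xi, yi)
  up <- integer(0); v <- xi
  while (v != k) { up <- c(up, v); v <- tree$parent[v] }
  dn <- integer(0); v <- yi
  while (v != k) { dn <- c(dn, v); v <- tree$parent[v] }
  nodes <- c(up, k, rev(dn))
  list(nodes = nodes, edges = c(up, dn), lca = k,
       labels = tree$node_label[nodes])
}
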