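#' Dated phylogenies with node ages
#'
#' A `dated_tree` wraps an [ape::phylo] tree together with node ages (Ma
#' before present, computed from root-to-tip path sums) and an
#' ultrametricity flag. Tip ages are zero on an ultrametric tree; on
#' non-ultrametric trees ages are measured relative to the furthest tip.
#'
#' @name dated_tree
NULL

new_dated_tree <- function(phy, tol = 1e-6) {
  n_tip <- length(phy$tip.label)
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (any(phy$edge.length < 0)) stop("negative branch length in tree")
  if (anyDuplicated(phy$tip.label)) stop("duplicate taxon labels in tree")
  depths <- ape::node.depth.edgelength(phy)
  max_depth <- max(depths[seq_len(n_tip)])
  age <- max_depth - depths
  tip_ages <- age[seq_len(n_tip)]
  ultra <- all(abs(tip_ages) <= tol * max(max_depth, .Machine$double.eps))
  structure(
    list(phylo = phy, node_age = age, is_ultrametric = ultra,
         n_tip = n_tip, n_node = phy$Nnode, root = n_tip + 1L),
    class = "dated_tree")
}

#' Parse a newick tree into a dated tree
#'
#' Accepts quoted labels and square-bracket comments (stripped), polytomies
#' are retained. Node ages are computed from path sums, so
#' `age(parent) = age(child) + branch_length(child)` holds by construction.
#'
#' @param newick_text Newick string (or a `phylo` object).
#' @param require_ultrametric Error unless all tip ages are 0 within `tol`.
#' @param tol Relative tolerance on tip ages for the ultrametricity check;
#'   dated trees from external tools carry rounding noise, hence 1e-6.
#' @return A `dated_tree`.
#' @examples
#' tr <- parse_tree("((A:1,B:1):1,C:2);")
#' node_ages(tr)
#' @export
parse_tree <- function(newick_text, require_ultrametric = FALSE, tol = 1e-6) {
  if (inherits(newick_text, "phylo")) {
    phy <- newick_text
  } else {
    txt <- gsub("\\[[^]]*\\]", "", newick_text)  # strip comments
    phy <- tryCatch(ape::read.tree(text = txt),
                    error = function(e) NULL, warning = function(w) NULL)
    if (is.null(phy) || !inherits(phy, "phylo")) stop("unparseable newick string")
  }
  tr <- new_dated_tree(phy, tol = tol)
  if (require_ultrametric && !tr$is_ultrametric) {
    stop("tree is not ultrametric (tip ages differ) but require_ultrametric = TRUE")
  }
  tr
}

#' Read a dated tree from a newick file
#'
#' @param path Path to a newick file (first tree is used; see
#'   [parse_trees()] for posterior samples).
#' @inheritParams parse_tree
#' @export
read_dated_tree <- function(path, require_ultrametric = FALSE, tol = 1e-6) {
  parse_tree(paste(readLines(path, warn = FALSE), collapse = ""),
             require_ultrametric = require_ultrametric, tol = tol)
}

#' Parse several newick trees (e.g. a posterior sample)
#'
#' @param path File with one newick tree per line.
#' @inheritParams parse_tree
#' @return List of `dated_tree` objects.
#' @export
parse_trees <- function(path, require_ultrametric = FALSE, tol = 1e-6) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, parse_tree, require_ultrametric = require_ultrametric, tol = tol)
}

#' Write a dated tree to newick
#'
#' @param tree A `dated_tree`.
#' @param path Optional output file; if `NULL` the newick string is returned.
#' @export
write_dated_tree <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "dated_tree"))
  txt <- ape::write.tree(tree$phylo)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' @export
print.dated_tree <- function(x, ...) {
  cat("<dated_tree>", x$n_tip, "tips,", x$n_node, "internal nodes, root age",
      format(root_age(x), digits = 6), "Ma,",
      if (x$is_ultrametric) "ultrametric" else "NOT ultrametric", "\n")
  invisible(x)
}

#' Node ages of a dated tree
#' @param tree A `dated_tree`.
#' @return Numeric vector over nodes (ape numbering: tips first).
#' @export
node_ages <- function(tree) tree$node_age

#' @rdname node_ages
#' @export
root_age <- function(tree) tree$node_age[tree$root]

#' Most recent common ancestor of a set of taxa
#'
#' A singleton set returns the terminal node itself.
#'
#' @param tree A `dated_tree`.
#' @param taxa Character vector of tip labels.
#' @return Node id (ape numbering).
#' @export
find_mrca <- function(tree, taxa) {
  stopifnot(inherits(tree, "dated_tree"))
  if (length(taxa) == 0) stop("taxa must be non-empty")
  idx <- match(taxa, tree$phylo$tip.label)
  if (anyNA(idx)) stop("unknown taxon label(s): ", paste(taxa[is.na(idx)], collapse = ", "))
  if (length(unique(idx)) == 1L) return(unique(idx))
  ape::getMRCA(tree$phylo, unique(idx))
}

#' Tidy per-node view of a dated tree
#'
#' @param tree A `dated_tree`.
#' @return Tibble with one row per node: `node`, `parent` (NA for the root),
#'   `branch_length` (Ma), `age` (Ma), `label` (tip label or ""), `is_tip`.
#' @export
tidy_tree <- function(tree) {
  phy <- tree$phylo
  n_all <- tree$n_tip + tree$n_node
  parent <- rep(NA_integer_, n_all)
  blen <- rep(NA_real_, n_all)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  blen[phy$edge[, 2]] <- phy$edge.length
  tibble(
    node = seq_len(n_all),
    parent = parent,
    branch_length = blen,
    age = tree$node_age,
    label = c(phy$tip.label, rep("", tree$n_node)),
    is_tip = seq_len(n_all) <= tree$n_tip)
}

# children of each node as a list indexed by node id
tree_children <- function(tree) {
  phy <- tree$phylo
  n_all <- tree$n_tip + tree$n_node
  split(phy$edge[, 2], factor(phy$edge[, 1], levels = seq_len(n_all)))
}

# internal nodes in postorder (children before parents)
tree_postorder <- function(tree) {
  edge <- ape::reorder.phylo(tree$phylo, "postorder")$edge
  unique(edge[, 1])
}

# edge matrix in postorder together with lengths
tree_postorder_edges <- function(tree) {
  phy <- ape::reorder.phylo(tree$phylo, "postorder")
  list(edge = phy$edge, length = phy$edge.length)
}

# all descendant tips of a node (including itself if a tip)
node_tips <- function(tree, node) {
  if (node <= tree$n_tip) return(node)
  kids <- tree_children(tree)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v <= tree$n_tip) out <- c(out, v) else stack <- c(stack, kids[[v]])
  }
  sort(out)
}

# all descendant nodes (internal + tips), excluding the node itself
node_descendants <- function(tree, node) {
  kids <- tree_children(tree)
  out <- integer(0)
  stack <- kids[[node]]
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    out <- c(out, v)
    if (v > tree$n_tip) stack <- c(stack, kids[[v]])
  }
  sort(out)
}
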