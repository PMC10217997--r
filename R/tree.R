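# Species tree with a foreground/background branch partition.
#
# Foreground marking follows the conventional control-file dialect: a "#1"
# suffix on a tip label flags that terminal branch; "#1" as an internal node
# label flags the node's whole clade (stem branch plus every branch within).

#' Construct a labeled tree (topology + foreground branch partition)
#'
#' @param tree An `ape::phylo` object, a Newick string, or a path to a Newick
#'   file.  `#1` suffixes on tip/node labels are parsed as foreground marks.
#' @param foreground Optional character vector of tip labels; the clade
#'   spanned by them (stem branch included) is marked foreground.  Overrides
#'   any `#1` labels.
#' @return An object of class `labeled_tree`: list with `phylo` (labels
#'   cleaned), and `fg_nodes` (integer ids of nodes whose subtending branch
#'   is foreground; empty if none marked).
#' @export
#' @examples
#' tr <- labeled_tree("((a:1,b:1)#1:0.5,c:1,d:1);")
#' sum(foreground_edges(tr))  # stem + 2 terminal branches
labeled_tree <- function(tree, foreground = NULL) {
  if (is.character(tree)) {
    tree <- if (length(tree) == 1L && !grepl("\\(", tree)) {
      ape::read.tree(tree)
    } else {
      ape::read.tree(text = tree)
    }
  }
  if (!inherits(tree, "phylo")) abort("`tree` must be a phylo object or Newick input")
  ntip <- length(tree$tip.label)
  fg_nodes <- integer(0)

  marked_tips <- grepl("#\\d+$", tree$tip.label)
  if (any(marked_tips)) {
    fg_nodes <- c(fg_nodes, which(marked_tips))
    tree$tip.label <- sub("\\s*#\\d+$", "", tree$tip.label)
  }
  if (!is.null(tree$node.label)) {
    marked_nodes <- grepl("#\\d+$", tree$node.label)
    if (any(marked_nodes)) {
      for (nd in ntip + which(marked_nodes)) {
        fg_nodes <- c(fg_nodes, nd, clade_descendants(tree, nd))
      }
      tree$node.label <- sub("\\s*#\\d+$", "", tree$node.label)
    }
  }
  if (!is.null(foreground)) {
    missing_taxa <- setdiff(foreground, tree$tip.label)
    if (length(missing_taxa)) {
      abort(paste0("foreground taxa not in tree: ", paste(missing_taxa, collapse = ", ")))
    }
    if (length(foreground) == 1L) {
      fg_nodes <- match(foreground, tree$tip.label)
    } else {
      mrca <- ape::getMRCA(tree, foreground)
      fg_nodes <- c(mrca, clade_descendants(tree, mrca))
    }
  }
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0.1, nrow(tree$edge))
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    abort("branch lengths must be finite and non-negative")
  }
  structure(list(phylo = tree, fg_nodes = sort(unique(as.integer(fg_nodes)))),
            class = "labeled_tree")
}

# all node ids strictly inside the clade rooted at `node`
clade_descendants <- function(phy, node) {
  edge <- phy$edge
  out <- integer(0)
  stack <- edge[edge[, 1] == node, 2]
  while (length(stack)) {
    out <- c(out, stack)
    stack <- edge[edge[, 1] %in% stack, 2]
  }
  out
}

#' @export
print.labeled_tree <- function(x, ...) {
  cat("<labeled_tree> ", length(x$phylo$tip.label), " tips, ",
      length(x$fg_nodes), " foreground branches\n", sep = "")
  invisible(x)
}

as_labeled_tree <- function(x) {
  if (inherits(x, "labeled_tree")) return(x)
  labeled_tree(x)
}

#' Foreground flag per edge of the underlying phylo object
#'
#' @param tree A [labeled_tree].
#' @return Logical vector along `tree$phylo$edge` rows.
#' @export
foreground_edges <- function(tree) {
  tree <- as_labeled_tree(tree)
  tree$phylo$edge[, 2] %in% tree$fg_nodes
}

#' Read a Newick tree with foreground marks
#'
#' @param file Path to a Newick file (or a Newick string).
#' @inheritParams labeled_tree
#' @return A [labeled_tree].
#' @export
read_labeled_tree <- function(file, foreground = NULL) {
  labeled_tree(file, foreground = foreground)
}

# topology/edge bundle for the likelihood engine: postorder edges, 0-based
tree_engine_data <- function(tree, taxa) {
  phy <- tree$phylo
  if (!setequal(phy$tip.label, taxa)) {
    abort("tree tip labels must match alignment taxa")
  }
  phy2 <- stats::reorder(phy, "postorder")
  ntip <- length(phy2$tip.label)
  root <- setdiff(unique(phy2$edge[, 1]), phy2$edge[, 2])
  fg <- as.integer(phy2$edge[, 2] %in% tree$fg_nodes)
  list(
    phylo = phy2,
    edges0 = phy2$edge - 1L,
    edge_len = phy2$edge.length,
    edge_fg = fg,
    n_node = max(phy2$edge),
    root0 = root - 1L,
    tip_order = phy2$tip.label,
    ntip = ntip
  )
}
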