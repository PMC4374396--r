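#' Dated species trees (chronograms)
#'
#' A chronogram is a rooted, fully resolved (binary) species tree with
#' branch lengths in millions of years. All downstream machinery — the
#' birth-death likelihood, the guest-tree simulator, reconciliation —
#' addresses branches by the label of the branch's child node, so
#' [as_chronogram()] assigns every unlabelled internal node a
#' deterministic label derived from a hash of its sorted descendant leaf
#' set. Labels are therefore stable across runs, across node
#' re-orderings, and across write/read round trips.
#'
#' Ultrametricity (all root-to-leaf path lengths equal) is checked with
#' a tolerance relative to tree depth (`tol_rel * depth`), because
#' published chronograms carry rounding error. A non-ultrametric tree is
#' flagged, not rejected: reconciliation tolerates it, but the
#' birth-death likelihood requires a dated tree and will refuse it.
#'
#' @param x For [read_chronogram()], a Newick string (must contain
#'   `";"`) or the path to a Newick file. For [as_chronogram()], an
#'   [ape::phylo] object.
#' @param tol_rel Relative ultrametricity tolerance (default `1e-6`
#'   times tree depth).
#' @return A `chronogram`: an [ape::phylo] with complete node labels and
#'   attributes `depth` (Myr) and `ultrametric` (logical flag).
#' @examples
#' tr <- read_chronogram("((A:1,B:1):1,C:2);")
#' tree_depth(tr)
#' branch_table(tr)
#' @export
read_chronogram <- function(x, tol_rel = 1e-6) {
  stopifnot(is.character(x), length(x) == 1)
  tr <- if (grepl("[(;]", x)) {
    suppressWarnings(ape::read.tree(text = x))
  } else {
    if (!file.exists(x)) abort(paste0("tree file not found: ", x))
    ape::read.tree(file = x)
  }
  if (is.null(tr)) abort("could not parse Newick input")
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1) abort("expected a single tree, found several")
    tr <- tr[[1]]
  }
  as_chronogram(tr, tol_rel = tol_rel)
}

#' @rdname read_chronogram
#' @export
as_chronogram <- function(x, tol_rel = 1e-6) {
  if (inherits(x, "chronogram")) return(x)
  if (!inherits(x, "phylo")) abort("`x` must be a phylo object or Newick input")
  if (!ape::is.rooted(x)) abort("tree must be rooted")
  if (!ape::is.binary(x)) abort("tree contains polytomies; fully resolved trees required")
  if (is.null(x$edge.length) || anyNA(x$edge.length)) {
    abort("all branches must carry branch lengths")
  }
  if (any(x$edge.length < 0)) abort("negative branch lengths are not allowed")
  if (anyDuplicated(x$tip.label)) abort("taxon names must be unique")

  x$node.label <- internal_labels(x)
  depths <- ape::node.depth.edgelength(x)
  leaf_depths <- depths[seq_len(ape::Ntip(x))]
  depth <- max(depths)
  ultra <- diff(range(leaf_depths)) <= tol_rel * max(depth, .Machine$double.eps)
  if (!ultra) {
    warn("tree is not ultrametric within tolerance; flagged (birth-death fitting will refuse it)")
  }
  attr(x, "depth") <- depth
  attr(x, "ultrametric") <- ultra
  class(x) <- c("chronogram", "phylo")
  x
}

# Deterministic internal-node labels: existing non-empty labels are
# kept, missing ones become "n<leafcount>x<hash of sorted leaf set>".
internal_labels <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  desc <- node_leafsets(tree)
  auto <- vapply(seq_len(nnode) + ntip, function(nd) {
    leaves <- sort(desc[[nd]])
    paste0("n", length(leaves), "x", str_hash(paste(leaves, collapse = "|")))
  }, character(1))
  labs <- tree$node.label
  if (is.null(labs) || length(labs) != nnode) labs <- rep("", nnode)
  labs[is.na(labs) | labs == ""] <- auto[is.na(labs) | labs == ""]
  if (anyDuplicated(labs)) labs <- make.unique(labs, sep = "_")
  labs
}

# List of descendant leaf-name sets, indexed by node number.
node_leafsets <- function(tree) {
  ntip <- ape::Ntip(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", ntip + tree$Nnode)
  desc[seq_len(ntip)] <- as.list(tree$tip.label)
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]
    ch <- po$edge[i, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

#' @rdname read_chronogram
#' @param tree A `chronogram`.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths on output.
#' @export
write_chronogram <- function(tree, file = NULL, digits = 12) {
  tree <- as_chronogram(tree)
  if (is.null(file)) {
    ape::write.tree(tree, digits = digits)
  } else {
    ape::write.tree(tree, file = file, digits = digits)
    invisible(file)
  }
}

#' @rdname read_chronogram
#' @export
tree_depth <- function(tree) attr(as_chronogram(tree), "depth")

#' @rdname read_chronogram
#' @export
is_dated <- function(tree) isTRUE(attr(as_chronogram(tree), "ultrametric"))

# Labels for all nodes, indexed by ape node number (tips first).
node_labels <- function(tree) c(tree$tip.label, tree$node.label)

#' Branch table of a chronogram
#'
#' One row per branch (every non-root node), identified by the child
#' node's label, with parent label, branch length and the absolute time
#' interval (Myr from the root) the branch spans.
#'
#' @inheritParams write_chronogram
#' @return A tibble with columns `branch`, `parent`, `length`,
#'   `time_start`, `time_end`, `is_leaf`.
#' @export
branch_table <- function(tree) {
  tree <- as_chronogram(tree)
  labs <- node_labels(tree)
  times <- ape::node.depth.edgelength(tree)
  ntip <- ape::Ntip(tree)
  tibble::tibble(
    branch = labs[tree$edge[, 2]],
    parent = labs[tree$edge[, 1]],
    length = tree$edge.length,
    time_start = times[tree$edge[, 1]],
    time_end = times[tree$edge[, 2]],
    is_leaf = tree$edge[, 2] <= ntip
  )
}
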