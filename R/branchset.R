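#' Branch sets: addressing a clade on the chronogram
#'
#' A branch set is a collection of branch identifiers (each branch is
#' named after its child node). The usual way to build one is
#' [mrca_branches()]: all branches of the subtree rooted at the most
#' recent common ancestor of a taxon set, optionally including the stem
#' branch leading to that ancestor. This is how the focal clade of a
#' rate-shift or expansion test is declared.
#'
#' @param tree A `chronogram` (see [read_chronogram()]).
#' @param taxa Character vector of at least two leaf names.
#' @param include_stem Include the branch immediately ancestral to the
#'   MRCA? Default `FALSE`. Rate-shift fits conventionally include it
#'   (rates apply from the clade's origin).
#' @return A `branch_set`: character vector of branch ids with
#'   provenance attributes (`mrca`, `taxa`, `include_stem`).
#' @examples
#' tr <- read_chronogram("((A:1,B:1):1,C:2);")
#' mrca_branches(tr, c("A", "B"), include_stem = TRUE)
#' @export
mrca_branches <- function(tree, taxa, include_stem = FALSE) {
  tree <- as_chronogram(tree)
  stopifnot(is.character(taxa))
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown) > 0) {
    abort(paste0("unknown taxa: ", paste(unknown, collapse = ", ")))
  }
  if (length(unique(taxa)) < 2) abort("need at least two taxa to define an MRCA")

  labs <- node_labels(tree)
  m <- ape::getMRCA(tree, taxa)
  desc <- descendant_nodes(tree, m)
  ids <- labs[desc]
  root <- ape::Ntip(tree) + 1L
  if (include_stem) {
    if (m == root) {
      warn("MRCA is the root: there is no stem branch to include")
    } else {
      ids <- c(labs[m], ids)
    }
  }
  new_branch_set(tree, ids, mrca = labs[m], taxa = sort(taxa),
                 include_stem = include_stem)
}

#' @rdname mrca_branches
#' @param branches Character vector of branch ids (child-node labels).
#' @export
branch_set <- function(tree, branches) {
  tree <- as_chronogram(tree)
  new_branch_set(tree, branches)
}

new_branch_set <- function(tree, ids, mrca = NA_character_, taxa = NULL,
                           include_stem = NA) {
  all_ids <- branch_table(tree)$branch
  bad <- setdiff(ids, all_ids)
  if (length(bad) > 0) {
    abort(paste0("branch ids not found in tree: ", paste(bad, collapse = ", ")))
  }
  structure(unique(ids), class = "branch_set",
            mrca = mrca, taxa = taxa, include_stem = include_stem)
}

#' @export
print.branch_set <- function(x, ...) {
  cat("<branch_set> ", length(x), " branches", sep = "")
  if (!is.na(attr(x, "mrca"))) {
    cat(" (MRCA ", attr(x, "mrca"),
        if (isTRUE(attr(x, "include_stem"))) " + stem" else "", ")", sep = "")
  }
  cat("\n", paste(unclass(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# All node numbers strictly below `node`.
descendant_nodes <- function(tree, node) {
  edge <- tree$edge
  out <- integer(0)
  stack <- edge[edge[, 1] == node, 2]
  while (length(stack) > 0) {
    nd <- stack[[1]]
    stack <- stack[-1]
    out <- c(out, nd)
    stack <- c(stack, edge[edge[, 1] == nd, 2])
  }
  sort(out)
}

# Map every branch to an integer class: 1 = background, 2 = focal set.
branch_classes <- function(tree, branches = NULL) {
  bt <- branch_table(tree)
  cls <- setNames(rep(1L, nrow(bt)), bt$branch)
  if (!is.null(branches)) cls[as.character(branches)] <- 2L
  cls
}
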