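#' Reconcile a gene tree with the species tree (LCA mapping)
#'
#' Embeds a rooted binary gene tree into the species tree: each gene
#' node is mapped to the last common ancestor of its descendants'
#' species. A gene node is a duplication when its mapping coincides
#' with a child's mapping; losses are implied along each gene edge
#' `(u, v)` as `path_edges(M(u), M(v)) - 1 + [u is duplication]`, and
#' each loss is charged to the species branch on which the vanished
#' copy must have lived. The LCA mapping simultaneously minimises the
#' duplication count and the loss count, so the weighted cost
#' `c_dup * D + c_loss * L` is reporting-only — the mapping does not
#' depend on the costs. The defaults `c_dup = 1.5`, `c_loss = 1.0` are
#' the conventional reconciliation weights.
#'
#' Gene-tree leaves carry their species as a `"SPECIES|gene"` prefix
#' (a label without `"|"` is taken to be a bare species name). The gene
#' root has no parent edge: losses above the root are not counted.
#' Duplications mapped to the species root are recorded under the root
#' label, which no [mrca_branches()] set contains, so they stay outside
#' any clade summary by default.
#'
#' @param gt A rooted binary [ape::phylo] gene tree (or a Newick
#'   string), leaf labels `"SPECIES|gene"`.
#' @param st The species `chronogram` (ultrametricity not required
#'   here).
#' @param c_dup,c_loss Event weights for the reported cost.
#' @return A `reconciliation`: list with `map` (tibble: `gene_node`,
#'   `species_node`, `event`), `per_branch` (tibble: `branch`,
#'   `duplications`, `losses`), totals `D`, `L`, and `cost`.
#' @examples
#' st <- read_chronogram("((A:1,B:1):1,C:2);")
#' lca_reconcile("(A|g1,(B|g1,C|g1));", st)
#' @export
lca_reconcile <- function(gt, st, c_dup = 1.5, c_loss = 1.0) {
  if (is.character(gt)) gt <- read_gene_tree(gt)
  st <- as_chronogram(st)
  if (!ape::is.rooted(gt) || !ape::is.binary(gt)) {
    abort("gene tree must be rooted and binary")
  }
  sp <- gene_leaf_species(gt$tip.label)
  bad <- setdiff(unique(sp), st$tip.label)
  if (length(bad) > 0) {
    abort(paste0("gene-tree species not in species tree: ",
                 paste(bad, collapse = ", ")))
  }

  slabs <- node_labels(st)
  sroot <- ape::Ntip(st) + 1L
  sparent <- rep(NA_integer_, length(slabs))
  sparent[st$edge[, 2]] <- st$edge[, 1]
  # ancestor chains for LCA computation
  chain <- lapply(seq_along(slabs), function(nd) {
    out <- nd
    while (!is.na(sparent[out[1]])) out <- c(sparent[out[1]], out)
    out # root ... nd
  })
  lca2 <- function(a, b) {
    ca <- chain[[a]]; cb <- chain[[b]]
    m <- min(length(ca), length(cb))
    i <- which(ca[seq_len(m)] != cb[seq_len(m)])
    if (length(i) == 0) ca[m] else ca[i[1] - 1]
  }

  gn <- ape::Ntip(gt) + gt$Nnode
  M <- integer(gn)
  sp_idx <- match(sp, st$tip.label)
  M[seq_len(ape::Ntip(gt))] <- sp_idx
  po <- ape::reorder.phylo(gt, "postorder")
  kids <- split(po$edge[, 2], po$edge[, 1])
  for (i in seq_len(nrow(po$edge))) {   # children complete before parents
    p <- po$edge[i, 1]
    ch <- po$edge[i, 2]
    M[p] <- if (M[p] == 0L) M[ch] else lca2(M[p], M[ch])
  }
  is_dup <- logical(gn)
  for (u in unique(po$edge[, 1])) {
    ch <- kids[[as.character(u)]]
    is_dup[u] <- any(M[ch] == M[u])
  }

  dup_branch <- integer(0)
  loss_branch <- integer(0)
  for (i in seq_len(nrow(po$edge))) {
    u <- po$edge[i, 1]
    v <- po$edge[i, 2]
    path <- species_path(chain, M[u], M[v]) # M(u) ... M(v)
    d <- length(path) - 1L
    # losses sit on the off-path child of each passed species node:
    # from M(u) itself when u duplicated, from the first split after
    # M(u) otherwise
    from <- if (is_dup[u]) 1L else 2L
    if (d >= from) {
      for (j in from:d) {
        node_j <- path[j]
        next_j <- path[j + 1]
        ch <- st$edge[st$edge[, 1] == node_j, 2]
        loss_branch <- c(loss_branch, setdiff(ch, next_j))
      }
    }
  }
  dup_branch <- M[which(is_dup)]

  bt <- branch_table(st)
  all_ids <- c(bt$branch, slabs[sroot])
  per_branch <- tibble::tibble(
    branch = all_ids,
    duplications = as.integer(vapply(all_ids, function(b)
      sum(slabs[dup_branch] == b), numeric(1))),
    losses = as.integer(vapply(all_ids, function(b)
      sum(slabs[loss_branch] == b), numeric(1)))
  )
  per_branch <- per_branch[per_branch$duplications + per_branch$losses > 0 |
                             per_branch$branch %in% bt$branch, ]
  D <- sum(is_dup)
  L <- length(loss_branch)
  glabs <- c(gt$tip.label,
             gt$node.label %||% paste0("gnode", seq_len(gt$Nnode)))
  structure(list(
    map = tibble::tibble(
      gene_node = glabs,
      species_node = slabs[M],
      event = ifelse(seq_len(gn) <= ape::Ntip(gt), "leaf",
                     ifelse(is_dup, "duplication", "speciation"))
    ),
    per_branch = per_branch,
    D = D, L = L, c_dup = c_dup, c_loss = c_loss,
    cost = c_dup * D + c_loss * L,
    species_root = slabs[sroot]
  ), class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat(sprintf("<reconciliation> D = %d, L = %d, cost = %.1f (c_dup = %g, c_loss = %g)\n",
              x$D, x$L, x$cost, x$c_dup, x$c_loss))
  invisible(x)
}

#' @rdname lca_reconcile
#' @param x A Newick string or file path.
#' @export
read_gene_tree <- function(x) {
  tr <- if (grepl(";", x, fixed = TRUE)) ape::read.tree(text = x)
        else ape::read.tree(file = x)
  if (is.null(tr)) abort("could not parse gene tree")
  if (any(tr$tip.label == "")) abort("gene tree has empty leaf labels")
  tr
}

gene_leaf_species <- function(labels) {
  sp <- sub("\\|.*$", "", labels)
  if (any(sp == "")) {
    offending <- labels[sp == ""]
    abort(paste0("malformed gene leaf label(s): ",
                 paste(offending, collapse = ", ")))
  }
  sp
}

# Node path root-ward node `a` down to its descendant `b` (inclusive).
species_path <- function(chain, a, b) {
  cb <- chain[[b]]
  ia <- match(a, cb)
  if (is.na(ia)) abort("invalid mapping: M(parent) is not ancestral to M(child)")
  cb[ia:length(cb)]
}

#' @rdname lca_reconcile
#' @param rec A `reconciliation`.
#' @param branches A `branch_set` or character vector of species branch
#'   ids.
#' @return For [clade_summary()], a one-row tibble `D`, `L`, `k`
#'   restricted to the branch set.
#' @export
clade_summary <- function(rec, branches) {
  stopifnot(inherits(rec, "reconciliation"))
  ids <- as.character(branches)
  known <- c(rec$per_branch$branch, rec$species_root)
  bad <- setdiff(ids, known)
  if (length(bad) > 0) {
    abort(paste0("branch ids not in reconciliation: ",
                 paste(bad, collapse = ", ")))
  }
  pb <- rec$per_branch[rec$per_branch$branch %in% ids, ]
  tibble::tibble(D = sum(pb$duplications), L = sum(pb$losses),
                 k = sum(pb$duplications) - sum(pb$losses))
}
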