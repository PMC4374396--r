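#' Ancestral gene-family sizes
#'
#' Two reconstructions of per-node copy numbers on the chronogram:
#'
#' * [sankoff_counts()] — linear-cost (Wagner) parsimony over integer
#'   states `0..cmax` by Sankoff dynamic programming. The default cost
#'   charges 1 per unit change in either direction (a duplication and a
#'   loss each change family size by one); asymmetric costs, e.g.
#'   1.5/1.0 to mirror conventional reconciliation weights, are
#'   available via `cost_dup`/`cost_loss`. The minimum total cost is
#'   unique; the point estimates are made deterministic by a preorder
#'   tie-break that picks, at each node, the optimal value closest to
#'   the parent's chosen value (smallest optimal value at the root).
#' * [ml_ancestral_counts()] — marginal posterior mode of each node's
#'   count under a fitted birth-death model, via the standard
#'   upward/downward dynamic programming; ties resolve to the smallest
#'   count.
#'
#' Both return a `count_history`: a tibble with one row per node
#' (`node`, `parent`, `is_leaf`, `count`, `delta` = child minus parent)
#' whose branch rows feed [branch_deltas()].
#'
#' @param counts Named vector of leaf copy numbers, or a one-row count
#'   table.
#' @param tree A `chronogram`.
#' @param cmax Upper bound of the reconstructed state space; default
#'   max observed count + 20 (parsimony never reconstructs above the
#'   observed maximum, so the bound is generous).
#' @param cost_dup,cost_loss Per-unit cost of an increase / decrease
#'   along a branch (parsimony only).
#' @return A `count_history` tibble; for [sankoff_counts()] the
#'   attribute `cost` holds the minimum total weighted change.
#' @examples
#' tr <- read_chronogram("((A:1,B:1):1,C:2);")
#' sankoff_counts(c(A = 1, B = 3, C = 1), tr)
#' @export
sankoff_counts <- function(counts, tree, cmax = NULL,
                           cost_dup = 1, cost_loss = 1) {
  obs <- leaf_count_vector(counts)
  tree <- as_chronogram(tree)
  if (!setequal(names(obs), tree$tip.label)) {
    abort("count names must match the tree's taxa")
  }
  obs <- obs[tree$tip.label]
  if (is.null(cmax)) cmax <- max(obs) + 20L
  if (cmax < max(obs)) abort("`cmax` is smaller than an observed count")
  S <- cmax + 1L
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")

  # upward pass: cost[v, s] = min cost of subtree of v given state s
  cost <- matrix(0, nnode, S)
  for (i in seq_len(ntip)) {
    cost[i, ] <- Inf
    cost[i, obs[i] + 1L] <- 0
  }
  relax <- function(m) {
    # min-plus convolution of child cost with the linear change cost
    A <- m
    for (s in 2:S) A[s] <- min(A[s], A[s - 1] + cost_loss)
    B <- m
    for (s in (S - 1):1) B[s] <- min(B[s], B[s + 1] + cost_dup)
    pmin(A, B)
  }
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]
    ch <- po$edge[i, 2]
    cost[p, ] <- cost[p, ] + relax(cost[ch, ])
  }

  root <- ntip + 1L
  total <- min(cost[root, ])
  assign_val <- integer(nnode)
  # root: smallest optimal state
  assign_val[root] <- which(cost[root, ] <= total + 1e-9)[1] - 1L
  # preorder: states closest to the parent's chosen value win ties
  pre <- rev(seq_len(nrow(po$edge)))
  states <- 0:cmax
  for (i in pre) {
    p <- po$edge[i, 1]
    ch <- po$edge[i, 2]
    pv <- assign_val[p]
    w <- ifelse(states > pv, cost_dup * (states - pv),
                cost_loss * (pv - states))
    v <- cost[ch, ] + w
    mn <- min(v)
    cand <- states[v <= mn + 1e-9]
    assign_val[ch] <- cand[order(abs(cand - pv), cand)][1]
  }
  new_count_history(tree, assign_val, method = "parsimony", cost = total)
}

#' @rdname sankoff_counts
#' @param params A fitted [bd_params()] object.
#' @param root_policy,root_count Root prior; see [family_loglik()].
#' @export
ml_ancestral_counts <- function(counts, tree, params,
                                root_policy = c("uniform", "fixed"),
                                root_count = NULL, cmax = NULL) {
  root_policy <- match.arg(root_policy)
  obs <- leaf_count_vector(counts)
  tree <- as_chronogram(tree)
  if (!setequal(names(obs), tree$tip.label)) {
    abort("count names must match the tree's taxa")
  }
  obs <- obs[tree$tip.label]
  if (is.null(cmax)) cmax <- max(obs) + 20L
  if (cmax < max(obs)) abort("`cmax` is smaller than an observed count")
  S <- cmax + 1L
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  labs <- node_labels(tree)
  classes <- params_classes(params, tree)
  po <- ape::reorder.phylo(tree, "postorder")

  P <- vector("list", nnode) # transition matrix of the branch above each node
  for (i in seq_len(nrow(po$edge))) {
    ch <- po$edge[i, 2]
    cl <- classes[[labs[ch]]]
    P[[ch]] <- bd_prob_matrix_cpp(po$edge.length[i], params$lambda[cl],
                                  params$mu[cl], cmax)
  }

  up <- vector("list", nnode)
  for (i in seq_len(ntip)) {
    up[[i]] <- numeric(S)
    up[[i]][obs[i] + 1L] <- 1
  }
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]
    ch <- po$edge[i, 2]
    msg <- as.numeric(P[[ch]] %*% up[[ch]])
    up[[p]] <- if (is.null(up[[p]])) msg else up[[p]] * msg
    s <- max(up[[p]])
    if (s > 0) up[[p]] <- up[[p]] / s
  }

  root <- ntip + 1L
  prior <- if (root_policy == "fixed") {
    if (is.null(root_count)) abort("`root_count` required for fixed root policy")
    v <- numeric(S)
    v[root_count + 1L] <- 1
    v
  } else {
    c(0, rep(1 / cmax, cmax))
  }

  children <- split(po$edge[, 2], po$edge[, 1])
  assign_val <- integer(nnode)
  down <- vector("list", nnode)
  down[[root]] <- prior
  pre <- rev(seq_len(nrow(po$edge)))   # parents before children
  post_root <- prior * up[[root]]
  assign_val[root] <- which.max(post_root) - 1L
  for (i in pre) {
    p <- po$edge[i, 1]
    ch <- po$edge[i, 2]
    sibs <- setdiff(children[[as.character(p)]], ch)
    above <- down[[p]]
    for (w in sibs) above <- above * as.numeric(P[[w]] %*% up[[w]])
    msg <- as.numeric(crossprod(P[[ch]], above))
    s <- max(msg)
    if (s > 0) msg <- msg / s
    down[[ch]] <- msg
    post <- msg * up[[ch]]
    assign_val[ch] <- which.max(post) - 1L
  }
  new_count_history(tree, assign_val, method = "ml")
}

leaf_count_vector <- function(counts) {
  if (is.data.frame(counts)) {
    if (nrow(counts) != 1) abort("`counts` must be a single family")
    counts <- unlist(counts[, setdiff(names(counts), "family")])
  }
  if (!is_count(counts) || is.null(names(counts))) {
    abort("counts must be a named vector of non-negative integers")
  }
  storage.mode(counts) <- "integer"
  counts
}

new_count_history <- function(tree, values, method, cost = NA_real_) {
  labs <- node_labels(tree)
  ntip <- ape::Ntip(tree)
  parent_of <- rep(NA_integer_, length(labs))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  df <- tibble::tibble(
    node = labs,
    parent = ifelse(is.na(parent_of), NA_character_, labs[parent_of]),
    is_leaf = seq_along(labs) <= ntip,
    count = as.integer(values),
    delta = as.integer(values) -
      ifelse(is.na(parent_of), NA_integer_, as.integer(values[parent_of]))
  )
  structure(df, class = c("count_history", class(df)),
            method = method, cost = cost)
}

#' Net expansion within a branch set from a count history
#'
#' Sums the per-branch size changes of a reconstructed [count
#' history][sankoff_counts()] over a branch set: total increases
#' (expansions), total decreases (contractions) and their net.
#'
#' @param history A `count_history`.
#' @param branches A `branch_set` or character vector of branch ids;
#'   `NULL` means all branches.
#' @return A one-row tibble with `expansions`, `contractions`, `net`.
#' @export
branch_deltas <- function(history, branches = NULL) {
  stopifnot(inherits(history, "count_history"))
  d <- history$delta[!is.na(history$parent)]
  ids <- history$node[!is.na(history$parent)]
  if (!is.null(branches)) {
    bad <- setdiff(as.character(branches), ids)
    if (length(bad) > 0) {
      abort(paste0("branch ids not in history: ", paste(bad, collapse = ", ")))
    }
    d <- d[ids %in% as.character(branches)]
  }
  tibble::tibble(expansions = sum(pmax(d, 0)),
                 contractions = sum(pmax(-d, 0)),
                 net = sum(d))
}
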