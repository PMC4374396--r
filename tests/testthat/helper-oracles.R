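# Independent oracles used by the unit and acceptance tests. All are
# brute-force or closed-form implementations kept deliberately separate
# from the package's own algorithms.

# Transition probabilities via matrix exponential of the truncated
# birth-death generator (states 0..n).
oracle_bd_matrix <- function(t, lambda, mu, n = 200) {
  Q <- matrix(0, n + 1, n + 1)
  for (s in 1:n) {
    if (s < n) Q[s + 1, s + 2] <- lambda * s
    Q[s + 1, s] <- mu * s
    Q[s + 1, s + 1] <- -(lambda + mu) * s
  }
  as.matrix(Matrix::expm(Q * t))
}

# Family likelihood by exhaustive enumeration over all internal-node
# count assignments 0..cmax. Tiny trees only.
oracle_family_lik <- function(tree, counts, lambda, mu, cmax,
                              root_policy = "fixed", root_count = NULL) {
  bt <- branch_table(tree)
  tips <- bt$branch[bt$is_leaf]
  internals <- unique(c(setdiff(bt$parent, bt$branch), bt$branch[!bt$is_leaf]))
  root_lab <- setdiff(bt$parent, bt$branch)
  grid <- do.call(expand.grid, setNames(rep(list(0:cmax), length(internals)),
                                        internals))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    val <- c(as.list(grid[g, , drop = FALSE]), as.list(counts[tips]))
    if (root_policy == "fixed" && val[[root_lab]] != root_count) next
    p <- if (root_policy == "uniform") {
      if (val[[root_lab]] == 0) 0 else 1 / cmax
    } else {
      1
    }
    for (i in seq_len(nrow(bt))) {
      p <- p * transition_prob(val[[bt$parent[i]]], val[[bt$branch[i]]],
                               bt$length[i], lambda, mu)
    }
    total <- total + p
  }
  log(total)
}

# Exhaustive reconciliation search: enumerate all monotone mappings of
# gene internal nodes to species nodes and minimise duplications and
# losses separately. Returns the attainable minima.
oracle_reconcile_minima <- function(gt, st) {
  st <- as_chronogram(st)
  slabs <- famshift:::node_labels(st)
  nsp <- length(slabs)
  sparent <- rep(NA_integer_, nsp)
  sparent[st$edge[, 2]] <- st$edge[, 1]
  anc <- lapply(seq_len(nsp), function(nd) {
    out <- nd
    while (!is.na(sparent[out[length(out)]])) {
      out <- c(out, sparent[out[length(out)]])
    }
    out # nd ... root
  })
  is_anc <- function(a, d) a %in% anc[[d]] # a ancestor-or-equal of d
  lca2 <- function(a, b) {
    ca <- rev(anc[[a]]); cb <- rev(anc[[b]])
    m <- min(length(ca), length(cb))
    i <- which(ca[seq_len(m)] != cb[seq_len(m)])
    if (length(i) == 0) ca[m] else ca[i[1] - 1]
  }
  sp <- famshift:::gene_leaf_species(gt$tip.label)
  gn_tips <- ape::Ntip(gt)
  gn <- gn_tips + gt$Nnode
  M0 <- integer(gn)
  M0[seq_len(gn_tips)] <- match(sp, st$tip.label)
  po <- ape::reorder.phylo(gt, "postorder")
  kids <- split(po$edge[, 2], po$edge[, 1])
  internal_ids <- sort(unique(po$edge[, 1]))

  count_events <- function(M) {
    D <- 0L; L <- 0L
    dup <- logical(gn)
    for (u in internal_ids) {
      ch <- kids[[as.character(u)]]
      l <- lca2(M[ch[1]], M[ch[2]])
      dup[u] <- (M[u] %in% M[ch]) || (M[u] != l)
      D <- D + dup[u]
    }
    for (i in seq_len(nrow(po$edge))) {
      u <- po$edge[i, 1]; v <- po$edge[i, 2]
      d <- length(anc[[M[v]]]) - length(anc[[M[u]]]) # path edge count
      L <- L + d - 1L + dup[u]
    }
    c(D = D, L = L)
  }

  grid <- do.call(expand.grid, rep(list(seq_len(nsp)), length(internal_ids)))
  best_D <- Inf; best_L <- Inf
  for (g in seq_len(nrow(grid))) {
    M <- M0
    M[internal_ids] <- as.integer(grid[g, ])
    ok <- TRUE
    for (u in internal_ids) {
      for (v in kids[[as.character(u)]]) {
        if (!is_anc(M[u], M[v])) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (!ok) next
    ev <- count_events(M)
    best_D <- min(best_D, ev["D"])
    best_L <- min(best_L, ev["L"])
  }
  c(D = best_D, L = best_L)
}

# Wagner parsimony cost by exhaustive enumeration of ancestral states.
oracle_sankoff_cost <- function(tree, counts, cmax,
                                cost_dup = 1, cost_loss = 1) {
  bt <- branch_table(tree)
  internals <- unique(c(setdiff(bt$parent, bt$branch),
                        bt$branch[!bt$is_leaf]))
  grid <- do.call(expand.grid, setNames(rep(list(0:cmax), length(internals)),
                                        internals))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    val <- c(as.list(grid[g, , drop = FALSE]), as.list(counts))
    cost <- 0
    for (i in seq_len(nrow(bt))) {
      d <- val[[bt$branch[i]]] - val[[bt$parent[i]]]
      cost <- cost + if (d > 0) cost_dup * d else -cost_loss * d
    }
    best <- min(best, cost)
  }
  best
}

# A reusable small ultrametric 4-taxon tree.
tree4 <- function() read_chronogram("(((A:1,B:1):1,C:2):1,D:3);")
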