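#' Simulate gene ("guest") trees along a species chronogram
#'
#' Runs a linear birth-death process along the host phylogeny: starting
#' from `root_copies` gene lineages at the host root node, each live
#' lineage independently duplicates at rate `lambda` and dies at rate
#' `mu` (exponential waiting times) along every host branch, and splits
#' into both daughter branches at each host speciation. Every
#' duplication and loss is recorded with the host branch (child-node
#' label) and absolute time (Myr from the root) at which it occurred,
#' so clade-restricted event counts can be read straight off the log.
#' A family may go globally extinct; by default such replicates are
#' retained (no conditioning on survival).
#'
#' @param host A `chronogram`.
#' @param lambda,mu Duplication and loss rates (per gene per Myr,
#'   `>= 0`): either scalars, or named vectors giving a rate for every
#'   branch id of the host (for clade-restricted rate shifts).
#' @param seed Optional integer seed; the same seed reproduces the
#'   simulation bit-identically.
#' @param root_copies Number of independent starting lineages at the
#'   host root (default 1: a single ancestral gene).
#' @param condition_on_survival If `TRUE`, resimulate until at least
#'   one gene copy survives to the present. Off by default; switching
#'   it on shifts null distributions and is reported with a message.
#' @return A `guest_tree`: list with `nodes` (tibble: `node`, `parent`,
#'   `type` in root/speciation/duplication/loss/extant, `time`,
#'   `host_branch`, `species`), `events` (tibble: `event`, `branch`,
#'   `time`), the host leaf labels and branch ids, and the rates used.
#' @examples
#' tr <- read_chronogram("((A:1,B:1):1,C:2);")
#' gt <- simulate_guest(tr, lambda = 0.3, mu = 0.1, seed = 7)
#' leaf_counts(gt)
#' @export
simulate_guest <- function(host, lambda, mu, seed = NULL, root_copies = 1,
                           condition_on_survival = FALSE) {
  host <- as_chronogram(host)
  stopifnot(lambda >= 0, mu >= 0, root_copies >= 1)
  if (condition_on_survival) {
    inform("conditioning on at least one surviving copy (shifts null distributions)")
  }
  with_seed_if(seed, {
    repeat {
      gt <- sim_guest_once(host, lambda, mu, root_copies)
      if (!condition_on_survival || sum(gt$nodes$type == "extant") > 0) break
    }
    gt
  })
}

# Precomputed host-tree structures shared by every replicate of a
# simulation study.
guest_sim_ctx <- function(host) {
  host <- as_chronogram(host)
  labs <- node_labels(host)
  ntip <- ape::Ntip(host)
  nnode <- ntip + host$Nnode
  kids <- vector("list", nnode)
  for (i in seq_len(nrow(host$edge))) {
    p <- host$edge[i, 1]
    kids[[p]] <- c(kids[[p]], host$edge[i, 2])
  }
  list(labs = labs, times = ape::node.depth.edgelength(host),
       ntip = ntip, root = ntip + 1L, kids = kids,
       tip_labels = host$tip.label, branch_ids = labs[host$edge[, 2]])
}

expand_branch_rate <- function(r, ids, what) {
  if (length(r) == 1) return(setNames(rep(as.double(r), length(ids)), ids))
  if (is.null(names(r)) || !all(ids %in% names(r))) {
    abort(paste0("per-branch `", what, "` must name every branch"))
  }
  r[ids]
}

# One replicate, raw vectors only (no tibbles): the hot path of the
# Monte-Carlo null. Rates are per-branch vectors indexed by node
# number of the branch's child.
sim_guest_core <- function(ctx, lam_n, mu_n, root_copies) {
  n <- 0L
  node_parent <- integer(64); node_type <- character(64)
  node_time <- double(64); node_branch <- integer(64)
  add <- function(parent, type, time, branch) {
    n <<- n + 1L
    node_parent[n] <<- parent; node_type[n] <<- type
    node_time[n] <<- time; node_branch[n] <<- branch
    n
  }
  times <- ctx$times
  ntip <- ctx$ntip
  kids <- ctx$kids
  descend <- function(parent_id, host_child, t0) {
    t_end <- times[host_child]
    lam <- lam_n[host_child]
    m <- mu_n[host_child]
    rate <- lam + m
    if (rate > 0) {
      w <- rexp(1, rate)
      if (t0 + w < t_end) {
        t <- t0 + w
        if (runif(1) < lam / rate) {
          nid <- add(parent_id, "duplication", t, host_child)
          descend(nid, host_child, t)
          descend(nid, host_child, t)
        } else {
          add(parent_id, "loss", t, host_child)
        }
        return(invisible(NULL))
      }
    }
    if (host_child <= ntip) {
      add(parent_id, "extant", t_end, host_child)
    } else {
      nid <- add(parent_id, "speciation", t_end, host_child)
      for (g in kids[[host_child]]) descend(nid, g, t_end)
    }
    invisible(NULL)
  }
  for (k in seq_len(root_copies)) {
    rid <- add(NA_integer_, "root", 0, NA_integer_)
    for (g in kids[[ctx$root]]) descend(rid, g, 0)
  }
  idx <- seq_len(n)
  list(parent = node_parent[idx], type = node_type[idx],
       time = node_time[idx], branch = node_branch[idx])
}

sim_guest_once <- function(host, lambda, mu, root_copies, ctx = NULL) {
  if (is.null(ctx)) ctx <- guest_sim_ctx(host)
  ids <- ctx$labs[-ctx$root]
  lam_n <- mu_n <- rep(0, length(ctx$labs))
  lam_n[match(ids, ctx$labs)] <-
    expand_branch_rate(lambda, ids, "lambda")[ids]
  mu_n[match(ids, ctx$labs)] <- expand_branch_rate(mu, ids, "mu")[ids]
  raw <- sim_guest_core(ctx, lam_n, mu_n, root_copies)

  branch_lab <- ifelse(is.na(raw$branch), NA_character_,
                       ctx$labs[raw$branch])
  nodes <- tibble::tibble(
    node = seq_along(raw$type), parent = raw$parent, type = raw$type,
    time = raw$time, host_branch = branch_lab,
    species = ifelse(raw$type == "extant", branch_lab, NA_character_)
  )
  keep <- raw$type %in% c("duplication", "loss")
  events <- tibble::tibble(
    event = raw$type[keep], branch = branch_lab[keep], time = raw$time[keep]
  )
  structure(list(nodes = nodes, events = events,
                 host_leaves = ctx$tip_labels,
                 host_branches = unique(ctx$branch_ids),
                 lambda = lambda, mu = mu),
            class = "guest_tree")
}

#' @export
print.guest_tree <- function(x, ...) {
  cat("<guest_tree> ", sum(x$nodes$type == "extant"), " extant copies, ",
      sum(x$events$event == "duplication"), " duplications, ",
      sum(x$events$event == "loss"), " losses\n", sep = "")
  invisible(x)
}

#' @rdname simulate_guest
#' @param gt A `guest_tree`.
#' @return For [leaf_counts()], a tibble (`species`, `n`) of extant
#'   copies per host leaf, zeros included.
#' @export
leaf_counts <- function(gt) {
  stopifnot(inherits(gt, "guest_tree"))
  ext <- gt$nodes$species[gt$nodes$type == "extant"]
  tibble::tibble(
    species = gt$host_leaves,
    n = as.integer(vapply(gt$host_leaves, function(s) sum(ext == s),
                          numeric(1)))
  )
}

#' Duplication/loss totals within a branch set
#'
#' Counts the logged events that fall on a designated set of host
#' branches, and the net expansion `k = D - L`.
#'
#' @param x A `guest_tree`, a [reconciliation][lca_reconcile], or an
#'   event tibble with columns `event` and `branch`.
#' @param branches A `branch_set` or character vector of branch ids.
#' @return A one-row tibble with `D`, `L`, `k`.
#' @export
clade_event_summary <- function(x, branches) {
  if (inherits(x, "reconciliation")) return(clade_summary(x, branches))
  events <- if (inherits(x, "guest_tree")) {
    bad <- setdiff(as.character(branches), x$host_branches)
    if (length(bad) > 0) {
      abort(paste0("branch ids not in host tree: ", paste(bad, collapse = ", ")))
    }
    x$events
  } else {
    stopifnot(is.data.frame(x), all(c("event", "branch") %in% names(x)))
    x
  }
  inside <- events$branch %in% as.character(branches)
  D <- sum(inside & events$event == "duplication")
  L <- sum(inside & events$event == "loss")
  tibble::tibble(D = D, L = L, k = D - L)
}

#' Prune a guest tree to its surviving gene tree
#'
#' Drops extinct lineages and suppresses the resulting single-child
#' nodes, yielding the gene tree an observer of present-day genomes
#' would reconstruct (leaf labels `"Species|g<id>"`). Useful for
#' feeding simulated families to [lca_reconcile()]. When the
#' simulation started from several ancestral copies, the surviving
#' root lineages are joined by basal splits at the host root — the
#' ancient duplications that produced the ancestral complement.
#'
#' @param gt A `guest_tree`.
#' @return A rooted binary [ape::phylo], or `NULL` when fewer than two
#'   copies survive.
#' @export
guest_to_gene_tree <- function(gt) {
  stopifnot(inherits(gt, "guest_tree"))
  nodes <- gt$nodes
  if (sum(nodes$type == "extant") < 2) return(NULL)
  kids <- split(nodes$node, factor(nodes$parent, levels = nodes$node))
  alive <- logical(nrow(nodes))
  mark <- function(i) {
    ch <- kids[[as.character(nodes$node[i])]]
    alive[i] <<- nodes$type[i] == "extant" ||
      (length(ch) > 0 && any(vapply(ch, mark, logical(1))))
    alive[i]
  }
  build <- function(i) {
    if (nodes$type[i] == "extant") {
      return(paste0(nodes$species[i], "|g", nodes$node[i]))
    }
    ch <- kids[[as.character(nodes$node[i])]]
    ch <- ch[alive[ch]]
    parts <- vapply(ch, build, character(1))
    if (length(parts) == 1) parts else paste0("(", paste(parts, collapse = ","), ")")
  }
  roots <- nodes$node[is.na(nodes$parent)]
  for (r in roots) mark(r)
  roots <- roots[alive[match(roots, nodes$node)]]
  parts <- vapply(roots, build, character(1))
  txt <- parts[1]
  for (p in parts[-1]) txt <- paste0("(", txt, ",", p, ")")
  ape::read.tree(text = paste0(txt, ";"))
}
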