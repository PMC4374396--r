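#' Synthetic chronograms and count matrices with known ground truth
#'
#' Generators for the inputs the pipeline consumes, so every analysis
#' stage can be exercised — and power/calibration studies run — without
#' any external data. [yule_tree()] draws a pure-birth (Yule) tree
#' conditioned on the number of tips and rescales it to a requested
#' depth; [simulate_count_matrix()] evolves family copy numbers down a
#' chronogram under the linear birth-death model, with an optional
#' clade-restricted rate shift, recording the true rates alongside the
#' data. Both are pure functions of their seed.
#'
#' @param n_taxa Number of leaves (`>= 2`).
#' @param depth Tree depth in Myr.
#' @param seed Optional integer seed.
#' @return For [yule_tree()], a `chronogram`.
#' @examples
#' tr <- yule_tree(6, depth = 300, seed = 1)
#' sim <- simulate_count_matrix(tr, n_families = 5, lambda = 1e-3,
#'                              seed = 2)
#' sim$counts
#' @export
yule_tree <- function(n_taxa, depth, seed = NULL) {
  stopifnot(n_taxa >= 2, depth > 0)
  tr <- with_seed_if(seed, ape::rphylo(n_taxa, birth = 1, death = 0))
  d <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * depth / d
  tr$tip.label <- paste0("t", seq_len(n_taxa))
  as_chronogram(tr)
}

#' @rdname yule_tree
#' @param tree A `chronogram` to evolve counts on.
#' @param n_families Number of independent families (`>= 1`).
#' @param lambda,mu Background duplication/loss rates (per gene per
#'   Myr); `mu` defaults to `lambda` (tied).
#' @param branches Optional focal `branch_set` receiving shifted rates.
#' @param shift_lambda,shift_mu Multipliers applied to the focal
#'   branches' rates (default 1 = no shift).
#' @param root_prior Root copy number prior: a length-2 integer range
#'   `c(lo, hi)` sampled uniformly (default `c(5, 15)`, the size range
#'   of well-populated transporter-like families), or a single fixed
#'   count.
#' @return For [simulate_count_matrix()], a list with `counts` (a count
#'   table, families x species), `root_counts`, and `truth` (tibble of
#'   per-class true rates).
#' @export
simulate_count_matrix <- function(tree, n_families, lambda, mu = lambda,
                                  branches = NULL, shift_lambda = 1,
                                  shift_mu = shift_lambda,
                                  root_prior = c(5L, 15L), seed = NULL) {
  stopifnot(n_families >= 1, lambda >= 0, mu >= 0,
            shift_lambda > 0, shift_mu > 0)
  tree <- as_chronogram(tree)
  lam <- c(lambda, lambda * shift_lambda)
  m <- c(mu, mu * shift_mu)
  params <- if (is.null(branches)) {
    bd_params(lambda, mu)
  } else {
    bd_params(lam, m, tree = tree, branches = branches)
  }
  counts <- with_seed_if(seed, {
    sim_counts_params(tree, params, n_families, root_prior = root_prior)
  })
  classes <- params_classes(params, tree)
  truth <- tibble::tibble(
    class = seq_along(params$lambda),
    lambda = params$lambda, mu = params$mu,
    n_branches = as.integer(table(factor(classes,
                                         levels = seq_along(params$lambda))))
  )
  list(counts = counts, root_counts = attr(counts, "root_counts"),
       truth = truth, params = params)
}

# Evolve `n_families` root-to-tip under `params` using the exact
# branch transition probabilities; uses the current RNG stream.
sim_counts_params <- function(tree, params, n_families,
                              root_prior = c(5L, 15L)) {
  tree <- as_chronogram(tree)
  classes <- params_classes(params, tree)
  labs <- node_labels(tree)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L

  roots <- if (length(root_prior) == 1) {
    rep(as.integer(root_prior), n_families)
  } else {
    sample(seq.int(root_prior[1], root_prior[2]), n_families, replace = TRUE)
  }

  cmax <- max(4L * max(roots) + 40L, 60L)
  po <- ape::reorder.phylo(tree, "postorder")
  pre <- rev(seq_len(nrow(po$edge)))
  state <- matrix(0L, nrow = ntip + tree$Nnode, ncol = n_families)
  state[root, ] <- roots

  repeat {
    hit_cap <- FALSE
    Pcache <- new.env(parent = emptyenv())
    for (i in pre) {
      p <- po$edge[i, 1]
      ch <- po$edge[i, 2]
      cl <- classes[[labs[ch]]]
      key <- paste0(cl, "|", format(po$edge.length[i], digits = 17))
      P <- Pcache[[key]]
      if (is.null(P)) {
        P <- bd_prob_matrix_cpp(po$edge.length[i], params$lambda[cl],
                                params$mu[cl], cmax)
        Pcache[[key]] <- P
      }
      for (s in unique(state[p, ])) {
        idx <- which(state[p, ] == s)
        state[ch, idx] <- sample.int(cmax + 1L, length(idx),
                                     replace = TRUE, prob = P[s + 1L, ]) - 1L
      }
    }
    if (max(state) < cmax) break
    cmax <- cmax * 2L   # truncation was reached; redo with more room
    hit_cap <- TRUE
  }

  counts <- t(state[seq_len(ntip), , drop = FALSE])
  colnames(counts) <- tree$tip.label
  out <- as_count_table(data.frame(family = paste0("fam", seq_len(n_families)),
                                   counts, check.names = FALSE))
  attr(out, "root_counts") <- roots
  out
}
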