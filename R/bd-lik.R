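#' Birth-death model parameters
#'
#' Bundles per-class duplication (`lambda`) and loss (`mu`) rates with a
#' branch-to-class map. Class 1 is the background; class 2 (if present)
#' is a focal branch set, typically built with [mrca_branches()]. With
#' `mu` omitted the model is "tied" (`lambda == mu` within each class),
#' the convention of single-rate gene family birth-death fits.
#'
#' @param lambda,mu Numeric vectors, one rate per class (per gene per
#'   Myr, in `[0, 10]`). `mu` defaults to `lambda` (tied model).
#' @param tree Optional `chronogram`; required when `branches` is given.
#' @param branches Optional `branch_set` receiving class-2 rates.
#' @return A `bd_params` object.
#' @export
bd_params <- function(lambda, mu = lambda, tree = NULL, branches = NULL) {
  tied <- missing(mu)
  if (length(mu) != length(lambda)) abort("`lambda` and `mu` must have one rate per class")
  if (any(lambda < 0) || any(mu < 0) || any(lambda > 10) || any(mu > 10)) {
    abort("rates must lie in [0, 10] per gene per Myr")
  }
  n_class <- length(lambda)
  classes <- NULL
  if (!is.null(branches)) {
    if (is.null(tree)) abort("`tree` is required when `branches` is given")
    if (n_class != 2) abort("a focal branch set requires exactly 2 rate classes")
    classes <- branch_classes(tree, branches)
  } else if (n_class != 1) {
    abort("more than one rate class requires `branches`")
  }
  structure(list(lambda = as.double(lambda), mu = as.double(mu),
                 classes = classes, tied = tied),
            class = "bd_params")
}

#' @export
print.bd_params <- function(x, ...) {
  k <- length(x$lambda)
  cat("<bd_params> ", k, if (k == 1) " class" else " classes",
      if (x$tied) " (tied lambda = mu)" else "", "\n", sep = "")
  for (i in seq_len(k)) {
    cat(sprintf("  class %d: lambda = %.6g, mu = %.6g\n", i,
                x$lambda[i], x$mu[i]))
  }
  invisible(x)
}

# class index per branch id for a params object on a given tree.
params_classes <- function(params, tree) {
  if (!is.null(params$classes)) return(params$classes)
  branch_classes(tree, NULL)
}

# ---------------------------------------------------------------------------
# Pruning likelihood
#
# Standard Felsenstein pruning over copy-number states 0..cmax, run for
# all families at once (state x family matrices). Tip messages are
# column gathers from the branch transition matrix; internal messages
# are dense matrix products. Columns are rescaled at every step and the
# log scale accumulated per family, so likelihoods never underflow.

# Precompute everything that does not depend on the rates.
bd_lik_context <- function(M, tree, cmax) {
  tree <- as_chronogram(tree)
  if (!isTRUE(attr(tree, "ultrametric"))) {
    abort("birth-death likelihood requires an ultrametric (dated) tree")
  }
  if (is.null(colnames(M)) || !setequal(colnames(M), tree$tip.label)) {
    abort("count columns must match the tree's taxa")
  }
  M <- M[, tree$tip.label, drop = FALSE]
  maxobs <- max(M)
  if (is.null(cmax)) cmax <- maxobs + 20L
  if (cmax < maxobs) abort("`cmax` is smaller than an observed count")
  po <- ape::reorder.phylo(tree, "postorder")
  labs <- node_labels(tree)
  list(tree = tree, M = M, cmax = as.integer(cmax),
       ntip = ape::Ntip(tree), root = ape::Ntip(tree) + 1L,
       edge = po$edge, edge_len = po$edge.length,
       branch_ids = labs[po$edge[, 2]])
}

# Per-family log-likelihood vector for given per-class rates.
# `classes` maps branch id -> class index; `root_policy` handles the
# unobserved root count.
bd_loglik_ctx <- function(ctx, lambda, mu, classes,
                          root_policy = "uniform", root_count = NULL) {
  S <- ctx$cmax + 1L
  nf <- nrow(ctx$M)
  cache <- new.env(parent = emptyenv())
  getP <- function(len, cl) {
    key <- paste0(cl, "|", format(len, digits = 17))
    P <- cache[[key]]
    if (is.null(P)) {
      P <- bd_prob_matrix_cpp(len, lambda[cl], mu[cl], ctx$cmax)
      cache[[key]] <- P
    }
    P
  }
  prune <- function(M) {
    nfam <- nrow(M)
    part <- vector("list", ctx$ntip + ctx$tree$Nnode)
    logscale <- numeric(nfam)
    for (i in seq_len(nrow(ctx$edge))) {
      p <- ctx$edge[i, 1]
      ch <- ctx$edge[i, 2]
      P <- getP(ctx$edge_len[i], classes[[ctx$branch_ids[i]]])
      msg <- if (ch <= ctx$ntip) {
        P[, M[, ch] + 1L, drop = FALSE]
      } else {
        P %*% part[[ch]]
      }
      part[ch] <- list(NULL)
      part[[p]] <- if (is.null(part[[p]])) msg else part[[p]] * msg
      if (i %% 4L == 0L) {
        sc <- colSums(part[[p]])
        sc[sc <= 0] <- 1
        part[[p]] <- part[[p]] / rep(sc, each = nrow(part[[p]]))
        logscale <- logscale + log(sc)
      }
    }
    list(R = part[[ctx$root]], logscale = logscale)
  }
  pr <- prune(ctx$M)
  R <- pr$R
  lik <- switch(root_policy,
    uniform = colMeans(R[-1L, , drop = FALSE]),
    fixed = {
      if (is.null(root_count)) abort("`root_count` required for fixed root policy")
      R[root_count + 1L, ]
    },
    uniform_surviving = {
      zero <- matrix(0L, 1, ctx$ntip)
      pz <- prune(zero)
      surv <- 1 - pz$R[-1L, 1] * exp(pz$logscale)
      colMeans(R[-1L, , drop = FALSE]) / mean(surv)
    },
    abort("unknown root policy")
  )
  log(lik) + pr$logscale
}

#' Log-likelihood of one family's counts under a birth-death model
#'
#' Computes the probability of the observed leaf copy numbers given the
#' chronogram and per-branch duplication/loss rates, by pruning over a
#' truncated state space `0..cmax`. The unobserved root count is
#' handled by `root_policy`:
#' * `"uniform"` (default): uniform prior on `1..cmax` — the family is
#'   assumed anciently present;
#' * `"fixed"`: condition on `root_count` copies at the root;
#' * `"uniform_surviving"`: uniform prior on `1..cmax`, conditioned on
#'   at least one copy surviving somewhere in the tree.
#'
#' @param counts A named vector of copy numbers (names = taxa), or a
#'   one-row count table (see [read_counts()]).
#' @param tree An ultrametric `chronogram`.
#' @param params A [bd_params()] object.
#' @param root_policy One of `"uniform"`, `"fixed"`,
#'   `"uniform_surviving"`.
#' @param root_count Root copy number for `root_policy = "fixed"`.
#' @param cmax State-space truncation; default max observed count + 20.
#' @return The log-likelihood (scalar).
#' @examples
#' tr <- read_chronogram("(A:1,B:1);")
#' p <- bd_params(0.5)
#' family_loglik(c(A = 1, B = 1), tr, p, root_policy = "fixed",
#'               root_count = 1)
#' @export
family_loglik <- function(counts, tree, params,
                          root_policy = c("uniform", "fixed",
                                          "uniform_surviving"),
                          root_count = NULL, cmax = NULL) {
  root_policy <- match.arg(root_policy)
  if (is.data.frame(counts)) {
    if (nrow(counts) != 1) abort("`counts` must be a single family")
    counts <- unlist(counts[, setdiff(names(counts), "family")])
  }
  if (!is_count(counts)) abort("counts must be non-negative integers")
  M <- matrix(as.integer(counts), nrow = 1,
              dimnames = list(NULL, names(counts)))
  ctx <- bd_lik_context(M, tree, cmax)
  classes <- params_classes(params, ctx$tree)
  as.numeric(bd_loglik_ctx(ctx, params$lambda, params$mu, classes,
                           root_policy, root_count))
}
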