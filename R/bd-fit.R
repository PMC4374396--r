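#' Fit birth-death models of gene copy-number evolution
#'
#' Maximum-likelihood estimation of duplication/loss rates on a dated
#' species tree, summed over gene families. Four nested model
#' structures are available:
#'
#' * `"single_lambda"` — one tied rate (`lambda == mu`) for the whole
#'   tree (1 parameter);
#' * `"multi_lambda"` — tied rates, but a separate rate on a focal
#'   branch set (2 parameters);
#' * `"single_lambda_mu"` — global `lambda` and `mu` allowed to differ
#'   (2 parameters);
#' * `"multi_lambda_mu"` — `lambda` and `mu` both shifting on the focal
#'   branch set (4 parameters).
#'
#' Optimisation is bounded (`[1e-10, 10]` per gene per Myr) on the log
#' scale, with multiple starts: a warm start from the simpler tied fit,
#' a deterministic start at `1e-3`, and seeded log-uniform random
#' starts. The warm start guarantees that a richer model never scores
#' below the nested one beyond optimiser noise.
#'
#' @param counts A count table (see [read_counts()]) with one row per
#'   family, or anything [as_count_table()] accepts.
#' @param tree An ultrametric `chronogram`.
#' @param model Model structure (see above).
#' @param branches `branch_set` of focal branches; required for the
#'   `multi_*` models. The conventional focal set is the MRCA subtree
#'   plus its stem ([mrca_branches()] with `include_stem = TRUE`).
#' @param root_policy,root_count,cmax Passed to the likelihood; see
#'   [family_loglik()].
#' @param n_starts Number of optimiser starts (default 5).
#' @param seed Integer seed for the random starts.
#' @param init Optional rate vector (recycled across the model's
#'   parameters) used as the warm start instead of an internal tied
#'   fit — e.g. rates from an already-fitted nested model. Saves one
#'   one-dimensional optimisation in refit loops.
#' @return A `bd_fit` object with elements `params` ([bd_params()]),
#'   `lnL`, `n_params`, `logliks` (per family), `convergence` (one row
#'   per start) and bookkeeping fields. Supports [tidy()], [glance()].
#' @export
fit_bd <- function(counts, tree, model = c("single_lambda", "multi_lambda",
                                           "single_lambda_mu",
                                           "multi_lambda_mu"),
                   branches = NULL, root_policy = "uniform",
                   root_count = NULL, cmax = NULL, n_starts = 5, seed = 1,
                   init = NULL) {
  model <- match.arg(model)
  counts <- as_count_table(counts)
  tree <- as_chronogram(tree)
  validate_counts(counts, tree)
  M <- counts_matrix(counts, tree$tip.label)
  ctx <- bd_lik_context(M, tree, cmax)

  multi <- model %in% c("multi_lambda", "multi_lambda_mu")
  tied <- model %in% c("single_lambda", "multi_lambda")
  if (multi && is.null(branches)) abort("`branches` is required for multi-class models")
  classes <- branch_classes(tree, if (multi) branches else NULL)
  n_class <- if (multi) 2L else 1L
  npar <- n_class * (if (tied) 1L else 2L)

  lb <- log(1e-10)
  ub <- log(10)
  unpack <- function(theta) {
    theta <- pmin(pmax(theta, lb), ub)
    r <- exp(theta)
    if (tied) list(lambda = r, mu = r)
    else list(lambda = r[seq_len(n_class)], mu = r[-seq_len(n_class)])
  }
  nll <- function(theta) {
    pr <- unpack(theta)
    v <- -sum(bd_loglik_ctx(ctx, pr$lambda, pr$mu, classes,
                            root_policy, root_count))
    if (!is.finite(v)) 1e12 else v
  }

  # Warm start: quick one-dimensional tied fit, replicated across
  # parameters. For the single tied model this IS the fit.
  warm <- NULL
  if (npar > 1L && !is.null(init)) {
    warm <- log(pmin(pmax(rep_len(as.double(init), npar), 1e-10), 10))
  } else {
    nll1 <- function(th) nll(rep(th, npar))
    o1 <- optimize(nll1, interval = c(lb, ub), tol = 1e-7)
    # polish near the boundary, where Brent's interior search stops short
    if (nll1(lb) < o1$objective) o1 <- list(minimum = lb, objective = nll1(lb))
    warm <- rep(o1$minimum, npar)
  }

  conv <- tibble::tibble(start = integer(), objective = double(),
                         convergence = integer())
  if (npar == 1L) {
    best <- list(par = o1$minimum, value = o1$objective, convergence = 0L)
    conv <- tibble::add_row(conv, start = 1L, objective = o1$objective,
                            convergence = 0L)
  } else {
    starts <- with_seed_if(seed, {
      rand <- matrix(runif(max(n_starts - 2, 0) * npar,
                           log(1e-6), log(1e-1)), ncol = npar)
      head(rbind(warm, rep(log(1e-3), npar), rand), max(n_starts, 1))
    })
    best <- NULL
    for (k in seq_len(nrow(starts))) {
      # Nelder-Mead on the log scale: derivative-free, robust on the
      # flat shoulders near the rate bounds; bounds enforced by
      # clamping inside the objective
      o <- optim(starts[k, ], nll, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-9))
      conv <- tibble::add_row(conv, start = k, objective = o$value,
                              convergence = as.integer(o$convergence))
      if (is.null(best) || o$value < best$value) best <- o
    }
  }

  pr <- unpack(best$par)
  params <- bd_params(pr$lambda, pr$mu,
                      tree = if (multi) tree else NULL,
                      branches = if (multi) branches else NULL)
  params$tied <- tied
  lnL <- -best$value
  converged <- any(conv$convergence == 0L)
  if (!converged) warn("no optimiser start converged; best objective returned")

  structure(list(model = model, params = params, lnL = lnL,
                 n_params = npar,
                 logliks = as.numeric(bd_loglik_ctx(
                   ctx, pr$lambda, pr$mu, classes, root_policy, root_count)),
                 convergence = conv, converged = converged,
                 cmax = ctx$cmax, root_policy = root_policy,
                 root_count = root_count,
                 n_families = nrow(M), families = rownames(M),
                 branches = if (multi) branches else NULL,
                 tree = tree),
            class = "bd_fit")
}

#' @export
print.bd_fit <- function(x, ...) {
  cat("<bd_fit> model = ", x$model, ", ", x$n_families, " families\n",
      sep = "")
  print(x$params)
  cat(sprintf("  lnL = %.4f  (%d parameters, AIC = %.2f)\n",
              x$lnL, x$n_params, aic_score(x$lnL, x$n_params)))
  invisible(x)
}

#' Likelihood-ratio statistic for nested fits
#'
#' `LR = 2 (lnL_alt - lnL_null)`. Tiny negative values from optimiser
#' noise are clamped to zero; a negative value beyond `-1e-6` raises a
#' warning (the models are then probably not nested or not fitted on
#' the same data).
#'
#' @param lnL_null,lnL_alt Log-likelihoods of the nested and richer
#'   model.
#' @return The LR statistic (`>= 0`).
#' @examples
#' lrt_statistic(-34.31, -34.28)
#' @export
lrt_statistic <- function(lnL_null, lnL_alt) {
  lr <- 2 * (lnL_alt - lnL_null)
  if (any(lr < -1e-6)) warn("likelihood ratio substantially negative; check model nesting")
  pmax(lr, 0)
}

#' @rdname lrt_statistic
#' @param lr LR statistic (`>= 0`).
#' @param df Degrees of freedom (difference in parameter count).
#' @return For [chisq_pvalue()], the upper-tail chi-square probability.
#' @export
chisq_pvalue <- function(lr, df) {
  if (any(lr < 0)) abort("`lr` must be non-negative")
  if (any(df < 1)) abort("`df` must be at least 1")
  pchisq(lr, df = df, lower.tail = FALSE)
}

#' Compare two nested birth-death fits
#'
#' @param fit_null,fit_alt `bd_fit` objects fitted on the same data;
#'   `fit_alt` must have more parameters.
#' @return An `lrt_result` with the LR statistic, `df` and the
#'   chi-square p-value. Supports [tidy()]/[glance()].
#' @export
lr_test <- function(fit_null, fit_alt) {
  stopifnot(inherits(fit_null, "bd_fit"), inherits(fit_alt, "bd_fit"))
  if (fit_null$n_families != fit_alt$n_families) {
    abort("fits must be on identical data")
  }
  df <- fit_alt$n_params - fit_null$n_params
  if (df <= 0) abort("`fit_alt` must have more parameters than `fit_null`")
  lr <- lrt_statistic(fit_null$lnL, fit_alt$lnL)
  structure(list(lr = lr, df = df, p_chisq = chisq_pvalue(lr, df),
                 p_simulated = NULL, n_null_reps = 0L,
                 null_model = fit_null$model, alt_model = fit_alt$model),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("<lrt_result> %s vs %s: LR = %.2f, df = %d, p[chisq] = %.3g",
              x$null_model, x$alt_model, x$lr, x$df, x$p_chisq))
  if (!is.null(x$p_simulated)) {
    cat(sprintf(", p[simulated] = %.3g (N = %d)", x$p_simulated,
                x$n_null_reps))
  }
  cat("\n")
  invisible(x)
}

#' Simulated null distribution for a likelihood-ratio test
#'
#' Parametric bootstrap of the LR statistic: families are simulated
#' under the fitted null model, both models are refitted on each
#' replicate, and the empirical p-value is
#' `(1 + #\{LR_sim >= LR_obs\}) / (reps + 1)`. Replicates whose refit
#' fails are dropped and logged; more than 5% drops aborts the run.
#'
#' @param fit_null,fit_alt `bd_fit` objects for the observed data.
#' @param reps Number of null replicates (`>= 100`).
#' @param seed Integer seed.
#' @param n_starts Optimiser starts per refit (smaller than the
#'   top-level default, since refits start near the truth).
#' @return The `lrt_result` from [lr_test()] augmented with
#'   `p_simulated`, `n_null_reps` and the vector `lr_null`.
#' @export
simulated_null_lrt <- function(fit_null, fit_alt, reps = 1000, seed = 1,
                               n_starts = 2) {
  if (reps < 100) abort("`reps` must be at least 100")
  res <- lr_test(fit_null, fit_alt)
  tree <- fit_null$tree
  lr_sim <- with_seed_if(seed, {
    out <- rep(NA_real_, reps)
    for (r in seq_len(reps)) {
      root_prior <- if (fit_null$root_policy == "fixed") {
        fit_null$root_count
      } else {
        c(1L, fit_null$cmax)  # matches the uniform root prior of the fit
      }
      sim <- sim_counts_params(tree, fit_null$params,
                               n_families = fit_null$n_families,
                               root_prior = root_prior)
      truth <- if (fit_null$params$tied) fit_null$params$lambda
               else c(fit_null$params$lambda, fit_null$params$mu)
      out[r] <- tryCatch({
        f0 <- fit_bd(sim, tree, model = fit_null$model,
                     branches = fit_null$branches,
                     root_policy = fit_null$root_policy,
                     root_count = fit_null$root_count,
                     n_starts = n_starts, seed = seed + r, init = truth)
        f1 <- fit_bd(sim, tree, model = fit_alt$model,
                     branches = fit_alt$branches,
                     root_policy = fit_alt$root_policy,
                     root_count = fit_alt$root_count,
                     n_starts = n_starts, seed = seed + r, init = truth)
        lrt_statistic(f0$lnL, f1$lnL)
      }, error = function(e) NA_real_)
    }
    out
  })
  dropped <- sum(is.na(lr_sim))
  if (dropped > 0) {
    inform(paste0(dropped, " replicate(s) dropped after refit failure"))
    if (dropped > 0.05 * reps) abort("more than 5% of null replicates failed")
  }
  lr_sim <- lr_sim[!is.na(lr_sim)]
  res$p_simulated <- empirical_pvalue(lr_sim, res$lr, tail = "upper")
  res$n_null_reps <- length(lr_sim)
  res$lr_null <- lr_sim
  res
}

#' Fold change between focal and background rates
#'
#' @param rate_focal,rate_background Positive rates.
#' @return `rate_focal / rate_background`.
#' @examples
#' round(fold_change(2.5049e-3, 0.7307e-3), 2)
#' @export
fold_change <- function(rate_focal, rate_background) {
  if (any(rate_background <= 0)) abort("background rate must be positive")
  rate_focal / rate_background
}

#' Akaike information criterion from a log-likelihood
#'
#' @param lnL Log-likelihood.
#' @param n_params Number of free parameters.
#' @return `2 * n_params - 2 * lnL`; lower is preferred.
#' @export
aic_score <- function(lnL, n_params) 2 * n_params - 2 * lnL
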