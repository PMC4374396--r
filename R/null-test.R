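#' Empirical p-value with the plus-one correction
#'
#' `p = (1 + #\{sim at least as extreme as obs\}) / (N + 1)` — the
#' permutation-style estimator, which can never report an impossible
#' zero. "At least as extreme" is `>=` for `tail = "upper"` and `<=`
#' for `tail = "lower"`.
#'
#' @param sims Numeric vector of null replicate statistics (non-empty).
#' @param obs Observed statistic.
#' @param tail `"upper"` or `"lower"`.
#' @return The empirical p-value in `(0, 1]`.
#' @examples
#' empirical_pvalue(c(5, 6, 7), 6, tail = "upper")
#' @export
empirical_pvalue <- function(sims, obs, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  if (length(sims) == 0) abort("`sims` must be non-empty")
  hits <- if (tail == "upper") sum(sims >= obs) else sum(sims <= obs)
  (1 + hits) / (length(sims) + 1)
}

#' Simulation null test for clade-specific expansion
#'
#' The headline test: are the duplications, losses and net expansion
#' (`k = D - L`) observed in a focal clade compatible with a neutral
#' birth-death process? `N` guest trees are simulated along the host
#' chronogram ([simulate_guest()]), each replicate's events are counted
#' within the branch set, and one-sided empirical p-values
#' ([empirical_pvalue()]) are computed for the observed values:
#' duplications and net expansion upper-tailed, losses in both tails
#' (an expansion can arise from more duplications or from fewer
#' losses, and the two explanations are reported separately).
#'
#' The rates should come from a fitted neutral model — conventionally
#' the single tied-rate fit ([fit_bd()] with `model = "single_lambda"`).
#'
#' @param host A `chronogram`.
#' @param lambda,mu Null duplication/loss rates (per gene per Myr).
#' @param branches Focal `branch_set` (e.g. [mrca_branches()]).
#' @param observed Observed clade statistics: a one-row tibble or named
#'   vector with `D`, `L`, `k` (from [clade_summary()] or
#'   [clade_event_summary()]).
#' @param N Number of replicates (`>= 100`; 1000 is customary).
#' @param seed Integer seed; the same seed reproduces every replicate.
#' @param root_copies,condition_on_survival Passed to
#'   [simulate_guest()].
#' @return A `null_distribution`: list with `replicates` (tibble `rep`,
#'   `D`, `L`, `k`), `observed`, `pvalues` (tibble `statistic`, `tail`,
#'   `p`), `N`, `seed` and the rates used. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @export
run_null_test <- function(host, lambda, mu, branches, observed, N = 1000,
                          seed = NULL, root_copies = 1,
                          condition_on_survival = FALSE) {
  if (N < 100) abort("`N` must be at least 100")
  host <- as_chronogram(host)
  obs <- as.list(observed)
  if (!all(c("D", "L", "k") %in% names(obs))) {
    abort("`observed` must provide D, L and k")
  }
  ctx <- guest_sim_ctx(host)
  ids <- ctx$labs[-ctx$root]
  bad <- setdiff(as.character(branches), ids)
  if (length(bad) > 0) {
    abort(paste0("branch ids not in host tree: ", paste(bad, collapse = ", ")))
  }
  lam_n <- mu_n <- rep(0, length(ctx$labs))
  lam_n[match(ids, ctx$labs)] <- expand_branch_rate(lambda, ids, "lambda")[ids]
  mu_n[match(ids, ctx$labs)] <- expand_branch_rate(mu, ids, "mu")[ids]
  inside <- ctx$labs %in% as.character(branches)
  reps <- with_seed_if(seed, {
    out <- matrix(0L, N, 3, dimnames = list(NULL, c("D", "L", "k")))
    for (r in seq_len(N)) {
      raw <- sim_guest_core(ctx, lam_n, mu_n, root_copies)
      if (condition_on_survival) {
        while (!any(raw$type == "extant")) {
          raw <- sim_guest_core(ctx, lam_n, mu_n, root_copies)
        }
      }
      hit <- !is.na(raw$branch) & inside[raw$branch]
      D <- sum(hit & raw$type == "duplication")
      L <- sum(hit & raw$type == "loss")
      out[r, ] <- c(D, L, D - L)
    }
    out
  })
  pv <- tibble::tibble(
    statistic = c("D", "L", "L", "k"),
    tail = c("upper", "lower", "upper", "upper"),
    p = c(empirical_pvalue(reps[, "D"], obs$D, "upper"),
          empirical_pvalue(reps[, "L"], obs$L, "lower"),
          empirical_pvalue(reps[, "L"], obs$L, "upper"),
          empirical_pvalue(reps[, "k"], obs$k, "upper"))
  )
  structure(list(
    replicates = tibble::as_tibble(cbind(rep = seq_len(N),
                                         as.data.frame(reps))),
    observed = tibble::tibble(D = obs$D, L = obs$L, k = obs$k),
    pvalues = pv, N = N, seed = seed, lambda = lambda, mu = mu,
    branches = as.character(branches),
    condition_on_survival = condition_on_survival
  ), class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution> N = ", x$N, " replicates, lambda = ",
      format(x$lambda), ", mu = ", format(x$mu), "\n", sep = "")
  cat(sprintf("  observed: D = %d, L = %d, k = %d\n",
              x$observed$D, x$observed$L, x$observed$k))
  for (i in seq_len(nrow(x$pvalues))) {
    cat(sprintf("  p[%s, %s] = %.4g\n", x$pvalues$statistic[i],
                x$pvalues$tail[i], x$pvalues$p[i]))
  }
  invisible(x)
}
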