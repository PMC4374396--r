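#' Broom-style tidiers for famshift results
#'
#' [tidy()] returns one row per estimated quantity (or per replicate /
#' branch for simulation and reconciliation objects); [glance()] a
#' one-row model summary.
#'
#' @param x A `bd_fit`, `lrt_result`, `null_distribution` or
#'   `reconciliation` object.
#' @param ... Unused.
#' @return A tibble.
#' @name famshift-tidiers
NULL

#' @rdname famshift-tidiers
#' @export
tidy.bd_fit <- function(x, ...) {
  k <- length(x$params$lambda)
  cls <- if (k == 1) "global" else c("background", "focal")
  out <- tibble::tibble(
    term = c(paste0("lambda_", cls), paste0("mu_", cls)),
    estimate = c(x$params$lambda, x$params$mu)
  )
  if (x$params$tied) out <- out[seq_len(k), ]
  out
}

#' @rdname famshift-tidiers
#' @export
glance.bd_fit <- function(x, ...) {
  tibble::tibble(model = x$model, logLik = x$lnL, n_params = x$n_params,
                 AIC = aic_score(x$lnL, x$n_params),
                 n_families = x$n_families, converged = x$converged)
}

#' @rdname famshift-tidiers
#' @export
tidy.lrt_result <- function(x, ...) {
  tibble::tibble(null_model = x$null_model, alt_model = x$alt_model,
                 lr = x$lr, df = x$df, p_chisq = x$p_chisq,
                 p_simulated = x$p_simulated %||% NA_real_,
                 n_null_reps = x$n_null_reps)
}

#' @rdname famshift-tidiers
#' @export
glance.lrt_result <- tidy.lrt_result

#' @rdname famshift-tidiers
#' @export
tidy.null_distribution <- function(x, ...) x$replicates

#' @rdname famshift-tidiers
#' @export
glance.null_distribution <- function(x, ...) {
  p <- setNames(x$pvalues$p, paste0("p_", x$pvalues$statistic, "_",
                                    x$pvalues$tail))
  tibble::as_tibble(c(as.list(x$observed), as.list(p),
                      list(N = x$N, lambda = x$lambda, mu = x$mu)))
}

#' @rdname famshift-tidiers
#' @export
tidy.reconciliation <- function(x, ...) x$per_branch

#' @rdname famshift-tidiers
#' @export
glance.reconciliation <- function(x, ...) {
  tibble::tibble(D = x$D, L = x$L, cost = x$cost,
                 c_dup = x$c_dup, c_loss = x$c_loss)
}
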