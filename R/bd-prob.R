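#' Linear birth-death transition probabilities
#'
#' Probability that a family with `s` gene copies at the top of a branch
#' has `c` copies after time `t`, when each copy independently
#' duplicates at rate `lambda` and is lost at rate `mu` (per gene per
#' Myr). Zero copies is absorbing: there is no gain from nothing.
#'
#' For `lambda == mu` this is the classical critical-process form with
#' `alpha = lambda * t / (1 + lambda * t)`:
#' `P(c|s) = sum_j C(s,j) C(s+c-j-1, s-1) alpha^(s+c-2j) (1-2 alpha)^j`.
#' For `lambda != mu` the general linear birth-death expression in
#' `alpha`/`beta` is used; both are evaluated through `expm1` so the
#' probability is continuous as `lambda` approaches `mu`. Sums are
#' accumulated in log space to guard against overflow at large counts.
#'
#' @param s,c Start and end copy numbers (non-negative integers,
#'   recycled).
#' @param t Elapsed time along the branch (Myr, `>= 0`).
#' @param lambda,mu Duplication and loss rates (per gene per Myr).
#' @return Probabilities in `[0, 1]`, recycled to the common length.
#' @examples
#' transition_prob(1, 0:3, t = 1, lambda = 0.5, mu = 0.5)
#' @export
transition_prob <- function(s, c, t, lambda, mu = lambda) {
  if (!is_count(s) || !is_count(c)) abort("`s` and `c` must be non-negative integers")
  if (any(t < 0)) abort("`t` must be non-negative")
  if (any(lambda < 0) || any(mu < 0)) abort("rates must be non-negative")
  n <- max(length(s), length(c), length(t), length(lambda), length(mu))
  bd_prob_cpp(as.integer(rep_len(s, n)), as.integer(rep_len(c, n)),
              rep_len(as.double(t), n), rep_len(as.double(lambda), n),
              rep_len(as.double(mu), n))
}

#' @rdname transition_prob
#' @param cmax Truncation bound: the matrix covers states `0..cmax`.
#' @return For [bd_prob_matrix()], a `(cmax+1) x (cmax+1)` matrix with
#'   rows indexed by start count `0..cmax` and columns by end count.
#' @export
bd_prob_matrix <- function(t, lambda, mu = lambda, cmax) {
  stopifnot(length(t) == 1, length(lambda) == 1, length(mu) == 1)
  if (t < 0 || lambda < 0 || mu < 0) abort("time and rates must be non-negative")
  if (!is_count(cmax) || cmax < 1) abort("`cmax` must be a positive integer")
  P <- bd_prob_matrix_cpp(as.double(t), as.double(lambda), as.double(mu),
                          as.integer(cmax))
  dimnames(P) <- list(0:cmax, 0:cmax)
  P
}

# Smallest truncation bound such that, for every branch of the tree,
# transition rows for start states up to `smax` lose at most `tail_tol`
# probability mass. Grows geometrically from `cmax0`.
adaptive_cmax <- function(tree, lambda, mu, smax, cmax0,
                          tail_tol = 1e-10, hard_cap = 4096L) {
  lens <- branch_table(tree)$length
  tmax <- max(lens)
  lam <- max(lambda)
  m <- max(mu)
  cmax <- as.integer(cmax0)
  repeat {
    P <- bd_prob_matrix_cpp(tmax, lam, m, cmax)
    deficit <- 1 - min(rowSums(P)[seq_len(min(smax, cmax) + 1L)])
    if (deficit <= tail_tol || cmax >= hard_cap) return(cmax)
    cmax <- min(hard_cap, cmax * 2L)
  }
}
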