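test_that("constant leaf counts reconstruct unchanged everywhere", {
  tr <- tree4()
  h <- sankoff_counts(setNames(rep(4L, 4), tr$tip.label), tr)
  expect_true(all(h$count == 4))
  expect_equal(attr(h, "cost"), 0)
  expect_equal(branch_deltas(h),
               tibble::tibble(expansions = 0, contractions = 0, net = 0))
})

test_that("cherry tie-break picks the smallest optimal root state", {
  tr <- read_chronogram("(A:1,B:1);")
  h <- sankoff_counts(c(A = 1, B = 3), tr)
  expect_equal(attr(h, "cost"), 2)
  # optimal root set is {1, 2, 3}; the rule picks the smallest
  expect_equal(h$count[is.na(h$parent)], 1L)
})

test_that("parsimony cost equals brute-force enumeration on 4-leaf trees", {
  tr <- tree4()
  set.seed(11)
  for (i in 1:12) {
    counts <- setNames(sample(0:4, 4, replace = TRUE), tr$tip.label)
    h <- sankoff_counts(counts, tr, cmax = 4)
    expect_equal(attr(h, "cost"),
                 oracle_sankoff_cost(tr, counts, cmax = 4),
                 info = paste(counts, collapse = ","))
    # asymmetric weighting
    h2 <- sankoff_counts(counts, tr, cmax = 4, cost_dup = 1.5,
                         cost_loss = 1)
    expect_equal(attr(h2, "cost"),
                 oracle_sankoff_cost(tr, counts, cmax = 4,
                                     cost_dup = 1.5, cost_loss = 1))
  }
})

test_that("leaf rows keep observed counts and deltas telescope", {
  tr <- hemiptera_chronogram()
  counts <- transporter_counts()
  apc <- counts[counts$family == "APC", ]
  h <- sankoff_counts(apc, tr)
  obs <- unlist(apc[setdiff(names(apc), "family")])
  expect_equal(setNames(h$count[h$is_leaf], h$node[h$is_leaf]),
               obs[h$node[h$is_leaf]])
  expect_equal(attr(h, "cost"), sum(abs(h$delta), na.rm = TRUE))
  # net over all branches telescopes to leaf totals minus root spread
  root <- h$count[is.na(h$parent)]
  for (leaf in c("Acyrthosiphon_pisum", "Rhodnius_prolixus")) {
    path_net <- 0
    nd <- leaf
    while (!is.na(h$parent[h$node == nd])) {
      path_net <- path_net + h$delta[h$node == nd]
      nd <- h$parent[h$node == nd]
    }
    expect_equal(root + path_net, h$count[h$node == leaf])
  }
})

test_that("posterior-mode ancestral counts match exhaustive enumeration", {
  tr3 <- read_chronogram("((A:1,B:1):1,C:2);")
  lam <- 0.25; mu <- 0.15; cm <- 5
  P1 <- bd_prob_matrix(1, lam, mu, cm)
  P2 <- bd_prob_matrix(2, lam, mu, cm)
  for (obs in list(c(A = 2, B = 1, C = 3), c(A = 0, B = 1, C = 1),
                   c(A = 4, B = 4, C = 1))) {
    joint <- matrix(0, cm + 1, cm + 1) # root state x internal state
    for (r in 1:cm) {
      for (n in 0:cm) {
        joint[r + 1, n + 1] <- (1 / cm) * P1[r + 1, n + 1] *
          P1[n + 1, obs[["A"]] + 1] * P1[n + 1, obs[["B"]] + 1] *
          P2[r + 1, obs[["C"]] + 1]
      }
    }
    h <- ml_ancestral_counts(obs, tr3, bd_params(lam, mu), cmax = cm)
    expect_equal(h$count[is.na(h$parent)], which.max(rowSums(joint)) - 1L)
    inner <- h$count[!h$is_leaf & !is.na(h$parent)]
    expect_equal(inner, which.max(colSums(joint)) - 1L)
    expect_equal(h$count[h$is_leaf], unname(obs[c("A", "B", "C")]))
  }
})

test_that("near-zero rates make ancestors copy their descendants", {
  tr <- hemiptera_chronogram()
  counts <- setNames(rep(3L, 13), tr$tip.label)
  h <- ml_ancestral_counts(counts, tr, bd_params(1e-9))
  expect_true(all(h$count == 3))
})

test_that("root counts are recovered at low rates in simulation", {
  tr <- hemiptera_chronogram()
  sim <- simulate_count_matrix(tr, 100, lambda = 1e-4, seed = 19,
                               root_prior = c(4L, 12L))
  p <- bd_params(1e-4)
  hit <- 0
  for (i in seq_len(100)) {
    h <- ml_ancestral_counts(sim$counts[i, ], tr, p)
    hit <- hit + (h$count[is.na(h$parent)] == sim$root_counts[i])
  }
  expect_gt(hit / 100, 0.8)
})

test_that("branch_deltas restricts to a branch set and validates ids", {
  tr <- read_chronogram("((A:1,B:1):1,C:2);")
  h <- sankoff_counts(c(A = 3, B = 3, C = 1), tr)
  all_d <- branch_deltas(h)
  clade <- branch_deltas(h, mrca_branches(tr, c("A", "B"),
                                          include_stem = TRUE))
  expect_lte(clade$expansions, all_d$expansions)
  expect_equal(clade$net, clade$expansions - clade$contractions)
  expect_error(branch_deltas(h, "nope"), "not in history")
})
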