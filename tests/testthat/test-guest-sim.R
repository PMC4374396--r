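test_that("zero rates yield one surviving copy per species and no events", {
  tr <- hemiptera_chronogram()
  gt <- simulate_guest(tr, 0, 0, seed = 1)
  expect_equal(leaf_counts(gt)$n, rep(1L, 13))
  expect_equal(nrow(gt$events), 0)
})

test_that("a pure-birth process never logs losses and covers every leaf", {
  tr <- hemiptera_chronogram()
  gt <- simulate_guest(tr, 2e-3, 0, seed = 2)
  expect_false(any(gt$events$event == "loss"))
  expect_true(all(leaf_counts(gt)$n >= 1))
})

test_that("the same seed reproduces the simulation bit-identically", {
  tr <- hemiptera_chronogram()
  a <- simulate_guest(tr, 2e-3, 2e-3, seed = 99)
  b <- simulate_guest(tr, 2e-3, 2e-3, seed = 99)
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$events, b$events)
})

test_that("event log and guest-tree nodes tell the same story", {
  tr <- hemiptera_chronogram()
  gt <- simulate_guest(tr, 3e-3, 2e-3, seed = 17)
  expect_equal(sum(gt$events$event == "duplication"),
               sum(gt$nodes$type == "duplication"))
  expect_equal(sum(gt$events$event == "loss"),
               sum(gt$nodes$type == "loss"))
  bt <- branch_table(tr)
  m <- match(gt$events$branch, bt$branch)
  expect_false(anyNA(m))
  # event times fall inside their branch's time window
  expect_true(all(gt$events$time >= bt$time_start[m] - 1e-12))
  expect_true(all(gt$events$time <= bt$time_end[m] + 1e-12))
})

test_that("extinction probability on one branch matches the closed form", {
  # lambda = mu = 0.5, t = 1: P(extinct) = lambda t / (1 + lambda t) = 1/3
  tr <- read_chronogram("(A:1,B:1);") # two independent branches of length 1
  ctx <- famshift:::guest_sim_ctx(tr)
  n <- 3000
  gone <- withr::with_seed(123, {
    sum(vapply(seq_len(n), function(i) {
      raw <- famshift:::sim_guest_core(ctx, c(0.5, 0.5, 0), c(0.5, 0.5, 0), 1L)
      ext <- raw$branch[raw$type == "extant"]
      sum(c(sum(ext == 1L), sum(ext == 2L)) == 0)
    }, integer(1)))
  })
  p_hat <- gone / (2 * n)
  se <- sqrt((1 / 3) * (2 / 3) / (2 * n))
  expect_lt(abs(p_hat - 1 / 3), 3 * se)
})

test_that("clade event summaries count and add up correctly", {
  tr <- read_chronogram("((A:1,B:1):1,C:2);")
  ab <- mrca_branches(tr, c("A", "B"), include_stem = TRUE)
  stem <- attr(ab, "mrca")
  log <- tibble::tibble(
    event = c("duplication", "duplication", "duplication", "loss",
              "duplication", "duplication"),
    branch = c("A", "B", stem, "A", "C", "C"),
    time = c(1.2, 1.5, 0.7, 1.9, 0.3, 1.1)
  )
  s <- clade_event_summary(log, ab)
  expect_equal(s, tibble::tibble(D = 3L, L = 1L, k = 2L))
  # additivity over a partition of all branches
  rest <- setdiff(branch_table(tr)$branch, as.character(ab))
  s2 <- clade_event_summary(log, rest)
  expect_equal(s$D + s2$D, sum(log$event == "duplication"))
  expect_equal(s$L + s2$L, sum(log$event == "loss"))
  # empty log
  empty <- clade_event_summary(log[0, ], ab)
  expect_equal(empty$k, 0L)
  # unknown ids against a guest tree are refused
  gt <- simulate_guest(tr, 0, 0, seed = 1)
  expect_error(clade_event_summary(gt, c("A", "nope")), "not in host")
})

test_that("mean surviving copies equal the exponential growth law", {
  tr <- read_chronogram("(A:40,B:40);")
  ctx <- famshift:::guest_sim_ctx(tr)
  cases <- list(c(0.02, 0.01), c(0.015, 0.015))
  withr::with_seed(42, {
    for (r in cases) {
      n <- 2500
      tot <- vapply(seq_len(n), function(i) {
        raw <- famshift:::sim_guest_core(ctx, c(r[1], r[1], 0),
                                         c(r[2], r[2], 0), 1L)
        sum(raw$type == "extant" & raw$branch == 1L)
      }, integer(1))
      expected <- exp((r[1] - r[2]) * 40)
      se <- sd(tot) / sqrt(n)
      expect_lt(abs(mean(tot) - expected), 3 * se + 1e-9)
    }
  })
})

test_that("pruned guest trees drop extinct lineages cleanly", {
  tr <- hemiptera_chronogram()
  gt <- simulate_guest(tr, 2.5e-3, 2e-3, seed = 31)
  pg <- guest_to_gene_tree(gt)
  counts <- leaf_counts(gt)
  if (!is.null(pg)) {
    sp <- famshift:::gene_leaf_species(pg$tip.label)
    expect_equal(as.integer(table(factor(sp, levels = counts$species))),
                 counts$n)
    expect_true(ape::is.binary(pg))
  }
  # global extinction gives all-zero leaf counts
  gt0 <- simulate_guest(read_chronogram("(A:1,B:1);"), 0.01, 5, seed = 3)
  expect_equal(leaf_counts(gt0)$n, c(0L, 0L))
  expect_null(guest_to_gene_tree(gt0))
})
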