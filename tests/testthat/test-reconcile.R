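test_that("a congruent gene tree reconciles with zero events", {
  st <- read_chronogram("((A:1,B:1):1,C:2);")
  rec <- lca_reconcile("((A|g,B|g),C|g);", st)
  expect_equal(rec$D, 0L)
  expect_equal(rec$L, 0L)
  expect_equal(rec$cost, 0)
  expect_equal(clade_summary(rec, mrca_branches(st, c("A", "B"))),
               tibble::tibble(D = 0L, L = 0L, k = 0L))
})

test_that("an in-paralog pair costs exactly one duplication", {
  st <- read_chronogram("(A:1,B:1);")
  rec <- lca_reconcile("((A|g1,A|g2),B|g1);", st)
  expect_equal(rec$D, 1L)
  expect_equal(rec$L, 0L)
  expect_equal(rec$cost, 1.5)
  expect_equal(rec$per_branch$duplications[rec$per_branch$branch == "A"], 1L)
})

test_that("the discordant three-leaf example yields D=1, L=3, cost 4.5", {
  st <- read_chronogram("((A:1,B:1):1,C:2);")
  rec <- lca_reconcile("(A|a,(B|b,C|c));", st)
  expect_equal(rec$D, 1L)
  expect_equal(rec$L, 3L)
  expect_equal(rec$cost, 4.5)
  # the duplication sits at the species root; one loss on each of A, B, C
  pb <- rec$per_branch
  expect_equal(pb$losses[match(c("A", "B", "C"), pb$branch)], c(1L, 1L, 1L))
  expect_equal(sum(pb$duplications[pb$branch %in% c("A", "B", "C")]), 0L)
  # clade restricted to {A, B} + stem sees two of the losses, no dups
  ab <- mrca_branches(st, c("A", "B"), include_stem = TRUE)
  expect_equal(clade_summary(rec, ab), tibble::tibble(D = 0L, L = 2L, k = -2L))
  # all-branch summary recovers the totals that are not on the root
  all_br <- branch_set(st, branch_table(st)$branch)
  cs <- clade_summary(rec, all_br)
  expect_equal(cs$L, rec$L)
})

test_that("LCA reconciliation minimises duplications and losses", {
  st3 <- read_chronogram("((A:1,B:1):1,C:2);")
  st4 <- tree4()
  cases <- list(
    list(gt = "(A|1,(B|1,C|1));", st = st3),
    list(gt = "((A|1,C|1),(B|1,C|2));", st = st3),
    list(gt = "((A|1,A|2),(B|1,C|1));", st = st3),
    list(gt = "(((A|1,C|1),B|1),C|2);", st = st3),
    list(gt = "((A|1,D|1),(B|1,C|1));", st = st4),
    list(gt = "(((A|1,B|1),(C|1,D|1)),D|2);", st = st4),
    list(gt = "((D|1,(C|1,A|1)),(B|1,B|2));", st = st4)
  )
  for (cs in cases) {
    gt <- read_gene_tree(cs$gt)
    rec <- lca_reconcile(gt, cs$st)
    minima <- oracle_reconcile_minima(gt, cs$st)
    expect_equal(rec$D, unname(minima["D"]), info = cs$gt)
    expect_equal(rec$L, unname(minima["L"]), info = cs$gt)
  }
})

test_that("randomised gene trees confirm LCA optimality", {
  st <- tree4()
  set.seed(202)
  for (i in 1:10) {
    nl <- sample(4:5, 1)
    species <- sample(c("A", "B", "C", "D"), nl, replace = TRUE)
    labels <- paste0(species, "|g", seq_len(nl))
    gt <- ape::rtree(nl, tip.label = labels)
    gt$edge.length <- NULL
    rec <- lca_reconcile(gt, st)
    minima <- oracle_reconcile_minima(gt, st)
    expect_equal(rec$D, unname(minima["D"]))
    expect_equal(rec$L, unname(minima["L"]))
  }
})

test_that("duplicating an extant subtree adds exactly one duplication", {
  st <- tree4()
  base <- "((A|1,B|1),(C|1,D|1));"
  doubled <- "(((A|1,B|1),(A|2,B|2)),(C|1,D|1));"
  r1 <- lca_reconcile(base, st)
  r2 <- lca_reconcile(doubled, st)
  expect_equal(r2$D, r1$D + 1L)
  expect_equal(r2$L, r1$L)
})

test_that("simulated guest trees reconcile back to their logged events", {
  tr <- hemiptera_chronogram()
  br <- mrca_branches(tr, sternorrhyncha_taxa(), include_stem = TRUE)
  found <- 0L
  for (s in 1:6) {
    gt <- simulate_guest(tr, 2e-3, 5e-4, seed = 1000 + s)
    pg <- guest_to_gene_tree(gt)
    if (is.null(pg)) next
    rec <- lca_reconcile(pg, tr)
    # simulated duplications whose two daughter lineages both survive
    # in overlapping species sets must be labelled duplications by the
    # LCA mapping; and parsimony can never infer more duplications
    # than were simulated
    nodes <- gt$nodes
    kids <- split(nodes$node, factor(nodes$parent, levels = nodes$node))
    sets <- vector("list", nrow(nodes))
    spset <- function(i) {
      if (!is.null(sets[[i]])) return(sets[[i]])
      out <- if (nodes$type[i] == "extant") nodes$species[i] else {
        unique(unlist(lapply(kids[[as.character(i)]], spset)))
      }
      sets[[i]] <<- if (is.null(out)) character(0) else out
      sets[[i]]
    }
    certain <- 0L
    for (i in which(nodes$type == "duplication")) {
      ch <- kids[[as.character(i)]]
      if (length(intersect(spset(ch[1]), spset(ch[2]))) > 0) {
        certain <- certain + 1L
      }
    }
    expect_gte(rec$D, certain)
    expect_lte(rec$D, sum(gt$events$event == "duplication"))
    sim_k <- clade_event_summary(gt, br)
    rec_k <- clade_summary(rec, br)
    expect_lte(rec_k$D, sim_k$D)
    found <- found + 1L
  }
  expect_gt(found, 0L)
})

test_that("unknown species and malformed labels are reported by name", {
  st <- read_chronogram("(A:1,B:1);")
  expect_error(lca_reconcile("(A|g1,Z|g1);", st), "Z")
  expect_error(lca_reconcile("(A|g1,|g2);", st), "\\|g2")
})
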