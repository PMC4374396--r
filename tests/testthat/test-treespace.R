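test_that("chronogram parsing validates structure and dates", {
  tr <- read_chronogram("((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "chronogram")
  expect_equal(ape::Ntip(tr), 3)
  expect_equal(tree_depth(tr), 2)
  expect_true(is_dated(tr))

  # unequal root-to-tip paths set the non-ultrametric flag
  expect_warning(tr2 <- read_chronogram("((A:1,B:2):1,C:2);"),
                 "not ultrametric")
  expect_false(is_dated(tr2))

  expect_error(read_chronogram("((A:1,B:1,C:1):1,D:2);"), "polytom")
  expect_error(read_chronogram("((A:1,B:1):1,C:2,"), "parse|read")
  expect_error(read_chronogram("((A:1,A:1):1,C:2);"), "unique")
})

test_that("internal-node labels are deterministic functions of the leaf set", {
  a <- read_chronogram("((A:1,B:1):1,C:2);")
  b <- read_chronogram("(C:2,(B:1,A:1):1);") # rotated input, same clades
  expect_setequal(a$node.label, b$node.label)
})

test_that("write/read round trip preserves topology and branch lengths", {
  tr <- yule_tree(12, depth = 387.123456789, seed = 42)
  back <- read_chronogram(write_chronogram(tr))
  expect_setequal(back$tip.label, tr$tip.label)
  bt1 <- branch_table(tr)
  bt2 <- branch_table(back)
  m <- match(bt1$branch, bt2$branch)
  expect_false(anyNA(m))
  expect_equal(bt2$parent[m], bt1$parent)
  expect_equal(bt2$length[m], bt1$length, tolerance = 1e-9)
})

test_that("mrca_branches returns the focal subtree, with optional stem", {
  tr <- read_chronogram("((A:1,B:1):1,C:2);")
  expect_setequal(as.character(mrca_branches(tr, c("A", "B"))), c("A", "B"))
  with_stem <- mrca_branches(tr, c("A", "B"), include_stem = TRUE)
  expect_length(with_stem, 3)
  expect_true(attr(with_stem, "mrca") %in% as.character(with_stem))
  expect_error(mrca_branches(tr, c("A", "Z")), "unknown")
  expect_error(mrca_branches(tr, "A"), "at least two")
})

test_that("mrca_branches is monotone: more taxa never shrink the set", {
  tr <- yule_tree(10, depth = 100, seed = 7)
  taxa <- sort(tr$tip.label)
  prev <- character(0)
  for (n in 2:10) {
    cur <- as.character(mrca_branches(tr, taxa[1:n]))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("the packaged 13-taxon chronogram matches the count table", {
  tr <- hemiptera_chronogram()
  counts <- transporter_counts()
  expect_equal(ape::Ntip(tr), 13)
  expect_true(is_dated(tr))
  expect_setequal(setdiff(names(counts), "family"), tr$tip.label)
  # the focal clade: 4 sternorrhynchan leaves, 2 internal branches, stem
  br <- mrca_branches(tr, sternorrhyncha_taxa(), include_stem = TRUE)
  expect_length(br, 7)
  expect_length(mrca_branches(tr, sternorrhyncha_taxa()), 6)
})

test_that("count tables are validated and published values are loaded", {
  counts <- transporter_counts()
  expect_equal(counts$Acyrthosiphon_pisum[counts$family == "APC"], 18L)
  expect_equal(counts$Planococcus_citri[counts$family == "AAAP"], 28L)
  expect_equal(counts$Bemisia_tabaci[counts$family == "AAAP"], 24L)
  expect_equal(counts$Rhodnius_prolixus[counts$family == "APC"], 7L)

  expect_error(as_count_table(data.frame()), "empty")
  expect_error(as_count_table(data.frame(family = "f", A = -1)),
               "non-negative")
  expect_error(as_count_table(data.frame(family = "f", A = 1.5)),
               "non-negative")
  expect_error(
    as_count_table(data.frame(family = c("f", "f"), A = c(1, 2))),
    "duplicated")
})

test_that("a transposed counts file is detected and re-oriented", {
  tr <- read_chronogram("((A:1,B:1):1,C:2);")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("family\tfam1\tfam2", "A\t1\t4", "B\t2\t5", "C\t3\t6"), f)
  expect_message(counts <- read_counts(f, tree = tr), "transposed")
  expect_setequal(counts$family, c("fam1", "fam2"))
  expect_equal(counts$B[counts$family == "fam2"], 5L)
})
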