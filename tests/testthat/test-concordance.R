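test_that("constraints are pruned to the taxa present in a gene tree", {
  bip <- bipartition(c("A", "B", "E"), c("C", "D"))

  pc <- prune_constraint(bip, c("A", "B", "C", "D"))
  expect_false(pc$trivial)
  expect_equal(pc$restricted$key, oracle_key(c("A", "B"), c("C", "D")))
  expect_equal(pc$taxa_removed, "E")

  # a one-taxon side cannot constrain anything: every tree on {A,C,D}
  # trivially displays {A}|{C,D}
  pc2 <- prune_constraint(bip, c("A", "C", "D"))
  expect_true(pc2$trivial)
  expect_null(pc2$restricted)

  pc3 <- prune_constraint(bipartition(c("A", "B"), c("C", "D")), c("A", "B"))
  expect_true(pc3$trivial)
})

test_that("bipartition construction validates its sides", {
  expect_error(bipartition(character(0), "A"), "non-empty")
  expect_error(bipartition(c("A", "B"), c("B", "C")), "overlap")
  expect_true(bipartition(c("B", "A"), c("C", "D")) ==
                bipartition(c("C", "D"), c("A", "B")))
  # whitespace-normalized comparison
  expect_equal(bipartition(c(" A ", "B"), "C")$side_a, c("A", "B"))
})

test_that("support verdicts follow hard monophyly-constraint semantics", {
  ab_cd <- bipartition(c("A", "B"), c("C", "D"))

  expect_equal(gene_tree_supports(read_newick(text = "((A,B),(C,D));"), ab_cd),
               "supports")
  expect_equal(gene_tree_supports(read_newick(text = "((A,C),(B,D));"), ab_cd),
               "conflicts_or_unresolved")
  # a polytomy does not display the split, so it cannot support it
  expect_equal(gene_tree_supports(read_newick(text = "(A,B,C,D);"), ab_cd),
               "conflicts_or_unresolved")
  # absent taxa are removed from the constraint before testing
  expect_equal(gene_tree_supports(read_newick(text = "((A,B),(C,D));"),
                                  bipartition(c("A", "B", "E"), c("C", "D"))),
               "supports")
  # fewer than 4 leaves can never yield a testable constraint
  expect_equal(gene_tree_supports(read_newick(text = "((A,B),C);"), ab_cd),
               "trivial")
})

test_that("soft mode accepts splits compatible with an unresolved tree", {
  ab_cd <- bipartition(c("A", "B"), c("C", "D"))
  poly <- read_newick(text = "(A,B,C,D);")
  expect_equal(gene_tree_supports(poly, ab_cd, mode = "soft"), "supports")
  conflicting <- read_newick(text = "((A,C),(B,D));")
  expect_equal(gene_tree_supports(conflicting, ab_cd, mode = "soft"),
               "conflicts_or_unresolved")
})

test_that("support test matches the brute-force enumeration oracle", {
  set.seed(202)
  full <- paste0("t", 1:8)
  n_checked <- 0L
  for (rep in 1:60) {
    n <- sample(5:8, 1)
    gt <- random_binary_tree(n, labels = full[seq_len(n)])
    # random dropout of up to n - 4 taxa
    drop <- sample(0:(n - 4), 1)
    if (drop > 0) gt <- ape::drop.tip(gt, sample(gt$tip.label, drop))
    # random reference bipartition of the full taxon set
    k <- sample(2:6, 1)
    side_a <- sample(full, k)
    bip <- bipartition(side_a, setdiff(full, side_a))
    got <- gene_tree_supports(gt, bip)
    want <- oracle_supports(gt, bip$side_a, bip$side_b)
    expect_identical(got, want)
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 60L)
})

test_that("tallies count verdicts per bipartition with a fixed denominator", {
  gts <- lapply(c("((A,B),(C,D));", "((A,B),(C,D));", "((A,C),(B,D));"),
                function(s) read_newick(text = s))
  tab <- tally_congruence(gts, bipartition(c("A", "B"), c("C", "D")))
  expect_equal(tab$n_support, 2L)
  expect_equal(tab$n_other, 1L)
  expect_equal(tab$n_trivial, 0L)
  expect_equal(tab$denominator, 3L)
  expect_equal(tab$fraction, 2 / 3)
})

test_that("trivial policy switches between vacuous support and exclusion", {
  # second tree lacks all of side_b, so the constraint is vacuously satisfied
  gts <- list(read_newick(text = "((A,B),(C,D));"),
              read_newick(text = "((A,E),(B,F));"))
  bip <- bipartition(c("A", "B"), c("C", "D"))
  inc <- tally_congruence(gts, bip, trivial_policy = "count_as_support")
  exc <- tally_congruence(gts, bip, trivial_policy = "exclude")
  expect_equal(inc$n_trivial, 1L)
  expect_equal(inc$fraction, 1)
  expect_equal(exc$fraction, 1 / 2)
  expect_equal(inc$n_support + inc$n_trivial + inc$n_other, inc$denominator)
})

test_that("verdict rows always conserve the denominator", {
  set.seed(303)
  sp <- pectinate_chronogram(8, durations = rep(0.5, 6))
  gts <- sim_gene_trees(sp, 40)
  gts <- Filter(Negate(is.null),
                lapply(gts, apply_dropout, retention_prob = 0.7, min_taxa = 4))
  bips <- tree_bipartitions(sp)
  for (pol in c("count_as_support", "exclude")) {
    tab <- tally_congruence(gts, bips, trivial_policy = pol)
    expect_equal(tab$n_support + tab$n_trivial + tab$n_other,
                 rep(length(gts), nrow(tab)))
    expect_true(all(tab$fraction >= 0 & tab$fraction <= 1))
  }
})

test_that("deleting taxa never turns support into conflict while non-trivial", {
  # the restriction of a displayed split stays displayed
  set.seed(404)
  for (rep in 1:40) {
    gt <- random_binary_tree(8)
    bips <- tree_bipartitions(gt)
    row <- sample(nrow(bips), 1)
    bip <- bipartition(bips$clade[[row]], bips$rest[[row]])
    expect_equal(gene_tree_supports(gt, bip), "supports")
    dropped <- ape::drop.tip(gt, sample(gt$tip.label, sample(1:4, 1)))
    expect_true(gene_tree_supports(dropped, bip) %in% c("supports", "trivial"))
  }
})

test_that("branch durations join onto matching bipartitions only", {
  chrono <- read_newick(text = "((A:10,B:10):15,(C:20,D:20):5);")
  gts <- list(read_newick(text = "((A,B),(C,D));"))
  tab <- tally_congruence(gts, tree_bipartitions(chrono))
  joined <- add_branch_durations(tab, chrono)
  # both root-adjacent branches carry this split: one unrooted edge, 15 + 5
  expect_equal(joined$duration[joined$clade_taxa == "A;B"], 20)

  # a bipartition foreign to the chronogram stays, flagged by NA
  tab2 <- tally_congruence(gts, list(bipartition(c("A", "C"), c("B", "D"))))
  expect_warning(j2 <- add_branch_durations(tab2, chrono), "no chronogram branch")
  expect_true(is.na(j2$duration))
  expect_equal(attr(j2, "n_unmatched"), 1L)
})

test_that("empty gene-tree lists are rejected", {
  expect_error(tally_congruence(list(), bipartition("A", "B")), "empty")
})
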