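test_that("gene-tree coalescences never predate species divergences", {
  set.seed(11)
  sp <- pectinate_chronogram(8, durations = runif(6, 0.2, 2))
  sp_d <- ape::cophenetic.phylo(sp)
  for (i in 1:25) {
    gt <- sim_gene_tree(sp)
    expect_setequal(gt$tip.label, sp$tip.label)
    gt_d <- ape::cophenetic.phylo(gt)[rownames(sp_d), colnames(sp_d)]
    expect_true(all(gt_d >= sp_d - 1e-8))
  }
})

test_that("a very long internal branch forces concordance, a zero branch a trichotomy", {
  set.seed(12)
  deep <- pectinate_chronogram(4, durations = c(50, 1))
  gts <- sim_gene_trees(deep, 300)
  tab <- tally_congruence(gts, tree_bipartitions(deep))
  expect_equal(tab$fraction[tab$clade_taxa == "t01;t02"], 1)

  flat <- pectinate_chronogram(4, durations = c(0, 1))
  gts0 <- sim_gene_trees(flat, 3000)
  keys <- c(
    concord = oracle_key(c("t01", "t02"), c("t03", "t04")),
    disc1 = oracle_key(c("t01", "t03"), c("t02", "t04")),
    disc2 = oracle_key(c("t01", "t04"), c("t02", "t03"))
  )
  counts <- vapply(keys, function(k) {
    sum(vapply(gts0, function(g) k %in% congrue:::.split_keys(g), logical(1)))
  }, numeric(1))
  # all three quartet topologies ~ 1/3; 3 binomial SE at n = 3000
  se3 <- 3 * sqrt((1 / 3) * (2 / 3) / 3000)
  expect_true(all(abs(counts / 3000 - 1 / 3) < se3))
})

test_that("dropout keeps each taxon independently and discards sparse loci", {
  tr <- pectinate_chronogram(10)
  expect_identical(apply_dropout(tr, 1), tr)
  set.seed(13)
  expect_null(apply_dropout(tr, 0, min_taxa = 3))

  kept <- apply_dropout(tr, 0.7, min_taxa = 4)
  expect_true(is.null(kept) || length(kept$tip.label) >= 4)

  # per-taxon probabilities: a taxon with p = 0 always drops
  p <- stats::setNames(rep(1, 10), tr$tip.label)
  p["t01"] <- 0
  got <- apply_dropout(tr, p)
  expect_false("t01" %in% got$tip.label)
  expect_equal(length(got$tip.label), 9L)
})

test_that("dropout calibrates to its expected retention", {
  set.seed(14)
  tr <- ape::rcoal(131, tip.label = sprintf("s%03d", 1:131))
  n_kept <- replicate(400, {
    out <- apply_dropout(tr, 121 / 131, min_taxa = 1)
    length(out$tip.label)
  })
  se <- sqrt(131 * (121 / 131) * (10 / 131) / 400)
  expect_lt(abs(mean(n_kept) - 121), 3 * se)
})

test_that("Jukes-Cantor simulation matches its expected p-distance", {
  set.seed(15)
  two <- read_newick(text = "(a:5,b:5);")
  aln <- sim_alignment(two, 10000, subst_rate = 0.01, missing_prob = 0)
  d <- 0.1  # total path length in substitutions/site
  p_exp <- 0.75 * (1 - exp(-4 * d / 3))
  p_obs <- mean(aln$matrix["a", ] != aln$matrix["b", ])
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 10000))

  # zero branch lengths give identical sequences
  zero <- read_newick(text = "((a:0,b:0):0,c:0);")
  aln0 <- sim_alignment(zero, 200, missing_prob = 0)
  expect_equal(profile_locus(aln0)$n_variable, 0L)

  # missingness masks cells to N
  alnN <- sim_alignment(two, 1000, missing_prob = 0.2)
  expect_gt(profile_locus(alnN)$pct_missing, 10)

  nolen <- read_newick(text = "((a,b),c);")
  expect_error(sim_alignment(nolen, 100), "branch lengths")
})

test_that("fixture generation is byte-identical under a fixed seed", {
  d1 <- tempfile(); d2 <- tempfile()
  sp <- pectinate_chronogram(6, durations = rep(1, 4))
  m1 <- make_fixture_dataset(d1, n_loci = 8, chronogram = sp, seed = 99)
  m2 <- make_fixture_dataset(d2, n_loci = 8, chronogram = sp, seed = 99)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE),
                     info = f)
  }
  # a different seed changes the data
  d3 <- tempfile()
  make_fixture_dataset(d3, n_loci = 8, chronogram = sp, seed = 100)
  tree1 <- readLines(file.path(d1, "gene_trees/locus0001.nwk"), warn = FALSE)
  tree3 <- readLines(file.path(d3, "gene_trees/locus0001.nwk"), warn = FALSE)
  expect_false(identical(tree1, tree3))
})

test_that("the fixture manifest lists discarded loci separately", {
  d <- tempfile()
  sp <- pectinate_chronogram(5, durations = rep(1, 3))
  m <- make_fixture_dataset(d, n_loci = 30, chronogram = sp,
                            retention_prob = 0.5, min_taxa = 4, seed = 7)
  expect_equal(nrow(m), 30L)
  expect_true(any(m$status == "discarded"))
  expect_true(all(is.na(m$n_taxa[m$status == "discarded"])))
  written <- list.files(file.path(d, "gene_trees"))
  expect_equal(sort(written), sort(paste0(m$locus_id[m$status == "kept"], ".nwk")))
  expect_true(file.exists(file.path(d, "params.json")))
})
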