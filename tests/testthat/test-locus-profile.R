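write_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

test_that("FASTA, PHYLIP and NEXUS readers agree on the same alignment", {
  seqs <- c(s1 = "ACGTACGTAC", s2 = "ACGAACGTAC", s3 = "ATGTACGTAC",
            s4 = "ATGAACGTNC")
  fa <- write_tmp(as.vector(rbind(paste0(">", names(seqs)), seqs)), ".fasta")
  phy <- write_tmp(c("4 10", paste(names(seqs), seqs)), ".phy")
  nex <- write_tmp(c(
    "#NEXUS", "BEGIN DATA;",
    "DIMENSIONS NTAX=4 NCHAR=10;",
    "FORMAT DATATYPE=DNA MISSING=? GAP=-;",
    "MATRIX",
    paste(names(seqs), seqs),
    ";", "END;"
  ), ".nex")

  a_fa <- read_alignment(fa)
  a_phy <- read_alignment(phy)
  a_nex <- read_alignment(nex)
  expect_equal(dim(a_fa$matrix), c(4L, 10L))
  expect_equal(unname(a_phy$matrix), unname(a_fa$matrix))
  expect_equal(unname(a_nex$matrix), unname(a_fa$matrix))
  expect_equal(rownames(a_nex$matrix), rownames(a_fa$matrix))
})

test_that("bad alignments are rejected with the locus and taxon named", {
  ragged <- write_tmp(c(">s1", "ACGT", ">s2", "ACG"), ".fasta")
  expect_error(read_alignment(ragged), "ragged")
  expect_error(read_alignment(ragged), "s2")

  dup <- write_tmp(c(">s1", "ACGT", ">s1", "ACGT"), ".fasta")
  expect_error(read_alignment(dup), "duplicate")

  empty <- write_tmp(character(0), ".fasta")
  expect_error(read_alignment(empty), "no FASTA records")

  one <- write_tmp(c(">s1", "ACGT"), ".fasta")
  expect_error(read_alignment(one), "at least 2")
})

test_that("site classification follows the two-states-twice rule", {
  expect_equal(classify_site(c("A", "A", "T", "T")), "parsimony_informative")
  expect_equal(classify_site(c("A", "A", "A", "T")), "variable_uninformative")
  expect_equal(classify_site(c("A", "-", "N", "A")), "constant")
  expect_equal(classify_site(c("-", "N", "?", "-")), "all_missing")
  # ambiguity codes are not states: (A,A,R,R) is constant
  expect_equal(classify_site(c("A", "A", "R", "R")), "constant")
  expect_error(classify_site(c("A", "X")), "illegal")
})

test_that("site classifier matches the counting oracle on random columns", {
  set.seed(505)
  for (i in 1:300) {
    col <- random_column(sample(4:40, 1))
    expect_identical(classify_site(col), oracle_classify(col))
  }
})

test_that("locus profiles enumerate columns correctly", {
  aln <- locus_alignment(c(s1 = "ACGT", s2 = "ACGA", s3 = "ATGT", s4 = "ATGA"))
  p <- profile_locus(aln)
  # site-by-site: (A,A,A,A) constant; (C,C,T,T) PIC; (G,G,G,G) constant;
  # (T,A,T,A) PIC
  expect_equal(p$n_variable, 2L)
  expect_equal(p$n_pic, 2L)
  expect_equal(p$pct_variation, 50)
  expect_equal(p$pct_missing, 0)

  ident <- locus_alignment(c(a = "AAAA", b = "AAAA"))
  pi <- profile_locus(ident)
  expect_equal(pi$n_variable, 0L)
  expect_equal(pi$n_pic, 0L)

  gappy <- locus_alignment(c(a = "A-GT", b = "A-GA", c = "A-GT", d = "A-GA"))
  pg <- profile_locus(gappy)
  expect_equal(pg$pct_missing, 25)
  expect_equal(congrue:::.classify_matrix(gappy$matrix)[2], "all_missing")
  # the all-missing column can be excluded from the variation denominator
  expect_equal(profile_locus(gappy, variation_denominator = "scored_columns")$pct_variation,
               100 * 1 / 3)
})

test_that("column class counts always sum to the alignment length", {
  set.seed(606)
  for (i in 1:20) {
    m <- matrix(random_column(8 * 30), nrow = 8)
    rownames(m) <- paste0("s", 1:8)
    cls <- congrue:::.classify_matrix(m)
    expect_length(cls, 30L)
    p <- profile_locus(locus_alignment(m))
    n_const <- sum(cls == "constant")
    n_miss <- sum(cls == "all_missing")
    expect_equal(p$n_variable + n_const + n_miss, 30L)
  }
})

test_that("summaries report mean (min-max) per class and ignore locus order", {
  profs <- dplyr::bind_rows(
    profile_locus(locus_alignment(c(a = paste(rep("ACGT", 100), collapse = ""),
                                    b = paste(rep("ACGT", 100), collapse = "")),
                                  locus_id = "L1")),
    profile_locus(locus_alignment(c(a = paste(rep("ACTTGA", 100), collapse = ""),
                                    b = paste(rep("ACTAGA", 100), collapse = "")),
                                  locus_id = "L2"))
  )
  s <- summarize_profiles(profs)
  len <- s[s$metric == "length", ]
  expect_equal(len$mean, 500)
  expect_equal(len$min, 400)
  expect_equal(len$max, 600)
  expect_match(len$label, "^500 \\(400–600\\)$")

  s_rev <- summarize_profiles(profs[2:1, ])
  expect_equal(s_rev, s)

  # class manifest splits the summary
  cls <- data.frame(locus_id = c("L1", "L2"), class = c("uce", "coding"))
  s2 <- summarize_profiles(profs, cls)
  expect_setequal(unique(s2$class), c("uce", "coding"))
  expect_true(all(s2$n_loci == 1L))

  expect_error(summarize_profiles(profs[0, ]), "non-empty")
})

test_that("longer loci with proportional signal give an exact linear fit", {
  profs <- tibble::tibble(
    locus_id = paste0("L", 1:5),
    n_taxa = 4L,
    length = c(100L, 200L, 300L, 400L, 500L),
    n_variable = as.integer(0.2 * c(100, 200, 300, 400, 500)),
    n_pic = as.integer(0.1 * c(100, 200, 300, 400, 500)),
    pct_variation = 20,
    pct_missing = 0
  )
  fit <- length_vs_informative(profs)
  expect_equal(fit$slope, 0.1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$adj_r_squared, 1, tolerance = 1e-12)
})

test_that("directory profiling skips malformed loci with a warning", {
  dir <- tempfile()
  dir.create(dir)
  writeLines(c(">a", "ACGTA", ">b", "ACGTT", ">c", "AGGTA", ">d", "AGGTT"),
             file.path(dir, "good.fasta"))
  writeLines(c(">a", "ACGT", ">b", "AC"), file.path(dir, "bad.fasta"))
  expect_warning(profs <- profile_loci(dir), "bad.fasta")
  expect_equal(profs$locus_id, "good")

  emptydir <- tempfile()
  dir.create(emptydir)
  expect_error(profile_loci(emptydir), "no parseable loci")
})
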