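# Multispecies-coalescent synthetic data: gene trees with incomplete
# lineage sorting, taxon dropout emulating capture inefficiency, and
# Jukes-Cantor sequence evolution.

# coalesce `lins` (list of list(nwk, time)) within [start, end]; rate
# k(k-1)/2 per coalescent unit; end may be Inf (root branch)
.coalesce_interval <- function(lins, start, end) {
  t <- start
  while (length(lins) > 1L) {
    k <- length(lins)
    t <- t + stats::rexp(1L, rate = k * (k - 1) / 2)
    if (t > end) break
    pair <- sample.int(k, 2L)
    a <- lins[[pair[1L]]]; b <- lins[[pair[2L]]]
    merged <- list(
      nwk = sprintf("(%s:%.12g,%s:%.12g)", a$nwk, t - a$time, b$nwk, t - b$time),
      time = t
    )
    lins <- c(lins[-pair], list(merged))
  }
  lins
}

#' Simulate one gene tree under the multispecies coalescent
#'
#' Within every branch of the species tree, the k gene lineages present
#' coalesce with exponential waiting times at rate k(k-1)/2 per coalescent
#' unit; lineages that fail to coalesce are passed rootward, and the root
#' branch is treated as infinitely long so all lineages eventually join.
#' Short internal branches therefore produce incomplete lineage sorting and
#' gene trees discordant with the species tree.  One lineage is sampled per
#' species.
#'
#' Gene-tree branch lengths are in coalescent units; every gene-tree
#' coalescence is at least as old as the divergence of the species
#' involved.
#'
#' @param species_tree A rooted ultrametric `phylo`; edge lengths times
#'   `scale` are coalescent units.
#' @param scale Multiplier converting the species-tree branch lengths
#'   (e.g. Ma) into coalescent units.
#' @return A binary rooted `phylo` gene tree on the same taxa.
#' @examples
#' set.seed(1)
#' sp <- pectinate_chronogram(4, durations = c(1, 1))
#' sim_gene_tree(sp)
#' @export
sim_gene_tree <- function(species_tree, scale = 1) {
  .sim_gene_tree_prepared(.msc_prepare(species_tree, scale))
}

# precompute the static walk over the species tree once per model
.msc_prepare <- function(species_tree, scale = 1) {
  .validate_chronogram(species_tree)
  tr <- species_tree
  tr$edge.length <- tr$edge.length * scale
  ntip <- length(tr$tip.label)
  depth <- ape::node.depth.edgelength(tr)
  ages <- max(depth[seq_len(ntip)]) - depth
  ages[seq_len(ntip)] <- 0
  ord <- ape::reorder.phylo(tr, "postorder")
  visit <- unique(ord$edge[, 1L])  # internal nodes, children-first
  list(
    ntip = ntip,
    root = ntip + 1L,
    ages = ages,
    visit = visit,
    children = split(ord$edge[, 2L], factor(ord$edge[, 1L], levels = visit)),
    tips_q = .quote_label(tr$tip.label)
  )
}

.sim_gene_tree_prepared <- function(prep) {
  lineages <- vector("list", length(prep$ages))
  for (i in seq_len(prep$ntip)) {
    lineages[[i]] <- list(list(nwk = prep$tips_q[i], time = 0))
  }
  for (j in seq_along(prep$visit)) {
    nd <- prep$visit[j]
    pool <- list()
    for (ch in prep$children[[j]]) {
      pool <- c(pool, .coalesce_interval(lineages[[ch]], prep$ages[ch],
                                         prep$ages[nd]))
    }
    if (nd == prep$root) {
      pool <- .coalesce_interval(pool, prep$ages[nd], Inf)
    }
    lineages[[nd]] <- pool
  }
  ape::read.tree(text = paste0(lineages[[prep$root]][[1L]]$nwk, ";"))
}

#' Simulate gene trees for many loci
#'
#' @inheritParams sim_gene_tree
#' @param n_loci Number of independent gene trees.
#' @param seed Optional integer seed.
#' @return A `multiPhylo` list of gene trees.
#' @export
sim_gene_trees <- function(species_tree, n_loci, scale = 1, seed = NULL) {
  if (n_loci < 1L) stop("`n_loci` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  prep <- .msc_prepare(species_tree, scale)
  out <- replicate(n_loci, .sim_gene_tree_prepared(prep), simplify = FALSE)
  class(out) <- "multiPhylo"
  out
}

#' Random taxon dropout
#'
#' Emulates sequence-capture inefficiency: each leaf is retained
#' independently with probability `retention_prob` (a scalar, or a named
#' vector giving per-taxon probabilities).  The induced tree on the
#' retained leaves is returned with unbranched nodes suppressed; when fewer
#' than `min_taxa` leaves remain the locus is discarded and `NULL` is
#' returned.
#'
#' @param tree A `phylo`.
#' @param retention_prob Retention probability in `[0, 1]`; the expected
#'   number of retained taxa is `Ntip(tree) * retention_prob`.
#' @param min_taxa Minimum retained leaves for the locus to be kept.
#' @return A pruned `phylo`, or `NULL` when discarded.
#' @export
apply_dropout <- function(tree, retention_prob, min_taxa = 4) {
  .assert_phylo(tree)
  labs <- tree$tip.label
  n <- length(labs)
  p <- if (length(retention_prob) == 1L) {
    rep(retention_prob, n)
  } else {
    if (is.null(names(retention_prob)) || !all(labs %in% names(retention_prob))) {
      stop("per-taxon `retention_prob` must be named for every tip", call. = FALSE)
    }
    unname(retention_prob[labs])
  }
  if (any(p < 0 | p > 1)) stop("retention probabilities must be in [0, 1]", call. = FALSE)
  keep <- stats::runif(n) < p
  if (sum(keep) < min_taxa) return(NULL)
  if (all(keep)) return(tree)
  ape::keep.tip(tree, labs[keep])
}

#' Simulate a locus alignment under Jukes-Cantor
#'
#' Draws a uniform root sequence and evolves each site independently along
#' the gene tree under the Jukes-Cantor model (via [phangorn::simSeq()]),
#' with gene-tree coalescent-unit branch lengths converted to expected
#' substitutions per site by `subst_rate`.  A fraction of cells is then
#' masked to `N`, emulating low-coverage missing data within otherwise
#' captured sequences.
#'
#' @param gene_tree A `phylo` with branch lengths (coalescent units).
#' @param n_sites Alignment length in bp.
#' @param subst_rate Expected substitutions per site per coalescent unit.
#' @param missing_prob Per-cell probability of masking to `N`.
#' @param locus_id Identifier for the resulting alignment.
#' @return A [locus_alignment()].
#' @export
sim_alignment <- function(gene_tree, n_sites, subst_rate = 0.01,
                          missing_prob = 0.05, locus_id = "locus") {
  .assert_phylo(gene_tree, "gene_tree")
  if (is.null(gene_tree$edge.length)) {
    stop("gene tree has no branch lengths", call. = FALSE)
  }
  if (n_sites < 1L) stop("`n_sites` must be >= 1", call. = FALSE)
  tr <- gene_tree
  tr$edge.length <- tr$edge.length * subst_rate
  sim <- phangorn::simSeq(tr, l = n_sites, type = "DNA")
  m <- toupper(as.character(sim))
  if (missing_prob > 0) {
    mask <- matrix(stats::runif(length(m)) < missing_prob, nrow = nrow(m))
    m[mask] <- "N"
  }
  locus_alignment(m, locus_id = locus_id)
}

#' Ladder (pectinate) chronogram with chosen internal branch durations
#'
#' A convenient deterministic species chronogram: taxa peel off one by one,
#' and the durations of the successive internal branches are set directly.
#' Useful for placing internal branches at chosen coalescent-unit lengths
#' when studying how congruence decays on short branches.
#'
#' @param n_taxa Number of leaves (>= 3).
#' @param durations Internal branch durations, from the innermost cherry
#'   outward; length `n_taxa - 2`.  Default: log-spaced between 0.2 and 5.
#' @param tip_branch Age of the innermost cherry node (the shallowest
#'   divergence).
#' @param labels Tip labels; default `t01`, `t02`, ...
#' @return A rooted ultrametric `phylo`.
#' @examples
#' pectinate_chronogram(4, durations = c(1, 1))
#' @export
pectinate_chronogram <- function(n_taxa = 12,
                                 durations = NULL,
                                 tip_branch = 1,
                                 labels = sprintf("t%02d", seq_len(n_taxa))) {
  if (n_taxa < 3L) stop("`n_taxa` must be >= 3", call. = FALSE)
  n_int <- n_taxa - 2L
  if (is.null(durations)) {
    durations <- exp(seq(log(0.2), log(5), length.out = n_int))
  }
  if (length(durations) != n_int) {
    stop("`durations` must have length n_taxa - 2 = ", n_int, call. = FALSE)
  }
  if (any(durations < 0)) stop("durations must be >= 0", call. = FALSE)
  labs <- .quote_label(labels)
  age <- tip_branch
  nwk <- sprintf("(%s:%.12g,%s:%.12g)", labs[1L], age, labs[2L], age)
  for (k in seq_len(n_int)) {
    new_age <- age + durations[k]
    nwk <- sprintf("(%s:%.12g,%s:%.12g)", nwk, durations[k], labs[k + 2L], new_age)
    age <- new_age
  }
  ape::read.tree(text = paste0(nwk, ";"))
}

.write_fasta <- function(aln, path) {
  m <- aln$matrix
  lines <- character(2L * nrow(m))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(m))
  lines[c(FALSE, TRUE)] <- apply(m, 1L, paste, collapse = "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Generate a complete synthetic phylogenomic dataset
#'
#' Writes, under `out_dir`: the species chronogram (`chronogram.nwk`),
#' per-locus gene trees (`gene_trees/locusNNNN.nwk`), per-locus FASTA
#' alignments (`alignments/locusNNNN.fasta`), a locus manifest
#' (`manifest.tsv`: id, class, status, taxa, length, per-locus seed) and a
#' parameter log (`params.json`).  Loci reduced below `min_taxa` by dropout
#' are listed as `discarded` in the manifest and produce no files.
#'
#' Defaults emulate a targeted sequence-capture study: 585 loci split
#' roughly 541:44 between a `uce` and a `coding` class, per-locus taxon
#' retention 121/131, UCE lengths 284-713 bp and protein-coding lengths
#' 355-664 bp (uniform draws), with the coding class evolving twice as
#' fast.
#'
#' Reproducibility: the root `seed` draws one sub-seed per locus, and each
#' locus is simulated entirely under its own sub-seed, so any locus can be
#' regenerated in isolation and a fixed seed fixes every output byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_loci Number of loci.
#' @param chronogram Species chronogram; default a 12-taxon
#'   [pectinate_chronogram()] with internal branches log-spaced over 0.2-5
#'   coalescent units.
#' @param scale Chronogram-to-coalescent-unit conversion factor.
#' @param retention_prob,min_taxa Passed to [apply_dropout()].
#' @param prop_uce Proportion of loci in the `uce` class.
#' @param uce_length_range,coding_length_range Alignment length ranges (bp).
#' @param subst_rate_uce,subst_rate_coding Substitution rates per
#'   coalescent unit for the two classes.
#' @param missing_prob Per-cell `N`-masking probability.
#' @param seed Root integer seed.
#' @return The manifest tibble, invisibly.
#' @export
make_fixture_dataset <- function(out_dir,
                                 n_loci = 585,
                                 chronogram = NULL,
                                 scale = 1,
                                 retention_prob = 121 / 131,
                                 min_taxa = 4,
                                 prop_uce = 541 / 585,
                                 uce_length_range = c(284, 713),
                                 coding_length_range = c(355, 664),
                                 subst_rate_uce = 0.01,
                                 subst_rate_coding = 0.02,
                                 missing_prob = 0.05,
                                 seed = 1) {
  if (n_loci < 1L) stop("`n_loci` must be >= 1", call. = FALSE)
  if (is.null(chronogram)) chronogram <- pectinate_chronogram(12)
  .validate_chronogram(chronogram)
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir, call. = FALSE)
  dir.create(file.path(out_dir, "gene_trees"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "alignments"), showWarnings = FALSE)

  set.seed(seed)
  locus_seeds <- sample.int(2147483646L, n_loci)
  n_uce <- round(n_loci * prop_uce)
  classes <- sample(c(rep("uce", n_uce), rep("coding", n_loci - n_uce)))

  write_newick(chronogram, file.path(out_dir, "chronogram.nwk"))

  rows <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    id <- sprintf("locus%04d", i)
    set.seed(locus_seeds[i])
    gt <- sim_gene_tree(chronogram, scale = scale)
    kept <- apply_dropout(gt, retention_prob, min_taxa = min_taxa)
    if (is.null(kept)) {
      rows[[i]] <- tibble::tibble(locus_id = id, class = classes[i],
                                  status = "discarded", n_taxa = NA_integer_,
                                  length = NA_integer_, seed = locus_seeds[i])
      next
    }
    rng <- if (classes[i] == "uce") uce_length_range else coding_length_range
    rate <- if (classes[i] == "uce") subst_rate_uce else subst_rate_coding
    len <- sample.int(rng[2L] - rng[1L] + 1L, 1L) + rng[1L] - 1L
    aln <- sim_alignment(kept, len, subst_rate = rate,
                         missing_prob = missing_prob, locus_id = id)
    write_newick(kept, file.path(out_dir, "gene_trees", paste0(id, ".nwk")))
    .write_fasta(aln, file.path(out_dir, "alignments", paste0(id, ".fasta")))
    rows[[i]] <- tibble::tibble(locus_id = id, class = classes[i],
                                status = "kept", n_taxa = length(kept$tip.label),
                                length = len, seed = locus_seeds[i])
  }
  manifest <- dplyr::bind_rows(rows)
  write_tsv_plain(manifest, file.path(out_dir, "manifest.tsv"))
  params <- list(
    n_loci = n_loci, scale = scale, retention_prob = retention_prob,
    min_taxa = min_taxa, prop_uce = prop_uce,
    uce_length_range = uce_length_range,
    coding_length_range = coding_length_range,
    subst_rate_uce = subst_rate_uce, subst_rate_coding = subst_rate_coding,
    missing_prob = missing_prob, seed = seed,
    seed_derivation = "set.seed(seed); locus_seeds <- sample.int(2147483646L, n_loci); locus i simulated under set.seed(locus_seeds[i])"
  )
  jsonlite::write_json(params, file.path(out_dir, "params.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
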