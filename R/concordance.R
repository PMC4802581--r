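#' Prune a monophyly constraint to the taxa present in a gene tree
#'
#' Gene trees from sequence capture usually miss taxa, so a reference
#' bipartition cannot be tested verbatim: each side is first intersected
#' with the taxa the gene tree actually contains.  When either restricted
#' side keeps fewer than two taxa the constraint is trivial — every tree on
#' those taxa satisfies it vacuously — and no support test is possible.
#'
#' @param bip A [bipartition()].
#' @param present Character vector of taxon labels present in the gene tree.
#' @return A list of class `pruned_constraint` with elements `original`,
#'   `restricted` (a `bipartition`, or `NULL` when trivial), `trivial`
#'   (logical) and `taxa_removed`.
#' @examples
#' prune_constraint(bipartition(c("A", "B", "E"), c("C", "D")),
#'                  c("A", "B", "C", "D"))
#' @export
prune_constraint <- function(bip, present) {
  if (!inherits(bip, "bipartition")) {
    stop("`bip` must be a bipartition object", call. = FALSE)
  }
  present <- .norm_label(as.character(present))
  if (length(present) == 0L) stop("`present` must be non-empty", call. = FALSE)
  a <- intersect(bip$side_a, present)
  b <- intersect(bip$side_b, present)
  removed <- setdiff(c(bip$side_a, bip$side_b), present)
  trivial <- length(a) < 2L || length(b) < 2L
  structure(
    list(
      original = bip,
      restricted = if (trivial) NULL else bipartition(a, b),
      trivial = trivial,
      taxa_removed = sort(removed)
    ),
    class = "pruned_constraint"
  )
}

#' Does a gene tree support a taxon bipartition?
#'
#' The reference bipartition is pruned to the gene tree's taxa
#' ([prune_constraint()]), then tested against the gene tree taken as
#' unrooted.  Under the default hard-constraint semantics the verdict is
#' `"supports"` only when the restricted split is literally among the gene
#' tree's splits; a polytomy that merely fails to resolve the split counts
#' as `"conflicts_or_unresolved"`, mirroring monophyly-constraint filtering
#' on the resolved tree.  The soft mode instead asks whether the restricted
#' split is compatible with every split of the gene tree, for sensitivity
#' analysis.
#'
#' @param gene_tree A `phylo`; its leaf labels must be a subset of the full
#'   taxon set the bipartition was defined on.
#' @param bip A [bipartition()].
#' @param mode `"hard"` (exact split presence, default) or `"soft"`
#'   (compatibility).
#' @return One of `"supports"`, `"conflicts_or_unresolved"`, `"trivial"`.
#' @examples
#' gt <- read_newick(text = "((A,B),(C,D));")
#' gene_tree_supports(gt, bipartition(c("A", "B"), c("C", "D")))
#' @export
gene_tree_supports <- function(gene_tree, bip, mode = c("hard", "soft")) {
  mode <- match.arg(mode)
  .assert_phylo(gene_tree, "gene_tree")
  pc <- prune_constraint(bip, gene_tree$tip.label)
  if (pc$trivial) return("trivial")
  if (mode == "hard") {
    if (pc$restricted$key %in% .split_keys(gene_tree)) "supports"
    else "conflicts_or_unresolved"
  } else {
    splits <- tree_bipartitions(gene_tree)
    ok <- all(vapply(seq_len(nrow(splits)), function(i) {
      .splits_compatible(pc$restricted$side_a, pc$restricted$side_b,
                         splits$clade[[i]], splits$rest[[i]])
    }, logical(1)))
    if (ok) "supports" else "conflicts_or_unresolved"
  }
}

.as_bip_list <- function(bips) {
  if (inherits(bips, "bipartition")) return(list(bips))
  if (is.data.frame(bips)) {
    if (!all(c("clade", "rest") %in% names(bips))) {
      stop("bipartition data frame needs `clade` and `rest` list columns ",
           "(as returned by tree_bipartitions())", call. = FALSE)
    }
    return(purrr::map2(bips$clade, bips$rest, bipartition))
  }
  if (is.list(bips) && all(vapply(bips, inherits, logical(1), "bipartition"))) {
    return(bips)
  }
  stop("`bips` must be a bipartition, a list of bipartitions, or a ",
       "tree_bipartitions() tibble", call. = FALSE)
}

#' Tally gene-tree support for reference bipartitions
#'
#' Applies [gene_tree_supports()] for every (gene tree, bipartition) pair
#' and tallies the verdicts per bipartition.  The denominator is always the
#' full number of gene trees supplied, so fractions are comparable across
#' bipartitions even when many loci are trivial for some of them (the
#' per-row counts let you recompute any other rate).
#'
#' Trivial verdicts arise when pruning leaves fewer than two taxa on a side.
#' Under the default policy `"count_as_support"` they count toward the
#' supporting fraction, replicating the vacuous satisfaction of a one-taxon
#' monophyly constraint; `"exclude"` counts strict support only.
#'
#' @param gene_trees A list of `phylo` objects (or a `multiPhylo`).
#' @param bips Reference bipartitions: a [tree_bipartitions()] tibble, a
#'   list of [bipartition()]s, or a single bipartition.
#' @param trivial_policy `"count_as_support"` (default) or `"exclude"`.
#' @param mode Passed to [gene_tree_supports()].
#' @return A tibble of class `tbl_congruence` with one row per bipartition:
#'   `bipartition_id`, `clade` (list column), `clade_taxa` (collapsed
#'   label), `n_support`, `n_trivial`, `n_other`, `denominator`, `fraction`
#'   and `key`.  Rows satisfy
#'   `n_support + n_trivial + n_other == denominator`.
#' @examples
#' gts <- lapply(c("((A,B),(C,D));", "((A,C),(B,D));"),
#'               function(s) read_newick(text = s))
#' sp <- read_newick(text = "((A,B),(C,D));")
#' tally_congruence(gts, tree_bipartitions(sp))
#' @export
tally_congruence <- function(gene_trees, bips,
                             trivial_policy = c("count_as_support", "exclude"),
                             mode = c("hard", "soft")) {
  trivial_policy <- match.arg(trivial_policy)
  mode <- match.arg(mode)
  if (.is_phylo(gene_trees)) gene_trees <- list(gene_trees)
  gene_trees <- unclass(gene_trees)
  if (length(gene_trees) == 0L) stop("empty gene-tree list", call. = FALSE)
  lapply(gene_trees, .assert_phylo, arg = "gene_trees[[i]]")
  bip_list <- .as_bip_list(bips)
  if (length(bip_list) == 0L) stop("no bipartitions to tally", call. = FALSE)

  # each gene tree's split keys and taxon set are reused across bipartitions
  gt_keys <- lapply(gene_trees, .split_keys)
  gt_taxa <- lapply(gene_trees, function(t) t$tip.label)
  gt_splits <- if (mode == "soft") lapply(gene_trees, tree_bipartitions) else NULL

  denom <- length(gene_trees)
  rows <- purrr::imap(bip_list, function(bip, i) {
    n_sup <- 0L; n_triv <- 0L; n_oth <- 0L
    for (g in seq_len(denom)) {
      pc <- prune_constraint(bip, gt_taxa[[g]])
      if (pc$trivial) {
        n_triv <- n_triv + 1L
      } else if (mode == "hard") {
        if (pc$restricted$key %in% gt_keys[[g]]) n_sup <- n_sup + 1L
        else n_oth <- n_oth + 1L
      } else {
        sp <- gt_splits[[g]]
        ok <- all(vapply(seq_len(nrow(sp)), function(j) {
          .splits_compatible(pc$restricted$side_a, pc$restricted$side_b,
                             sp$clade[[j]], sp$rest[[j]])
        }, logical(1)))
        if (ok) n_sup <- n_sup + 1L else n_oth <- n_oth + 1L
      }
    }
    numer <- if (trivial_policy == "count_as_support") n_sup + n_triv else n_sup
    tibble::tibble(
      bipartition_id = sprintf("b%03d", i),
      clade = list(bip$side_a),
      clade_taxa = paste(bip$side_a, collapse = ";"),
      n_support = n_sup,
      n_trivial = n_triv,
      n_other = n_oth,
      denominator = denom,
      fraction = numer / denom,
      key = bip$key
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "trivial_policy") <- trivial_policy
  attr(out, "mode") <- mode
  class(out) <- c("tbl_congruence", class(out))
  out
}

#' Join branch durations onto a congruence table
#'
#' Matches each tallied bipartition against the branches of a chronogram
#' (same split of the full taxon set) and attaches the branch duration.
#' Bipartitions with no matching chronogram branch are kept with `NA`
#' duration; their count is reported in a warning and stored in the
#' `n_unmatched` attribute.
#'
#' When the chronogram root is a dichotomy, its two child branches subtend
#' complementary clades and therefore carry the same bipartition; they are
#' the two halves of a single unrooted edge, so their durations are summed
#' for that split.
#'
#' @param table A `tbl_congruence` from [tally_congruence()].
#' @param chronogram A rooted ultrametric `phylo` (ages in Ma), or a
#'   precomputed [branch_durations()] tibble.
#' @param include_tips Passed to [branch_durations()] when a tree is given.
#' @return The table with a `duration` column (Ma).
#' @export
add_branch_durations <- function(table, chronogram, include_tips = FALSE) {
  if (!is.data.frame(table) || !"key" %in% names(table)) {
    stop("`table` must be a congruence table with a `key` column", call. = FALSE)
  }
  durs <- if (is.data.frame(chronogram)) chronogram
          else branch_durations(chronogram, include_tips = include_tips)
  durs <- durs |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(duration = sum(.data$duration), .groups = "drop")
  out <- dplyr::left_join(table, durs, by = "key")
  n_un <- sum(is.na(out$duration))
  if (n_un > 0L) {
    warning(n_un, " bipartition(s) matched no chronogram branch; duration set to NA",
            call. = FALSE)
  }
  attr(out, "n_unmatched") <- n_un
  attr(out, "trivial_policy") <- attr(table, "trivial_policy")
  attr(out, "mode") <- attr(table, "mode")
  class(out) <- unique(c("tbl_congruence", class(out)))
  out
}
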