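# High-level runners tying the stages together; these back the `congrue`
# command-line script (exec/congrue) with subcommands profile, concordance
# and simulate.

.write_config <- function(out_dir, config) {
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

.read_gene_trees <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(nwk|newick|tre|tree)$",
                             full.names = TRUE))
    if (length(files) == 0L) stop("no newick files in ", path, call. = FALSE)
    trees <- lapply(files, function(f) {
      t <- read_newick(file = f)
      if (inherits(t, "multiPhylo")) stop("expected one tree per file: ", f,
                                          call. = FALSE)
      t
    })
  } else {
    t <- read_newick(file = path)
    trees <- if (.is_phylo(t)) list(t) else unclass(t)
  }
  class(trees) <- "multiPhylo"
  trees
}

#' Run the locus-profiling stage
#'
#' Reads every alignment in a directory, profiles each locus, summarizes
#' per locus class, and fits the length-vs-informative-sites regression.
#' With `out_dir` set, writes `locus_profiles.tsv`, `profile_summary.tsv`,
#' `length_pic_fit.tsv` and the resolved `config.json`.
#'
#' @param alignment_dir Directory of per-locus alignments.
#' @param out_dir Optional output directory.
#' @param format Passed to [read_alignment()].
#' @param classes Optional locus-class manifest: a data frame or TSV path
#'   with columns `locus_id`, `class`.
#' @param variation_denominator Passed to [profile_locus()].
#' @param quiet Suppress progress messages.
#' @return A list with `profiles`, `summary` and `fit` (the latter `NULL`
#'   when the regression is not estimable), invisibly.
#' @export
run_profile <- function(alignment_dir, out_dir = NULL, format = "auto",
                        classes = NULL,
                        variation_denominator = c("length", "scored_columns"),
                        quiet = FALSE) {
  variation_denominator <- match.arg(variation_denominator)
  if (!dir.exists(alignment_dir)) {
    stop("alignment directory not found: ", alignment_dir, call. = FALSE)
  }
  if (is.character(classes)) {
    classes <- utils::read.delim(classes, sep = "\t", stringsAsFactors = FALSE)
  }
  profiles <- profile_loci(alignment_dir, format = format,
                           variation_denominator = variation_denominator)
  if (!quiet) message("profiled ", nrow(profiles), " loci")
  summary <- summarize_profiles(profiles, classes = classes)
  fit <- tryCatch(length_vs_informative(profiles), error = function(e) {
    warning("length-vs-PIC regression not estimable: ", conditionMessage(e),
            call. = FALSE)
    NULL
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_plain(profiles, file.path(out_dir, "locus_profiles.tsv"))
    write_tsv_plain(summary, file.path(out_dir, "profile_summary.tsv"))
    if (!is.null(fit)) {
      write_tsv_plain(cbind(glance(fit),
                            slope = fit$slope, intercept = fit$intercept),
                      file.path(out_dir, "length_pic_fit.tsv"))
    }
    .write_config(out_dir, list(
      subcommand = "profile", alignment_dir = alignment_dir,
      format = format, variation_denominator = variation_denominator
    ))
  }
  invisible(list(profiles = profiles, summary = summary, fit = fit))
}

#' Run the gene-tree concordance stage
#'
#' Extracts the reference bipartitions of a species tree, tallies how many
#' gene trees support each (with missing-taxon-aware constraint pruning),
#' joins chronogram branch durations when available, and fits the
#' congruence-versus-duration regression.  With `out_dir` set, writes
#' `congruence.tsv`, `duration_fit.tsv` (when fitted) and `config.json`.
#'
#' @param gene_trees Directory of per-locus newick files, or one
#'   multi-tree newick file, or a list of `phylo` objects.
#' @param species_tree Path to the reference species tree, or a `phylo`.
#' @param chronogram Optional path to an ultrametric chronogram (ages in
#'   Ma), or a `phylo`; enables durations and the regression.
#' @param out_dir Optional output directory.
#' @param trivial_policy,mode Passed to [tally_congruence()].
#' @param include_tips Passed to [branch_durations()].
#' @param response Passed to [congruence_duration_fit()].
#' @param min_side Passed to [tree_bipartitions()].
#' @param quiet Suppress progress messages.
#' @return A list with `table` (a `tbl_congruence`) and `fit`, invisibly.
#' @export
run_concordance <- function(gene_trees, species_tree, chronogram = NULL,
                            out_dir = NULL,
                            trivial_policy = c("count_as_support", "exclude"),
                            mode = c("hard", "soft"),
                            include_tips = FALSE,
                            response = c("n_support", "fraction"),
                            min_side = 2, quiet = FALSE) {
  trivial_policy <- match.arg(trivial_policy)
  mode <- match.arg(mode)
  response <- match.arg(response)
  if (is.character(gene_trees)) gene_trees <- .read_gene_trees(gene_trees)
  if (.is_phylo(gene_trees)) gene_trees <- structure(list(gene_trees),
                                                     class = "multiPhylo")
  if (is.character(species_tree)) species_tree <- read_newick(file = species_tree)
  .assert_phylo(species_tree, "species_tree")
  sp_taxa <- .norm_label(species_tree$tip.label)
  offenders <- sort(unique(unlist(lapply(gene_trees, function(t) {
    setdiff(.norm_label(t$tip.label), sp_taxa)
  }))))
  if (length(offenders) > 0L) {
    stop("gene-tree taxa absent from the species tree: ",
         .fmt_labels(offenders), call. = FALSE)
  }
  bips <- tree_bipartitions(species_tree, min_side = min_side)
  if (nrow(bips) == 0L) stop("species tree has no non-trivial bipartitions",
                             call. = FALSE)
  if (!quiet) {
    message("tallying ", nrow(bips), " bipartitions over ",
            length(gene_trees), " gene trees")
  }
  table <- tally_congruence(gene_trees, bips,
                            trivial_policy = trivial_policy, mode = mode)
  fit <- NULL
  if (!is.null(chronogram)) {
    if (is.character(chronogram)) chronogram <- read_newick(file = chronogram)
    table <- add_branch_durations(table, chronogram, include_tips = include_tips)
    fit <- tryCatch(congruence_duration_fit(table, response = response),
                    error = function(e) {
                      warning("duration regression not estimable: ",
                              conditionMessage(e), call. = FALSE)
                      NULL
                    })
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    # the canonical key embeds tabs; keep the TSV to display columns
    out_tab <- dplyr::select(as.data.frame(table),
                             -dplyr::any_of(c("clade", "key")))
    names(out_tab)[names(out_tab) == "duration"] <- "duration_ma"
    write_tsv_plain(out_tab, file.path(out_dir, "congruence.tsv"))
    if (!is.null(fit)) {
      write_tsv_plain(cbind(glance(fit),
                            slope = fit$slope, intercept = fit$intercept,
                            response = response),
                      file.path(out_dir, "duration_fit.tsv"))
    }
    .write_config(out_dir, list(
      subcommand = "concordance", trivial_policy = trivial_policy,
      mode = mode, include_tips = include_tips, response = response,
      min_side = min_side, n_gene_trees = length(gene_trees)
    ))
  }
  invisible(list(table = table, fit = fit))
}

#' Run the synthetic-data stage
#'
#' Thin wrapper over [make_fixture_dataset()] that also records the
#' resolved configuration.
#'
#' @param out_dir Output directory.
#' @param ... Passed to [make_fixture_dataset()].
#' @param quiet Suppress the manifest-path message.
#' @return The manifest tibble, invisibly.
#' @export
run_simulate <- function(out_dir, ..., quiet = FALSE) {
  manifest <- make_fixture_dataset(out_dir, ...)
  if (!quiet) message("wrote fixture dataset manifest: ",
                      file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}
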