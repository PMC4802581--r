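#' Read Newick trees
#'
#' Parses one or more Newick statements from a file or a string into
#' [ape::phylo] objects.  Bracketed comments (`[...]`) are stripped, quoted
#' labels are supported (the quotes are removed and `''` unescaped), and the
#' tree is validated: duplicate or empty leaf labels and unbalanced
#' parentheses are errors.  Underscores in labels are taken literally, never
#' turned into spaces.
#'
#' @param file Path to a plain-text Newick file (one or more trees, each
#'   terminated by `;`).  Mutually exclusive with `text`.
#' @param text A character scalar holding Newick statement(s).
#' @return A `phylo` object, or a `multiPhylo` list when the input holds
#'   more than one tree.
#' @examples
#' read_newick(text = "((A:1,B:1):0.5,C:1.5);")
#' @seealso [write_newick()], [tree_bipartitions()]
#' @export
read_newick <- function(file = NULL, text = NULL) {
  if (is.null(text) == is.null(file)) {
    stop("supply exactly one of `file` or `text`", call. = FALSE)
  }
  if (!is.null(file)) {
    if (!file.exists(file)) stop("no such file: ", file, call. = FALSE)
    text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  }
  text <- .strip_newick_comments(text)
  .check_balance(text)
  # split on statement-terminating semicolons (quotes already cannot hide
  # semicolons after the scanner pass below marks them)
  stmts <- .split_statements(text)
  if (length(stmts) == 0L) stop("no newick statement found", call. = FALSE)
  trees <- lapply(stmts, .parse_one_newick)
  if (length(trees) == 1L) return(trees[[1L]])
  class(trees) <- "multiPhylo"
  trees
}

# remove [...] comments (nesting allowed) outside of quoted labels
.strip_newick_comments <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  out <- character(0)
  depth <- 0L
  in_quote <- FALSE
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (in_quote) {
      out <- c(out, ch)
      if (ch == "'") {
        if (i < n && chars[i + 1L] == "'") {  # escaped quote
          out <- c(out, "'"); i <- i + 1L
        } else {
          in_quote <- FALSE
        }
      }
    } else if (depth > 0L) {
      if (ch == "[") depth <- depth + 1L
      if (ch == "]") depth <- depth - 1L
    } else if (ch == "[") {
      depth <- 1L
    } else {
      if (ch == "'") in_quote <- TRUE
      out <- c(out, ch)
    }
    i <- i + 1L
  }
  if (depth > 0L) stop("unterminated '[' comment in newick input", call. = FALSE)
  paste(out, collapse = "")
}

.check_balance <- function(text) {
  chars <- strsplit(gsub("'[^']*'", "", text), "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("unbalanced parentheses: unmatched ')' at position ", i,
             call. = FALSE)
      }
    }
  }
  if (depth > 0L) {
    stop("unbalanced parentheses: ", depth, " unclosed '(' in newick input",
         call. = FALSE)
  }
  invisible(TRUE)
}

.split_statements <- function(text) {
  stmts <- strsplit(text, ";", fixed = TRUE)[[1L]]
  stmts <- trimws(stmts)
  stmts <- stmts[nzchar(stmts)]
  paste0(stmts, ";")
}

# replace quoted labels by placeholders so the parser cannot mangle their
# contents (spaces, punctuation, escaped quotes)
.protect_quotes <- function(stmt) {
  chars <- strsplit(stmt, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  out <- character(0)
  labels <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "'") {
      lab <- character(0)
      i <- i + 1L
      repeat {
        if (i > n) stop("unterminated quoted label in newick input", call. = FALSE)
        if (chars[i] == "'") {
          if (i < n && chars[i + 1L] == "'") {
            lab <- c(lab, "'"); i <- i + 2L
          } else {
            i <- i + 1L; break
          }
        } else {
          lab <- c(lab, chars[i]); i <- i + 1L
        }
      }
      labels <- c(labels, paste(lab, collapse = ""))
      out <- c(out, sprintf("xQx%dxQx", length(labels)))
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  list(text = paste(out, collapse = ""), labels = labels)
}

.restore_quotes <- function(x, labels) {
  m <- regmatches(x, regexec("^xQx([0-9]+)xQx$", x))
  idx <- vapply(m, function(g) if (length(g) == 2L) as.integer(g[2L]) else NA_integer_,
                integer(1))
  x[!is.na(idx)] <- labels[idx[!is.na(idx)]]
  x
}

.parse_one_newick <- function(stmt) {
  prot <- .protect_quotes(stmt)
  tree <- tryCatch(
    ape::read.tree(text = prot$text),
    error = function(e) NULL
  )
  if (is.null(tree)) {
    stop("newick parse error in statement: ", substr(stmt, 1, 60), call. = FALSE)
  }
  tree$tip.label <- .restore_quotes(tree$tip.label, prot$labels)
  if (!is.null(tree$node.label)) {
    tree$node.label <- .restore_quotes(tree$node.label, prot$labels)
  }
  bad <- !nzchar(.norm_label(tree$tip.label))
  if (any(bad)) {
    stop("empty leaf label at tip position ", .fmt_labels(which(bad)),
         call. = FALSE)
  }
  norm <- .norm_label(tree$tip.label)
  if (anyDuplicated(norm)) {
    stop("duplicate leaf labels: ",
         .fmt_labels(unique(norm[duplicated(norm)])), call. = FALSE)
  }
  if (!is.null(tree$edge.length)) {
    if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
      stop("edge lengths must be finite and >= 0", call. = FALSE)
    }
  }
  tree
}

.quote_label <- function(x) {
  needs <- grepl("[][ \t\n(),:;']", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Write a tree as a Newick string
#'
#' The inverse of [read_newick()]: topology, labels and edge lengths round
#' trip (lengths to well below 1e-9 relative error).  Labels containing
#' spaces, quotes or Newick punctuation are quoted.
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when given the string is written there
#'   (UTF-8, `\n` newline) and returned invisibly.
#' @param digits Significant digits used for edge lengths.
#' @return The Newick string (invisibly when `file` is given).
#' @export
write_newick <- function(tree, file = NULL, digits = 15) {
  .assert_phylo(tree)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  lab_tip <- .quote_label(tree$tip.label)
  lab_node <- if (is.null(tree$node.label)) character(0) else .quote_label(tree$node.label)
  fmt <- paste0("%.", digits, "g")
  fmt_len <- function(e) {
    if (is.null(tree$edge.length)) "" else
      paste0(":", sprintf(fmt, tree$edge.length[e]))
  }
  rec <- function(node) {
    if (node <= ntip) return(lab_tip[node])
    parts <- vapply(kids[[as.character(node)]], function(e) {
      paste0(rec(tree$edge[e, 2L]), fmt_len(e))
    }, character(1))
    nl <- if (length(lab_node) >= node - ntip) lab_node[node - ntip] else ""
    paste0("(", paste(parts, collapse = ","), ")", nl)
  }
  out <- paste0(rec(root), ";")
  if (!is.null(file)) {
    writeLines(out, file, useBytes = TRUE)
    return(invisible(out))
  }
  out
}

# tip-label sets descending from every node, in one postorder pass
.tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  sets <- vector("list", nn)
  sets[seq_len(ntip)] <- as.list(tree$tip.label)
  ord <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(ord$edge))) {
    p <- ord$edge[i, 1L]; ch <- ord$edge[i, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

#' Extract the taxon bipartitions of a tree
#'
#' Returns one bipartition per internal edge of the unrooted form of the
#' tree, as a tibble.  Rooting is ignored: gene trees from single-locus
#' analyses carry arbitrary roots, so all split work treats trees as
#' unrooted.  Splits with either side smaller than `min_side` are excluded
#' (with the default 2 this drops the trivial leaf splits); a fully binary
#' unrooted tree on n leaves yields exactly n - 3 rows.
#'
#' @param tree A `phylo` object.
#' @param min_side Minimum taxa allowed on each side of a reported split.
#' @return A tibble with columns `clade` (list of labels on the smaller,
#'   reported side as stored), `rest` (the complement), `n_clade`, `n_rest`
#'   and the canonical `key` used for split identity.
#' @examples
#' tree_bipartitions(read_newick(text = "((A,B),(C,D));"))
#' @export
tree_bipartitions <- function(tree, min_side = 2) {
  .assert_phylo(tree)
  taxa <- tree$tip.label
  ntip <- length(taxa)
  empty <- tibble::tibble(clade = list(), rest = list(),
                          n_clade = integer(0), n_rest = integer(0),
                          key = character(0))
  if (ntip < 4L) return(empty)
  sets <- .tip_sets(tree)
  root <- ntip + 1L
  internal <- setdiff(seq.int(ntip + 1L, ntip + tree$Nnode), root)
  if (length(internal) == 0L) return(empty)
  rows <- lapply(internal, function(nd) {
    cl <- sets[[nd]]
    rs <- setdiff(taxa, cl)
    if (length(cl) < min_side || length(rs) < min_side) return(NULL)
    key <- .split_key(cl, taxa)
    tibble::tibble(clade = list(sort(cl)), rest = list(sort(rs)),
                   n_clade = length(cl), n_rest = length(rs),
                   key = key)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) return(empty)
  # a root with two children produces the same split from both sides
  dplyr::distinct(out, .data$key, .keep_all = TRUE)
}

# internal: the set of split keys displayed by a tree (unrooted view);
# lean path used in tight tally loops, equivalent to tree_bipartitions()$key
.split_keys <- function(tree, min_side = 2) {
  taxa <- tree$tip.label
  ntip <- length(taxa)
  if (ntip < 4L) return(character(0))
  sets <- .tip_sets(tree)
  root <- ntip + 1L
  internal <- setdiff(seq.int(ntip + 1L, ntip + tree$Nnode), root)
  keys <- character(0)
  for (nd in internal) {
    cl <- sets[[nd]]
    if (length(cl) < min_side || ntip - length(cl) < min_side) next
    keys[length(keys) + 1L] <- .split_key(cl, taxa)
  }
  unique(keys)
}

.validate_chronogram <- function(chronogram, tol = 1e-6) {
  .assert_phylo(chronogram, "chronogram")
  if (is.null(chronogram$edge.length)) {
    stop("chronogram has no edge lengths", call. = FALSE)
  }
  if (!ape::is.rooted(chronogram)) {
    stop("chronogram must be rooted", call. = FALSE)
  }
  invisible(chronogram)
}

#' Node ages of a chronogram
#'
#' Ages are measured backwards in time (typically Ma): leaves sit at 0 and
#' ages increase toward the root.  The tree must be ultrametric within
#' `tol`, a relative tolerance on the root age; otherwise the worst
#' leaf pair is reported in the error.
#'
#' @param chronogram A rooted `phylo` with edge lengths in time units.
#' @param tol Relative ultrametricity tolerance (fraction of root age).
#' @return A tibble with columns `node`, `age`, `is_tip`, `label`.
#' @examples
#' node_ages(read_newick(text = "((A:10,B:10):15,C:25);"))
#' @export
node_ages <- function(chronogram, tol = 1e-6) {
  .validate_chronogram(chronogram, tol)
  ntip <- length(chronogram$tip.label)
  depth <- ape::node.depth.edgelength(chronogram)
  root_age <- max(depth[seq_len(ntip)])
  tip_depth <- depth[seq_len(ntip)]
  if (root_age > 0) {
    spread <- max(tip_depth) - min(tip_depth)
    if (spread > tol * root_age) {
      hi <- which.max(tip_depth); lo <- which.min(tip_depth)
      stop("tree is not ultrametric within tolerance: leaves '",
           chronogram$tip.label[hi], "' (depth ", format(tip_depth[hi]),
           ") and '", chronogram$tip.label[lo], "' (depth ",
           format(tip_depth[lo]), ") differ by ", format(spread),
           call. = FALSE)
    }
  }
  age <- root_age - depth
  age[seq_len(ntip)] <- 0
  nn <- ntip + chronogram$Nnode
  tibble::tibble(
    node = seq_len(nn),
    age = age,
    is_tip = seq_len(nn) <= ntip,
    label = c(chronogram$tip.label,
              if (is.null(chronogram$node.label)) rep(NA_character_, chronogram$Nnode)
              else chronogram$node.label)
  )
}

#' Branch durations of a chronogram
#'
#' One row per non-root branch, identified by the clade it subtends: the
#' duration is the parent age minus the child age, i.e. how long the branch
#' persisted before the next divergence.  The root has no parent branch and
#' never appears.
#'
#' @inheritParams node_ages
#' @param include_tips Include terminal (leaf) branches?  Terminal branches
#'   subtend single-taxon clades, which never form non-trivial splits, so
#'   the default keeps internal branches only.
#' @return A tibble with columns `clade` (list of subtended taxon labels),
#'   `key` (canonical split key against the full taxon set), `duration`,
#'   `age` (of the child node) and `parent_age`.
#' @examples
#' branch_durations(read_newick(text = "((A:10,B:10):15,C:25);"))
#' @export
branch_durations <- function(chronogram, include_tips = FALSE, tol = 1e-6) {
  ages <- node_ages(chronogram, tol = tol)
  ntip <- length(chronogram$tip.label)
  taxa <- chronogram$tip.label
  sets <- .tip_sets(chronogram)
  edge <- chronogram$edge
  keep <- if (include_tips) rep(TRUE, nrow(edge)) else edge[, 2L] > ntip
  child <- edge[keep, 2L]
  parent <- edge[keep, 1L]
  dur <- ages$age[parent] - ages$age[child]
  if (any(dur <= 0)) {
    stop("non-positive branch duration in chronogram (parent age must exceed child age)",
         call. = FALSE)
  }
  tibble::tibble(
    clade = lapply(sets[child], sort),
    key = vapply(sets[child], .split_key, character(1), taxa = taxa),
    duration = dur,
    age = ages$age[child],
    parent_age = ages$age[parent]
  )
}
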