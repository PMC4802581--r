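#' Taxon bipartitions
#'
#' A bipartition (split) divides a taxon set into two disjoint, non-empty
#' blocks; it is the unrooted analogue of a clade and the unit of gene-tree
#' support.  Equality is orientation-free: `bipartition(A, B)` equals
#' `bipartition(B, A)`.
#'
#' Labels are whitespace-normalized before comparison; duplicate or
#' overlapping labels are rejected.
#'
#' @param side_a,side_b Character vectors of taxon labels; disjoint and
#'   non-empty.
#' @return An object of class `bipartition`: a list with sorted `side_a`,
#'   `side_b` and a canonical `key` string.
#' @examples
#' bipartition(c("A", "B"), c("C", "D"))
#' @export
bipartition <- function(side_a, side_b) {
  side_a <- unique(.norm_label(as.character(side_a)))
  side_b <- unique(.norm_label(as.character(side_b)))
  if (length(side_a) == 0L || length(side_b) == 0L) {
    stop("both sides of a bipartition must be non-empty", call. = FALSE)
  }
  if (any(side_a == "") || any(side_b == "")) {
    stop("empty taxon label in bipartition", call. = FALSE)
  }
  both <- intersect(side_a, side_b)
  if (length(both) > 0L) {
    stop("bipartition sides overlap: ", .fmt_labels(both), call. = FALSE)
  }
  side_a <- sort(side_a)
  side_b <- sort(side_b)
  # orientation-free canonical form: lexicographically smaller side first
  ka <- paste(side_a, collapse = "\t")
  kb <- paste(side_b, collapse = "\t")
  if (kb < ka) {
    tmp <- side_a; side_a <- side_b; side_b <- tmp
    tmp <- ka; ka <- kb; kb <- tmp
  }
  structure(
    list(side_a = side_a, side_b = side_b, key = paste(ka, kb, sep = "|")),
    class = "bipartition"
  )
}

#' @export
print.bipartition <- function(x, ...) {
  cat("<bipartition> {", .fmt_labels(x$side_a), "} | {",
      .fmt_labels(x$side_b), "}\n")
  invisible(x)
}

#' @export
`==.bipartition` <- function(e1, e2) {
  if (!inherits(e1, "bipartition") || !inherits(e2, "bipartition")) {
    stop("both operands must be bipartitions", call. = FALSE)
  }
  e1$key == e2$key
}

# canonical key for a split given as the clade side plus the full taxon set
.split_key <- function(clade, taxa) {
  rest <- setdiff(taxa, clade)
  ka <- paste(sort(clade), collapse = "\t")
  kb <- paste(sort(rest), collapse = "\t")
  if (kb < ka) paste(kb, ka, sep = "|") else paste(ka, kb, sep = "|")
}

# are two splits of (subsets of) one taxon set compatible?
# classic four-intersection test: compatible iff at least one of the four
# pairwise intersections is empty
.splits_compatible <- function(a1, a2, b1, b2) {
  !length(intersect(a1, b1)) || !length(intersect(a1, b2)) ||
    !length(intersect(a2, b1)) || !length(intersect(a2, b2))
}
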