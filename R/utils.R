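# shared internal helpers

# collapse a character vector for error messages, capped
.fmt_labels <- function(x, max = 8) {
  if (length(x) > max) {
    paste0(paste(x[seq_len(max)], collapse = ", "), ", ... (", length(x), " total)")
  } else {
    paste(x, collapse = ", ")
  }
}

# whitespace normalization used before any label comparison
.norm_label <- function(x) {
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

.is_phylo <- function(x) inherits(x, "phylo")

.assert_phylo <- function(x, arg = "tree") {
  if (!.is_phylo(x)) {
    stop("`", arg, "` must be a 'phylo' object (see read_newick())", call. = FALSE)
  }
  invisible(x)
}

# tab-separated writer: header row, '.' decimal, '\n' newlines
write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.list(df[[j]])) {
      df[[j]] <- vapply(df[[j]], function(v) paste(v, collapse = ";"), character(1))
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}
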