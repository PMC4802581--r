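# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: split enumeration goes through phangorn, the
# regression oracle solves the normal equations directly, and the site
# classifier recounts states by hand.

# canonical orientation-free identifier for a split, oracle-side
oracle_key <- function(side_a, side_b) {
  ka <- paste(sort(side_a), collapse = "\t")
  kb <- paste(sort(side_b), collapse = "\t")
  if (kb < ka) paste(kb, ka, sep = "|") else paste(ka, kb, sep = "|")
}

# every non-trivial split displayed by a tree, enumerated via phangorn
oracle_split_keys <- function(tree) {
  if (length(tree$tip.label) < 4L) return(character(0))
  sp <- phangorn::as.splits(ape::unroot(tree))
  labs <- attr(sp, "labels")
  keys <- vapply(sp, function(idx) {
    a <- labs[idx]
    b <- setdiff(labs, a)
    if (length(a) < 2L || length(b) < 2L) return(NA_character_)
    oracle_key(a, b)
  }, character(1))
  unique(keys[!is.na(keys)])
}

# brute-force support verdict: prune, then membership among enumerated splits
oracle_supports <- function(gene_tree, side_a, side_b) {
  present <- gene_tree$tip.label
  a <- intersect(side_a, present)
  b <- intersect(side_b, present)
  if (length(a) < 2L || length(b) < 2L) return("trivial")
  if (oracle_key(a, b) %in% oracle_split_keys(gene_tree)) "supports"
  else "conflicts_or_unresolved"
}

# >= 2 unambiguous states each occurring >= 2 times
oracle_classify <- function(column) {
  column <- toupper(column)
  counts <- vapply(c("A", "C", "G", "T"), function(s) sum(column == s), integer(1))
  k <- sum(counts > 0L)
  if (k == 0L) return("all_missing")
  if (k == 1L) return("constant")
  if (sum(counts >= 2L) >= 2L) return("parsimony_informative")
  "variable_uninformative"
}

# closed-form simple OLS via the normal equations
oracle_ols <- function(x, y) {
  n <- length(x)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  sigma2 <- rss / (n - 2)
  se_slope <- sqrt(sigma2 / sum((x - mean(x))^2))
  tstat <- beta[2] / se_slope
  list(
    slope = beta[2], intercept = beta[1],
    r_squared = r2,
    adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - 2),
    p_value = 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  )
}

random_binary_tree <- function(n_taxa, labels = paste0("t", seq_len(n_taxa))) {
  tr <- ape::rtree(n_taxa, tip.label = sample(labels))
  tr
}

random_column <- function(n) {
  pool <- c("A", "C", "G", "T", "A", "C", "G", "T",  # bias toward real states
            "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V",
            "N", "-", "?")
  sample(pool, n, replace = TRUE)
}
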