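# Per-locus alignment statistics: taxa, length, variable sites,
# parsimony-informative characters, missing data.

# character sets used throughout
.DNA_STATES <- c("A", "C", "G", "T")
.DNA_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
.DNA_MISSING <- c("N", "-", "?")
.DNA_LEGAL <- c(.DNA_STATES, .DNA_AMBIG, .DNA_MISSING)

#' Construct a locus alignment
#'
#' @param seqs Named character vector of equal-length sequence strings, or a
#'   character matrix (rows = taxa, one character per cell).
#' @param locus_id Identifier carried into profiles and reports.
#' @return An object of class `locus_alignment` wrapping an upper-case
#'   character matrix.
#' @export
locus_alignment <- function(seqs, locus_id = "locus") {
  if (is.matrix(seqs)) {
    m <- toupper(seqs)
  } else {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
      stop("sequences must be named by taxon", call. = FALSE)
    }
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      off <- names(seqs)[lens != lens[1L]][1L]
      stop("locus '", locus_id, "': ragged alignment, sequence length differs for taxon '",
           off, "'", call. = FALSE)
    }
    m <- do.call(rbind, strsplit(toupper(unname(seqs)), "", fixed = TRUE))
    rownames(m) <- names(seqs)
  }
  if (nrow(m) < 2L) {
    stop("locus '", locus_id, "': an alignment needs at least 2 sequences",
         call. = FALSE)
  }
  labs <- .norm_label(rownames(m))
  if (anyDuplicated(labs)) {
    stop("locus '", locus_id, "': duplicate taxa: ",
         .fmt_labels(unique(labs[duplicated(labs)])), call. = FALSE)
  }
  rownames(m) <- labs
  bad <- setdiff(unique(as.vector(m)), .DNA_LEGAL)
  if (length(bad) > 0L) {
    stop("locus '", locus_id, "': illegal character(s): ",
         .fmt_labels(bad), call. = FALSE)
  }
  structure(list(locus_id = locus_id, matrix = m),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("<locus_alignment> ", x$locus_id, ": ", nrow(x$matrix), " taxa x ",
      ncol(x$matrix), " bp\n", sep = "")
  invisible(x)
}

#' Read a multiple sequence alignment
#'
#' Supports FASTA, relaxed sequential PHYLIP, and NEXUS `data` blocks.
#' Sequences are upper-cased and validated (equal lengths, >= 2 taxa, no
#' duplicate taxa, DNA alphabet with IUPAC ambiguity plus `-`, `N`, `?`).
#'
#' @param path Path to the alignment file.
#' @param format `"auto"` (from the extension), `"fasta"`, `"phylip"` or
#'   `"nexus"`.
#' @param locus_id Defaults to the file name without extension.
#' @return A [locus_alignment()].
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "phylip", "nexus"),
                           locus_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(locus_id)) locus_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", basename(path)))
    format <- switch(ext,
      fa = , fas = , fasta = , fna = "fasta",
      phy = , phylip = "phylip",
      nex = , nexus = "nexus",
      "fasta")
  }
  seqs <- switch(format,
    fasta = .read_fasta_chars(path, locus_id),
    phylip = .read_phylip_chars(path, locus_id),
    nexus = .read_nexus_chars(path, locus_id))
  locus_alignment(seqs, locus_id = locus_id)
}

.read_fasta_chars <- function(path, locus_id) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) {
    stop("locus '", locus_id, "': no FASTA records in ", path, call. = FALSE)
  }
  ends <- c(hdr[-1L] - 1L, length(lines))
  nm <- sub("^>\\s*", "", lines[hdr])
  nm <- sub("\\s.*$", "", nm)  # first token only
  seqs <- vapply(seq_along(hdr), function(i) {
    if (hdr[i] + 1L > ends[i]) return("")
    paste(gsub("\\s", "", lines[(hdr[i] + 1L):ends[i]]), collapse = "")
  }, character(1))
  names(seqs) <- nm
  seqs
}

.read_phylip_chars <- function(path, locus_id) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stop("locus '", locus_id, "': empty or truncated PHYLIP file", call. = FALSE)
  }
  hd <- scan(text = lines[1L], what = integer(), n = 2, quiet = TRUE)
  body <- lines[-1L]
  parts <- regmatches(body, regexpr("\\S+", body))
  seqs <- vapply(body, function(l) {
    gsub("\\s", "", sub("^\\s*\\S+", "", l))
  }, character(1), USE.NAMES = FALSE)
  names(seqs) <- parts
  if (length(seqs) != hd[1L]) {
    stop("locus '", locus_id, "': PHYLIP header promises ", hd[1L],
         " sequences, found ", length(seqs), call. = FALSE)
  }
  seqs
}

.read_nexus_chars <- function(path, locus_id) {
  dat <- tryCatch(ape::read.nexus.data(path), error = function(e) {
    stop("locus '", locus_id, "': NEXUS parse failure: ", conditionMessage(e),
         call. = FALSE)
  })
  vapply(dat, function(v) paste(toupper(v), collapse = ""), character(1))
}

#' Classify one alignment column
#'
#' Only the unambiguous nucleotides A, C, G, T count as states; ambiguity
#' codes, `N`, `-` and `?` are ignored for state counting.  A column is
#' `parsimony_informative` when at least two states each occur at least
#' twice; `constant` when at most one state is present (in at least one
#' sequence); `all_missing` when no unambiguous state remains; anything
#' else is `variable_uninformative`.
#'
#' @param column Character vector of single characters (one per sequence).
#' @return One of `"constant"`, `"variable_uninformative"`,
#'   `"parsimony_informative"`, `"all_missing"`.
#' @examples
#' classify_site(c("A", "A", "T", "T"))  # parsimony_informative
#' classify_site(c("A", "A", "A", "T"))  # variable_uninformative
#' classify_site(c("A", "-", "N", "A"))  # constant
#' @export
classify_site <- function(column) {
  column <- toupper(as.character(column))
  bad <- setdiff(unique(column), .DNA_LEGAL)
  if (length(bad) > 0L) {
    stop("illegal character(s) in column: ", .fmt_labels(bad), call. = FALSE)
  }
  counts <- tabulate(match(column, .DNA_STATES), nbins = 4L)
  k <- sum(counts > 0L)
  if (k == 0L) return("all_missing")
  if (k == 1L) return("constant")
  if (sum(counts >= 2L) >= 2L) return("parsimony_informative")
  "variable_uninformative"
}

# vectorized column classification over a character matrix (rows = taxa)
.classify_matrix <- function(m) {
  counts <- vapply(.DNA_STATES, function(s) colSums(m == s), numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L)
  k <- rowSums(counts > 0)
  two <- rowSums(counts >= 2)
  cls <- rep("variable_uninformative", ncol(m))
  cls[k == 0L] <- "all_missing"
  cls[k == 1L] <- "constant"
  cls[k >= 2L & two >= 2L] <- "parsimony_informative"
  cls
}

#' Profile one locus alignment
#'
#' Classifies every column and derives the per-locus statistics used to
#' assess a phylogenomic dataset: number of taxa, alignment length,
#' variable sites (variable-uninformative plus parsimony-informative),
#' parsimony-informative characters (PIC), percent variation, and percent
#' missing cells (`-`, `N`, `?`).
#'
#' @param aln A [locus_alignment()].
#' @param variation_denominator Denominator of `pct_variation`: the full
#'   alignment `"length"` (default) or only `"scored_columns"`, i.e.
#'   columns that are not entirely missing.
#' @return A one-row tibble: `locus_id`, `n_taxa`, `length`, `n_variable`,
#'   `n_pic`, `pct_variation`, `pct_missing`.
#' @export
profile_locus <- function(aln, variation_denominator = c("length", "scored_columns")) {
  variation_denominator <- match.arg(variation_denominator)
  if (!inherits(aln, "locus_alignment")) {
    stop("`aln` must be a locus_alignment", call. = FALSE)
  }
  m <- aln$matrix
  cls <- .classify_matrix(m)
  n_pic <- sum(cls == "parsimony_informative")
  n_var <- n_pic + sum(cls == "variable_uninformative")
  denom <- switch(variation_denominator,
                  length = ncol(m),
                  scored_columns = sum(cls != "all_missing"))
  tibble::tibble(
    locus_id = aln$locus_id,
    n_taxa = nrow(m),
    length = ncol(m),
    n_variable = n_var,
    n_pic = n_pic,
    pct_variation = if (denom > 0) 100 * n_var / denom else 0,
    pct_missing = 100 * mean(m %in% .DNA_MISSING)
  )
}

#' Profile a set of loci
#'
#' @param alns A list of [locus_alignment()] objects, or a directory path
#'   holding per-locus alignment files.
#' @param format Passed to [read_alignment()] when `alns` is a directory.
#' @param on_error When a file fails to parse: `"skip"` (warn and continue,
#'   default) or `"stop"`.
#' @inheritParams profile_locus
#' @return A tibble with one [profile_locus()] row per locus.
#' @export
profile_loci <- function(alns, format = "auto",
                         variation_denominator = c("length", "scored_columns"),
                         on_error = c("skip", "stop")) {
  variation_denominator <- match.arg(variation_denominator)
  on_error <- match.arg(on_error)
  if (is.character(alns) && length(alns) == 1L && dir.exists(alns)) {
    files <- sort(list.files(alns, full.names = TRUE))
    files <- files[!dir.exists(files)]
    alns <- list()
    for (f in files) {
      a <- tryCatch(read_alignment(f, format = format), error = function(e) e)
      if (inherits(a, "error")) {
        if (on_error == "stop") stop(a)
        warning("skipping unparseable locus file ", basename(f), ": ",
                conditionMessage(a), call. = FALSE)
      } else {
        alns[[length(alns) + 1L]] <- a
      }
    }
  }
  if (length(alns) == 0L) stop("no parseable loci", call. = FALSE)
  dplyr::bind_rows(lapply(alns, profile_locus,
                          variation_denominator = variation_denominator))
}

#' Summarize locus profiles as mean (min-max) per group
#'
#' Produces the classic locus-assessment table: per locus class, the locus
#' count and, for each metric, its mean with the min-max range, plus a
#' preformatted `"mean (min-max)"` label.
#'
#' @param profiles A [profile_loci()] tibble.
#' @param classes Optional two-column data frame (`locus_id`, `class`)
#'   assigning each locus to a class (e.g. UCE vs protein-coding).  Loci
#'   without an assignment fall into class `"unclassified"`; with no
#'   `classes` at all, everything is summarized as `"all"`.
#' @return A tibble with columns `class`, `n_loci`, `metric`, `mean`,
#'   `min`, `max`, `label`.
#' @export
summarize_profiles <- function(profiles, classes = NULL) {
  if (!is.data.frame(profiles) || nrow(profiles) == 0L) {
    stop("`profiles` must be a non-empty profile tibble", call. = FALSE)
  }
  df <- profiles
  if (is.null(classes)) {
    df$class <- "all"
  } else {
    if (!all(c("locus_id", "class") %in% names(classes))) {
      stop("`classes` needs columns locus_id and class", call. = FALSE)
    }
    df <- dplyr::left_join(df, classes[, c("locus_id", "class")], by = "locus_id")
    df$class[is.na(df$class)] <- "unclassified"
  }
  metrics <- c("n_taxa", "length", "n_variable", "n_pic",
               "pct_variation", "pct_missing")
  long <- tidyr::pivot_longer(
    df[, c("class", metrics)],
    dplyr::all_of(metrics),
    names_to = "metric", values_to = "value"
  )
  n_by <- dplyr::count(df, .data$class, name = "n_loci")
  out <- long |>
    dplyr::group_by(.data$class, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value),
      min = min(.data$value),
      max = max(.data$value),
      .groups = "drop"
    ) |>
    dplyr::left_join(n_by, by = "class") |>
    dplyr::mutate(
      metric = factor(.data$metric, levels = metrics),
      label = sprintf("%s (%s–%s)",
                      format(round(.data$mean), trim = TRUE, scientific = FALSE),
                      format(round(.data$min), trim = TRUE, scientific = FALSE),
                      format(round(.data$max), trim = TRUE, scientific = FALSE))
    ) |>
    dplyr::arrange(.data$class, .data$metric) |>
    dplyr::select("class", "n_loci", "metric", "mean", "min", "max", "label")
  out
}

#' Alignment length versus informative sites
#'
#' Fits the simple linear regression of parsimony-informative characters on
#' alignment length across loci — the standard check that longer loci carry
#' more signal.
#'
#' @param profiles A [profile_loci()] tibble with >= 3 rows.
#' @return A [linear_fit()] object.
#' @export
length_vs_informative <- function(profiles) {
  linear_fit(profiles, length, n_pic)
}
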