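#' Gene-family count tables
#'
#' A count table holds non-negative integer gene-copy numbers, one row
#' per gene family and one column per species, plus a leading `family`
#' column. When paired with a chronogram the species names must match
#' the tree's taxa exactly.
#'
#' [read_counts()] reads a TSV with species as columns. If a
#' chronogram is supplied and the file turns out to be transposed
#' (species as rows), the orientation is detected by matching taxon
#' names and fixed, with a message.
#'
#' @param file Path to a tab-separated table with a header row.
#' @param tree Optional `chronogram` used to validate (and, if needed,
#'   re-orient) the species labels.
#' @return A tibble with column `family` plus one integer column per
#'   species.
#' @export
read_counts <- function(file, tree = NULL) {
  if (!file.exists(file)) abort(paste0("counts file not found: ", file))
  df <- utils::read.delim(file, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) abort("counts table is empty")
  names(df)[1] <- "family"

  if (!is.null(tree)) {
    taxa <- as_chronogram(tree)$tip.label
    cols <- setdiff(names(df), "family")
    if (length(intersect(cols, taxa)) == 0 &&
        length(intersect(df$family, taxa)) > 0) {
      inform("counts table appears transposed (species as rows); re-orienting")
      fam_names <- names(df)[-1]
      sp <- df$family
      m <- t(as.matrix(df[, -1, drop = FALSE]))
      df <- data.frame(family = fam_names, m, check.names = FALSE,
                       stringsAsFactors = FALSE)
      names(df)[-1] <- sp
    }
  }
  counts <- as_count_table(df)
  if (!is.null(tree)) validate_counts(counts, tree)
  counts
}

#' @rdname read_counts
#' @param x A data frame with a `family` column (or rownames) and one
#'   numeric column per species.
#' @export
as_count_table <- function(x) {
  x <- as.data.frame(x, check.names = FALSE)
  if (!"family" %in% names(x)) {
    x <- cbind(family = rownames(x) %||% paste0("fam", seq_len(nrow(x))), x)
  }
  x <- x[, c("family", setdiff(names(x), "family")), drop = FALSE]
  species <- setdiff(names(x), "family")
  if (length(species) == 0 || nrow(x) == 0) abort("counts table is empty")
  if (anyDuplicated(species)) abort("duplicated species columns")
  if (anyDuplicated(x$family)) abort("duplicated family labels")
  for (sp in species) {
    v <- x[[sp]]
    if (!is_count(v)) {
      abort(paste0("column '", sp, "' must contain non-negative integers"))
    }
    x[[sp]] <- as.integer(v)
  }
  tibble::as_tibble(x)
}

validate_counts <- function(counts, tree) {
  taxa <- as_chronogram(tree)$tip.label
  species <- setdiff(names(counts), "family")
  missing <- setdiff(taxa, species)
  extra <- setdiff(species, taxa)
  if (length(missing) > 0 || length(extra) > 0) {
    abort(paste0(
      "species labels do not match the tree",
      if (length(missing) > 0) paste0("; missing: ", paste(missing, collapse = ", ")),
      if (length(extra) > 0) paste0("; extra: ", paste(extra, collapse = ", "))
    ))
  }
  invisible(counts)
}

# families x species integer matrix in the given species order.
counts_matrix <- function(counts, species) {
  m <- as.matrix(counts[, species, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- counts$family
  m
}
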