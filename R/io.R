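# header comment stamped into every file the pipeline writes
file_header <- function(seed = NULL, hash = NULL) {
  ver <- as.character(utils::packageVersion("neffbiome"))
  paste0("# neffbiome v", ver,
         if (!is.null(seed)) paste0("; seed=", seed),
         if (!is.null(hash)) paste0("; config=", hash))
}

write_with_header <- function(df, path, delim, header = NULL) {
  if (!is.null(header)) {
    readr::write_lines(header, path)
    readr::write_delim(df, path, delim = delim, append = TRUE,
                       col_names = TRUE)
  } else {
    readr::write_delim(df, path, delim = delim)
  }
  invisible(path)
}

#' Read and write feature tables as TSV
#'
#' On disk the orientation is features x samples with a `#FeatureID`
#' sentinel heading the first column (the QIIME/BIOM-TSV convention); in
#' memory tables are samples x features. `read_feature_table()`
#' auto-detects orientation by the sentinel and transposes as needed.
#'
#' @param x A [feature_table()] or samples-x-features count matrix.
#' @param path File path.
#' @param header Optional comment line written above the table.
#' @param meta Optional metadata tibble to attach on read.
#' @return `read_feature_table()`: a count matrix, or a [feature_table()]
#'   when `meta` is given.
#' @export
write_feature_table <- function(x, path, header = NULL) {
  counts <- ft_counts(x)
  df <- dplyr::bind_cols(
    tibble(`#FeatureID` = colnames(counts)),
    as_tibble(t(counts))
  )
  write_with_header(df, path, "\t", header)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, meta = NULL) {
  df <- readr::read_tsv(path, comment = "", show_col_types = FALSE,
                        skip = if (startsWith(readr::read_lines(path, n_max = 1), "# ")) 1L else 0L)
  first <- names(df)[1]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (identical(first, "#FeatureID")) m <- t(m) # disk is features x samples
  storage.mode(m) <- "integer"
  if (is.null(meta)) m else feature_table(m, meta)
}

#' Read and validate a herd CSV
#'
#' One row per cow with the columns of [simulate_herd()]. Validation
#' failures (refusals exceeding offered feed, fractions outside `[0, 1)`,
#' non-positive markers) raise an error naming the offending row(s).
#'
#' @param path CSV path.
#' @param herd A herd tibble (for `write_herd_csv()`).
#' @param header Optional comment line.
#' @return A validated herd tibble.
#' @export
read_herd_csv <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  validate_herd(df)
}

#' @rdname read_herd_csv
#' @export
write_herd_csv <- function(herd, path, header = NULL) {
  write_with_header(as_tibble(herd), path, ",", header)
}

#' Write / read a labelled square distance matrix as TSV
#'
#' @param d A [stats::dist] or square matrix.
#' @param path File path.
#' @param header Optional comment line.
#' @return `read_distance_tsv()` returns a [stats::dist].
#' @export
write_distance_tsv <- function(d, path, header = NULL) {
  m <- as.matrix(d)
  df <- dplyr::bind_cols(tibble(sample_id = rownames(m)), as_tibble(m))
  write_with_header(df, path, "\t", header)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  stats::as.dist(m)
}

#' Write a phylogeny to newick
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()] so trees
#' round-trip topology and branch lengths.
#'
#' @param tree An [ape::phylo].
#' @param path File path.
#' @return `read_newick()` returns an [ape::phylo].
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
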