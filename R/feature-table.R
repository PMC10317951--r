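#' A samples-by-features count table with sample metadata
#'
#' Lightweight container pairing an integer count matrix (samples in rows,
#' ASVs in columns) with a metadata tibble keyed by `sample_id`. All
#' community-analysis functions in the package accept it.
#'
#' @param counts Non-negative integer matrix, samples x features, with
#'   unique row (sample) and column (feature) names.
#' @param meta Tibble with a `sample_id` column covering every row of
#'   `counts`; typically also `cow_id`, `site` and `phenotype`.
#' @return An object of class `feature_table` with elements `counts` and
#'   `meta` (meta re-ordered to match the count rows).
#' @export
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L), 2, dimnames = list(c("s1", "s2"), c("a", "b")))
#' ft <- feature_table(m, tibble::tibble(sample_id = c("s1", "s2"), site = "rumen"))
#' ft
feature_table <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort_domain("`counts` needs sample row names and feature column names")
  }
  if (anyNA(counts) || any(counts < 0)) {
    abort_domain("`counts` must be non-negative with no missing values")
  }
  if (any(counts != round(counts))) {
    abort_domain("`counts` must be integer read counts")
  }
  if (anyDuplicated(colnames(counts))) abort_domain("feature ids must be unique")
  if (anyDuplicated(rownames(counts))) abort_domain("sample ids must be unique")
  meta <- as_tibble(meta)
  if (!"sample_id" %in% names(meta)) abort_domain("`meta` needs a `sample_id` column")
  missing <- setdiff(rownames(counts), meta$sample_id)
  if (length(missing)) {
    abort_domain(sprintf("samples without metadata: %s",
                         paste(head(missing, 5), collapse = ", ")))
  }
  meta <- meta[match(rownames(counts), meta$sample_id), , drop = FALSE]
  structure(list(counts = counts, meta = meta), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features (total reads %s)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  if ("site" %in% names(x$meta)) {
    cat("  sites:", paste(unique(x$meta$site), collapse = ", "), "\n")
  }
  invisible(x)
}

ft_counts <- function(x) {
  if (inherits(x, "feature_table")) x$counts else as.matrix(x)
}

#' Convert counts to counts-per-million relative abundance
#'
#' @param x A [feature_table()] or samples-x-features count matrix.
#' @return A numeric matrix of the same shape; each row sums to 1e6.
#' @export
cpm <- function(x) {
  m <- ft_counts(x)
  rs <- rowSums(m)
  if (any(rs == 0)) abort_domain("cannot scale a sample with zero reads")
  m / rs * 1e6
}

#' Merge two site tables over a shared feature universe
#'
#' Features absent from one table are zero-filled, so cross-site analyses
#' (e.g. site-level beta diversity) can run on one combined table.
#'
#' @param ... Two or more [feature_table()] objects with disjoint samples.
#' @return A [feature_table()] over the union of features and samples.
#' @export
combine_tables <- function(...) {
  tabs <- list(...)
  stopifnot(length(tabs) >= 2L)
  feats <- sort(unique(unlist(lapply(tabs, function(t) colnames(t$counts)))))
  samples <- unlist(lapply(tabs, function(t) rownames(t$counts)))
  if (anyDuplicated(samples)) abort_domain("tables to combine share sample ids")
  counts <- matrix(0L, length(samples), length(feats),
                   dimnames = list(samples, feats))
  for (t in tabs) counts[rownames(t$counts), colnames(t$counts)] <- t$counts
  meta <- dplyr::bind_rows(lapply(tabs, function(t) t$meta))
  feature_table(counts, meta)
}

#' Subset a feature table to selected samples
#'
#' @param x A [feature_table()].
#' @param samples Character sample ids or a logical/integer index on rows.
#' @param drop_empty Drop features with zero total count after subsetting.
#' @return A [feature_table()].
#' @export
filter_samples <- function(x, samples, drop_empty = FALSE) {
  stopifnot(inherits(x, "feature_table"))
  counts <- x$counts[samples, , drop = FALSE]
  if (drop_empty) counts <- counts[, colSums(counts) > 0, drop = FALSE]
  feature_table(counts, x$meta[x$meta$sample_id %in% rownames(counts), ])
}
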