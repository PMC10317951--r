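#' Rarefy a feature table to even depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' (a single draw, not an average over draws). Samples with fewer than
#' `depth` total reads are dropped with a warning rather than padded.
#'
#' @param x A [feature_table()] or samples-x-features count matrix.
#' @param depth Target reads per sample (>= 1).
#' @param seed Optional integer seed for a reproducible draw.
#' @return An object of the same kind as `x`, with every retained sample
#'   summing to exactly `depth`.
#' @export
#' @examples
#' m <- matrix(c(60L, 40L, 10L, 0L), 2, dimnames = list(c("s1", "s2"), c("a", "b")))
#' rarefy_table(m, depth = 10, seed = 1)
rarefy_table <- function(x, depth = 5834, seed = NULL) {
  if (length(depth) != 1L || !is.finite(depth) || depth < 1) {
    abort_domain("`depth` must be a single positive integer")
  }
  depth <- as.integer(depth)
  counts <- ft_counts(x)
  totals <- rowSums(counts)
  keep <- totals >= depth
  if (!all(keep)) {
    warn(sprintf("dropping %d sample(s) below depth %d: %s",
                 sum(!keep), depth,
                 paste(head(rownames(counts)[!keep], 5), collapse = ", ")))
  }
  if (!any(keep)) abort_domain("no sample reaches the rarefaction depth")
  counts <- counts[keep, , drop = FALSE]

  out <- with_seed_if(seed, {
    t(apply(counts, 1, function(row) {
      if (sum(row) == depth) return(as.integer(row))
      reads <- rep.int(seq_along(row), row)
      tabulate(sample(reads, depth), nbins = length(row))
    }))
  })
  dimnames(out) <- dimnames(counts)
  storage.mode(out) <- "integer"
  if (inherits(x, "feature_table")) {
    feature_table(out, x$meta[x$meta$sample_id %in% rownames(out), ])
  } else {
    out
  }
}

check_sample <- function(x) {
  check_numeric(x, "counts")
  if (any(x < 0)) abort_domain("counts must be non-negative")
  if (sum(x) <= 0) abort_domain("sample has no reads")
  x
}

#' Alpha-diversity metrics for a single sample
#'
#' `goods_coverage()` is Good's estimator `1 - F1/N` (F1 = features seen
#' exactly once, N = total reads): the estimated fraction of the community
#' captured at this depth. `shannon_index()` is the Shannon-Weiner index in
#' bits (base-2 logarithm, the QIIME 2 convention). `pielou_evenness()` is
#' Shannon divided by its maximum `log2(S)` over the S observed features
#' (NA when S < 2). `evenness_from_shannon()` applies the same identity to
#' already-computed summary values.
#'
#' @param x Non-negative count vector for one sample.
#' @return A single number.
#' @name alpha_metrics
#' @export
#' @examples
#' goods_coverage(c(1, 1, 2, 6)) # 0.8
#' shannon_index(c(1, 1, 1, 1)) # 2 bits
#' pielou_evenness(c(9, 1)) # ~0.469
goods_coverage <- function(x) {
  x <- check_sample(x)
  1 - sum(x == 1) / sum(x)
}

#' @rdname alpha_metrics
#' @export
shannon_index <- function(x) {
  x <- check_sample(x)
  p <- x[x > 0] / sum(x)
  -sum(p * log2(p))
}

#' @rdname alpha_metrics
#' @export
pielou_evenness <- function(x) {
  x <- check_sample(x)
  s <- sum(x > 0)
  if (s < 2) return(NA_real_)
  shannon_index(x) / log2(s)
}

#' @rdname alpha_metrics
#' @param shannon Shannon index in bits.
#' @param richness Observed feature count.
#' @export
evenness_from_shannon <- function(shannon, richness) {
  check_numeric(shannon, "shannon")
  check_numeric(richness, "richness")
  if (any(richness < 2)) abort_domain("evenness needs at least 2 features")
  shannon / log2(richness)
}

#' Per-sample alpha diversity of a feature table
#'
#' Computes observed features, Shannon (bits), Pielou evenness and Good's
#' coverage for every sample, joined with the sample metadata. Typically
#' run on a rarefied table (see [rarefy_table()]); coverage before
#' rarefaction can be had by passing the unrarefied table instead.
#'
#' @param x A [feature_table()] or samples-x-features count matrix.
#' @return A tibble: `sample_id`, `observed`, `shannon`, `pielou`, `goods`,
#'   plus any metadata columns.
#' @export
alpha_diversity <- function(x) {
  counts <- ft_counts(x)
  res <- tibble(
    sample_id = rownames(counts),
    observed = apply(counts, 1, function(r) sum(r > 0)),
    shannon = apply(counts, 1, shannon_index),
    pielou = apply(counts, 1, pielou_evenness),
    goods = apply(counts, 1, goods_coverage)
  )
  if (inherits(x, "feature_table")) {
    res <- dplyr::left_join(res, x$meta, by = "sample_id")
  }
  res
}

#' Compare alpha-diversity metrics between groups (Kruskal-Wallis)
#'
#' Rank-based Kruskal-Wallis test (tie-corrected, chi-square p) per metric;
#' with two groups this is the standard nonparametric two-sample comparison
#' used for alpha diversity. When every value is tied the statistic is 0
#' and p is 1.
#'
#' @param data A tibble from [alpha_diversity()].
#' @param metrics Metric columns to test.
#' @param group_col Grouping column.
#' @param groups Optional subset of group levels (default: all present).
#' @return A tibble: `metric`, `statistic` (H), `df`, `p.value`.
#' @export
alpha_compare <- function(data, metrics = c("observed", "shannon", "pielou", "goods"),
                          group_col = "phenotype", groups = NULL) {
  data <- as_tibble(data)
  g <- as.character(data[[group_col]])
  groups <- groups %||% sort(unique(g))
  if (length(groups) < 2) abort_domain("need at least two groups")
  keep <- g %in% groups
  if (any(table(g[keep]) == 0)) abort_domain("a requested group is empty")
  purrr::map_dfr(metrics, function(mname) {
    x <- data[[mname]][keep]
    gg <- factor(g[keep], levels = groups)
    if (length(unique(x)) == 1L) {
      return(tibble(metric = mname, statistic = 0, df = length(groups) - 1L,
                    p.value = 1))
    }
    kw <- kruskal.test(x, gg)
    tibble(metric = mname, statistic = unname(kw$statistic),
           df = unname(kw$parameter), p.value = kw$p.value)
  })
}
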