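# vectorised two-plus-group Kruskal-Wallis over the columns of a matrix,
# tie-corrected, chi-square p; matches stats::kruskal.test
kw_screen <- function(x, groups) {
  n <- nrow(x)
  k <- nlevels(groups)
  ranks <- apply(x, 2L, rank)
  ss <- 0
  for (lev in levels(groups)) {
    sel <- groups == lev
    ss <- ss + colSums(ranks[sel, , drop = FALSE])^2 / sum(sel)
  }
  h <- 12 / (n * (n + 1)) * ss - 3 * (n + 1)
  tie_c <- apply(x, 2L, function(col) {
    t <- table(col)
    1 - sum(t^3 - t) / (n^3 - n)
  })
  h <- ifelse(tie_c == 0, 0, h / tie_c)
  p <- ifelse(tie_c == 0, 1, pchisq(h, df = k - 1, lower.tail = FALSE))
  list(statistic = h, p.value = p)
}

#' LEfSe-style differential abundance between two phenotype groups
#'
#' A two-stage screen in the spirit of linear discriminant analysis effect
#' size (LEfSe): (1) scale each sample to counts per million; (2) keep
#' features whose Kruskal-Wallis raw p across the two groups is below
#' `alpha` (no multiplicity adjustment at this stage, matching LEfSe);
#' (3) score each retained feature with a bootstrap-averaged log10 effect
#' size — over `n_boot` seeded rounds, resample `ceiling(2n/3)` samples per
#' group with replacement and take `log10(max(|mean CPM difference|, 1))` —
#' and keep features with effect at or above `lda_threshold`; (4) the
#' enriched group is the one with the larger full-data mean CPM.
#'
#' The effect size is a documented surrogate for LEfSe's LDA score: it is
#' monotone in the planted between-group difference and deterministic
#' under a seed, but is not bit-identical to the original LEfSe
#' implementation.
#'
#' @param x A [feature_table()] (with `phenotype` metadata) or a
#'   samples-x-features count matrix (then supply `labels`).
#' @param labels Optional per-sample group labels overriding the metadata.
#' @param groups The two group labels to contrast; samples outside them are
#'   dropped. More than two groups is unsupported.
#' @param alpha Raw Kruskal-Wallis p threshold (default 0.05).
#' @param lda_threshold Minimum log10 effect size (default 2.0).
#' @param n_boot Bootstrap rounds for the effect size (default 30).
#' @param seed Optional seed for the bootstrap stream.
#' @return A tibble sorted by decreasing effect: `feature_id`, `kw_p`,
#'   `effect`, `enriched_group`, and per-group mean CPM columns.
#' @export
lefse_da <- function(x, labels = NULL, groups = c("low", "high"),
                     alpha = 0.05, lda_threshold = 2.0, n_boot = 30,
                     seed = NULL) {
  if (length(groups) != 2L) {
    abort_domain("exactly two groups are supported (class-only design)")
  }
  counts <- ft_counts(x)
  labels <- labels %||% {
    if (!inherits(x, "feature_table") || !"phenotype" %in% names(x$meta)) {
      abort_domain("supply `labels` or a feature_table with phenotype metadata")
    }
    as.character(x$meta$phenotype)
  }
  if (length(labels) != nrow(counts)) {
    abort_domain("`labels` must have one entry per sample")
  }
  keep <- labels %in% groups
  counts <- counts[keep, , drop = FALSE]
  g <- factor(labels[keep], levels = groups)
  sizes <- table(g)
  if (any(sizes == 0)) abort_domain("a contrast group is empty")
  if (any(sizes < 3)) abort_domain("each group needs at least 3 samples")

  rel <- cpm(counts)
  kw <- kw_screen(rel, g)
  cand <- which(kw$p.value < alpha)

  empty <- tibble(
    feature_id = character(), kw_p = numeric(), effect = numeric(),
    enriched_group = character()
  )
  empty[[paste0("mean_cpm_", groups[1])]] <- numeric()
  empty[[paste0("mean_cpm_", groups[2])]] <- numeric()
  if (!length(cand)) return(empty)

  idx1 <- which(g == groups[1])
  idx2 <- which(g == groups[2])
  m1 <- ceiling(2 * length(idx1) / 3)
  m2 <- ceiling(2 * length(idx2) / 3)
  sub <- rel[, cand, drop = FALSE]

  effect <- with_seed_if(seed, {
    acc <- numeric(length(cand))
    for (b in seq_len(n_boot)) {
      s1 <- sample(idx1, m1, replace = TRUE)
      s2 <- sample(idx2, m2, replace = TRUE)
      delta <- colMeans(sub[s1, , drop = FALSE]) -
        colMeans(sub[s2, , drop = FALSE])
      acc <- acc + log10(pmax(abs(delta), 1))
    }
    acc / n_boot
  })

  mean1 <- colMeans(rel[idx1, , drop = FALSE])
  mean2 <- colMeans(rel[idx2, , drop = FALSE])
  res <- tibble(
    feature_id = colnames(rel)[cand],
    kw_p = unname(kw$p.value[cand]),
    effect = unname(effect),
    enriched_group = unname(ifelse(mean1[cand] >= mean2[cand],
                                   groups[1], groups[2]))
  )
  res[[paste0("mean_cpm_", groups[1])]] <- unname(mean1[cand])
  res[[paste0("mean_cpm_", groups[2])]] <- unname(mean2[cand])
  res <- res[res$effect >= lda_threshold, , drop = FALSE]
  res[order(-res$effect), , drop = FALSE]
}

#' Hierarchically cluster differential features by abundance profile
#'
#' Agglomerative clustering (average linkage by default) of feature CPM
#' profiles across samples, Euclidean metric, optionally z-scored per
#' feature. Zero-variance profiles z-score to all zeros (with a message)
#' rather than NaN.
#'
#' @param x A [feature_table()] or samples-x-features count/CPM matrix.
#' @param features Feature ids to cluster (>= 2), e.g. from [lefse_da()].
#' @param method Linkage passed to [stats::hclust()].
#' @param scale Z-score each feature profile before clustering (default
#'   TRUE).
#' @return An object of class `feature_clustering`: `hclust` (the tree),
#'   `leaf_order` (features in dendrogram order), `profile` (the matrix
#'   clustered, features x samples).
#' @export
cluster_features <- function(x, features = NULL, method = "average",
                             scale = TRUE) {
  rel <- if (inherits(x, "feature_table")) cpm(x) else as.matrix(x)
  features <- features %||% colnames(rel)
  missing <- setdiff(features, colnames(rel))
  if (length(missing)) {
    abort_domain(sprintf("unknown feature(s): %s",
                         paste(head(missing, 5), collapse = ", ")))
  }
  if (length(features) < 2L) abort_domain("need at least 2 features to cluster")

  prof <- t(rel[, features, drop = FALSE]) # features x samples
  if (scale) {
    sds <- apply(prof, 1L, sd)
    flat <- sds == 0
    if (any(flat)) {
      message(sprintf("%d zero-variance feature profile(s) set to zero",
                      sum(flat)))
    }
    prof <- (prof - rowMeans(prof)) / ifelse(sds == 0, 1, sds)
    prof[flat, ] <- 0
  }
  hc <- hclust(dist(prof), method = method)
  structure(
    list(hclust = hc, leaf_order = hc$labels[hc$order], profile = prof),
    class = "feature_clustering"
  )
}

#' @export
print.feature_clustering <- function(x, ...) {
  cat(sprintf("<feature_clustering> %d features, %s linkage\n",
              length(x$leaf_order), x$hclust$method))
  invisible(x)
}
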