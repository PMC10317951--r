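#' Pooled-variance Student t-test between two groups
#'
#' Two-sided Student t with pooled variance and `n1 + n2 - 2` degrees of
#' freedom. Degenerate inputs are flagged rather than erroring: zero pooled
#' variance with equal means gives t = 0, p = 1; with unequal means the
#' statistic is signed infinity with p = 0.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return A one-row tibble: `estimate` (mean difference x - y),
#'   `statistic`, `df`, `p.value`.
#' @export
#' @examples
#' ttest_groups(c(1, 2, 3), c(4, 5, 6))
ttest_groups <- function(x, y) {
  check_numeric(x, "x")
  check_numeric(y, "y")
  if (length(x) < 2L || length(y) < 2L) {
    abort_domain("each group needs at least 2 values")
  }
  n1 <- length(x)
  n2 <- length(y)
  df <- n1 + n2 - 2L
  pooled <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / df
  diff <- mean(x) - mean(y)
  if (pooled == 0) {
    if (diff == 0) {
      return(tibble(estimate = 0, statistic = 0, df = df, p.value = 1))
    }
    return(tibble(estimate = diff, statistic = sign(diff) * Inf, df = df,
                  p.value = 0))
  }
  tt <- t.test(x, y, var.equal = TRUE)
  tibble(estimate = diff, statistic = unname(tt$statistic),
         df = unname(tt$parameter), p.value = tt$p.value)
}

#' Correlation with a t-approximation p-value
#'
#' Pearson or Spearman correlation; Spearman is Pearson on average-ranked
#' data (ties get average ranks). The p-value uses the t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom
#' (`p = 0` when `|r| = 1`), which is the convention for small panels; an
#' exact permutation p is available via `n_perm`.
#'
#' @param x,y Paired numeric vectors, length >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @param n_perm If positive, replace the t-approximation with a seeded
#'   permutation p over `n_perm` shuffles of `y`.
#' @param seed Optional seed for the permutation p.
#' @return A one-row tibble: `method`, `n`, `r`, `p.value`. Zero variance
#'   in either vector yields `r = NA` (undefined, excluded from any FDR
#'   family downstream).
#' @export
#' @examples
#' cor_test(1:5, c(1, 3, 2, 5, 4), method = "spearman") # r = 0.8
cor_test <- function(x, y, method = c("pearson", "spearman"), n_perm = 0,
                     seed = NULL) {
  method <- match.arg(method)
  check_numeric(x, "x")
  check_numeric(y, "y")
  if (length(x) != length(y)) abort_domain("`x` and `y` must be paired")
  n <- length(x)
  if (n < 3L) abort_domain("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(method = method, n = n, r = NA_real_, p.value = NA_real_))
  }
  r <- cor(x, y, method = method)
  p <- if (n_perm > 0) {
    r_perm <- with_seed_if(seed, {
      vapply(seq_len(n_perm), function(i) cor(x, sample(y), method = method),
             numeric(1))
    })
    (sum(abs(r_perm) >= abs(r)) + 1) / (n_perm + 1)
  } else if (abs(r) >= 1) {
    0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  tibble(method = method, n = n, r = r, p.value = p)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Thin validated wrapper over [stats::p.adjust()] with `method = "BH"`:
#' `q_i = min over rank j >= i of p_(j) * m / j`, capped at 1. Never
#' decreases a p-value, preserves the p ordering, and is idempotent.
#'
#' @param p Raw p-values in `[0, 1]` (NA allowed and propagated).
#' @return The q-values, same length and order as `p`.
#' @export
#' @examples
#' fdr_bh(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
fdr_bh <- function(p) {
  if (!is.numeric(p)) abort_domain("`p` must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort_domain("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Classify correlation strength into the reported bands
#'
#' `|r|` (rounded to 2 decimals, matching 2-decimal reporting) between
#' 0.51 and 0.70 is `moderate`, between 0.71 and 1.00 is `strong`,
#' anything weaker is `none`. The band is symmetric in sign.
#'
#' @param r Correlation coefficient(s) in `[-1, 1]`; NA propagates.
#' @return Character vector in `{"none", "moderate", "strong"}`.
#' @export
#' @examples
#' classify_strength(c(-0.61, 0.70, 0.71, 0.50))
classify_strength <- function(r) {
  if (!is.numeric(r)) abort_domain("`r` must be numeric")
  if (any(abs(r) > 1 + 1e-8, na.rm = TRUE)) {
    abort_domain("|r| cannot exceed 1")
  }
  a <- round(pmin(abs(r), 1), 2)
  out <- rep(NA_character_, length(r))
  out[!is.na(a) & a >= 0.71] <- "strong"
  out[!is.na(a) & a >= 0.51 & a < 0.71] <- "moderate"
  out[!is.na(a) & a < 0.51] <- "none"
  out
}

#' Correlate features or analytes against the Neff phenotype
#'
#' Per-target correlation with Neff, Benjamini-Hochberg adjustment within
#' the supplied family (call once per family — e.g. rumen features, fecal
#' features, plasma analytes — to mirror separate reporting), significance
#' declared on `q <= alpha` (the raw p is also returned), and the strength
#' band attached. Constant targets are returned with `r = NA` and excluded
#' from the FDR family.
#'
#' @param x A [feature_table()] (targets = features, scaled to CPM), or a
#'   tibble/matrix with samples in rows and numeric target columns (an id
#'   column named `cow_id`/`sample_id` is ignored).
#' @param neff_values Per-sample Neff values aligned with the rows of `x`.
#' @param method `"spearman"` (features) or `"pearson"` (plasma analytes).
#' @param alpha Significance level on the adjusted q (default 0.05).
#' @return A tibble: `target_id`, `method`, `n`, `r`, `p`, `q`,
#'   `significant`, `strength`.
#' @export
correlate_features <- function(x, neff_values,
                               method = c("spearman", "pearson"),
                               alpha = 0.05) {
  method <- match.arg(method)
  if (inherits(x, "feature_table")) {
    mat <- cpm(x)
  } else {
    df <- as.data.frame(x)
    df <- df[, !(names(df) %in% c("cow_id", "sample_id")), drop = FALSE]
    num <- vapply(df, is.numeric, logical(1))
    mat <- as.matrix(df[, num, drop = FALSE])
  }
  if (ncol(mat) == 0L) {
    return(tibble(target_id = character(), method = character(),
                  n = integer(), r = numeric(), p = numeric(), q = numeric(),
                  significant = logical(), strength = character()))
  }
  if (nrow(mat) != length(neff_values)) {
    abort_domain("`neff_values` must align with the rows of `x`")
  }

  res <- purrr::map_dfr(seq_len(ncol(mat)), function(j) {
    ct <- cor_test(mat[, j], neff_values, method = method)
    tibble(target_id = colnames(mat)[j], method = method, n = ct$n,
           r = ct$r, p = ct$p.value)
  })
  res$q <- NA_real_
  ok <- !is.na(res$p)
  res$q[ok] <- fdr_bh(res$p[ok])
  res$significant <- !is.na(res$q) & res$q <= alpha
  res$strength <- classify_strength(res$r)
  res
}

#' Lollipop chart of correlation results
#'
#' @param assoc A tibble from [correlate_features()].
#' @param only_significant Keep only `significant` targets.
#' @return A ggplot.
#' @export
plot_correlations <- function(assoc, only_significant = FALSE) {
  df <- as_tibble(assoc)
  if (only_significant) df <- dplyr::filter(df, .data$significant)
  df <- dplyr::arrange(df, .data$r)
  df$target_id <- factor(df$target_id, levels = df$target_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$target_id,
                                   colour = .data$strength)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$r,
                                       yend = .data$target_id),
                          colour = "grey70") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "correlation with Neff", y = NULL,
                  colour = "strength") +
    ggplot2::theme_minimal()
}

#' Boxplots of an alpha-diversity metric by group
#'
#' @param data Output of [alpha_diversity()].
#' @param metric Metric column to plot.
#' @param group_col Grouping column.
#' @return A ggplot.
#' @export
plot_alpha_diversity <- function(data, metric = "shannon",
                                 group_col = "phenotype") {
  ggplot2::ggplot(as_tibble(data),
                  ggplot2::aes(x = .data[[group_col]],
                               y = .data[[metric]],
                               colour = .data[[group_col]])) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}
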