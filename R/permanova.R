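permanova_f <- function(d2, groups, n, a, idx_by_group = NULL) {
  # groups: integer group codes; idx list avoids re-splitting inside perms
  idx <- idx_by_group %||% split(seq_len(n), groups)
  ss_w <- 0
  for (ii in idx) ss_w <- ss_w + sum(d2[ii, ii]) / (2 * length(ii))
  ss_t <- sum(d2) / (2 * n)
  ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
}

#' Permutational multivariate ANOVA (PERMANOVA) on a distance matrix
#'
#' One-factor PERMANOVA: with total sum of squares
#' `SS_T = sum_{i<j} d_ij^2 / N` and within-group
#' `SS_W = sum_g sum_{i<j in g} d_ij^2 / n_g`, the pseudo-F is
#' `((SS_T - SS_W)/(a - 1)) / (SS_W/(N - a))` for `a` groups. Significance
#' comes from freely permuting the labels (no strata):
#' `p = (#(F_perm >= F_obs) + 1) / (n_perm + 1)`, so the smallest
#' attainable p is `1/(n_perm + 1)`.
#'
#' @param d A [stats::dist] or symmetric distance matrix.
#' @param labels Group label per sample; at least 2 groups of >= 2 samples.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Optional seed for the permutation stream.
#' @return An object of class `neff_permanova`: `statistic` (pseudo-F),
#'   `p.value`, sums of squares, degrees of freedom, `n_perm`, and the
#'   permuted F values.
#' @export
#' @examples
#' pts <- rbind(matrix(rnorm(10), 5), matrix(rnorm(10, 3), 5))
#' fit <- permanova(dist(pts), rep(c("a", "b"), each = 5), n_perm = 199, seed = 1)
#' glance(fit)
permanova <- function(d, labels, n_perm = 999, seed = NULL) {
  m <- as.matrix(d)
  n <- nrow(m)
  if (length(labels) != n) abort_domain("`labels` must match the matrix size")
  if (n_perm < 1) abort_domain("`n_perm` must be at least 1")
  groups <- as.integer(factor(labels))
  sizes <- table(groups)
  a <- length(sizes)
  if (a < 2) abort_domain("need at least 2 groups")
  if (any(sizes < 2)) abort_domain("every group needs at least 2 samples")

  d2 <- m^2
  idx <- split(seq_len(n), groups)
  f_obs <- permanova_f(d2, groups, n, a, idx)

  f_perm <- with_seed_if(seed, {
    vapply(seq_len(n_perm), function(i) {
      permanova_f(d2, sample(groups), n, a)
    }, numeric(1))
  })
  p <- (sum(f_perm >= f_obs) + 1) / (n_perm + 1)

  ss_w <- 0
  for (ii in idx) ss_w <- ss_w + sum(d2[ii, ii]) / (2 * length(ii))
  ss_t <- sum(d2) / (2 * n)

  structure(
    list(statistic = f_obs, p.value = p,
         ss_between = ss_t - ss_w, ss_within = ss_w, ss_total = ss_t,
         df_between = a - 1L, df_within = n - a,
         n_perm = n_perm, permuted_f = f_perm),
    class = "neff_permanova"
  )
}

#' @export
print.neff_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F(%d, %d) = %.3f, p = %.4g (%d permutations)\n",
              x$df_between, x$df_within, x$statistic, x$p.value, x$n_perm))
  invisible(x)
}

#' @describeIn permanova ANOVA-style table: one row per term
#'   (between-groups, within-groups, total).
#' @param x A `neff_permanova` object.
#' @param ... Unused.
#' @method tidy neff_permanova
#' @export
tidy.neff_permanova <- function(x, ...) {
  tibble(
    term = c("groups", "residual", "total"),
    df = c(x$df_between, x$df_within, x$df_between + x$df_within),
    sum_of_squares = c(x$ss_between, x$ss_within, x$ss_total),
    statistic = c(x$statistic, NA, NA),
    p.value = c(x$p.value, NA, NA)
  )
}

#' @describeIn permanova One-row summary with the pseudo-F, p, and the R2
#'   share of between-group variation.
#' @method glance neff_permanova
#' @export
glance.neff_permanova <- function(x, ...) {
  tibble(
    statistic = x$statistic, p.value = x$p.value,
    r.squared = x$ss_between / x$ss_total,
    df_between = x$df_between, df_within = x$df_within, n_perm = x$n_perm
  )
}

#' @describeIn permanova Histogram of the permutation null with the
#'   observed pseudo-F marked.
#' @param object A `neff_permanova` object.
#' @method autoplot neff_permanova
#' @export
autoplot.neff_permanova <- function(object, ...) {
  df <- tibble(f = object$permuted_f)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$statistic, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(x = "permuted pseudo-F", y = "count",
                  title = sprintf("observed F = %.2f, p = %.4g",
                                  object$statistic, object$p.value)) +
    ggplot2::theme_minimal()
}
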