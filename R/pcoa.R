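#' Principal coordinate analysis of a distance matrix
#'
#' Classical metric scaling: Gower double-centering of `-d^2/2`, symmetric
#' eigendecomposition, coordinates as eigenvectors scaled by the square
#' root of their (positive) eigenvalues. Eigenvalues within 1e-10 of zero
#' are snapped to zero; negative eigenvalues (non-Euclidean input) are
#' reported unchanged and carry no coordinate axis — no Lingoes/Cailliez
#' correction is applied.
#'
#' @param d A [stats::dist] or symmetric matrix of distances.
#' @return An object of class `neff_pcoa`: list with `coordinates`
#'   (samples x positive axes, columns `PCo1`, `PCo2`, ...), `eigenvalues`
#'   (all, descending), `proportion_explained` (over positive eigenvalues,
#'   summing to 1) and `labels`.
#' @export
#' @examples
#' pts <- cbind(x = c(0, 1, 0, 1), y = c(0, 0, 2, 2))
#' ord <- pcoa(dist(pts))
#' head(tidy(ord))
pcoa <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m) || !isSymmetric(unname(m), tol = 1e-8)) {
    abort_domain("`d` must be a symmetric distance matrix")
  }
  if (any(diag(m) != 0)) abort_domain("`d` must have a zero diagonal")
  n <- nrow(m)
  labels <- rownames(m) %||% paste0("sample_", seq_len(n))

  a <- -0.5 * m^2
  b <- sweep(sweep(a, 1L, rowMeans(a)), 2L, colMeans(a)) + mean(a)
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  vals <- e$values
  vals[abs(vals) < 1e-10] <- 0

  pos <- which(vals > 0)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(vals[pos]), nrow = length(pos))
  axis_names <- if (length(pos)) paste0("PCo", seq_along(pos)) else character(0)
  dimnames(coords) <- list(labels, axis_names)
  prop <- if (length(pos)) vals[pos] / sum(vals[pos]) else numeric()

  structure(
    list(coordinates = coords, eigenvalues = vals,
         proportion_explained = prop, labels = labels),
    class = "neff_pcoa"
  )
}

#' @export
print.neff_pcoa <- function(x, ...) {
  cat(sprintf("<pcoa> %d samples, %d positive axes\n",
              length(x$labels), ncol(x$coordinates)))
  if (length(x$proportion_explained)) {
    cat(sprintf("  axis 1-2 explain %.1f%% / %.1f%% of positive inertia\n",
                100 * x$proportion_explained[1],
                100 * (x$proportion_explained[2] %||% NA)))
  }
  invisible(x)
}

#' @describeIn pcoa Tidy the sample scores: one row per sample with axis
#'   columns.
#' @param x A `neff_pcoa` object.
#' @param ... Unused.
#' @method tidy neff_pcoa
#' @export
tidy.neff_pcoa <- function(x, ...) {
  dplyr::bind_cols(tibble(sample_id = x$labels), as_tibble(x$coordinates))
}

#' @describeIn pcoa One-row summary: sample count, axis count, variance
#'   shares of the first two axes, total negative inertia.
#' @method glance neff_pcoa
#' @export
glance.neff_pcoa <- function(x, ...) {
  tibble(
    n_samples = length(x$labels),
    n_positive_axes = ncol(x$coordinates),
    prop_axis1 = x$proportion_explained[1] %||% NA_real_,
    prop_axis2 = if (length(x$proportion_explained) > 1) x$proportion_explained[2] else NA_real_,
    negative_inertia = sum(x$eigenvalues[x$eigenvalues < 0])
  )
}

#' @describeIn pcoa Ordination scatter plot of the first two axes,
#'   optionally coloured/shaped by metadata columns joined on `sample_id`.
#' @param object A `neff_pcoa` object.
#' @param metadata Optional tibble with `sample_id` and grouping columns.
#' @param colour,shape Metadata column names to map.
#' @method autoplot neff_pcoa
#' @export
autoplot.neff_pcoa <- function(object, metadata = NULL, colour = NULL,
                               shape = NULL, ...) {
  df <- tidy(object)
  if (!is.null(metadata)) df <- dplyr::left_join(df, metadata, by = "sample_id")
  pct <- round(100 * object$proportion_explained[1:2], 1)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PCo1, y = .data$PCo2))
  if (!is.null(colour)) p <- p + ggplot2::aes(colour = .data[[colour]])
  if (!is.null(shape)) p <- p + ggplot2::aes(shape = .data[[shape]])
  p +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(
      x = sprintf("PCo1 (%.1f%%)", pct[1]),
      y = sprintf("PCo2 (%.1f%%)", pct[2]),
      colour = colour, shape = shape
    ) +
    ggplot2::theme_minimal()
}
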