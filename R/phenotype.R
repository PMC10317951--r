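#' Classify cows into low / mid / high nitrogen-efficiency phenotypes
#'
#' Applies the divergent-phenotype rule: cows more than `sd_split` sample
#' standard deviations (n - 1 denominator) below the cohort Neff mean are
#' `low`, more than `sd_split` SD above are `high`, and everything else —
#' including values exactly on a boundary — is `mid` (the inequalities are
#' strict). Labels are invariant to shifting all Neff values by a constant
#' or scaling them by a positive factor.
#'
#' `neff_labels()` is the vector workhorse; `classify_phenotype()` is the
#' data-frame interface that appends a `phenotype` column.
#'
#' @param x Numeric vector of per-cow Neff values (%); length >= 2.
#' @param sd_split SD multiplier of the split (default 0.5).
#' @return `neff_labels()`: a character vector in `{"low", "mid", "high"}`
#'   with attributes `cohort_mean` and `cohort_sd`.
#' @export
#' @examples
#' neff_labels(c(20, 22, 24, 26, 28, 30)) # low low mid mid high high
neff_labels <- function(x, sd_split = 0.5) {
  check_numeric(x, "x")
  if (length(x) < 2L) {
    abort_domain("need at least 2 cows: the cohort SD is undefined otherwise")
  }
  if (sd_split <= 0) abort_domain("`sd_split` must be positive")
  m <- mean(x)
  s <- sd(x)
  lab <- rep("mid", length(x))
  lab[x < m - sd_split * s] <- "low"
  lab[x > m + sd_split * s] <- "high"
  structure(lab, cohort_mean = m, cohort_sd = s)
}

#' @rdname neff_labels
#' @param data A data frame with a per-cow Neff column, e.g. the output of
#'   [partition_n()].
#' @param neff_col Name of the Neff column.
#' @return `classify_phenotype()`: `data` with an added `phenotype` factor
#'   (levels low, mid, high) and attributes `cohort_mean` / `cohort_sd`.
#' @export
classify_phenotype <- function(data, sd_split = 0.5, neff_col = "neff") {
  data <- as_tibble(data)
  if (!neff_col %in% names(data)) {
    abort_domain(sprintf("no `%s` column in `data`", neff_col))
  }
  lab <- neff_labels(data[[neff_col]], sd_split = sd_split)
  data$phenotype <- factor(lab, levels = c("low", "mid", "high"))
  attr(data, "cohort_mean") <- attr(lab, "cohort_mean")
  attr(data, "cohort_sd") <- attr(lab, "cohort_sd")
  data
}

#' Per-group mean and SEM of every numeric variable
#'
#' Summarises a per-cow table (typically [partition_n()] output with a
#' `phenotype` column) as mean +/- SEM per group, the form nitrogen-balance
#' group tables are reported in. SEM is `sd / sqrt(n)` and is NA for a
#' single-cow group.
#'
#' @param data A data frame of per-cow values.
#' @param group_col Grouping column name (default `"phenotype"`).
#' @param groups Optional subset/order of group levels to keep (e.g.
#'   `c("low", "high")`); groups absent from the data raise an error.
#' @return A long tibble: `variable`, `group`, `n`, `mean`, `sem`.
#' @export
#' @examples
#' part <- classify_phenotype(partition_n(simulate_herd(sim_config(1))))
#' group_summary(part, groups = c("low", "high"))
group_summary <- function(data, group_col = "phenotype", groups = NULL) {
  data <- as_tibble(data)
  if (!group_col %in% names(data)) {
    abort_domain(sprintf("no `%s` column in `data`", group_col))
  }
  g <- as.character(data[[group_col]])
  groups <- groups %||% unique(g)
  empty <- setdiff(groups, g)
  if (length(empty)) {
    abort_domain(sprintf("empty group(s): %s", paste(empty, collapse = ", ")))
  }
  keep <- g %in% groups
  data <- data[keep, , drop = FALSE]
  g <- factor(g[keep], levels = groups)

  num <- names(data)[vapply(data, is.numeric, logical(1))]
  purrr::map_dfr(num, function(v) {
    purrr::map_dfr(levels(g), function(lev) {
      x <- data[[v]][g == lev]
      tibble(variable = v, group = lev, n = length(x),
             mean = mean(x), sem = sem(x))
    })
  })
}
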