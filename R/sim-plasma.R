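# plausible free plasma AA panel for lactating Holsteins (ug/mL)
plasma_panel <- function() {
  tibble(
    analyte = c("Arg", "His", "Ile", "Leu", "Lys", "Met", "Phe", "Thr",
                "Trp", "Val", "Ala", "Asn", "Asp", "Gln", "Glu", "Gly",
                "Pro", "Ser", "Tyr"),
    mean = c(75, 55, 120, 150, 80, 25, 50, 95,
             45, 250, 230, 45, 10, 33, 60, 110,
             75, 65, 55),
    sd = c(11, 8, 18, 22, 12, 4, 7, 14,
           6, 37, 34, 7, 1.5, 5, 9, 16,
           11, 10, 8)
  )
}

#' Simulate a plasma amino-acid matrix with planted Neff correlations
#'
#' Builds a Gaussian-copula panel of free plasma amino acids: the Gln
#' analyte targets Pearson correlation `+aa_corr_pos` with the supplied
#' Neff values, Trp targets `-aa_corr_neg`, and every other analyte is
#' independent noise. Concentrations are scaled to a plausible panel of
#' means and SDs (ug/mL).
#'
#' @param config A [sim_config()].
#' @param neff Per-cow Neff values (%); length must equal `config$n_cows`.
#' @param cow_id Optional cow ids.
#' @return A tibble with `cow_id` and one numeric column per analyte, with
#'   a `truth` attribute naming the planted analytes and their target r.
#' @export
simulate_plasma <- function(config, neff, cow_id = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- length(neff)
  if (n != config$n_cows) {
    abort_config("`neff` must have one value per cow in the config")
  }
  cow_id <- cow_id %||% sprintf("cow_%02d", seq_len(n))
  panel <- plasma_panel()
  target <- setNames(rep(0, nrow(panel)), panel$analyte)
  target["Gln"] <- config$aa_corr_pos
  target["Trp"] <- -config$aa_corr_neg

  z <- if (sd(neff) > 0) (neff - mean(neff)) / sd(neff) else rep(0, n)

  vals <- withr::with_seed(sim_seed(config, "plasma"), {
    vapply(seq_len(nrow(panel)), function(j) {
      r <- target[[j]]
      x <- r * z + sqrt(1 - r^2) * rnorm(n)
      pmax(panel$mean[j] + panel$sd[j] * x, 0.1)
    }, numeric(n))
  })
  colnames(vals) <- panel$analyte

  out <- dplyr::bind_cols(tibble(cow_id = cow_id), as_tibble(vals))
  attr(out, "truth") <- tibble(
    analyte = c("Gln", "Trp"),
    target_r = c(config$aa_corr_pos, -config$aa_corr_neg)
  )
  out
}
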