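#' Simulate a full synthetic nitrogen-efficiency study
#'
#' End-to-end generator: a herd, its nitrogen partition and phenotype
#' labels, a shared phylogeny over the ASV universe, Dirichlet-multinomial
#' rumen and fecal count tables with planted differential features, plasma
#' amino acids with planted Neff correlations, and a truth ledger of
#' everything planted. Every component is reproducible from
#' `config$seed` alone.
#'
#' @param config A [sim_config()].
#' @return An object of class `neff_dataset`: a list with
#'   \describe{
#'     \item{config}{the generating [sim_config()]}
#'     \item{herd}{per-cow raw measurements ([simulate_herd()])}
#'     \item{partition}{[partition_n()] output plus the `phenotype` column}
#'     \item{tables}{named list of per-site [feature_table()]s}
#'     \item{combined}{one [feature_table()] over both sites (zero-filled)}
#'     \item{tree}{master phylogeny over the full ASV universe}
#'     \item{trees}{per-site prunings of the master tree}
#'     \item{plasma}{plasma amino-acid tibble ([simulate_plasma()])}
#'     \item{truth}{list: `differential` (planted features), `plasma`
#'       (planted correlations), `phenotype` (generator labels)}
#'   }
#' @export
#' @examples
#' ds <- simulate_dataset(sim_config(seed = 1, n_cows = 8,
#'   n_features_rumen = 60, n_features_feces = 40, n_features_shared = 20))
#' ds$partition$phenotype
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))

  herd <- simulate_herd(config)
  part <- classify_phenotype(partition_n(herd), sd_split = config$sd_split)

  n_total <- config$n_features_rumen + config$n_features_feces -
    config$n_features_shared
  tree <- simulate_tree(n_total, seed = sim_seed(config, "tree"))

  phen <- as.character(part$phenotype)
  tabs <- lapply(c(rumen = "rumen", feces = "feces"), function(s) {
    simulate_counts(config, phen, site = s, cow_id = herd$cow_id, tree = tree)
  })
  trees <- lapply(tabs, function(t) ape::keep.tip(tree, colnames(t$counts)))

  plasma <- simulate_plasma(config, part$neff, cow_id = herd$cow_id)

  truth <- list(
    differential = dplyr::bind_rows(lapply(tabs, attr, "truth")),
    plasma = attr(plasma, "truth"),
    phenotype = tibble(cow_id = herd$cow_id, label = phen)
  )

  structure(
    list(
      config = config, herd = herd, partition = part, tables = tabs,
      combined = combine_tables(tabs$rumen, tabs$feces),
      tree = tree, trees = trees, plasma = plasma, truth = truth
    ),
    class = "neff_dataset"
  )
}

#' @export
print.neff_dataset <- function(x, ...) {
  cat("<neff_dataset>\n")
  cat(sprintf("  %d cows (%s)\n", nrow(x$herd),
              paste(sprintf("%s: %d", levels(x$partition$phenotype),
                            table(x$partition$phenotype)), collapse = ", ")))
  for (s in names(x$tables)) {
    cat(sprintf("  %s: %d features, %d samples\n", s,
                ncol(x$tables[[s]]$counts), nrow(x$tables[[s]]$counts)))
  }
  cat(sprintf("  planted: %d differential features, plasma targets %s\n",
              nrow(x$truth$differential),
              paste(sprintf("%s r=%.2f", x$truth$plasma$analyte,
                            x$truth$plasma$target_r), collapse = ", ")))
  invisible(x)
}

#' Write / read the truth ledger of a synthetic dataset
#'
#' The ledger (planted differential features, planted plasma correlations,
#' generator phenotype labels) round-trips losslessly through JSON.
#'
#' @param truth The `truth` element of a [simulate_dataset()] result.
#' @param path File path.
#' @return `read_truth()` returns the ledger list with tibble elements.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, as_tibble)
}
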