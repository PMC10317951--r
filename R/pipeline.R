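#' Run the full phenotype-and-microbiome analysis end to end
#'
#' Chains every stage of the analysis on a synthetic study (or on a
#' pre-built [simulate_dataset()] result): nitrogen partition and
#' phenotype classification; rarefaction; per-site alpha diversity with
#' Kruskal-Wallis group comparisons; weighted UniFrac, PCoA and PERMANOVA
#' for sample site (all cows) and for phenotype within each site (low and
#' high cows only, mirroring a divergent-phenotype design); LEfSe-style
#' differential abundance per site; Spearman correlations of differential
#' features and Pearson correlations of plasma amino acids against Neff,
#' each family FDR-adjusted separately.
#'
#' @param config A [sim_config()]; ignored when `dataset` is supplied.
#' @param dataset Optional pre-built `neff_dataset`.
#' @param depth Rarefaction depth in reads (default 5834).
#' @param n_perm PERMANOVA permutations (default 999).
#' @param lefse_alpha,lda_threshold,n_boot LEfSe-style screen settings.
#' @param fdr_alpha Significance level on adjusted q for correlations.
#' @param out_dir Optional directory; when given, all result tables are
#'   written there (TSV/CSV/JSON/newick) with a version + seed + config
#'   hash header where the format allows comments.
#' @return An object of class `neff_pipeline`: list with `dataset`,
#'   `partition`, `group_table`, `alpha` (per-site tibbles), `alpha_tests`,
#'   `beta` (distance, pcoa, site and phenotype PERMANOVAs), `diffabund`,
#'   `clustering`, `correlations` (per family), and `params`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(sim_config(seed = 1, n_cows = 10,
#'   n_features_rumen = 80, n_features_feces = 60, n_features_shared = 30,
#'   library_size_mean = 4000, library_size_sd = 200), depth = 2000,
#'   n_perm = 99)
#' res$beta$site_permanova
#' }
run_pipeline <- function(config = sim_config(), dataset = NULL,
                         depth = 5834, n_perm = 999, lefse_alpha = 0.05,
                         lda_threshold = 2.0, n_boot = 30,
                         fdr_alpha = 0.05, out_dir = NULL) {
  ds <- dataset %||% simulate_dataset(config)
  config <- ds$config
  part <- ds$partition
  contrast <- c("low", "high")
  lowhigh <- part$cow_id[part$phenotype %in% contrast]

  # alpha diversity per site on rarefied tables
  rare <- lapply(ds$tables, rarefy_table, depth = depth,
                 seed = sim_seed(config, "rarefy"))
  alpha <- lapply(rare, alpha_diversity)
  alpha_tests <- lapply(alpha, function(a) {
    alpha_compare(a, groups = contrast)
  })

  # beta diversity across sites on the combined rarefied table
  rare_comb <- rarefy_table(ds$combined, depth = depth,
                            seed = sim_seed(config, "rarefy"))
  wu <- weighted_unifrac(rare_comb, ds$tree)
  ord <- pcoa(wu)
  site_perm <- permanova(wu, rare_comb$meta$site, n_perm = n_perm,
                         seed = config$seed)
  phen_perm <- lapply(rare, function(tab) {
    sub <- filter_samples(tab, tab$meta$phenotype %in% contrast)
    permanova(weighted_unifrac(sub, ds$tree), sub$meta$phenotype,
              n_perm = n_perm, seed = config$seed)
  })

  # feature-level contrast between low and high cows
  da <- lapply(rare, function(tab) {
    lefse_da(tab, groups = contrast, alpha = lefse_alpha,
             lda_threshold = lda_threshold, n_boot = n_boot,
             seed = config$seed)
  })
  clus <- lapply(names(da), function(s) {
    if (nrow(da[[s]]) >= 2) cluster_features(rare[[s]], da[[s]]$feature_id)
  })
  names(clus) <- names(da)

  # correlations with Neff on the divergent (low/high) cows
  neff_lh <- part$neff[match(lowhigh, part$cow_id)]
  corr <- lapply(names(rare), function(s) {
    tab <- rare[[s]]
    keep <- tab$meta$cow_id %in% lowhigh
    feats <- da[[s]]$feature_id
    if (!length(feats)) {
      return(correlate_features(matrix(numeric(), sum(keep), 0),
                                part$neff[match(tab$meta$cow_id[keep], part$cow_id)]))
    }
    sub <- cpm(filter_samples(tab, keep))[, feats, drop = FALSE]
    correlate_features(sub,
                       part$neff[match(tab$meta$cow_id[keep], part$cow_id)],
                       method = "spearman", alpha = fdr_alpha)
  })
  names(corr) <- names(rare)
  plasma_lh <- ds$plasma[match(lowhigh, ds$plasma$cow_id), , drop = FALSE]
  corr$plasma <- correlate_features(plasma_lh, neff_lh, method = "pearson",
                                    alpha = fdr_alpha)

  out <- structure(
    list(
      dataset = ds, partition = part,
      group_table = group_summary(part, groups = contrast),
      alpha = alpha, alpha_tests = alpha_tests,
      beta = list(distance = wu, pcoa = ord, site_permanova = site_perm,
                  phenotype_permanova = phen_perm),
      diffabund = da, clustering = clus, correlations = corr,
      params = list(depth = depth, n_perm = n_perm,
                    lefse_alpha = lefse_alpha, lda_threshold = lda_threshold,
                    n_boot = n_boot, fdr_alpha = fdr_alpha,
                    seed = config$seed)
    ),
    class = "neff_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

#' @export
print.neff_pipeline <- function(x, ...) {
  cat("<neff_pipeline>\n")
  cat(sprintf("  %d cows; rarefied to %d reads\n",
              nrow(x$partition), x$params$depth))
  cat(sprintf("  site PERMANOVA p = %.4g; phenotype p = %s\n",
              x$beta$site_permanova$p.value,
              paste(sprintf("%s %.3g", names(x$beta$phenotype_permanova),
                            vapply(x$beta$phenotype_permanova,
                                   function(f) f$p.value, numeric(1))),
                    collapse = ", ")))
  cat(sprintf("  differential features: %s\n",
              paste(sprintf("%s %d", names(x$diffabund),
                            vapply(x$diffabund, nrow, integer(1))),
                    collapse = ", ")))
  invisible(x)
}

#' Write every pipeline artifact to a directory
#'
#' @param x A `neff_pipeline` result.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- x$dataset$config
  hdr <- file_header(seed = cfg$seed, hash = config_hash(cfg))
  path <- function(...) file.path(out_dir, paste0(...))

  write_herd_csv(x$dataset$herd, path("herd.csv"), header = hdr)
  write_with_header(x$partition, path("partition.csv"), ",", hdr)
  write_with_header(x$group_table, path("group_summary.csv"), ",", hdr)
  for (s in names(x$alpha)) {
    write_with_header(x$alpha[[s]], path("alpha_", s, ".tsv"), "\t", hdr)
    write_with_header(x$diffabund[[s]], path("diffabund_", s, ".tsv"), "\t", hdr)
    write_feature_table(x$dataset$tables[[s]], path("table_", s, ".tsv"), hdr)
  }
  write_distance_tsv(x$beta$distance, path("weighted_unifrac.tsv"), hdr)
  write_with_header(tidy(x$beta$pcoa), path("pcoa_coordinates.tsv"), "\t", hdr)
  jsonlite::write_json(
    list(eigenvalues = x$beta$pcoa$eigenvalues,
         proportion_explained = x$beta$pcoa$proportion_explained),
    path("pcoa.json"), digits = NA, auto_unbox = TRUE
  )
  perm <- c(list(site = x$beta$site_permanova), x$beta$phenotype_permanova)
  jsonlite::write_json(
    lapply(perm, function(f) list(pseudo_F = f$statistic, p = f$p.value,
                                  n_perm = f$n_perm)),
    path("permanova.json"), digits = NA, auto_unbox = TRUE
  )
  for (fam in names(x$correlations)) {
    write_with_header(x$correlations[[fam]],
                      path("correlations_", fam, ".tsv"), "\t", hdr)
  }
  write_newick(x$dataset$tree, path("tree.nwk"))
  write_truth(x$dataset$truth, path("truth.json"))
  invisible(out_dir)
}
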