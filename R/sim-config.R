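#' Configuration for the synthetic herd-and-microbiome generator
#'
#' Bundles every tunable of the seeded generator behind one validated object.
#' The defaults emulate the design of a divergent nitrogen-efficiency (Neff)
#' study in mid-lactation Holstein cows: 23 cows on a 16.5% crude-protein
#' total mixed ration, dry matter intake (DMI) around 26.7 +/- 2.5 kg/day,
#' body weight 633.5 +/- 49.8 kg, rumen and fecal 16S communities with
#' several hundred amplicon sequence variants (ASVs) each, library sizes
#' around 20,000 reads, and a plasma amino-acid panel carrying one positive
#' (Gln-like) and one negative (Trp-like) planted correlation with Neff.
#'
#' @param seed Integer master seed. Every generator derives its own
#'   substream from it by a fixed offset, so reproducibility survives
#'   reordering of calls.
#' @param n_cows Number of cows in the herd (>= 4).
#' @param sd_split Multiplier of the cohort SD used by the phenotype rule
#'   (low below `mean - sd_split*sd`, high above `mean + sd_split*sd`).
#' @param n_features_rumen,n_features_feces ASV richness of the rumen and
#'   fecal communities.
#' @param n_features_shared Number of ASVs present in both site communities;
#'   the remaining features are site-specific, which is what separates the
#'   sites in beta-diversity space.
#' @param n_differential Number of differentially abundant ASVs planted per
#'   site between the low and high phenotype groups.
#' @param effect_cpm Planted between-group difference in mean relative
#'   abundance, in counts per million. The enriched group's base composition
#'   gains `effect_cpm/1e6` on each planted feature and is renormalised.
#' @param concentration Dirichlet-multinomial concentration (sum of the
#'   Dirichlet parameters). Smaller values give stronger cow-to-cow
#'   overdispersion of composition.
#' @param library_size_mean,library_size_sd Normal parameters of per-sample
#'   sequencing depth (reads); must comfortably exceed the rarefaction depth.
#' @param sdlog_rumen,sdlog_feces Log-scale SD of the ranked lognormal base
#'   composition per site; controls how steep (uneven) the community is.
#' @param dmi_mean,dmi_sd Dry matter intake, kg DM/day.
#' @param diet_cp Diet crude protein as a fraction of DM.
#' @param refusal_rate Refusals as a fraction of feed offered.
#' @param refusal_cp_sd SD of the cow-level deviation of refusal CP from
#'   diet CP (fraction of DM).
#' @param milk_yield_mean Milk yield, kg/day, at average DMI.
#' @param milk_yield_dmi_slope kg extra milk per kg extra DMI.
#' @param milk_yield_sd Residual SD of milk yield, kg/day. Together with
#'   `dmi_sd` this is what gives the induced Neff distribution its spread.
#' @param milk_true_protein_mean,milk_true_protein_sd Milk true protein as a
#'   fraction of milk.
#' @param bw_mean,bw_sd Body weight, kg.
#' @param creatinine_mean,creatinine_sd Urine creatinine, mg/L.
#' @param urine_n_mean,urine_n_sd Urine N concentration, g N/L.
#' @param diet_marker Indigestible ADF marker in the diet, % of DM.
#' @param fecal_marker_mean,fecal_marker_sd Marker in feces, % of DM.
#' @param fecal_n_mean,fecal_n_sd Fecal N, % of DM.
#' @param aa_corr_pos Target Pearson correlation (+) between the planted
#'   Gln-like analyte and Neff; `|r| < 1`.
#' @param aa_corr_neg Magnitude of the target negative correlation between
#'   the planted Trp-like analyte and Neff; `|r| < 1`.
#'
#' @return An object of class `sim_config` (a named list).
#' @seealso [simulate_dataset()], [simulate_herd()], [simulate_counts()]
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$n_cows
sim_config <- function(seed = 1L,
                       n_cows = 23L,
                       sd_split = 0.5,
                       n_features_rumen = 800L,
                       n_features_feces = 550L,
                       n_features_shared = 300L,
                       n_differential = 20L,
                       effect_cpm = 2000,
                       concentration = 200,
                       library_size_mean = 20000,
                       library_size_sd = 2000,
                       sdlog_rumen = 1.75,
                       sdlog_feces = 1.45,
                       dmi_mean = 26.7,
                       dmi_sd = 2.5,
                       diet_cp = 0.165,
                       refusal_rate = 0.10,
                       refusal_cp_sd = 0.005,
                       milk_yield_mean = 37.7,
                       milk_yield_dmi_slope = 1.3,
                       milk_yield_sd = 5.5,
                       milk_true_protein_mean = 0.0305,
                       milk_true_protein_sd = 0.0012,
                       bw_mean = 633.5,
                       bw_sd = 49.8,
                       creatinine_mean = 730,
                       creatinine_sd = 60,
                       urine_n_mean = 8.7,
                       urine_n_sd = 0.9,
                       diet_marker = 2.0,
                       fecal_marker_mean = 5.7,
                       fecal_marker_sd = 0.35,
                       fecal_n_mean = 2.59,
                       fecal_n_sd = 0.12,
                       aa_corr_pos = 0.59,
                       aa_corr_neg = 0.61) {
  cfg <- as.list(environment())

  if (length(seed) != 1L || !is.finite(seed)) {
    abort_config("`seed` must be a single finite integer")
  }
  counts <- c(
    n_cows = n_cows, n_features_rumen = n_features_rumen,
    n_features_feces = n_features_feces,
    library_size_mean = library_size_mean, concentration = concentration
  )
  if (any(counts <= 0)) {
    abort_config(sprintf(
      "all count parameters must be positive (offending: %s)",
      paste(names(counts)[counts <= 0], collapse = ", ")
    ))
  }
  if (n_cows < 4) abort_config("`n_cows` must be at least 4")
  if (sd_split <= 0) abort_config("`sd_split` must be positive")
  if (diet_cp <= 0 || diet_cp >= 1) abort_config("`diet_cp` must lie in (0, 1)")
  if (refusal_rate < 0 || refusal_rate >= 1) {
    abort_config("`refusal_rate` must lie in [0, 1)")
  }
  if (n_features_shared < 0 ||
      n_features_shared > min(n_features_rumen, n_features_feces)) {
    abort_config("`n_features_shared` must not exceed either site's richness")
  }
  if (n_differential < 0) abort_config("`n_differential` must be >= 0")
  if (effect_cpm < 0) {
    abort_config("`effect_cpm` must be >= 0: a negative planted effect would push base proportions below zero")
  }
  if (effect_cpm >= 1e6) abort_config("`effect_cpm` must be below 1e6")
  if (abs(aa_corr_pos) >= 1 || abs(aa_corr_neg) >= 1) {
    abort_config("planted correlation targets must satisfy |r| < 1")
  }
  sds <- c(dmi_sd = dmi_sd, milk_yield_sd = milk_yield_sd, bw_sd = bw_sd,
           creatinine_sd = creatinine_sd, urine_n_sd = urine_n_sd,
           library_size_sd = library_size_sd)
  if (any(sds < 0)) abort_config("standard deviations must be >= 0")
  if (diet_marker <= 0 || fecal_marker_mean <= 0) {
    abort_config("marker percentages must be positive")
  }

  cfg$seed <- as.integer(seed)
  cfg$n_cows <- as.integer(n_cows)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  seed %d; %d cows; +/- %.2f SD phenotype split\n",
              x$seed, x$n_cows, x$sd_split))
  cat(sprintf("  features: %d rumen / %d feces (%d shared); %d planted at %g CPM\n",
              x$n_features_rumen, x$n_features_feces, x$n_features_shared,
              x$n_differential, x$effect_cpm))
  cat(sprintf("  library size ~ N(%g, %g); DM concentration %g\n",
              x$library_size_mean, x$library_size_sd, x$concentration))
  invisible(x)
}

# fixed substream offsets off the master seed (see sim_config docs)
sim_seed <- function(config, stream) {
  offsets <- c(herd = 1L, tree = 2L, base_rumen = 11L, base_feces = 12L,
               plant_rumen = 13L, plant_feces = 14L, counts_rumen = 15L,
               counts_feces = 16L, plasma = 17L, rarefy = 21L)
  (config$seed + offsets[[stream]]) %% .Machine$integer.max
}
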