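test_that("config validation rejects impossible study designs", {
  expect_error(sim_config(n_cows = 3), class = "neffbiome_config_error")
  expect_error(sim_config(sd_split = 0), class = "neffbiome_config_error")
  expect_error(sim_config(diet_cp = 1.2), class = "neffbiome_config_error")
  expect_error(sim_config(aa_corr_pos = 1), class = "neffbiome_config_error")
  expect_error(sim_config(effect_cpm = -10), class = "neffbiome_config_error")
  expect_error(sim_config(n_features_shared = 900), class = "neffbiome_config_error")
})

test_that("herd generation is deterministic under a seed", {
  cfg <- sim_config(seed = 11)
  expect_identical(simulate_herd(cfg), simulate_herd(cfg))
  cfg2 <- sim_config(seed = 12)
  expect_false(identical(simulate_herd(cfg), simulate_herd(cfg2)))
})

test_that("zero-noise herd collapses to a single Neff value", {
  cfg <- sim_config(seed = 5, dmi_sd = 0, milk_yield_sd = 0,
                    milk_true_protein_sd = 0, refusal_cp_sd = 0,
                    bw_sd = 0, creatinine_sd = 0, urine_n_sd = 0,
                    fecal_marker_sd = 0, fecal_n_sd = 0)
  part <- partition_n(simulate_herd(cfg))
  expect_equal(diff(range(part$neff)), 0)
})

test_that("herd-level DMI concentrates on its target mean", {
  cfg <- sim_config(seed = 1, n_cows = 200)
  herd <- simulate_herd(cfg)
  dmi <- herd$offered - herd$refused
  se <- 2.5 / sqrt(200)
  expect_lt(abs(mean(dmi) - 26.7), 3 * se)
  expect_true(all(herd$offered >= herd$refused))
  expect_true(all(herd$refused >= 0))
})

test_that("simulated trees are rooted, bifurcating and reproducible", {
  tr2 <- simulate_tree(2, seed = 1)
  expect_equal(length(tr2$tip.label), 2)
  expect_equal(tr2$Nnode, 1)

  tr5 <- simulate_tree(5, seed = 1)
  expect_equal(length(tr5$tip.label) + tr5$Nnode, 2 * 5 - 1)
  expect_true(ape::is.rooted(tr5))
  expect_true(ape::is.binary(tr5))
  expect_true(all(tr5$edge.length >= 0))

  expect_identical(ape::write.tree(simulate_tree(40, seed = 9)),
                   ape::write.tree(simulate_tree(40, seed = 9)))
  expect_error(simulate_tree(1), class = "neffbiome_config_error")
})

test_that("count tables conserve library sizes and record planted truth", {
  cfg <- small_config(seed = 2, n_differential = 5, effect_cpm = 5000)
  herd <- simulate_herd(cfg)
  part <- classify_phenotype(partition_n(herd))
  phen <- as.character(part$phenotype)

  tab <- simulate_counts(cfg, phen, site = "rumen", cow_id = herd$cow_id)
  tab2 <- simulate_counts(cfg, phen, site = "rumen", cow_id = herd$cow_id)
  expect_identical(tab$counts, tab2$counts) # determinism

  truth <- attr(tab, "truth")
  expect_equal(nrow(truth), 5)
  expect_true(all(truth$feature_id %in% colnames(tab$counts)))
  expect_true(all(truth$enriched_group %in% c("low", "high")))

  # row sums are exactly the drawn library sizes (multinomial conservation)
  libs <- withr::with_seed((cfg$seed + 15L) %% .Machine$integer.max, {
    pmax(round(rnorm(cfg$n_cows, cfg$library_size_mean, cfg$library_size_sd)), 1000)
  })
  expect_equal(unname(rowSums(tab$counts)), libs)
})

test_that("a null effect leaves the truth ledger empty", {
  cfg <- small_config(seed = 3, effect_cpm = 0)
  phen <- rep(c("low", "high"), 5)
  tab <- simulate_counts(cfg, phen, site = "feces")
  expect_equal(nrow(attr(tab, "truth")), 0)
})

test_that("planted CPM difference matches its target at low dispersion", {
  # near-multinomial counts, many cows, one planted feature: the empirical
  # between-group CPM difference should sit within 20% of the target
  cfg <- sim_config(seed = 4, n_cows = 40, n_differential = 1,
                    effect_cpm = 50000, concentration = 1e9,
                    n_features_rumen = 200, n_features_feces = 150,
                    n_features_shared = 50)
  phen <- rep(c("low", "high"), 20)
  tab <- simulate_counts(cfg, phen, site = "rumen")
  truth <- attr(tab, "truth")
  rel <- cpm(tab)
  enriched <- phen == truth$enriched_group
  diff <- mean(rel[enriched, truth$feature_id]) -
    mean(rel[!enriched, truth$feature_id])
  expect_gt(diff, 0.8 * 50000)
  expect_lt(diff, 1.2 * 50000)
})

test_that("plasma panel plants the requested correlations", {
  cfg <- sim_config(seed = 6, n_cows = 500, aa_corr_pos = 0.6)
  neff_vals <- rnorm(500, 26, 4)
  pl <- simulate_plasma(cfg, neff_vals)
  expect_identical(pl, simulate_plasma(cfg, neff_vals)) # determinism
  expect_lt(abs(cor(pl$Gln, neff_vals) - 0.6), 0.1)
  expect_lt(cor(pl$Trp, neff_vals), -0.4)

  # a zero target leaves the "positive" analyte independent of Neff
  cfg0 <- sim_config(seed = 6, n_cows = 500, aa_corr_pos = 0)
  pl0 <- simulate_plasma(cfg0, neff_vals)
  expect_lt(abs(cor(pl0$Gln, neff_vals)), 0.15)
})

test_that("the assembled dataset is internally consistent", {
  ds <- simulate_dataset(small_config(seed = 7, n_differential = 4,
                                      effect_cpm = 3000))
  expect_s3_class(ds, "neff_dataset")
  expect_setequal(unique(ds$truth$differential$site), c("rumen", "feces"))
  expect_true(all(ds$truth$differential$feature_id %in%
                    colnames(ds$combined$counts)))
  expect_true(all(colnames(ds$combined$counts) %in% ds$tree$tip.label))
  # generator labels come from the same rule the classifier applies
  expect_identical(ds$truth$phenotype$label,
                   as.character(ds$partition$phenotype))
  # truth ledger round-trips through JSON
  tmp <- withr::local_tempfile(fileext = ".json")
  write_truth(ds$truth, tmp)
  back <- read_truth(tmp)
  expect_equal(as.data.frame(back$differential),
               as.data.frame(ds$truth$differential))
  expect_equal(back$plasma$target_r, ds$truth$plasma$target_r)
})
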