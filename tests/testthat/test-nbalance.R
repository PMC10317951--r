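test_that("N intake follows the offered/refused crude-protein arithmetic", {
  expect_equal(n_intake(25, 0.165), 660)
  expect_equal(n_intake(30, 0.165, 3, 0.17), (4.95 - 0.51) / 6.25 * 1000)
  expect_equal(n_intake(0, 0.165, 0, 0.165), 0)
  expect_error(n_intake(10, 0.165, 12, 0.165), class = "neffbiome_domain_error")
  expect_error(n_intake(-1, 0.165), class = "neffbiome_domain_error")
})

test_that("milk N uses the 6.38 true-protein conversion", {
  expect_equal(milk_n(0, 0.031), 0)
  expect_equal(milk_n(32.8, 0.0311), 159.9, tolerance = 0.05 / 159.9)
  expect_equal(milk_n(1, 0.0638), 10)
  expect_error(milk_n(30, 1.2), class = "neffbiome_domain_error")
})

test_that("creatinine marker converts body weight to urine volume", {
  expect_equal(urine_volume(600, 2900), 6)
  expect_equal(urine_volume(633.5, 1450), 12.67, tolerance = 0.01 / 12.67)
  bw <- 512
  expect_equal(urine_volume(bw, 29 * bw), 1)
  expect_error(urine_volume(600, 0), class = "neffbiome_domain_error")
})

test_that("marker-ratio digestibility spans its limiting cases", {
  expect_equal(apparent_digestibility(2, 2, 3, 3), 0)
  expect_equal(apparent_digestibility(2, 4, 1.5, 3), 75)
  expect_equal(apparent_digestibility(2, 4, 0, 3), 100)
  expect_error(apparent_digestibility(0, 4, 1, 3), class = "neffbiome_domain_error")
})

test_that("fecal N is the indigestible share of intake", {
  expect_equal(fecal_n(713, 100), 0)
  expect_equal(fecal_n(713, 65.6), 245.3, tolerance = 0.1 / 245.3)
  expect_equal(fecal_n(0, 50), 0)
  expect_error(fecal_n(700, 120), class = "neffbiome_domain_error")
})

test_that("Neff is milk N over intake N in percent", {
  expect_equal(neff(0, 700), 0)
  expect_equal(neff(199, 658), 30.24, tolerance = 0.01 / 30.24)
  expect_equal(neff(162, 713), 22.72, tolerance = 0.01 / 22.72)
  expect_error(neff(100, 0), class = "neffbiome_domain_error")
})

make_cow <- function(cow_id = "c1", offered = 27, refused = 0,
                     diet_cp = 0.165, refusal_cp = 0.165, milk_yield = 35,
                     milk_true_protein = 0.031, bw = 633.5, creatinine = 730,
                     urine_n_conc = 8.8, diet_marker = 2, fecal_marker = 5.7,
                     diet_n = 2.64, fecal_n_frac = 2.59) {
  tibble::tibble(cow_id = cow_id, offered = offered, refused = refused,
                 diet_cp = diet_cp, refusal_cp = refusal_cp,
                 milk_yield = milk_yield,
                 milk_true_protein = milk_true_protein, bw = bw,
                 creatinine = creatinine, urine_n_conc = urine_n_conc,
                 diet_marker = diet_marker, fecal_marker = fecal_marker,
                 diet_n = diet_n, fecal_n_frac = fecal_n_frac)
}

test_that("partition satisfies the additive N identities to machine precision", {
  herd <- simulate_herd(sim_config(seed = 3))
  part <- partition_n(herd)
  expect_equal(part$manure_n, part$urinary_n + part$fecal_n, tolerance = 0)
  expect_equal(part$n_intake - part$milk_n - part$manure_n - part$retained_n,
               rep(0, nrow(part)), tolerance = 1e-12)
  expect_equal(part$manure_n_per_kg_milk, part$manure_n / herd$milk_yield)
})

test_that("partition flags undefined per-kg values instead of dividing by zero", {
  cow <- make_cow(milk_yield = 0)
  part <- partition_n(cow)
  expect_true(is.na(part$manure_n_per_kg_milk))
  expect_equal(part$milk_n, 0)
  expect_false(is.na(part$manure_n))
})

test_that("Neff increases in milk N and fecal N decreases in digestibility", {
  milk <- seq(100, 250, by = 25)
  expect_true(all(diff(neff(milk, 700)) > 0))
  dig <- seq(40, 90, by = 10)
  expect_true(all(diff(fecal_n(700, dig)) < 0))
})

test_that("digestibility and fecal N round-trip the marker-implied fecal fraction", {
  # constructed so that indigestible fraction = (md/mf)*(nf/nd)
  md <- 2; mf <- 5; nf <- 2.4; nd <- 2.64; intake <- 650
  dig <- apparent_digestibility(md, mf, nf, nd)
  expect_equal(fecal_n(intake, dig), intake * (md / mf) * (nf / nd))
})

test_that("phenotype rule splits at +/- 0.5 cohort SD with strict bounds", {
  x <- c(20, 22, 24, 26, 28, 30)
  lab <- neff_labels(x)
  expect_equal(as.character(lab), c("low", "low", "mid", "mid", "high", "high"))
  expect_equal(attr(lab, "cohort_sd"), sqrt(14))

  # boundary values are mid (strict inequalities)
  m <- mean(x); s <- sd(x)
  expect_equal(unclass(neff_labels(c(x, m + 0.5 * s)))[7], "mid")

  # all-equal cohort: sd = 0, everything mid
  expect_true(all(neff_labels(rep(25, 6)) == "mid"))

  # shift and positive scaling leave labels unchanged
  expect_equal(as.character(neff_labels(x + 7)), as.character(lab))
  expect_equal(as.character(neff_labels(x * 3.2)), as.character(lab))

  # labels partition the herd
  expect_true(all(neff_labels(rnorm(20, 25, 3)) %in% c("low", "mid", "high")))
  expect_error(neff_labels(25), class = "neffbiome_domain_error")
})

test_that("group summary reports mean and SEM per group", {
  df <- tibble::tibble(value = c(10, 14, 20, 30, 40),
                       phenotype = c("low", "low", "high", "high", "high"))
  gs <- group_summary(df)
  low <- gs[gs$group == "low" & gs$variable == "value", ]
  expect_equal(low$mean, 12)
  expect_equal(low$sem, 2)

  single <- group_summary(tibble::tibble(value = 5, phenotype = "low"))
  expect_true(is.na(single$sem))

  # means are invariant to row order within groups
  gs2 <- group_summary(df[c(3, 1, 5, 2, 4), ])
  expect_equal(dplyr::arrange(gs, group), dplyr::arrange(gs2, group))

  expect_error(group_summary(df, groups = c("low", "absent")),
               class = "neffbiome_domain_error")
})

test_that("herd validation names the offending row", {
  bad <- make_cow(cow_id = c("a", "b"), offered = c(20, 10),
                  refused = c(1, 12), milk_yield = c(30, 30))
  expect_error(partition_n(bad), "row\\(s\\) 2")
})
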