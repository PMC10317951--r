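#' Nitrogen-balance arithmetic for lactating cows
#'
#' The building blocks of an apparent nitrogen balance: N intake from feed
#' offered and refused, milk N from true protein, urine volume from the
#' creatinine marker, marker-based apparent digestibility, fecal N, and the
#' nitrogen-efficiency ratio. All functions vectorise over cows.
#'
#' Conventions: feed and fecal crude protein convert at N x 6.25, milk true
#' protein at N x 6.38; creatinine excretion is taken as 29 mg per kg of
#' body weight per day.
#'
#' @param offered Feed offered, kg DM/day.
#' @param diet_cp Diet crude protein, fraction of DM.
#' @param refused Feed refused, kg DM/day.
#' @param refusal_cp Refusal crude protein, fraction of DM.
#' @return `n_intake()`: N intake in g N/day,
#'   `(offered * diet_cp - refused * refusal_cp) / 6.25 * 1000`.
#' @name nbalance
#' @export
#' @examples
#' n_intake(25, 0.165) # 660 g/day
#' milk_n(32.8, 0.0311) # ~159.9 g/day
#' urine_volume(600, 2900) # 6 L/day
#' apparent_digestibility(2, 4, 1.5, 3) # 75%
n_intake <- function(offered, diet_cp, refused = 0, refusal_cp = 0) {
  check_numeric(offered, "offered")
  check_numeric(refused, "refused")
  if (any(offered < 0) || any(refused < 0)) {
    abort_domain("feed amounts must be non-negative")
  }
  if (any(refused > offered)) {
    abort_domain("`refused` cannot exceed `offered`")
  }
  (offered * diet_cp - refused * refusal_cp) / 6.25 * 1000
}

#' @rdname nbalance
#' @param milk_yield Milk yield, kg/day.
#' @param true_protein Milk true protein, fraction of milk.
#' @return `milk_n()`: milk N in g N/day,
#'   `milk_yield * (true_protein / 6.38) * 1000`.
#' @export
milk_n <- function(milk_yield, true_protein) {
  check_numeric(milk_yield, "milk_yield")
  check_numeric(true_protein, "true_protein")
  if (any(milk_yield < 0)) abort_domain("`milk_yield` must be non-negative")
  if (any(true_protein < 0) || any(true_protein >= 1)) {
    abort_domain("`true_protein` must be a fraction in [0, 1)")
  }
  milk_yield * (true_protein / 6.38) * 1000
}

#' @rdname nbalance
#' @param bw Body weight, kg.
#' @param creatinine Urine creatinine concentration, mg/L.
#' @return `urine_volume()`: estimated urine output in L/day,
#'   `29 * bw / creatinine`.
#' @export
urine_volume <- function(bw, creatinine) {
  check_numeric(bw, "bw")
  check_numeric(creatinine, "creatinine")
  if (any(bw <= 0)) abort_domain("`bw` must be positive")
  if (any(creatinine <= 0)) abort_domain("`creatinine` must be positive")
  29 * bw / creatinine
}

#' @rdname nbalance
#' @param marker_diet,marker_feces Internal marker (iADF), % of DM in diet
#'   and feces.
#' @param nutrient_feces,nutrient_diet Nutrient of interest, % of DM in
#'   feces and diet.
#' @return `apparent_digestibility()`: apparent digestibility in %,
#'   `100 - 100 * (marker_diet / marker_feces) * (nutrient_feces / nutrient_diet)`.
#' @export
apparent_digestibility <- function(marker_diet, marker_feces,
                                   nutrient_feces, nutrient_diet) {
  for (v in list(marker_diet = marker_diet, marker_feces = marker_feces,
                 nutrient_diet = nutrient_diet)) {
    check_numeric(v, "marker/nutrient input")
  }
  check_numeric(nutrient_feces, "nutrient_feces")
  if (any(marker_diet <= 0) || any(marker_feces <= 0) || any(nutrient_diet <= 0)) {
    abort_domain("marker and diet-nutrient percentages must be positive")
  }
  if (any(nutrient_feces < 0)) {
    abort_domain("`nutrient_feces` must be non-negative")
  }
  100 - 100 * (marker_diet / marker_feces) * (nutrient_feces / nutrient_diet)
}

#' @rdname nbalance
#' @param n_in N intake, g N/day.
#' @param n_digestibility Apparent N digestibility, %.
#' @return `fecal_n()`: fecal N in g N/day, the indigestible share of
#'   intake `n_in * (1 - n_digestibility / 100)`.
#' @export
fecal_n <- function(n_in, n_digestibility) {
  check_numeric(n_in, "n_in")
  check_numeric(n_digestibility, "n_digestibility")
  if (any(n_digestibility < 0) || any(n_digestibility > 100)) {
    abort_domain("`n_digestibility` must lie in [0, 100]")
  }
  n_in * (1 - n_digestibility / 100)
}

#' @rdname nbalance
#' @param milk_n_out Milk N, g N/day.
#' @return `neff()`: nitrogen efficiency in %, `milk_n_out / n_in * 100`.
#' @export
neff <- function(milk_n_out, n_in) {
  check_numeric(milk_n_out, "milk_n_out")
  check_numeric(n_in, "n_in")
  if (any(n_in <= 0)) abort_domain("`n_in` must be positive")
  milk_n_out / n_in * 100
}

herd_columns <- c(
  "cow_id", "offered", "refused", "diet_cp", "refusal_cp", "milk_yield",
  "milk_true_protein", "bw", "creatinine", "urine_n_conc", "diet_marker",
  "fecal_marker", "diet_n", "fecal_n_frac"
)

validate_herd <- function(herd) {
  herd <- as_tibble(herd)
  missing <- setdiff(herd_columns, names(herd))
  if (length(missing)) {
    abort_domain(sprintf("herd table is missing columns: %s",
                         paste(missing, collapse = ", ")))
  }
  bad <- which(herd$refused > herd$offered | herd$offered < 0 | herd$refused < 0)
  if (length(bad)) {
    abort_domain(sprintf("refused exceeds offered (or negative feed) in row(s) %s",
                         paste(bad, collapse = ", ")))
  }
  bad <- which(herd$bw <= 0 | herd$creatinine <= 0 |
                 herd$diet_marker <= 0 | herd$fecal_marker <= 0)
  if (length(bad)) {
    abort_domain(sprintf("non-positive body weight, creatinine or marker in row(s) %s",
                         paste(bad, collapse = ", ")))
  }
  frac <- c("diet_cp", "refusal_cp", "milk_true_protein")
  for (col in frac) {
    bad <- which(herd[[col]] < 0 | herd[[col]] >= 1)
    if (length(bad)) {
      abort_domain(sprintf("`%s` outside [0, 1) in row(s) %s", col,
                           paste(bad, collapse = ", ")))
    }
  }
  herd
}

#' Partition nitrogen flows for every cow in a herd
#'
#' Composes the N-balance building blocks into the full per-cow budget:
#' intake, milk, urinary, fecal, manure (urinary + fecal) and retained N
#' (intake - milk - manure), the Neff percentage, and manure components
#' expressed per kg of milk. The additive identities hold to machine
#' precision by construction.
#'
#' Urinary N is urine volume (creatinine marker) times the acid-adjusted
#' urine N concentration; fecal N is the indigestible share of N intake
#' using the cow's own marker-based apparent N digestibility.
#'
#' @param herd A herd tibble as produced by [simulate_herd()] or
#'   [read_herd_csv()] (see [simulate_herd()] for columns and units).
#' @return A tibble, one row per cow: `cow_id`, `dmi`, `milk_yield`,
#'   `n_intake`, `milk_n`, `urine_volume`, `urinary_n`, `n_digestibility`,
#'   `fecal_n`, `manure_n`, `retained_n`, `neff`, and `urinary_n_per_kg_milk`,
#'   `fecal_n_per_kg_milk`, `manure_n_per_kg_milk` (NA when milk yield is
#'   zero rather than infinite).
#' @export
#' @examples
#' herd <- simulate_herd(sim_config(seed = 1))
#' partition_n(herd)
partition_n <- function(herd) {
  herd <- validate_herd(herd)
  intake_n <- n_intake(herd$offered, herd$diet_cp, herd$refused, herd$refusal_cp)
  out_milk_n <- milk_n(herd$milk_yield, herd$milk_true_protein)
  uvol <- urine_volume(herd$bw, herd$creatinine)
  urinary <- uvol * herd$urine_n_conc
  dig <- apparent_digestibility(herd$diet_marker, herd$fecal_marker,
                                herd$fecal_n_frac, herd$diet_n)
  fecal <- fecal_n(intake_n, dig)
  manure <- urinary + fecal
  retained <- intake_n - (out_milk_n + manure)
  eff <- ifelse(intake_n > 0, out_milk_n / intake_n * 100, NA_real_)
  per_kg <- function(x) ifelse(herd$milk_yield > 0, x / herd$milk_yield, NA_real_)

  tibble(
    cow_id = herd$cow_id,
    dmi = herd$offered - herd$refused,
    milk_yield = herd$milk_yield,
    n_intake = intake_n,
    milk_n = out_milk_n,
    urine_volume = uvol,
    urinary_n = urinary,
    n_digestibility = dig,
    fecal_n = fecal,
    manure_n = manure,
    retained_n = retained,
    neff = eff,
    urinary_n_per_kg_milk = per_kg(urinary),
    fecal_n_per_kg_milk = per_kg(fecal),
    manure_n_per_kg_milk = per_kg(manure)
  )
}
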