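#' @rdname simulate_counts
#' @export
site_features <- function(config, site = c("rumen", "feces")) {
  site <- match.arg(site)
  n_total <- config$n_features_rumen + config$n_features_feces -
    config$n_features_shared
  idx <- if (site == "rumen") {
    seq_len(config$n_features_rumen)
  } else {
    seq.int(config$n_features_rumen - config$n_features_shared + 1L, n_total)
  }
  sprintf("ASV_%04d", idx)
}

# site-specific base composition: ranked lognormal relative abundances
# (a logistic-normal prior), steeper in the rumen than in feces
base_composition <- function(config, site = c("rumen", "feces")) {
  site <- match.arg(site)
  ids <- site_features(config, site)
  sdlog <- if (site == "rumen") config$sdlog_rumen else config$sdlog_feces
  p <- withr::with_seed(sim_seed(config, paste0("base_", site)), {
    x <- rlnorm(length(ids), meanlog = 0, sdlog = sdlog)
    x / sum(x)
  })
  setNames(p, ids)
}

# choose planted features and directions for one site
plant_differential <- function(config, site = c("rumen", "feces")) {
  site <- match.arg(site)
  if (config$n_differential == 0L || config$effect_cpm == 0) {
    return(tibble(feature_id = character(), site = character(),
                  enriched_group = character(), effect_cpm = numeric()))
  }
  ids <- site_features(config, site)
  if (config$n_differential > length(ids)) {
    abort_config("`n_differential` exceeds the site's feature count")
  }
  withr::with_seed(sim_seed(config, paste0("plant_", site)), {
    chosen <- sample(ids, config$n_differential)
  })
  tibble(
    feature_id = chosen,
    site = site,
    enriched_group = rep(c("high", "low"), length.out = config$n_differential),
    effect_cpm = config$effect_cpm
  )
}

#' Simulate a Dirichlet-multinomial ASV count table for one sample site
#'
#' Each cow's composition is drawn from a Dirichlet distribution centred on
#' the site's base composition (concentration `config$concentration`), then
#' counts are multinomial at a normally drawn library size. Cows in the
#' phenotype group a planted feature is enriched in use a base composition
#' with `effect_cpm/1e6` added to that feature (renormalised); all other
#' cows (including mid cows) use the unshifted base.
#'
#' `site_features()` returns the feature ids making up one site's community
#' within the shared feature universe.
#'
#' @param config A [sim_config()].
#' @param phenotype Per-cow phenotype labels (`"low"`, `"mid"`, `"high"`),
#'   typically from [classify_phenotype()].
#' @param site `"rumen"` or `"feces"`.
#' @param cow_id Optional per-cow ids (defaults to `cow_01`, ...).
#' @param tree Optional phylogeny; if supplied, every feature must be one of
#'   its tips (validated, error otherwise).
#' @return A [feature_table()] whose row sums equal the drawn library sizes
#'   exactly, with a `truth` attribute: a tibble of planted feature ids,
#'   their enriched group and planted effect (empty when `effect_cpm = 0`
#'   or `n_differential = 0`).
#' @export
simulate_counts <- function(config, phenotype, site = c("rumen", "feces"),
                            cow_id = NULL, tree = NULL) {
  stopifnot(inherits(config, "sim_config"))
  site <- match.arg(site)
  n <- length(phenotype)
  if (n == 0L) abort_config("`phenotype` must be nonempty")
  if (!all(phenotype %in% c("low", "mid", "high"))) {
    abort_config("`phenotype` labels must be 'low', 'mid' or 'high'")
  }
  cow_id <- cow_id %||% sprintf("cow_%02d", seq_len(n))

  base <- base_composition(config, site)
  truth <- plant_differential(config, site)

  shift <- config$effect_cpm / 1e6
  comp <- list(low = base, mid = base, high = base)
  for (g in c("low", "high")) {
    planted <- truth$feature_id[truth$enriched_group == g]
    if (length(planted)) {
      comp[[g]][planted] <- comp[[g]][planted] + shift
      if (any(comp[[g]] < 0)) {
        abort_config("planted effect pushes a base proportion below zero")
      }
      comp[[g]] <- comp[[g]] / sum(comp[[g]])
    }
  }

  if (!is.null(tree)) {
    missing <- setdiff(names(base), tree$tip.label)
    if (length(missing)) {
      abort_config(sprintf("features not in tree: %s",
                           paste(head(missing, 5), collapse = ", ")))
    }
  }

  nf <- length(base)
  counts <- withr::with_seed(sim_seed(config, paste0("counts_", site)), {
    lib <- pmax(round(rnorm(n, config$library_size_mean,
                            config$library_size_sd)), 1000)
    out <- matrix(0L, nrow = n, ncol = nf)
    for (i in seq_len(n)) {
      p <- comp[[phenotype[i]]]
      g <- rgamma(nf, shape = config$concentration * p)
      if (sum(g) <= 0) g <- p
      out[i, ] <- rmultinom(1, size = lib[i], prob = g / sum(g))[, 1]
    }
    out
  })
  dimnames(counts) <- list(paste(site, cow_id, sep = "_"), names(base))

  meta <- tibble(
    sample_id = rownames(counts),
    cow_id = cow_id,
    site = site,
    phenotype = as.character(phenotype)
  )
  ft <- feature_table(counts, meta)
  attr(ft, "truth") <- truth
  ft
}
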