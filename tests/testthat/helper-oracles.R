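# Brute-force weighted UniFrac: for every branch, find its descendant tips
# by walking root-to-tip node paths, then accumulate length * |p_A - p_B|.
# Deliberately independent of the package's postorder accumulation.
unifrac_oracle <- function(counts, tree) {
  p <- counts / rowSums(counts)
  paths <- ape::nodepath(tree)
  d <- matrix(0, nrow(p), nrow(p))
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    tips <- which(vapply(paths, function(pp) child %in% pp, logical(1)))
    labs <- tree$tip.label[tips]
    labs <- intersect(labs, colnames(p))
    mass <- if (length(labs)) rowSums(p[, labs, drop = FALSE]) else rep(0, nrow(p))
    d <- d + tree$edge.length[e] * abs(outer(mass, mass, "-"))
  }
  stats::as.dist(d)
}

# random table + tree pair for property tests
random_community <- function(n_samples, n_tips, seed) {
  withr::with_seed(seed, {
    tree <- ape::rtree(n_tips, br = function(k) stats::rexp(k, 5))
    tree$tip.label <- sprintf("T%03d", seq_len(n_tips))
    counts <- matrix(stats::rpois(n_samples * n_tips, 15) + 1L,
                     n_samples, n_tips,
                     dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                                     tree$tip.label))
    list(counts = counts, tree = tree)
  })
}

small_config <- function(seed = 1, ...) {
  defaults <- list(seed = seed, n_cows = 10, n_features_rumen = 80,
                   n_features_feces = 60, n_features_shared = 30,
                   library_size_mean = 4000, library_size_sd = 200)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
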