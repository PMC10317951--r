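#' Simulate a rooted bifurcating phylogeny over ASV tips
#'
#' Random rooted bifurcating topology (via [ape::rtree()]) with i.i.d.
#' exponential branch lengths and tips labelled `ASV_0001`, `ASV_0002`, ...
#' Used as the phylogeny behind weighted UniFrac on synthetic communities.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed; the same seed always returns the same tree.
#' @param rate Rate of the exponential branch-length distribution
#'   (mean branch length `1/rate`).
#' @param tip_prefix Prefix for tip labels.
#' @return An [ape::phylo] object with `2 * n_tips - 1` nodes.
#' @export
#' @examples
#' tr <- simulate_tree(8, seed = 1)
#' ape::is.rooted(tr)
simulate_tree <- function(n_tips, seed = 1L, rate = 10, tip_prefix = "ASV_") {
  if (length(n_tips) != 1L || !is.finite(n_tips) || n_tips < 2) {
    abort_config("`n_tips` must be a single integer >= 2")
  }
  n_tips <- as.integer(n_tips)
  tree <- withr::with_seed(as.integer(seed), {
    ape::rtree(n_tips, rooted = TRUE, br = function(k) rexp(k, rate))
  })
  # rtree scatters t1..tn over the topology; fix labels to the ASV scheme
  # in tip-index order so feature ids are stable across calls
  tree$tip.label <- sprintf("%s%04d", tip_prefix, seq_len(n_tips))
  tree
}
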