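#' Weighted UniFrac distances between community samples
#'
#' For each pair of samples A and B the distance is the branch-length
#' weighted difference in read mass placed on the tree:
#' `sum over branches b of length(b) * |p_A(b) - p_B(b)|`, where `p_X(b)`
#' is the fraction of sample X's reads on tips descending from branch b.
#' This is the unnormalised weighted UniFrac (the QIIME 2 / q2-diversity
#' default); set `normalized = TRUE` to divide each pair by
#' `sum length(b) * (p_A(b) + p_B(b))`, bounding distances by 1.
#'
#' Per-branch proportions use each sample's total reads as denominator, so
#' tables are usually rarefied first. Unrooted trees are midpoint-rooted
#' before computing. Tips absent from the table carry zero mass in every
#' sample and contribute nothing; features absent from the tree are an
#' error.
#'
#' @param x A [feature_table()] or samples-x-features count matrix; every
#'   sample must have at least one read.
#' @param tree An [ape::phylo] whose tips cover all features of `x`.
#' @param normalized Divide by the pairwise maximum attainable mass
#'   (default FALSE, the unnormalised variant).
#' @return A [stats::dist] over the samples.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "(A:1,B:1);")
#' m <- matrix(c(10L, 0L, 0L, 10L), 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("A", "B")))
#' weighted_unifrac(m, tr) # 2
weighted_unifrac <- function(x, tree, normalized = FALSE) {
  counts <- ft_counts(x)
  if (!inherits(tree, "phylo")) abort_domain("`tree` must be an ape phylo object")
  missing <- setdiff(colnames(counts), tree$tip.label)
  if (length(missing)) {
    abort_domain(sprintf("feature(s) missing from the tree: %s",
                         paste(head(missing, 5), collapse = ", ")))
  }
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    abort_domain(sprintf("sample(s) with zero reads: %s",
                         paste(head(rownames(counts)[totals == 0], 5),
                               collapse = ", ")))
  }
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  if (is.null(tree$edge.length)) abort_domain("`tree` must have branch lengths")

  ntip <- length(tree$tip.label)
  prop <- counts / totals

  # place sample mass on the tips, then accumulate it rootwards in
  # postorder so each edge's child-subtree mass is complete when read
  node_mass <- matrix(0, nrow(prop), ntip + tree$Nnode)
  node_mass[, match(colnames(prop), tree$tip.label)] <- prop
  tre <- stats::reorder(tree, "postorder")
  for (k in seq_len(nrow(tre$edge))) {
    par <- tre$edge[k, 1L]
    chi <- tre$edge[k, 2L]
    node_mass[, par] <- node_mass[, par] + node_mass[, chi]
  }
  edge_mass <- node_mass[, tre$edge[, 2L], drop = FALSE]

  scaled <- sweep(edge_mass, 2L, tre$edge.length, `*`)
  d <- dist(scaled, method = "manhattan")
  if (normalized) {
    s <- rowSums(scaled) # per-sample total branch mass
    denom <- as.dist(outer(s, s, `+`))
    d <- d / denom
  }
  attr(d, "Labels") <- rownames(counts)
  attr(d, "method") <- if (normalized) "weighted_unifrac_normalized" else "weighted_unifrac"
  d
}
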