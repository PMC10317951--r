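test_that("weighted UniFrac reproduces hand-computed branch sums", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  m <- matrix(c(10L, 0L, 0L, 10L), 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("A", "B")))
  expect_equal(as.numeric(weighted_unifrac(m, tr)), 2)

  # identical samples are at distance zero
  m2 <- rbind(s1 = c(A = 7L, B = 3L), s2 = c(A = 7L, B = 3L))
  expect_equal(as.numeric(weighted_unifrac(m2, tr)), 0)
})

test_that("weighted UniFrac validates its inputs", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  m <- matrix(c(1L, 1L, 1L, 1L), 2,
              dimnames = list(c("s1", "s2"), c("A", "Z")))
  expect_error(weighted_unifrac(m, tr), "Z")
  m0 <- matrix(c(1L, 0L, 1L, 0L), 2, byrow = FALSE,
               dimnames = list(c("s1", "empty"), c("A", "B")))
  m0["empty", ] <- 0L
  expect_error(weighted_unifrac(m0, tr), "zero reads")
})

test_that("weighted UniFrac matches the branch-enumeration oracle", {
  for (seed in 1:25) {
    cm <- random_community(n_samples = 4, n_tips = sample(4:16, 1), seed = seed)
    got <- weighted_unifrac(cm$counts, cm$tree)
    want <- unifrac_oracle(cm$counts, cm$tree)
    expect_lt(max(abs(got - want)), 1e-9)
  }
})

test_that("weighted UniFrac agrees with an independent implementation", {
  skip_if_not_installed("phyloseq")
  cm <- random_community(n_samples = 6, n_tips = 30, seed = 99)
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(cm$counts, taxa_are_rows = FALSE),
    phyloseq::phy_tree(cm$tree)
  )
  expect_equal(as.numeric(weighted_unifrac(cm$counts, cm$tree)),
               as.numeric(phyloseq::UniFrac(ps, weighted = TRUE,
                                            normalized = FALSE)),
               tolerance = 1e-10)
  expect_equal(as.numeric(weighted_unifrac(cm$counts, cm$tree, normalized = TRUE)),
               as.numeric(phyloseq::UniFrac(ps, weighted = TRUE,
                                            normalized = TRUE)),
               tolerance = 1e-10)
})

test_that("weighted UniFrac is a metric on random communities", {
  cm <- random_community(n_samples = 10, n_tips = 20, seed = 5)
  d <- as.matrix(weighted_unifrac(cm$counts, cm$tree))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0))
  n <- nrow(d)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
})

test_that("PCoA recovers planted Euclidean configurations", {
  withr::with_seed(2, {
    pts <- matrix(rnorm(10), 5, 2,
                  dimnames = list(paste0("p", 1:5), NULL))
  })
  ord <- pcoa(dist(pts))
  expect_lt(max(abs(dist(ord$coordinates[, 1:2]) - dist(pts))), 1e-8)
  # a truly Euclidean matrix has no meaningful negative eigenvalue
  expect_gt(min(ord$eigenvalues), -1e-8)
  expect_equal(sum(ord$proportion_explained), 1)
  expect_true(all(diff(ord$eigenvalues) <= 0))
})

test_that("PCoA handles degenerate and 1-D configurations", {
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(pcoa(z)$eigenvalues, rep(0, 4))

  col <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
                dimnames = list(letters[1:3], letters[1:3]))
  ordc <- pcoa(col)
  expect_equal(sum(ordc$eigenvalues > 0), 1)
  expect_equal(ordc$proportion_explained, 1)

  bad <- matrix(c(0, 1, 2, 0), 2)
  expect_error(pcoa(bad), class = "neffbiome_domain_error")
})

test_that("PCoA eigenvalues match classical scaling", {
  withr::with_seed(3, d <- dist(matrix(rnorm(24), 8, 3)))
  ord <- pcoa(d)
  cs <- stats::cmdscale(d, k = 3, eig = TRUE)
  expect_equal(ord$eigenvalues[1:3], cs$eig[1:3], tolerance = 1e-10)
})

test_that("PCoA tidiers expose scores and axis summaries", {
  withr::with_seed(4, d <- dist(matrix(rnorm(20), 5, 4)))
  ord <- pcoa(d)
  td <- tidy(ord)
  expect_equal(nrow(td), 5)
  expect_true(all(c("sample_id", "PCo1", "PCo2") %in% names(td)))
  gl <- glance(ord)
  expect_equal(gl$n_samples, 5)
  expect_s3_class(autoplot(ord), "ggplot")
})

test_that("PERMANOVA pseudo-F matches vegan::adonis2", {
  skip_if_not_installed("vegan")
  withr::with_seed(6, d <- dist(matrix(rnorm(36), 12, 3)))
  lab <- rep(c("a", "b", "c"), each = 4)
  fit <- permanova(d, lab, n_perm = 49, seed = 1)
  ref <- vegan::adonis2(d ~ lab, permutations = 49)
  expect_equal(fit$statistic, ref$F[1], tolerance = 1e-10)
  expect_equal(fit$ss_total, ref$SumOfSqs[nrow(ref)], tolerance = 1e-10)
  expect_equal(fit$ss_between, ref$SumOfSqs[1], tolerance = 1e-10)
})

test_that("separated clusters dominate every permutation", {
  # within-group distances 0, between-group 1: no permutation beats the
  # observed F (ties only when a permutation reproduces the partition)
  m <- matrix(1, 8, 8) - diag(8)
  m[1:4, 1:4] <- 0
  m[5:8, 5:8] <- 0
  diag(m) <- 0
  dimnames(m) <- list(paste0("s", 1:8), paste0("s", 1:8))
  lab <- rep(c("g1", "g2"), each = 4)
  fit <- permanova(m, lab, n_perm = 999, seed = 2)
  expect_true(all(fit$permuted_f <= fit$statistic + 1e-9))
  expect_lt(fit$p.value, 0.05)

  # with distinct distances and well-separated groups the permutation p
  # reaches its floor of 1/(n_perm + 1)
  pts <- withr::with_seed(11, rbind(matrix(rnorm(30, 0, 0.05), 10),
                                    matrix(rnorm(30, 10, 0.05), 10)))
  fit2 <- permanova(dist(pts), rep(c("a", "b"), each = 10),
                    n_perm = 999, seed = 2)
  expect_equal(fit2$p.value, 1 / 1000)
})

test_that("PERMANOVA is invariant to relabeling and consistent reordering", {
  withr::with_seed(8, d <- dist(matrix(rnorm(30), 10, 3)))
  lab <- rep(c("a", "b"), 5)
  f1 <- permanova(d, lab, n_perm = 99, seed = 3)
  f2 <- permanova(d, ifelse(lab == "a", "x", "y"), n_perm = 99, seed = 3)
  expect_equal(f1$statistic, f2$statistic)
  expect_equal(f1$p.value, f2$p.value)

  perm <- withr::with_seed(9, sample(10))
  m <- as.matrix(d)[perm, perm]
  f3 <- permanova(m, lab[perm], n_perm = 99, seed = 3)
  expect_equal(f3$statistic, f1$statistic)

  expect_error(permanova(d, c(rep("a", 9), "b"), n_perm = 9),
               class = "neffbiome_domain_error")
  expect_error(permanova(d, lab, n_perm = 0), class = "neffbiome_domain_error")
})

test_that("PERMANOVA tidiers summarise the fit", {
  withr::with_seed(10, d <- dist(matrix(rnorm(24), 8, 3)))
  fit <- permanova(d, rep(c("a", "b"), 4), n_perm = 49, seed = 1)
  td <- tidy(fit)
  expect_equal(td$term, c("groups", "residual", "total"))
  expect_equal(sum(td$sum_of_squares[1:2]), td$sum_of_squares[3])
  gl <- glance(fit)
  expect_true(gl$r.squared >= 0 && gl$r.squared <= 1)
})
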