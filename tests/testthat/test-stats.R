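test_that("correlation matrices are symmetric, unit-diagonal, oracle-exact", {
  set.seed(61)
  M <- matrix(runif(8 * 71), 8, 71)
  rownames(M) <- paste0("s", 1:8)
  R <- correlation_matrix(M)
  expect_equal(R, t(R))
  expect_equal(diag(R), rep(1, 8), ignore_attr = TRUE)
  expect_true(all(abs(R) <= 1 + 1e-12))
  for (i in 1:3) for (j in 5:8)
    expect_equal(R[i, j], slow_pearson(M[i, ], M[j, ]), tolerance = 1e-12)
  # duplicate rows correlate perfectly
  M2 <- rbind(M[1, ], M[1, ], M[3, ])
  rownames(M2) <- c("a", "b", "c")
  expect_equal(correlation_matrix(M2)["a", "b"], 1)
  # orthogonal mean-centered rows correlate at zero
  M3 <- rbind(c(1, -1, 1, -1), c(1, 1, -1, -1), c(1, 2, 3, 4))
  expect_equal(correlation_matrix(M3)[1, 2], 0)
  # zero-variance rows are flagged
  M4 <- rbind(rep(0.5, 5), runif(5), runif(5))
  expect_warning(R4 <- correlation_matrix(M4), "zero-variance")
  expect_true(is.na(R4[1, 2]))
})

test_that("ANOVA + Tukey matches the first-principles oracle to 1e-6", {
  set.seed(62)
  groups <- rep(c("g1", "g2", "g3", "g4"), each = 4)
  for (rep in 1:5) {
    y <- rnorm(16, mean = rep(runif(4, 0, 0.3), each = 4), sd = 0.1)
    M <- matrix(y, 16, 3, dimnames = list(paste0("s", 1:16), c("A", "B", "C")))
    res <- anova_tukey(M, "A", groups)
    oracle <- slow_anova_tukey(y, groups)
    expect_equal(res$F, oracle$F, tolerance = 1e-6)
    expect_equal(res$p, oracle$p, tolerance = 1e-6)
    expect_equal(res$tukey$p_adj, unname(oracle$p_adj[res$tukey$pair]),
                 tolerance = 1e-6)
  }
})

test_that("degenerate and strongly separated designs behave as declared", {
  groups <- rep(c("g1", "g2", "g3", "g4"), each = 4)
  same <- matrix(rep(0.2, 16), 16, 1, dimnames = list(NULL, "A"))
  res <- anova_tukey(same, "A", groups)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  expect_false(any(res$tukey$significant))
  set.seed(63)
  y <- rnorm(16, mean = rep(c(0, 0, 0, 10), each = 4), sd = 0.01)
  M <- matrix(y, 16, 1, dimnames = list(NULL, "A"))
  res2 <- anova_tukey(M, "A", groups)
  sig <- res2$tukey$significant
  names(sig) <- res2$tukey$pair
  expect_true(all(sig[c("g4-g1", "g4-g2", "g4-g3")]))
  expect_false(any(sig[c("g2-g1", "g3-g1", "g3-g2")]))
  expect_error(anova_tukey(M, "A", groups = rep("g1", 16)), ">= 2 groups")
})

test_that("ANOVA p-values are invariant to shifts and group relabeling", {
  set.seed(64)
  groups <- rep(c("g1", "g2", "g3", "g4"), each = 4)
  y <- rnorm(16, mean = rep(c(0, 0.1, 0.2, 0.3), each = 4), sd = 0.15)
  M <- matrix(y, 16, 1, dimnames = list(NULL, "A"))
  Ms <- M + 100
  expect_equal(anova_tukey(M, "A", groups)$p, anova_tukey(Ms, "A", groups)$p)
  relabeled <- c("gB", "gA", "gD", "gC")[match(groups,
                                               c("g1", "g2", "g3", "g4"))]
  expect_equal(anova_tukey(M, "A", groups)$p,
               anova_tukey(M, "A", relabeled)$p)
})

test_that("hierarchical clustering merges duplicates first, at height zero", {
  set.seed(65)
  a <- runif(30); b <- runif(30)
  M <- rbind(a, a, b, b + rnorm(30, sd = 1e-8))
  rownames(M) <- c("a1", "a2", "b1", "b2")
  tree <- hcluster(M)
  h <- tree$hclust$height
  expect_lt(h[1], 1e-9)
  sets <- tree$node_sets
  expect_true(list(c("a1", "a2")) %in% sets || any(
    vapply(sets, function(s) identical(s, c("a1", "a2")), logical(1))))
})

test_that("three-item average linkage equals the hand computation", {
  # construct items with known pairwise correlations via fixed vectors
  M <- rbind(c(1, 2, 3, 4, 5),
             c(1, 2, 3, 4, 6),
             c(5, 3, 4, 1, 2))
  rownames(M) <- c("x", "y", "z")
  R <- cor(t(M))
  d <- 1 - R
  tree <- hcluster(M)
  # first merge: the closest pair (x, y)
  expect_equal(sort(tree$node_sets[[1]]), c("x", "y"))
  expect_equal(tree$hclust$height[1], d["x", "y"])
  # second merge joins z at the average of its two distances
  expect_equal(tree$hclust$height[2], mean(c(d["x", "z"], d["y", "z"])))
})

test_that("cluster topology is invariant to item order and affine rescaling", {
  M <- two_cluster_matrix()
  key <- function(tree) sort(vapply(tree$node_sets, paste, character(1),
                                    collapse = "+"))
  t1 <- hcluster(M)
  perm <- c(5, 2, 7, 1, 8, 3, 6, 4)
  t2 <- hcluster(M[perm, ])
  expect_identical(key(t1), key(t2))
  Ms <- M * 3 + 17  # positive affine per-item rescaling
  expect_identical(key(t1), key(hcluster(Ms)))
  degenerate <- rbind(M[1:2, ], rep(1, ncol(M)))
  expect_error(hcluster(degenerate), "zero-variance")
})

test_that("bootstrap support is deterministic and separates real clusters", {
  M <- two_cluster_matrix()
  t1 <- bootstrap_support(M, n_boot = 150, seed = 42)
  t2 <- bootstrap_support(M, n_boot = 150, seed = 42)
  expect_identical(t1$bp, t2$bp)
  expect_identical(t1$au, t2$au)
  # the two planted 4-item clusters get near-unanimous support
  sizes <- lengths(t1$node_sets)
  top <- t1$bp[sizes == 4]
  expect_true(all(top >= 0.95))
  expect_true(all(t1$bp >= 0) && all(t1$bp <= 1))
  expect_true(all(t1$au >= 0) && all(t1$au <= 1))
  expect_error(bootstrap_support(M, n_boot = 150), "seed")
  expect_error(bootstrap_support(M, n_boot = 10, seed = 1), "n_boot")
  expect_error(bootstrap_support(M, n_boot = 150, scales = c(0.5, 2),
                                 seed = 1), "include 1")
})

test_that("pure noise earns no confident clusters", {
  set.seed(66)
  maxbp <- replicate(6, {
    Mn <- matrix(rnorm(8 * 150), 8)
    rownames(Mn) <- paste0("n", 1:8)
    tr <- bootstrap_support(Mn, n_boot = 150, scales = 1,
                            seed = sample.int(100000, 1))
    max(tr$bp[lengths(tr$node_sets) < 8])
  })
  expect_lt(median(maxbp), 0.8)
})
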