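test_that("tau-b matches brute-force pair counting, with and without ties", {
  expect_equal(kendall_tau_b(1:6, 1:6), 1)
  expect_equal(kendall_tau_b(1:6, 6:1), -1)
  x <- c(1, 2, 2, 3); y <- c(1, 2, 3, 3)
  expect_equal(kendall_tau_b(x, y), oracle_tau_b(x, y), tolerance = 1e-12)
  set.seed(71)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    a <- sample(1:5, n, replace = TRUE)   # ties likely
    b <- sample(1:5, n, replace = TRUE)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    expect_equal(suppressWarnings(kendall_tau_b(a, b)), oracle_tau_b(a, b),
                 tolerance = 1e-12)
  }
  # tie-free case reduces to plain Kendall tau
  for (rep in 1:5) {
    a <- sample(100, 8); b <- sample(100, 8)
    expect_equal(kendall_tau_b(a, b), oracle_tau_b(a, b), tolerance = 1e-12)
  }
})

test_that("pairwise-complete handling flags uncomputable cells", {
  expect_true(is.na(kendall_tau_b(c(1, 2, NA, NA), c(1, NA, 2, 3))))
  expect_equal(kendall_tau_b(c(1, 2, 3, NA), c(2, 4, 6, 1)), 1)
})

test_that("group averaging is an unweighted cell-wise mean, order invariant", {
  d <- tibble::tibble(
    group = rep(c("g1", "g2"), each = 6),
    m1 = c(1, 2, 3, 4, 5, 6, 1, 2, 3, 4, 5, 6),
    m2 = c(1, 2, 3, 4, 5, 6, 6, 5, 4, 3, 2, 1))   # tau +1 in g1, -1 in g2
  assoc <- groupwise_average_tau(d, measures = c("m1", "m2"))
  expect_equal(assoc$tau["m1", "m2"], 0)
  expect_equal(diag(assoc$tau), c(m1 = 1, m2 = 1))

  one <- groupwise_average_tau(d[d$group == "g1", ], measures = c("m1", "m2"))
  expect_equal(one$tau["m1", "m2"], 1)

  shuffled <- groupwise_average_tau(d[sample(nrow(d)), ],
                                    measures = c("m1", "m2"))
  expect_equal(shuffled$tau, assoc$tau)
})

test_that("a factored battery shows structure a factorless control lacks", {
  set.seed(72)
  n <- 100
  f <- rnorm(n)
  factored <- tibble::tibble(group = rep("a", n),
                             m1 = pnorm(0.8 * f + 0.6 * rnorm(n)),
                             m2 = pnorm(0.8 * f + 0.6 * rnorm(n)),
                             m3 = pnorm(0.8 * f + 0.6 * rnorm(n)))
  control <- tibble::tibble(group = rep("a", n),
                            m1 = runif(n), m2 = runif(n), m3 = runif(n))
  tf <- groupwise_average_tau(factored)$tau
  tc <- groupwise_average_tau(control)$tau
  expect_gt(mean(tf[upper.tri(tf)]), 0)
  expect_gt(mean(tf[upper.tri(tf)]), mean(tc[upper.tri(tc)]))
})

test_that("correlation distance supports signed and absolute readings", {
  tau <- matrix(c(1, -0.5, -0.5, 1), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(correlation_distance(tau)["a", "b"], 1.5)
  expect_equal(correlation_distance(tau, absolute = TRUE)["a", "b"], 0.5)
  expect_equal(diag(correlation_distance(tau)), c(a = 0, b = 0))
  expect_equal(correlation_distance(matrix(c(1, 1, 1, 1), 2))[1, 2], 0)
  tau[1, 2] <- NA
  expect_error(correlation_distance(tau), "missing cells")
})

test_that("UPGMA reproduces the hand-worked merges and ultrametric inputs", {
  d <- matrix(c(0, 2, 8,
                2, 0, 8,
                8, 8, 0), 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- upgma(d)
  expect_equal(sort(tree$height), c(2, 8))

  # 4-leaf ultrametric: cophenetic distances reproduce the input exactly
  u <- matrix(c(0, 1, 4, 4,
                1, 0, 4, 4,
                4, 4, 0, 2,
                4, 4, 2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tu <- upgma(u)
  expect_equal(cophenetic_distances(tu)[letters[1:4], letters[1:4]], u,
               tolerance = 1e-12)

  expect_error(upgma(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_error(upgma(matrix(c(0.5, 1, 1, 0), 2, 2)), "zero diagonal")
})

test_that("merge heights never decrease and leaf order does not matter", {
  set.seed(73)
  for (rep in 1:100) {
    pts <- matrix(runif(6 * 2), 6, 2)
    d <- as.matrix(dist(pts))
    tree <- upgma(d)
    expect_true(all(diff(tree$height) >= -1e-12))
  }
  d <- as.matrix(dist(matrix(runif(10 * 3), 10, 3)))
  rownames(d) <- colnames(d) <- paste0("m", 1:10)
  perm <- sample(10)
  t1 <- cophenetic_distances(upgma(d))
  t2 <- cophenetic_distances(upgma(d[perm, perm]))
  expect_equal(t2[rownames(t1), colnames(t1)], t1, tolerance = 1e-12)
})

test_that("dendrograms export to readable Newick", {
  d <- as.matrix(dist(matrix(runif(5 * 2), 5, 2)))
  rownames(d) <- colnames(d) <- paste0("m", 1:5)
  tree <- upgma(d)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(tree, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, paste0("m", 1:5))
})
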