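whiten_rows <- function(M) {
  # independent whitening used only by these tests
  M <- sweep(M, 1L, rowMeans(M))
  e <- eigen(tcrossprod(M) / ncol(M), symmetric = TRUE)
  diag(1 / sqrt(e$values)) %*% t(e$vectors) %*% M
}

test_that("subject reduction is lossless at full rank and tracks discarded eigenvalues", {
  # exact temporal rank 2
  coh <- make_cohort(cohort_config(n_subjects = 2, grid_dims = c(8, 8, 4),
                                   n_timepoints = 64, n_sources = 2,
                                   noise_sd = 0, missing_rate = 0, seed = 5))
  red <- reduce_subject(coh$scans[[1]], 2)
  X <- t(matrix(coh$scans[[1]]$voxels, prod(c(8, 8, 4)), 64))
  Xc <- sweep(X, 2, colMeans(X))
  recon <- red$model$basis %*% red$reduced
  expect_lt(sum((Xc - recon)^2) / sum(Xc^2), 1e-8)

  # random data: residual energy equals the sum of discarded eigenvalues
  set.seed(12)
  arr <- array(rnorm(6 * 6 * 3 * 20), c(6, 6, 3, 20))
  scan <- bold4d(arr, 2)
  red5 <- reduce_subject(scan, 5)
  Xr <- t(matrix(arr, 108, 20)); Xr <- sweep(Xr, 2, colMeans(Xr))
  resid <- sum((Xr - red5$model$basis %*% red5$reduced)^2) / 108
  expect_equal(resid, sum(red5$model$all_eigenvalues[-(1:5)]), tolerance = 1e-8)

  # voxel demeaning leaves temporal rank t - 1: k = t - 1 is lossless, t errors
  red_full <- reduce_subject(scan, 19)
  resid_full <- sum((Xr - red_full$model$basis %*% red_full$reduced)^2)
  expect_lt(resid_full / sum(Xr^2), 1e-16)
  expect_error(reduce_subject(scan, 20), "at most 19")

  # rows of the reduced data are uncorrelated (diagonal second moments)
  sm <- tcrossprod(red5$reduced) / 108
  expect_lt(max(abs(sm[upper.tri(sm)])) / max(diag(sm)), 1e-10)
})

test_that("group concatenation whitens and two identical subjects add no subspace", {
  set.seed(13)
  arr <- array(rnorm(6 * 6 * 3 * 30), c(6, 6, 3, 30))
  scan <- bold4d(arr, 2)
  r <- reduce_subject(scan, 6)$reduced
  one <- concatenate_and_reduce(list(r), 4)
  sm <- tcrossprod(one$whitened) / ncol(one$whitened)
  expect_lt(max(abs(sm - diag(4))), 1e-6)

  two <- concatenate_and_reduce(list(r, r), 4)
  # same retained subspace: principal angles between row spaces ~ 0
  sv <- svd(whiten_rows(one$whitened) %*% t(whiten_rows(two$whitened)) /
              ncol(one$whitened))$d
  expect_true(all(sv > 1 - 1e-8))

  bad <- matrix(rnorm(6 * 50), 6, 50)
  expect_error(concatenate_and_reduce(list(r, bad), 4), "different voxel mask")
})

test_that("InfoMax separates mixed Laplacian sources and is seed-deterministic", {
  set.seed(14)
  S <- matrix(sample(c(-1, 1), 2 * 2000, TRUE) * rexp(2 * 2000), 2, 2000)
  A <- matrix(c(0.8, 0.3, -0.4, 0.9), 2, 2)
  Y <- whiten_rows(A %*% S)
  fit <- infomax_unmix(Y, seed = 2)
  rec <- fit$W %*% Y
  cc <- abs(cor(t(rec), t(S)))
  # best match per planted source
  expect_true(all(apply(cc, 2, max) > 0.99))

  fit2 <- infomax_unmix(Y, seed = 2)
  expect_identical(fit$W, fit2$W)

  # already independent, unit-variance input: unmixing is a signed permutation
  Yind <- (S - rowMeans(S)) / apply(S, 1, sd)
  fit3 <- infomax_unmix(Yind, seed = 3)
  Wn <- fit3$W / sqrt(rowSums(fit3$W^2))
  expect_true(all(apply(abs(Wn), 1, max) > 0.99))
})

test_that("back-projection recovers planted time courses and handles edge cases", {
  coh <- clean_cohort()
  dec <- clean_ica()
  for (i in c(1, 5, 10)) {
    m <- match_components(t(dec$subject_timecourses[[i]]),
                          t(coh$truth_timeseries[[i]]))
    expect_true(all(abs(m$correlation) > 0.999))
  }

  # zero-signal subject: all-zero time courses
  zero <- bold4d(array(0, c(dim(coh$scans[[1]]$voxels))), 2)
  bp <- back_project(dec$group_maps, zero)
  expect_true(all(bp$timecourses == 0))

  # orthonormal maps: time courses are plain inner products
  set.seed(15)
  Q <- qr.Q(qr(matrix(rnorm(40 * 3), 40, 3)))   # 40 voxels, 3 maps
  maps <- t(Q)
  arr <- array(rnorm(40 * 30), c(5, 4, 2, 30))
  scan <- bold4d(arr, 2)
  bp2 <- back_project(maps, scan)
  X <- t(matrix(arr, 40, 30)); Xc <- sweep(X, 2, colMeans(X))
  expect_equal(bp2$timecourses, Xc %*% t(maps), tolerance = 1e-10)
})

test_that("restart stability is 1 for identical seeds, high for planted sources, lower for noise", {
  coh <- clean_cohort()
  dec <- clean_ica()
  expect_true(all(dec$stability$stability_index > 0.9))

  red <- lapply(coh$scans[1:3], function(s) reduce_subject(s, 5)$reduced)
  grp <- concatenate_and_reduce(red, 5)
  same <- stability_restarts(grp$whitened, seeds = rep(7, 4))
  expect_equal(same$stability_index, rep(1, 5), tolerance = 1e-12)

  set.seed(16)
  noise <- whiten_rows(matrix(rnorm(5 * 500), 5, 500))
  noisy <- suppressWarnings(stability_restarts(noise, n_restarts = 6, base_seed = 1))
  expect_lt(mean(noisy$stability_index), mean(dec$stability$stability_index))
})

test_that("group ICA recovers planted sources, is deterministic, and guards rank", {
  coh <- clean_cohort()
  dec <- clean_ica()
  m <- match_components(dec$group_maps, coh$truth_sources$spatial_maps)
  expect_true(all(abs(m$correlation) >= 0.95))

  dec2 <- run_group_ica(coh$scans, n_components = 5, seed = 11)
  expect_identical(dec2$group_maps, dec$group_maps)
  expect_identical(dec2$subject_timecourses, dec$subject_timecourses)

  # group rank of a noiseless 3-source cohort is 3: requesting 8 must fail
  small <- make_cohort(cohort_config(n_subjects = 3, grid_dims = c(8, 8, 4),
                                     n_timepoints = 64, n_sources = 3,
                                     noise_sd = 0, missing_rate = 0, seed = 6))
  expect_error(run_group_ica(small$scans, n_components = 8, seed = 1),
               "exceeds the group rank")
})

test_that("average subject maps align with group maps and recovery degrades with noise", {
  dec <- clean_ica()
  avg <- Reduce(`+`, dec$subject_maps) / length(dec$subject_maps)
  for (c in 1:5) {
    expect_gte(abs(cor(avg[c, ], dec$group_maps[c, ])), 0.9)
  }

  mean_match <- vapply(c(0, 0.5, 2), function(ns) {
    coh <- make_cohort(cohort_config(n_subjects = 6, grid_dims = c(10, 10, 6),
                                     n_timepoints = 80, n_sources = 3,
                                     noise_sd = ns, missing_rate = 0, seed = 17))
    d <- suppressWarnings(run_group_ica(coh$scans, n_components = 3, seed = 2))
    mean(abs(match_components(d$group_maps,
                              coh$truth_sources$spatial_maps)$correlation))
  }, numeric(1))
  expect_true(all(diff(mean_match) <= 1e-6))
})

test_that("fALFF features are invariant to component relabeling across restarts", {
  coh <- clean_cohort()
  dec_a <- clean_ica()
  dec_b <- run_group_ica(coh$scans, n_components = 5, seed = 99)
  fa <- falff_features(dec_a, 2)
  fb <- falff_features(dec_b, 2)
  m <- match_components(dec_b$group_maps, dec_a$group_maps)
  expect_equal(unname(fb$normalized[, m$component]), unname(fa$normalized),
               tolerance = 1e-3)
})
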