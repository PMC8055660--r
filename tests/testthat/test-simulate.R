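test_that("planted sources are deterministic, separated, and refuse infeasible grids", {
  s1 <- make_sources(2, c(10, 10, 5), seed = 1)
  s2 <- make_sources(2, c(10, 10, 5), seed = 1)
  expect_identical(s1$spatial_maps, s2$spatial_maps)

  cc <- cor(t(s1$spatial_maps))
  expect_lt(abs(cc[1, 2]), 0.2)
  expect_true(all(rowSums(s1$spatial_maps != 0) > 0))

  expect_error(make_sources(500, c(4, 4, 2), seed = 1),
               class = "falffprog_config_error")
  # many sources under the voxel bound but unplaceable at separation
  expect_error(make_sources(12, c(5, 5, 5), seed = 1),
               class = "falffprog_config_error")
})

test_that("synthesized time series hit their target fALFF within 0.02", {
  for (target in c(0, 0.15, 0.4, 0.65, 0.9, 1)) {
    for (seed in c(2, 9)) {
      x <- make_component_timeseries(target, 120, 2, seed = seed)
      expect_lt(abs(component_falff(x, 2) - target), 0.02)
    }
  }
  # full-length acquisition
  x <- make_component_timeseries(1, 210, 2, seed = 4)
  expect_gte(component_falff(x, 2), 0.98)
  x0 <- make_component_timeseries(0, 210, 2, seed = 4)
  expect_lte(component_falff(x0, 2), 0.02)

  expect_identical(make_component_timeseries(0.5, 120, 2, seed = 8),
                   make_component_timeseries(0.5, 120, 2, seed = 8))
  # TR so long the band reaches past Nyquist
  expect_error(make_component_timeseries(0.5, 120, 7, seed = 1),
               class = "falffprog_config_error")
})

test_that("noiseless scans are exactly the planted mixing and cohorts are bit-reproducible", {
  cfg <- cohort_config(n_subjects = 3, grid_dims = c(8, 8, 4), n_timepoints = 64,
                       n_sources = 2, noise_sd = 0, missing_rate = 0, seed = 5)
  coh <- make_cohort(cfg)
  for (i in 1:3) {
    expected <- cfg$baseline +
      t(coh$truth_sources$spatial_maps) %*% t(coh$truth_timeseries[[i]])
    expect_lt(max(abs(as.vector(coh$scans[[i]]$voxels) - as.vector(expected))), 1e-9)
  }
  coh2 <- make_cohort(cfg)
  expect_identical(coh$scans[[2]]$voxels, coh2$scans[[2]]$voxels)
  expect_identical(coh$behavioral, coh2$behavioral)
})

test_that("noiseless outcomes equal the clamped linear model of the planted truth", {
  cfg <- cohort_config(n_subjects = 12, grid_dims = c(8, 8, 4), n_timepoints = 64,
                       n_sources = 3, outcome_noise_sd = 0, missing_rate = 0,
                       seed = 6)
  coh <- make_cohort(cfg)
  nf <- coh$truth_falff / rowSums(coh$truth_falff)
  w <- cfg$outcome_weights
  expected <- clamp_prediction(w[1] * coh$behavioral$pre_tsm + as.vector(nf %*% w[-1]))
  expect_equal(coh$behavioral$post_tsm, expected, tolerance = 1e-12)
})

test_that("behavioral missingness hits the configured MCAR rate and spares outcomes", {
  cfg <- cohort_config(n_subjects = 30, grid_dims = c(8, 8, 4), n_timepoints = 64,
                       n_sources = 2, missing_rate = 0.033, seed = 8)
  coh <- make_cohort(cfg)
  meas <- dplyr::select(coh$behavioral, dplyr::starts_with("measure_"))
  n_cells <- prod(dim(meas))
  phat <- sum(is.na(meas)) / n_cells
  # binomial tolerance: 3 sd of the cell-wise rate
  expect_lt(abs(phat - 0.033), 3 * sqrt(0.033 * 0.967 / n_cells))
  expect_false(anyNA(coh$behavioral$pre_tsm))
  expect_false(anyNA(coh$behavioral$post_tsm))
  expect_true(all(coh$behavioral$pre_tsm >= 0 & coh$behavioral$pre_tsm <= 1))
  expect_true(all(coh$behavioral$post_tsm >= 0 & coh$behavioral$post_tsm <= 1))
})

test_that("battery measures sharing a factor correlate more strongly than those that do not", {
  coh <- make_cohort(cohort_config(n_subjects = 60, grid_dims = c(8, 8, 4),
                                   n_timepoints = 64, n_sources = 2, seed = 21))
  assoc <- groupwise_average_tau(coh$behavioral)
  blocks <- sort(rep_len(1:3, 27))
  same <- outer(blocks, blocks, "==") & upper.tri(diag(27))
  diff <- outer(blocks, blocks, "!=") & upper.tri(diag(27))
  expect_gt(mean(assoc$tau[same], na.rm = TRUE),
            mean(assoc$tau[diff], na.rm = TRUE))
})

test_that("cohorts round-trip through NIfTI and CSV on disk", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_subjects = 2, grid_dims = c(8, 8, 4), n_timepoints = 64,
                       n_sources = 2, seed = 9)
  coh <- make_cohort(cfg)
  write_cohort(coh, dir)
  back <- read_bold_nifti(file.path(dir, "sub-001_bold.nii.gz"),
                          mask_path = file.path(dir, "mask.nii.gz"))
  expect_equal(back$tr_seconds, 2)
  expect_equal(dim(back$voxels), dim(coh$scans[[1]]$voxels))
  expect_equal(as.vector(back$voxels), as.vector(coh$scans[[1]]$voxels),
               tolerance = 1e-6)
  tab <- readr::read_csv(file.path(dir, "behavioral.csv"), show_col_types = FALSE)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("pre_tsm", "post_tsm") %in% names(tab)))
})
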