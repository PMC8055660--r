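# Shared fixtures, built lazily once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# 10 subjects, 5 planted sources, no scanner noise: the ICA recovery regime.
clean_cohort <- function() {
  fixture("clean_cohort", function() {
    make_cohort(cohort_config(n_subjects = 10, noise_sd = 0, missing_rate = 0,
                              seed = 3))
  })
}

clean_ica <- function() {
  fixture("clean_ica", function() {
    run_group_ica(clean_cohort()$scans, n_components = 5, seed = 11,
                  n_restarts = 10)
  })
}

# 30 subjects at the generator defaults: the parameter-recovery regime
# (scanner noise 0.1, outcome noise 0.03, 3.3% behavioral missingness).
recovery_cohort <- function() {
  fixture("recovery_cohort", function() make_cohort(cohort_config(seed = 7)))
}

recovery_features <- function() {
  fixture("recovery_features", function() {
    dec <- run_group_ica(recovery_cohort()$scans, n_components = 5, seed = 11)
    falff_features(dec, tr_by_subject = recovery_cohort()$config$tr_seconds)
  })
}

recovery_table <- function() {
  fixture("recovery_table", function() {
    dplyr::left_join(
      tidy(recovery_features()),
      recovery_cohort()$behavioral[c("subject_id", "pre_tsm", "post_tsm")],
      by = "subject_id")
  })
}

recovery_fit <- function() {
  fixture("recovery_fit", function() loocv_predict(recovery_table()))
}

# Scan whose every in-mask voxel time course has exactly the requested
# temporal mean and sd (z-profile normalized to unit sd, shared across voxels
# unless jitter_seed is given).
exact_tsnr_scan <- function(mean, sd, dims = c(4, 4, 2), n_t = 40,
                            jitter_seed = NULL, mask = NULL) {
  z <- seq(-1, 1, length.out = n_t)
  z <- (z - mean(z)) / stats::sd(z)
  arr <- array(0, c(dims, n_t))
  for (t in seq_len(n_t)) arr[, , , t] <- mean + sd * z[t]
  if (!is.null(jitter_seed)) {
    set.seed(jitter_seed)
    # random per-voxel phase: permute the profile independently per voxel
    vox <- matrix(arr, prod(dims), n_t)
    for (v in seq_len(nrow(vox))) vox[v, ] <- mean + sd * sample(z)
    arr <- array(vox, c(dims, n_t))
  }
  bold4d(arr, tr_seconds = 2, mask = mask, subject_id = sprintf("tsnr-%g", mean / sd))
}

# Small complete prognostic table with a planted linear signal.
toy_table <- function(n = 10, p = 3, seed = 42, noise_sd = 0.02) {
  set.seed(seed)
  X <- matrix(runif(n * p, 0.1, 0.9), n, p)
  colnames(X) <- paste0("x", seq_len(p))
  pre <- runif(n, 0.3, 0.9)
  post <- clamp_prediction(0.5 * pre + X %*% c(0.4, -0.3, 0.2) +
                             rnorm(n, sd = noise_sd))
  tibble::tibble(subject_id = sprintf("s%02d", seq_len(n))) |>
    dplyr::bind_cols(tibble::as_tibble(X)) |>
    dplyr::mutate(pre_tsm = pre, post_tsm = as.vector(post))
}
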