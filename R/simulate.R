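#' Planted spatial sources on a small 3D grid
#'
#' Generates approximately independent spatial sources as smoothed random
#' blobs with compact support: each source is a Gaussian bump with a random
#' centre and width, thresholded to zero outside its core. Centres are placed
#' with a minimum separation so that pairwise spatial correlations stay small
#' (|r| < 0.2), mimicking the statistical independence of ICA components
#' without committing to any anatomical template.
#'
#' @param n_sources Number of sources.
#' @param grid_dims Integer vector of length 3, the spatial grid.
#' @param seed Integer seed; the result is deterministic given the arguments.
#' @param min_separation Minimum Euclidean distance between source centres, in
#'   voxels.
#' @return An object of class `source_set`: list with `spatial_maps`
#'   (n_sources x n_voxels, column-major voxel order), `grid_dims`, `centres`,
#'   `sigmas`.
#' @export
make_sources <- function(n_sources, grid_dims, seed, min_separation = 4) {
  n_sources <- check_count(n_sources, "n_sources")
  if (length(grid_dims) != 3L || any(grid_dims < 2)) {
    abort("`grid_dims` must be three integers >= 2.", class = "falffprog_config_error")
  }
  grid_dims <- as.integer(grid_dims)
  n_voxels <- prod(grid_dims)
  if (n_sources > n_voxels / 10) {
    abort(sprintf(
      "Grid too small: %d sources requested but only %d voxels (need n_sources <= n_voxels/10).",
      n_sources, n_voxels), class = "falffprog_config_error")
  }
  coords <- as.matrix(expand.grid(x = seq_len(grid_dims[1]),
                                  y = seq_len(grid_dims[2]),
                                  z = seq_len(grid_dims[3])))

  for (attempt in seq_len(25L)) {
    res <- with_seed(derive_seed(seed, attempt, 11L), {
      centres <- matrix(NA_real_, n_sources, 3)
      sigmas <- stats::runif(n_sources, 1.0, min(1.7, min_separation / 3))
      placed <- 0L
      tries <- 0L
      while (placed < n_sources && tries < 400L * n_sources) {
        cand <- c(stats::runif(1, 1, grid_dims[1]),
                  stats::runif(1, 1, grid_dims[2]),
                  stats::runif(1, 1, grid_dims[3]))
        ok <- placed == 0L ||
          min(sqrt(rowSums(sweep(centres[seq_len(placed), , drop = FALSE], 2, cand)^2))) >=
            min_separation
        if (ok) {
          placed <- placed + 1L
          centres[placed, ] <- cand
        }
        tries <- tries + 1L
      }
      if (placed < n_sources) NULL else {
        maps <- matrix(0, n_sources, n_voxels)
        for (k in seq_len(n_sources)) {
          d2 <- rowSums(sweep(coords, 2, centres[k, ])^2)
          v <- exp(-d2 / (2 * sigmas[k]^2))
          v[v < 0.05] <- 0
          maps[k, ] <- v
        }
        list(maps = maps, centres = centres, sigmas = sigmas)
      }
    })
    if (is.null(res)) next
    if (any(rowSums(res$maps != 0) == 0)) next
    ok_cor <- TRUE
    if (n_sources > 1L) {
      cc <- stats::cor(t(res$maps))
      ok_cor <- max(abs(cc[upper.tri(cc)])) < 0.2
    }
    if (ok_cor) {
      return(structure(
        list(spatial_maps = res$maps, grid_dims = grid_dims,
             centres = res$centres, sigmas = res$sigmas, seed = seed),
        class = "source_set"))
    }
  }
  abort("Grid too small to place sufficiently separated sources; enlarge the grid or reduce `n_sources`.",
        class = "falffprog_config_error")
}

#' Synthesize a time series with a prescribed fALFF
#'
#' Inverts the fALFF definition: mixes a sum of random-phase sinusoids at DFT
#' bin frequencies strictly inside the 0.01-0.08 Hz low-frequency band with a
#' sum at bins strictly above 0.09 Hz (plus a small white-noise floor on the
#' out-of-band part), amplitude-ratioed so that the realized band-power
#' fraction — as measured by [component_falff()] — hits the target.
#'
#' @param target_falff Target band-power fraction in \[0, 1\].
#' @param n_timepoints Series length (>= 64).
#' @param tr_seconds Sampling interval in seconds; the band must lie below the
#'   Nyquist frequency 1/(2 TR).
#' @param seed Integer seed.
#' @param band_hz Low-frequency band, default `c(0.01, 0.08)`.
#' @return Numeric vector of length `n_timepoints`, unit standard deviation.
#' @export
make_component_timeseries <- function(target_falff, n_timepoints, tr_seconds, seed,
                                      band_hz = c(0.01, 0.08)) {
  target_falff <- check_number(target_falff, "target_falff", 0, 1)
  n_timepoints <- check_count(n_timepoints, "n_timepoints", min = 64L)
  tr_seconds <- check_number(tr_seconds, "tr_seconds", min = 1e-6)
  nyquist <- 1 / (2 * tr_seconds)
  if (band_hz[2] >= nyquist) {
    abort(sprintf("Band upper edge %.3f Hz is not below Nyquist %.3f Hz (TR = %g s).",
                  band_hz[2], nyquist, tr_seconds),
          class = "falffprog_config_error")
  }
  freqs <- seq_len(floor(n_timepoints / 2)) / (n_timepoints * tr_seconds)
  in_idx <- which(freqs >= band_hz[1] & freqs <= band_hz[2])
  out_idx <- which(freqs > 0.09 & freqs < nyquist)
  if (length(in_idx) == 0L || length(out_idx) == 0L) {
    abort("Target unreachable: no DFT bins inside (or outside) the band at this length/TR.",
          class = "falffprog_config_error")
  }
  tt <- seq_len(n_timepoints) * tr_seconds
  detrend_lin <- function(v) stats::lm.fit(cbind(1, seq_along(v)), v)$residuals
  bandlimit <- function(v, idx) {
    F <- stats::fft(v)
    keep <- logical(n_timepoints)
    keep[idx + 1L] <- TRUE
    keep[n_timepoints - idx + 1L] <- TRUE
    F[!keep] <- 0
    Re(stats::fft(F, inverse = TRUE)) / n_timepoints
  }
  with_seed(seed, {
    mk <- function(idx) {
      ph <- stats::runif(length(idx), 0, 2 * pi)
      v <- rowSums(vapply(seq_along(idx),
                          function(j) cos(2 * pi * freqs[idx[j]] * tt + ph[j]),
                          numeric(n_timepoints)))
      # alternate detrending and band-limiting so the component lies in both
      # subspaces: its detrended spectrum then stays confined to `idx` bins
      for (it in seq_len(10L)) v <- bandlimit(detrend_lin(v), idx)
      v
    }
    u_in <- mk(in_idx)
    u_out <- mk(out_idx) + stats::rnorm(n_timepoints, sd = 0.03)
    u_in <- u_in / stats::sd(u_in)
    u_out <- u_out / stats::sd(u_out)
    f_in <- component_falff(u_in, tr_seconds, band_hz)
    f_out <- component_falff(u_out, tr_seconds, band_hz)
    x <- if (target_falff >= f_in) {
      u_in
    } else if (target_falff <= f_out) {
      u_out
    } else {
      # the realized band fraction of a*u_in + u_out is monotone in a;
      # bisect on log-amplitude so cross-spectral leakage cannot bias the mix
      g <- function(a) {
        component_falff(a * u_in + u_out, tr_seconds, band_hz) - target_falff
      }
      lo <- 1e-4; hi <- 1e4
      for (iter in seq_len(60L)) {
        mid <- sqrt(lo * hi)
        if (g(mid) < 0) lo <- mid else hi <- mid
      }
      sqrt(lo * hi) * u_in + u_out
    }
    x / stats::sd(x)
  })
}

default_factor_loadings <- function(n_measures = 27L, n_factors = 3L) {
  # one weak general factor (all measures) + block-diagonal specific factors,
  # emulating the strong within-assessment correlations of a language battery
  blocks <- sort(rep_len(seq_len(n_factors), n_measures))
  L <- matrix(0, n_measures, n_factors + 1L)
  L[, 1L] <- 0.35
  for (m in seq_len(n_measures)) L[m, blocks[m] + 1L] <- 0.7
  rownames(L) <- sprintf("measure_%02d", seq_len(n_measures))
  colnames(L) <- c("general", sprintf("factor_%d", seq_len(n_factors)))
  L
}

#' Configuration for a synthetic cohort
#'
#' Collects every knob of the generator with defaults that emulate the study
#' conditions the pipeline is designed for: TR = 2 s acquisitions, a
#' multicollinear 27-measure behavioral battery with 3.3% missingness
#' (missing completely at random, never applied to the pre/post outcome
#' columns), and bounded outcomes generated as a linear function of the
#' pre-treatment score and the sum-to-one standardized per-source fALFF plus
#' Gaussian noise. The default grid (12 x 12 x 8) and length (120 volumes)
#' are desk-scale; full-length 210-volume runs are supported.
#'
#' @param n_subjects Number of subjects.
#' @param grid_dims Spatial grid, 3 integers.
#' @param n_timepoints Volumes per scan (>= 64; the study's runs were 210 or
#'   175).
#' @param tr_seconds Repetition time in seconds (2 or 2.4 in the study).
#' @param n_sources Number of planted spatial sources.
#' @param target_falff Optional n_subjects x n_sources matrix of target band
#'   fractions in \[0, 1\]; default drawn uniformly in \[0.2, 0.8\] under the
#'   seed.
#' @param noise_sd Scanner noise standard deviation added to every voxel time
#'   series (signal components have unit variance).
#' @param baseline Mean signal intensity added to every voxel (default 1000,
#'   a typical BOLD baseline), so temporal SNR is on a realistic scale.
#' @param behavioral_factor_loadings Measures x factors loading matrix for the
#'   behavioral battery; default 27 measures, one general + three block
#'   factors.
#' @param missing_rate MCAR missingness rate for baseline behavioral cells
#'   (default 0.033; outcomes are never masked).
#' @param outcome_weights Numeric vector: coefficient on the pre-treatment
#'   score followed by one coefficient per source's standardized fALFF.
#' @param outcome_noise_sd Outcome noise standard deviation.
#' @param seed Master integer seed; all sub-seeds derive from it.
#' @return A `cohort_config` list, validated.
#' @export
cohort_config <- function(n_subjects = 30L,
                          grid_dims = c(12L, 12L, 8L),
                          n_timepoints = 120L,
                          tr_seconds = 2,
                          n_sources = 5L,
                          target_falff = NULL,
                          noise_sd = 0.1,
                          baseline = 1000,
                          behavioral_factor_loadings = default_factor_loadings(),
                          missing_rate = 0.033,
                          outcome_weights = NULL,
                          outcome_noise_sd = 0.03,
                          seed = 1L) {
  n_subjects <- check_count(n_subjects, "n_subjects")
  n_timepoints <- check_count(n_timepoints, "n_timepoints", min = 64L)
  n_sources <- check_count(n_sources, "n_sources")
  tr_seconds <- check_number(tr_seconds, "tr_seconds", min = 1e-6)
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0)
  baseline <- check_number(baseline, "baseline", min = 0)
  missing_rate <- check_number(missing_rate, "missing_rate", 0, 1)
  outcome_noise_sd <- check_number(outcome_noise_sd, "outcome_noise_sd", min = 0)
  seed <- check_count(seed, "seed", min = 0L)
  if (is.null(target_falff)) {
    target_falff <- with_seed(derive_seed(seed, 0L, 2L),
                              matrix(stats::runif(n_subjects * n_sources, 0.2, 0.8),
                                     n_subjects, n_sources))
  }
  target_falff <- as.matrix(target_falff)
  if (!all(dim(target_falff) == c(n_subjects, n_sources)) ||
      any(target_falff < 0 | target_falff > 1)) {
    abort("`target_falff` must be n_subjects x n_sources with entries in [0, 1].",
          class = "falffprog_config_error")
  }
  if (is.null(outcome_weights)) {
    # alternating-sign contrasts carry the learnable signal; since the
    # standardized fALFF vector sums to one, a constant added to every source
    # weight shifts outcomes without altering that signal. The constant is set
    # so the expected post-pre gain is +0.1 (patients improve under therapy):
    # E[post - pre] = -(1 - w0) E[pre] + sum(base)/k + c with E[pre] = 0.6.
    base <- seq(0.8, 0.3, length.out = n_sources) * (-1)^(seq_len(n_sources) + 1)
    shift <- 0.1 + 0.5 * 0.6 - sum(base) / n_sources
    outcome_weights <- c(0.5, base + shift)
  }
  if (length(outcome_weights) != n_sources + 1L) {
    abort("`outcome_weights` must have length n_sources + 1 (pre-score first).",
          class = "falffprog_config_error")
  }
  structure(
    list(n_subjects = n_subjects, grid_dims = as.integer(grid_dims),
         n_timepoints = n_timepoints, tr_seconds = tr_seconds,
         n_sources = n_sources, target_falff = target_falff,
         noise_sd = noise_sd, baseline = baseline,
         behavioral_factor_loadings = as.matrix(behavioral_factor_loadings),
         missing_rate = missing_rate,
         outcome_weights = as.numeric(outcome_weights),
         outcome_noise_sd = outcome_noise_sd, seed = seed),
    class = "cohort_config")
}

simulate_behavioral <- function(config) {
  L <- config$behavioral_factor_loadings
  n <- config$n_subjects
  p <- nrow(L)
  uniq <- sqrt(pmax(1 - rowSums(L^2), 0.05))
  with_seed(derive_seed(config$seed, 0L, 5L), {
    factors <- matrix(stats::rnorm(n * ncol(L)), n, ncol(L))
    z <- factors %*% t(L) + matrix(stats::rnorm(n * p), n, p) %*% diag(uniq)
    scores <- stats::pnorm(z)  # bounded scores in (0, 1)
    colnames(scores) <- rownames(L) %||% sprintf("measure_%02d", seq_len(p))
    if (config$missing_rate > 0) {
      miss <- matrix(stats::runif(n * p) < config$missing_rate, n, p)
      scores[miss] <- NA_real_
    }
    scores
  })
}

#' Generate a fully seeded synthetic cohort
#'
#' Builds, deterministically from `config`: (i) planted spatial sources and,
#' per subject, component time series whose realized fALFF hits the subject's
#' target values, mixed into a 4D scan as sum of map x time-series outer
#' products plus white noise; (ii) a multicollinear behavioral battery with
#' MCAR missingness on baseline cells only; (iii) pre-treatment scores and
#' post-treatment outcomes from a known linear model, clamped to \[0, 1\].
#' Subjects are assigned to three impairment groups in the study's
#' proportions (28:11:18).
#'
#' @param config A [cohort_config()] object.
#' @return An object of class `synthetic_cohort`: list with `scans` (list of
#'   [bold4d()]), `truth_sources` (a `source_set`), `truth_falff` (targets),
#'   `truth_timeseries` (list of t x k matrices), `behavioral` (tibble:
#'   subject_id, group, measures, pre_tsm, post_tsm), `config`.
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  src <- make_sources(config$n_sources, config$grid_dims,
                      seed = derive_seed(config$seed, 0L, 1L))
  n <- config$n_subjects
  k <- config$n_sources
  V <- prod(config$grid_dims)
  ids <- sprintf("sub-%03d", seq_len(n))

  ts_list <- vector("list", n)
  scans <- vector("list", n)
  for (i in seq_len(n)) {
    ts <- vapply(seq_len(k), function(j) {
      make_component_timeseries(config$target_falff[i, j], config$n_timepoints,
                                config$tr_seconds,
                                seed = derive_seed(config$seed, i * 997L + j, 3L))
    }, numeric(config$n_timepoints))
    ts_list[[i]] <- ts
    vox <- config$baseline + t(src$spatial_maps) %*% t(ts)  # V x T
    if (config$noise_sd > 0) {
      vox <- vox + with_seed(derive_seed(config$seed, i, 4L),
                             matrix(stats::rnorm(V * config$n_timepoints,
                                                 sd = config$noise_sd),
                                    V, config$n_timepoints))
    }
    scans[[i]] <- bold4d(array(vox, c(config$grid_dims, config$n_timepoints)),
                         tr_seconds = config$tr_seconds, subject_id = ids[i])
  }

  scores <- simulate_behavioral(config)

  nf <- config$target_falff / rowSums(config$target_falff)
  w <- config$outcome_weights
  outc <- with_seed(derive_seed(config$seed, 0L, 6L), {
    pre <- stats::runif(n, 0.3, 0.9)
    eps <- if (config$outcome_noise_sd > 0) {
      stats::rnorm(n, sd = config$outcome_noise_sd)
    } else rep(0, n)
    post <- clamp_prediction(w[1] * pre + as.vector(nf %*% w[-1]) + eps)
    list(pre = pre, post = post)
  })

  sizes <- round(n * c(28, 11, 18) / 57)
  sizes[1] <- n - sum(sizes[-1])
  group <- rep(c("anomia", "agrammatism", "dysgraphia"), times = pmax(sizes, 0))[seq_len(n)]

  behavioral <- dplyr::bind_cols(
    tibble(subject_id = ids, group = group),
    as_tibble(scores),
    tibble(pre_tsm = outc$pre, post_tsm = outc$post))

  structure(
    list(scans = scans, truth_sources = src, truth_falff = config$target_falff,
         truth_timeseries = ts_list, behavioral = behavioral, config = config),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d planted sources, grid %s, %d volumes @ TR %g s\n",
              x$config$n_subjects, x$config$n_sources,
              paste(x$config$grid_dims, collapse = "x"),
              x$config$n_timepoints, x$config$tr_seconds))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Scans go out as NIfTI-1 (`.nii.gz`, TR in the time-axis header field) with
#' one shared byte mask; behavioral/outcome tables as CSV with a header row,
#' one row per subject, empty cell = missing; the configuration (minus large
#' matrices) as YAML.
#'
#' @param cohort A [make_cohort()] result.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (scan in cohort$scans) {
    write_bold_nifti(scan, file.path(dir, paste0(scan$subject_id, "_bold.nii.gz")))
  }
  write_bold_nifti(cohort$scans[[1]], tempfile(fileext = ".nii.gz"),
                   mask_path = file.path(dir, "mask.nii.gz"))
  readr::write_csv(cohort$behavioral, file.path(dir, "behavioral.csv"), na = "")
  tf <- as.data.frame(cohort$truth_falff)
  names(tf) <- sprintf("source_%02d", seq_len(ncol(tf)))
  readr::write_csv(dplyr::bind_cols(tibble(subject_id = cohort$behavioral$subject_id), tf),
                   file.path(dir, "truth_falff.csv"))
  cfg <- cohort$config
  yaml::write_yaml(
    list(n_subjects = cfg$n_subjects, grid_dims = cfg$grid_dims,
         n_timepoints = cfg$n_timepoints, tr_seconds = cfg$tr_seconds,
         n_sources = cfg$n_sources, noise_sd = cfg$noise_sd,
         baseline = cfg$baseline, missing_rate = cfg$missing_rate,
         outcome_weights = cfg$outcome_weights,
         outcome_noise_sd = cfg$outcome_noise_sd, seed = cfg$seed),
    file.path(dir, "config.yaml"))
  invisible(dir)
}
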