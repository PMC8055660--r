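#' Fractional amplitude of low-frequency fluctuations
#'
#' The fraction of a time series' spectral power lying in the low-frequency
#' band (default 0.01-0.08 Hz): the series is linearly detrended and
#' demeaned, an unpadded, untapered periodogram is computed by discrete
#' Fourier transform, and the sum of power at positive frequencies f with
#' band\[1\] <= f <= band\[2\] (edges inclusive) is divided by the sum over
#' all positive frequencies. The default ratio is of power (squared
#' magnitude); `mode = "amplitude"` uses magnitude instead, the convention of
#' the original fALFF literature.
#'
#' @param timeseries Numeric vector, length >= 64.
#' @param tr_seconds Sampling interval in seconds; the band's upper edge must
#'   lie below the Nyquist frequency 1/(2 TR).
#' @param band_hz Band edges in Hz, default `c(0.01, 0.08)`.
#' @param mode `"power"` (default) or `"amplitude"`.
#' @param detrend Remove a linear trend before the transform (default TRUE).
#' @return A single number in \[0, 1\]. A constant series (zero total power)
#'   returns 0 with a warning.
#' @examples
#' t <- seq_len(210) * 2
#' component_falff(sin(2 * pi * 0.05 * t), tr_seconds = 2)
#' @export
component_falff <- function(timeseries, tr_seconds, band_hz = c(0.01, 0.08),
                            mode = c("power", "amplitude"), detrend = TRUE) {
  mode <- match.arg(mode)
  n <- length(timeseries)
  if (n < 64L) abort("`timeseries` must have length >= 64.")
  tr_seconds <- check_number(tr_seconds, "tr_seconds", min = 1e-6)
  nyquist <- 1 / (2 * tr_seconds)
  if (band_hz[2] >= nyquist) {
    abort(sprintf("Band upper edge %.3f Hz must be below Nyquist %.3f Hz.",
                  band_hz[2], nyquist), class = "falffprog_config_error")
  }
  x <- as.numeric(timeseries)
  if (detrend) {
    tt <- seq_len(n)
    x <- stats::lm.fit(cbind(1, tt), x)$residuals
  } else {
    x <- x - mean(x)
  }
  spec <- Mod(stats::fft(x))[seq_len(floor(n / 2)) + 1L]
  pw <- if (mode == "power") spec^2 else spec
  total <- sum(pw)
  if (total <= .Machine$double.eps * n) {
    warn("Constant time series: total power is zero; fALFF defined as 0.")
    return(0)
  }
  freqs <- seq_len(floor(n / 2)) / (n * tr_seconds)
  sum(pw[freqs >= band_hz[1] & freqs <= band_hz[2]]) / total
}

#' Standardize a subject's fALFF vector to sum to one
#'
#' Divides each component's band fraction by the subject's total, so the
#' vector expresses relative component power and sums to exactly one. This
#' normalizes activity ranges across subjects before regression.
#'
#' @param raw_vector Nonnegative numeric vector with positive sum.
#' @return Vector of the same length summing to 1.
#' @export
normalize_subject <- function(raw_vector) {
  if (any(raw_vector < 0) || anyNA(raw_vector)) {
    abort("`raw_vector` must be nonnegative and complete.")
  }
  s <- sum(raw_vector)
  if (s <= 0) abort("All-zero fALFF vector: no spectral content to standardize.")
  raw_vector / s
}

#' Per-subject, per-component fALFF feature matrix
#'
#' Applies [component_falff()] to every back-projected component time course
#' of every subject (using that subject's TR), then standardizes each
#' subject's vector to sum to one.
#'
#' @param decomp A [run_group_ica()] decomposition (or any list with a
#'   `subject_timecourses` list of t x k matrices and `subject_ids`).
#' @param tr_by_subject Numeric vector of TRs, one per subject (recycled if
#'   length 1).
#' @param band_hz,mode Passed to [component_falff()].
#' @return An object of class `falff_features`: list with `raw` and
#'   `normalized` (n_subjects x n_components matrices), `band_hz`,
#'   `tr_by_subject`, plus a tibble via [tidy()].
#' @export
falff_features <- function(decomp, tr_by_subject, band_hz = c(0.01, 0.08),
                           mode = "power") {
  tcs <- decomp$subject_timecourses
  n <- length(tcs)
  if (n == 0L) abort("Decomposition contains no subject time courses.")
  if (length(tr_by_subject) == 1L) tr_by_subject <- rep(tr_by_subject, n)
  if (length(tr_by_subject) != n || anyNA(tr_by_subject)) {
    abort("`tr_by_subject` must supply one finite TR per subject.")
  }
  k <- ncol(tcs[[1]])
  raw <- t(vapply(seq_len(n), function(i) {
    vapply(seq_len(k),
           function(j) component_falff(tcs[[i]][, j], tr_by_subject[i],
                                       band_hz = band_hz, mode = mode),
           numeric(1))
  }, numeric(k)))
  normalized <- t(apply(raw, 1L, normalize_subject))
  ids <- decomp$subject_ids %||% sprintf("sub-%03d", seq_len(n))
  dimnames(raw) <- dimnames(normalized) <-
    list(ids, sprintf("component_%02d", seq_len(k)))
  structure(list(raw = raw, normalized = normalized, band_hz = band_hz,
                 tr_by_subject = tr_by_subject, mode = mode),
            class = "falff_features")
}

#' @export
print.falff_features <- function(x, ...) {
  cat(sprintf("<falff_features> %d subjects x %d components, band %.3f-%.3f Hz (%s ratio)\n",
              nrow(x$raw), ncol(x$raw), x$band_hz[1], x$band_hz[2], x$mode))
  invisible(x)
}

#' @rdname tidy_falffprog
#' @export
tidy.falff_features <- function(x, ...) {
  as_tibble(x$normalized) |>
    dplyr::mutate(subject_id = rownames(x$normalized), .before = 1L)
}
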