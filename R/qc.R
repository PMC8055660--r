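#' Slice-wise temporal signal-to-noise ratio
#'
#' Computes a per-slice temporal SNR — the ratio of mean signal to temporal
#' standard deviation — and aggregates it across axial slices weighted by the
#' number of in-mask voxels per slice. By default each in-mask voxel's tSNR
#' (temporal mean / temporal sd, n - 1 denominator) is averaged within the
#' slice; `method = "pooled"` instead divides the slice's mean signal by the
#' temporal sd of the slice-mean time course. Slices with no in-mask voxels,
#' or whose tSNR is non-finite (zero temporal variance), are excluded from
#' the weighted mean with a warning.
#'
#' The slice axis is the third spatial axis of the stored array.
#'
#' @param scan A [bold4d()] object.
#' @param threshold Pass threshold on the weighted aggregate (default 100);
#'   a scan passes iff weighted tSNR >= threshold.
#' @param method `"voxel"` (default) or `"pooled"`, see above.
#' @return An object of class `tsnr_report`: tibble of per-slice values
#'   (`slice`, `tsnr`, `weight`) plus attributes, with fields `weighted_tsnr`,
#'   `passed`, `threshold`, `subject_id` accessible via `$`.
#' @export
slice_tsnr <- function(scan, threshold = 100, method = c("voxel", "pooled")) {
  stopifnot(inherits(scan, "bold4d"))
  method <- match.arg(method)
  d <- dim(scan$voxels)
  n_slices <- d[3]
  tsnr <- weight <- numeric(n_slices)
  for (s in seq_len(n_slices)) {
    msk <- scan$mask[, , s]
    weight[s] <- sum(msk)
    if (weight[s] == 0) { tsnr[s] <- NA_real_; next }
    sl <- matrix(scan$voxels[, , s, ], prod(d[1:2]), d[4])[as.vector(msk), , drop = FALSE]
    if (method == "voxel") {
      mu <- rowMeans(sl)
      sdv <- apply(sl, 1L, stats::sd)
      v <- mu / sdv
      v[!is.finite(v)] <- NA_real_
      tsnr[s] <- mean(v, na.rm = TRUE)
      if (all(is.na(v))) tsnr[s] <- NA_real_
    } else {
      tsnr[s] <- mean(sl) / stats::sd(colMeans(sl))
    }
    if (!is.finite(tsnr[s])) tsnr[s] <- NA_real_
  }
  usable <- weight > 0 & is.finite(tsnr)
  if (any(weight > 0 & !is.finite(tsnr))) {
    warn(sprintf("%d slice(s) with zero temporal variance excluded from the weighted tSNR.",
                 sum(weight > 0 & !is.finite(tsnr))))
  }
  if (!any(usable)) abort("No slice yields a finite tSNR.")
  weighted <- sum(tsnr[usable] * weight[usable]) / sum(weight[usable])
  out <- tibble(slice = seq_len(n_slices), tsnr = tsnr, weight = weight)
  structure(
    list(per_slice = out, weighted_tsnr = weighted,
         passed = weighted >= threshold, threshold = threshold,
         subject_id = scan$subject_id, method = method),
    class = "tsnr_report")
}

#' @export
print.tsnr_report <- function(x, ...) {
  cat(sprintf("<tsnr_report> %s: weighted tSNR = %.2f (threshold %g) -> %s\n",
              x$subject_id, x$weighted_tsnr, x$threshold,
              if (x$passed) "PASS" else "FAIL"))
  invisible(x)
}

#' @rdname tidy_falffprog
#' @export
tidy.tsnr_report <- function(x, ...) x$per_slice

#' @rdname tidy_falffprog
#' @export
glance.tsnr_report <- function(x, ...) {
  tibble(subject_id = x$subject_id, weighted_tsnr = x$weighted_tsnr,
         passed = x$passed, threshold = x$threshold)
}

#' Filter scans by temporal SNR
#'
#' Retains exactly the scans whose weighted slice-wise tSNR is at or above
#' the threshold (the study excluded scans with tSNR < 100), and logs each
#' exclusion with its value.
#'
#' @param scans Nonempty list of [bold4d()] objects.
#' @param threshold Minimum weighted tSNR (default 100).
#' @param method Passed to [slice_tsnr()].
#' @return List with `retained` (scans, input order preserved) and `log`
#'   (tibble: subject_id, weighted_tsnr, passed).
#' @export
qc_filter <- function(scans, threshold = 100, method = "voxel") {
  if (length(scans) == 0L) abort("`scans` must be a nonempty list.")
  reports <- purrr::map(scans, slice_tsnr, threshold = threshold, method = method)
  log <- purrr::map_dfr(reports, glance)
  keep <- log$passed
  if (!any(keep)) {
    abort(sprintf(
      "All %d scan(s) fall below the tSNR threshold %g; re-acquire or lower the threshold.",
      length(scans), threshold), class = "falffprog_pipeline_error")
  }
  list(retained = scans[keep], log = log)
}

#' Select the best of several runs for one subject
#'
#' Returns the run with the highest weighted slice-wise tSNR (the study kept
#' only the highest-tSNR run when two were acquired). Ties break
#' deterministically in favour of the earliest run in the list, with a
#' message.
#'
#' @param runs Nonempty list of [bold4d()] objects for one subject.
#' @param method Passed to [slice_tsnr()].
#' @return The selected [bold4d()] run.
#' @export
select_best_run <- function(runs, method = "voxel") {
  if (length(runs) == 0L) abort("`runs` must be a nonempty list.")
  vals <- purrr::map_dbl(runs, ~ slice_tsnr(.x, method = method)$weighted_tsnr)
  best <- which(vals == max(vals))
  if (length(best) > 1L) {
    inform(sprintf("tSNR tie between runs %s; keeping run %d.",
                   paste(best, collapse = ", "), best[1]))
  }
  runs[[best[1]]]
}
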