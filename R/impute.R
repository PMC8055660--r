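#' Iterative random-forest imputation
#'
#' Fills missing cells in the numeric columns of a cohort table by iterated
#' random-forest regression: missing cells are initialized at the column
#' median, then each incomplete column in turn is re-predicted from all other
#' numeric columns by a forest fit on its originally observed rows, cycling
#' until the filled values stabilize or `max_iter` passes complete. Observed
#' cells are never touched; the result is deterministic given the seed.
#'
#' @param data Data frame; non-numeric columns pass through untouched.
#'   Outcome columns are expected to be complete.
#' @param seed Integer seed.
#' @param n_trees Trees per forest (default 100).
#' @param max_iter Maximum sweeps over the incomplete columns (default 10).
#' @param rel_tol Relative-change threshold declaring stabilization.
#' @return `data` with all numeric missing cells filled.
#' @export
impute_missing <- function(data, seed = 1L, n_trees = 100L, max_iter = 10L,
                           rel_tol = 1e-4) {
  stopifnot(is.data.frame(data))
  num_cols <- names(data)[vapply(data, is.numeric, logical(1))]
  X <- as.matrix(data[num_cols])
  obs <- !is.na(X)
  too_few <- colSums(obs) < 2L
  if (any(too_few)) {
    abort(sprintf("Column(s) with fewer than 2 observed values: %s.",
                  paste(num_cols[too_few], collapse = ", ")))
  }
  incomplete <- which(colSums(!obs) > 0L)
  if (length(incomplete) == 0L) return(data)
  incomplete <- incomplete[order(colSums(!obs)[incomplete])]

  filled <- X
  for (j in seq_len(ncol(X))) {
    filled[!obs[, j], j] <- stats::median(X[obs[, j], j])
  }
  with_seed(seed, {
    for (iter in seq_len(max_iter)) {
      change <- 0; scale <- 0
      for (j in incomplete) {
        rf <- randomForest::randomForest(
          x = filled[obs[, j], -j, drop = FALSE],
          y = filled[obs[, j], j],
          ntree = n_trees)
        new <- stats::predict(rf, filled[!obs[, j], -j, drop = FALSE])
        change <- change + sum((new - filled[!obs[, j], j])^2)
        scale <- scale + sum(new^2)
        filled[!obs[, j], j] <- new
      }
      if (scale > 0 && sqrt(change / scale) < rel_tol) break
    }
  })
  out <- data
  out[num_cols] <- as.data.frame(filled)
  out
}

#' Choose the forest size minimizing imputation output variance
#'
#' Runs several seeded imputations per candidate forest size and returns the
#' size whose imputed cells vary least across seeds (the selection criterion
#' described for the study's imputation hyperparameters).
#'
#' @param data Data frame with missing numeric cells.
#' @param trees Candidate forest sizes.
#' @param n_rep Seeded imputations per candidate.
#' @param seed Base seed.
#' @return The selected element of `trees`.
#' @export
select_imputation_trees <- function(data, trees = c(50L, 100L, 300L),
                                    n_rep = 10L, seed = 1L) {
  num_cols <- names(data)[vapply(data, is.numeric, logical(1))]
  miss <- is.na(as.matrix(data[num_cols]))
  if (!any(miss)) return(trees[1])
  variances <- vapply(trees, function(nt) {
    fills <- vapply(seq_len(n_rep), function(r) {
      as.matrix(impute_missing(data, seed = derive_seed(seed, r, nt),
                               n_trees = nt)[num_cols])[miss]
    }, numeric(sum(miss)))
    mean(apply(fills, 1L, stats::var))
  }, numeric(1))
  trees[which.min(variances)]
}

#' Multiple-imputation ensemble of LOOCV prognostic models
#'
#' Repeats [impute_missing()] + [loocv_predict()] across `n_imputations`
#' seeded imputations and aggregates: per-subject predictions by elementwise
#' median, coefficients by elementwise median with the min/max range across
#' imputations recorded. With no missing data every imputation is identical,
#' so the ensemble equals a single run exactly and only one model is fit.
#'
#' @param data Cohort table (predictors may contain missing cells; the
#'   outcome must be complete).
#' @param n_imputations Number of imputations (the study used 1000).
#' @param base_seed Seed from which per-imputation seeds derive.
#' @param n_trees,max_iter Passed to [impute_missing()].
#' @param ... Passed to [loocv_predict()] (outcome, predictors, grid shape,
#'   nesting, clamp range).
#' @return Object of class `ensemble_fit`: `predictions` (tibble with median
#'   predicted per subject), `coefficients` (tibble: term, estimate = median,
#'   min, max), `n_imputations`, `prediction_draws` and `coefficient_draws`
#'   matrices (provenance), `had_missing`.
#' @export
ensemble_run <- function(data, n_imputations = 1000L, base_seed = 1L,
                         n_trees = 100L, max_iter = 10L, ...) {
  n_imputations <- check_count(n_imputations, "n_imputations")
  num_cols <- names(data)[vapply(data, is.numeric, logical(1))]
  had_missing <- anyNA(data[num_cols])

  run_one <- function(m) {
    completed <- if (had_missing) {
      impute_missing(data, seed = derive_seed(base_seed, m, 31L),
                     n_trees = n_trees, max_iter = max_iter)
    } else data
    loocv_predict(completed, ...)
  }

  n_fits <- if (had_missing) n_imputations else 1L
  fits <- lapply(seq_len(n_fits), run_one)

  pred_mat <- vapply(fits, function(f) f$predictions$predicted,
                     numeric(nrow(fits[[1]]$predictions)))
  pred_mat <- matrix(pred_mat, ncol = n_fits)
  coef_mat <- vapply(fits, function(f) f$coefficients$estimate,
                     numeric(nrow(fits[[1]]$coefficients)))
  coef_mat <- matrix(coef_mat, ncol = n_fits)

  predictions <- fits[[1]]$predictions
  predictions$predicted <- apply(pred_mat, 1L, stats::median)
  coefficients <- tibble(
    term = fits[[1]]$coefficients$term,
    estimate = apply(coef_mat, 1L, stats::median),
    min = apply(coef_mat, 1L, min),
    max = apply(coef_mat, 1L, max))

  structure(
    list(predictions = predictions, coefficients = coefficients,
         n_imputations = n_imputations, had_missing = had_missing,
         prediction_draws = pred_mat, coefficient_draws = coef_mat,
         settings = fits[[1]]$settings, base_seed = base_seed),
    class = "ensemble_fit")
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat(sprintf("<ensemble_fit> %d imputation(s)%s, n = %d subjects\n",
              x$n_imputations,
              if (x$had_missing) "" else " (no missing data: single fit)",
              nrow(x$predictions)))
  invisible(x)
}

#' @rdname tidy_falffprog
#' @export
tidy.ensemble_fit <- function(x, ...) x$coefficients

#' @rdname tidy_falffprog
#' @export
glance.ensemble_fit <- function(x, ...) {
  p <- x$predictions
  r2 <- suppressWarnings(r_squared_with_test(p$predicted, p$actual))
  tibble(n = nrow(p), n_imputations = x$n_imputations,
         mad = prediction_mad(p$predicted, p$actual),
         r_squared = r2$r_squared,
         correlation_test_p = r2$p_value,
         wilcoxon_p_vs_zero_order = compare_to_zero_order(p$predicted, p$actual))
}

#' @rdname tidy_falffprog
#' @export
augment.ensemble_fit <- function(x, ...) x$predictions
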