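prep_design <- function(data, outcome, predictors, id_col = "subject_id") {
  stopifnot(is.data.frame(data))
  if (!outcome %in% names(data)) abort(sprintf("Outcome column '%s' not found.", outcome))
  if (is.null(predictors)) {
    predictors <- names(data)[vapply(data, is.numeric, logical(1))]
    predictors <- setdiff(predictors, c(outcome, id_col))
  }
  missing_cols <- setdiff(predictors, names(data))
  if (length(missing_cols)) {
    abort(sprintf("Predictor column(s) not found: %s.", paste(missing_cols, collapse = ", ")))
  }
  X <- as.matrix(data[predictors])
  storage.mode(X) <- "double"
  y <- as.numeric(data[[outcome]])
  if (anyNA(X)) {
    abort("Predictors contain missing values; impute first (see `impute_missing()` / `ensemble_run()`).")
  }
  if (anyNA(y)) abort("Outcome contains missing values.")
  ids <- if (id_col %in% names(data)) as.character(data[[id_col]]) else
    sprintf("row-%03d", seq_len(nrow(data)))
  list(X = X, y = y, ids = ids, predictors = predictors)
}

#' Leave-one-out cross-validated elastic-net prognosis
#'
#' For every subject i: standardization parameters, hyperparameters, and the
#' model itself are derived from the other n - 1 rows only, the held-out row
#' is predicted, and the prediction is clamped to the outcome's dynamic
#' range. With `nested = TRUE` (default) hyperparameter selection by inner
#' LOOCV is repeated inside each outer fold, avoiding optimistic bias; with
#' `nested = FALSE` hyperparameters are tuned once on the full table and held
#' fixed across folds. A final model on all rows supplies the reported
#' coefficient vector (on the z-scored scale).
#'
#' @param data Data frame: one row per subject, numeric predictor columns,
#'   the outcome column, and optionally `subject_id`/`group`.
#' @param outcome Name of the outcome column (default `"post_tsm"`).
#' @param predictors Character vector of predictor columns; default all
#'   numeric columns except the outcome and `subject_id`.
#' @param alphas,n_lambda Tuning grid shape, see [enet_grid()].
#' @param nested Nest hyperparameter tuning inside each outer fold (default
#'   TRUE).
#' @param clamp_range Dynamic range for predictions (default \[0, 1\]).
#' @return Object of class `loocv_fit`: `predictions` (tibble: subject_id,
#'   actual, predicted), `folds` (per-fold chosen hyperparameters),
#'   `coefficients` (tibble from the full-data fit), `settings`.
#' @export
loocv_predict <- function(data, outcome = "post_tsm", predictors = NULL,
                          alphas = c(0.1, 0.325, 0.55, 0.775, 1.0),
                          n_lambda = 25L, nested = TRUE,
                          clamp_range = c(0, 1)) {
  d <- prep_design(data, outcome, predictors)
  n <- nrow(d$X)
  if (n < 4L) abort("LOOCV prediction needs n >= 4 (inner CV infeasible below that).")

  fixed <- NULL
  if (!nested) {
    zf <- suppressWarnings(zscore_fit_apply(d$X))
    fixed <- tune_hyperparameters(zf$train, d$y, enet_grid(zf$train, d$y, alphas, n_lambda))
  }

  preds <- numeric(n)
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    z <- suppressWarnings(zscore_fit_apply(d$X[-i, , drop = FALSE],
                                           d$X[i, , drop = FALSE]))
    ytr <- d$y[-i]
    hp <- if (nested) {
      tune_hyperparameters(z$train, ytr, enet_grid(z$train, ytr, alphas, n_lambda))
    } else fixed
    fit <- elastic_net_fit(z$train, ytr, hp$mixing_alpha, hp$penalty_lambda)
    preds[i] <- clamp_prediction(predict(fit, z$test), clamp_range)
    folds[[i]] <- tibble(subject_id = d$ids[i], alpha = hp$mixing_alpha,
                         lambda = hp$penalty_lambda, n_dropped = length(z$dropped))
  }

  zall <- suppressWarnings(zscore_fit_apply(d$X))
  hp_all <- if (nested) {
    tune_hyperparameters(zall$train, d$y, enet_grid(zall$train, d$y, alphas, n_lambda))
  } else fixed
  full_fit <- elastic_net_fit(zall$train, d$y, hp_all$mixing_alpha, hp_all$penalty_lambda)
  coefs <- tibble(term = d$predictors,
                  estimate = unname(full_fit$coefficients[d$predictors]))
  coefs$estimate[is.na(coefs$estimate)] <- 0   # columns dropped as constant

  structure(
    list(predictions = tibble(subject_id = d$ids, actual = d$y, predicted = preds),
         folds = dplyr::bind_rows(folds),
         coefficients = coefs,
         full_fit = full_fit,
         settings = list(outcome = outcome, predictors = d$predictors,
                         alphas = alphas, n_lambda = n_lambda, nested = nested,
                         clamp_range = clamp_range)),
    class = "loocv_fit")
}

#' @export
print.loocv_fit <- function(x, ...) {
  r2 <- suppressWarnings(r_squared_with_test(x$predictions$predicted,
                                             x$predictions$actual))
  cat(sprintf("<loocv_fit> n = %d, %d predictors (%s tuning), LOOCV R^2 = %.3f, MAD = %.3f\n",
              nrow(x$predictions), length(x$settings$predictors),
              if (x$settings$nested) "nested" else "non-nested",
              r2$r_squared,
              prediction_mad(x$predictions$predicted, x$predictions$actual)))
  invisible(x)
}

#' @rdname tidy_falffprog
#' @export
tidy.loocv_fit <- function(x, ...) x$coefficients

#' @rdname tidy_falffprog
#' @export
glance.loocv_fit <- function(x, ...) {
  p <- x$predictions
  r2 <- suppressWarnings(r_squared_with_test(p$predicted, p$actual))
  tibble(n = nrow(p),
         mad = prediction_mad(p$predicted, p$actual),
         r_squared = r2$r_squared,
         correlation_test_p = r2$p_value,
         wilcoxon_p_vs_zero_order = compare_to_zero_order(p$predicted, p$actual))
}

#' @rdname tidy_falffprog
#' @export
augment.loocv_fit <- function(x, ...) x$predictions
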