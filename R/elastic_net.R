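#' Z-score standardization fit on training rows only
#'
#' Computes per-column mean and standard deviation (n - 1 denominator) from
#' the training rows and applies them to both training and test rows, so no
#' information leaks from held-out data. Columns that are constant in the
#' training rows are dropped with a warning and recorded, never an error.
#'
#' @param train Numeric matrix or data frame of training predictors.
#' @param test Optional matrix/data frame with the same columns.
#' @return List with `train` (standardized matrix), `test` (or NULL),
#'   `center`, `scale`, `dropped` (character vector of dropped column names).
#' @export
zscore_fit_apply <- function(train, test = NULL) {
  train <- as.matrix(train)
  if (is.null(colnames(train))) colnames(train) <- paste0("x", seq_len(ncol(train)))
  center <- colMeans(train)
  scale <- apply(train, 2L, stats::sd)
  dropped <- colnames(train)[!is.finite(scale) | scale == 0]
  if (length(dropped)) {
    warn(sprintf("Dropping constant training column(s): %s.",
                 paste(dropped, collapse = ", ")))
  }
  keep <- setdiff(colnames(train), dropped)
  center <- center[keep]; scale <- scale[keep]
  std <- function(m) {
    m <- as.matrix(m)[, keep, drop = FALSE]
    sweep(sweep(m, 2L, center), 2L, scale, `/`)
  }
  list(train = std(train), test = if (!is.null(test)) std(test),
       center = center, scale = scale, dropped = dropped)
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# Coordinate descent on precomputed second moments of *centered* data:
# G = X'X/n, c = X'y/n. Minimizes (1/2n)||y - X b||^2 + lambda(a|b|_1 + (1-a)/2 |b|_2^2).
# The sweep itself is compiled (src/enet.cpp); tol is on the scaled change
# max_j (delta beta_j)^2 G_jj.
enet_gram <- function(G, c_xy, alpha, lambda, beta = NULL,
                      tol = 1e-14, max_iter = 100000L) {
  p <- length(c_xy)
  if (is.null(beta)) beta <- numeric(p)
  fit <- .enet_cd(G, c_xy, alpha, lambda, beta, tol, as.integer(max_iter))
  if (!fit$converged) {
    abort(sprintf("Elastic net failed to converge after %d sweeps (tol %.1g).",
                  fit$iterations, tol))
  }
  list(beta = fit$beta, iterations = fit$iterations)
}

#' Fit an elastic net at fixed hyperparameters
#'
#' Minimizes (1/2n) sum_i (y_i - b0 - x_i' b)^2 +
#' lambda (alpha ||b||_1 + (1 - alpha)/2 ||b||_2^2) by cyclic coordinate
#' descent on covariance updates; the intercept is unpenalized. At lambda = 0
#' this is ordinary least squares; at alpha = 0, ridge regression.
#'
#' @param X Numeric predictor matrix (typically z-scored; see
#'   [zscore_fit_apply()]).
#' @param y Numeric response.
#' @param mixing_alpha Mixing parameter alpha in \[0, 1\] (1 = lasso,
#'   0 = ridge).
#' @param penalty_lambda Penalty strength lambda >= 0.
#' @param tol,max_iter Coordinate-descent stopping rule (tolerance on the
#'   scaled coordinate change, glmnet-style); non-convergence is an error
#'   with iteration diagnostics.
#' @param beta_init Optional warm start.
#' @return Object of class `elastic_net_fit`: `coefficients` (named),
#'   `intercept`, `mixing_alpha`, `penalty_lambda`, `iterations`.
#' @export
elastic_net_fit <- function(X, y, mixing_alpha, penalty_lambda,
                            tol = 1e-14, max_iter = 100000L, beta_init = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L || length(y) != n) abort("Need n >= 2 rows with matching `y`.")
  mixing_alpha <- check_number(mixing_alpha, "mixing_alpha", 0, 1)
  penalty_lambda <- check_number(penalty_lambda, "penalty_lambda", min = 0)
  xbar <- colMeans(X); ybar <- mean(y)
  Xc <- sweep(X, 2L, xbar)
  G <- crossprod(Xc) / n
  c_xy <- as.vector(crossprod(Xc, y - ybar)) / n
  fit <- enet_gram(G, c_xy, mixing_alpha, penalty_lambda, beta = beta_init,
                   tol = tol, max_iter = max_iter)
  beta <- fit$beta
  names(beta) <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  structure(
    list(coefficients = beta, intercept = ybar - sum(xbar * beta),
         mixing_alpha = mixing_alpha, penalty_lambda = penalty_lambda,
         iterations = fit$iterations),
    class = "elastic_net_fit")
}

#' @export
predict.elastic_net_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)[, names(object$coefficients), drop = FALSE]
  drop(object$intercept + newdata %*% object$coefficients)
}

#' @export
print.elastic_net_fit <- function(x, ...) {
  cat(sprintf("<elastic_net_fit> alpha = %g, lambda = %g, %d/%d nonzero coefficients\n",
              x$mixing_alpha, x$penalty_lambda,
              sum(x$coefficients != 0), length(x$coefficients)))
  invisible(x)
}

#' @rdname tidy_falffprog
#' @export
tidy.elastic_net_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", names(x$coefficients)),
         estimate = c(x$intercept, unname(x$coefficients)))
}

# lambda path for one alpha: log grid from lambda_max (smallest lambda zeroing
# every coefficient) down `decades` decades, descending. With more predictors
# than observations the path stops two decades down (the unpenalized end is
# underdetermined there), mirroring glmnet's lambda.min.ratio convention.
lambda_path <- function(X, y, alpha, n_lambda = 25L, decades = NULL) {
  Xc <- sweep(as.matrix(X), 2L, colMeans(X))
  decades <- decades %||% if (nrow(Xc) > ncol(Xc)) 4 else 2
  c_xy <- abs(as.vector(crossprod(Xc, y - mean(y)))) / nrow(Xc)
  lmax <- max(c_xy) / max(alpha, 1e-3)
  if (lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(lmax) - decades * log(10), length.out = n_lambda))
}

#' Hyperparameter grid for elastic-net tuning
#'
#' The default grid crosses five mixing values with a 25-point log-spaced
#' lambda path per mixing value, from the smallest lambda that zeroes all
#' coefficients down four decades.
#'
#' @param X,y Training data the lambda path is anchored to.
#' @param alphas Mixing values.
#' @param n_lambda Path length per alpha.
#' @return Tibble with columns `alpha`, `lambda`.
#' @export
enet_grid <- function(X, y, alphas = c(0.1, 0.325, 0.55, 0.775, 1.0),
                      n_lambda = 25L) {
  purrr::map_dfr(alphas, function(a) {
    tibble(alpha = a, lambda = lambda_path(X, y, a, n_lambda))
  })
}

#' Select elastic-net hyperparameters by leave-one-out cross-validation
#'
#' For every grid point, each row is predicted by a model fit on the
#' remaining rows (warm-started along the descending lambda path), and the
#' grid point minimizing the LOOCV mean squared error is returned. Ties break
#' deterministically toward larger lambda, then smaller alpha.
#'
#' @param X Standardized predictor matrix.
#' @param y Response.
#' @param grid Tibble with `alpha` and `lambda` columns; default
#'   [enet_grid()] on `(X, y)`.
#' @return List with `mixing_alpha`, `penalty_lambda`, `cv_mse` (the winning
#'   error), and `cv_table` (per-grid-point errors).
#' @export
tune_hyperparameters <- function(X, y, grid = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) abort("LOOCV tuning needs n >= 3.")
  if (is.null(grid)) grid <- enet_grid(X, y)
  if (nrow(grid) == 0L) abort("`grid` must be nonempty.")
  alphas <- unique(grid$alpha)
  sse <- numeric(nrow(grid))
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; ytr <- y[-i]
    xbar <- colMeans(Xtr); ybar <- mean(ytr)
    Xc <- sweep(Xtr, 2L, xbar)
    G <- crossprod(Xc) / (n - 1)
    c_xy <- as.vector(crossprod(Xc, ytr - ybar)) / (n - 1)
    for (a in alphas) {
      rows <- which(grid$alpha == a)
      rows <- rows[order(grid$lambda[rows], decreasing = TRUE)]
      beta <- NULL
      for (r in rows) {
        fit <- enet_gram(G, c_xy, a, grid$lambda[r], beta = beta)
        beta <- fit$beta
        pred <- ybar + sum((X[i, ] - xbar) * beta)
        sse[r] <- sse[r] + (y[i] - pred)^2
      }
    }
  }
  cv <- grid
  cv$cv_mse <- sse / n
  best <- cv[order(cv$cv_mse, -cv$lambda, cv$alpha), ][1, ]
  list(mixing_alpha = best$alpha, penalty_lambda = best$lambda,
       cv_mse = best$cv_mse, cv_table = cv)
}
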