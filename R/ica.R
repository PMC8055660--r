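effective_rank <- function(eigenvalues, tol = 1e-10) {
  sum(eigenvalues > max(eigenvalues[1], 0) * tol)
}

#' Subject-level dimensionality reduction
#'
#' Temporal PCA of one subject's masked data prior to group concatenation:
#' each in-mask voxel's time course is demeaned, the t x t temporal
#' covariance (second moments over voxels) is eigendecomposed, and the data
#' are projected onto the top `k` eigenvectors. The residual energy equals
#' the sum of discarded eigenvalues.
#'
#' @param scan A [bold4d()] object.
#' @param k Number of retained directions; must not exceed the temporal rank.
#' @return List with `reduced` (k x n_voxels), and `model` (class
#'   `reduction_model`): `basis` (t x k, orthonormal columns),
#'   `eigenvalues`, `explained_variance` (nonincreasing fractions),
#'   `centering` (per-voxel temporal means).
#' @export
reduce_subject <- function(scan, k) {
  stopifnot(inherits(scan, "bold4d"))
  X <- bold_matrix(scan)                      # t x v
  v <- ncol(X)
  k <- check_count(k, "k")
  centering <- colMeans(X)
  Xc <- sweep(X, 2L, centering)
  C <- tcrossprod(Xc) / v
  eig <- eigen(C, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  rank <- effective_rank(ev)
  if (k > rank) {
    abort(sprintf("k = %d exceeds the temporal rank of subject '%s'; at most %d directions are achievable.",
                  k, scan$subject_id, rank))
  }
  basis <- eig$vectors[, seq_len(k), drop = FALSE]
  reduced <- crossprod(basis, Xc)
  model <- structure(
    list(basis = basis, eigenvalues = ev[seq_len(k)],
         explained_variance = ev[seq_len(k)] / sum(ev),
         all_eigenvalues = ev, centering = centering),
    class = "reduction_model")
  list(reduced = reduced, model = model)
}

#' Concatenate reduced subjects and whiten to the group dimension
#'
#' Stacks the subjects' reduced matrices (temporal concatenation), performs a
#' second PCA to `n_components` directions, and whitens, so the output has
#' identity second-moment covariance over voxels.
#'
#' @param reduced_list List of k_i x n_voxels matrices sharing one voxel
#'   grid/mask.
#' @param n_components Group dimension; must not exceed the group rank.
#' @return List with `whitened` (n_components x n_voxels) and `model`
#'   (`reduction_model` for the group stage, including the dewhitening
#'   eigenvalues).
#' @export
concatenate_and_reduce <- function(reduced_list, n_components) {
  n_components <- check_count(n_components, "n_components")
  widths <- vapply(reduced_list, ncol, integer(1))
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])
    abort(sprintf("Subjects %s were reduced on a different voxel mask than subject 1.",
                  paste(bad, collapse = ", ")))
  }
  M <- do.call(rbind, reduced_list)
  v <- ncol(M)
  C <- tcrossprod(M) / v
  eig <- eigen(C, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  rank <- effective_rank(ev)
  if (n_components > rank) {
    abort(sprintf("n_components = %d exceeds the group rank %d.", n_components, rank))
  }
  basis <- eig$vectors[, seq_len(n_components), drop = FALSE]
  whitened <- diag(1 / sqrt(ev[seq_len(n_components)]), n_components) %*% crossprod(basis, M)
  model <- structure(
    list(basis = basis, eigenvalues = ev[seq_len(n_components)],
         explained_variance = ev[seq_len(n_components)] / sum(ev),
         all_eigenvalues = ev, centering = NULL),
    class = "reduction_model")
  list(whitened = whitened, model = model)
}

#' InfoMax ICA unmixing
#'
#' Batch natural-gradient InfoMax with a logistic nonlinearity and bias term:
#' W <- W + lr (I + (1 - 2 g(U)) U') W with U = W Y + b, g the logistic
#' function, run on whitened data until the relative update norm falls below
#' `tol`. The learning rate halves whenever the update direction reverses
#' (negative inner product with the previous update). Deterministic given the
#' seed (random orthogonal initialization, full-batch updates).
#'
#' @param whitened n x v whitened matrix (rows: directions, columns:
#'   samples).
#' @param seed Integer seed for the initialization.
#' @param lr Initial learning rate.
#' @param max_iter Iteration cap (default 1000); reaching it without
#'   converging produces a warning.
#' @param tol Convergence tolerance on ||dW||_F / ||W||_F (default 1e-7).
#' @return List with `W` (unmixing matrix), `bias`, `converged`,
#'   `iterations`, `seed`. Sources are `W %*% whitened + bias`.
#' @export
infomax_unmix <- function(whitened, seed, lr = 0.2, max_iter = 1000L, tol = 1e-7) {
  n <- nrow(whitened)
  v <- ncol(whitened)
  W <- with_seed(seed, qr.Q(qr(matrix(stats::rnorm(n * n), n, n))))
  b <- numeric(n)
  I_n <- diag(n)
  dW_prev <- NULL
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    U <- W %*% whitened + b
    g <- 1 / (1 + exp(-U))
    grad <- (I_n + (1 - 2 * g) %*% t(U) / v)
    dW <- lr * grad %*% W
    db <- lr * rowMeans(1 - 2 * g)
    if (!all(is.finite(dW))) {
      abort("InfoMax diverged (non-finite weights); try a smaller learning rate `lr`.")
    }
    if (!is.null(dW_prev) && sum(dW * dW_prev) < 0) lr <- lr / 2
    W <- W + dW
    b <- b + db
    dW_prev <- dW
    if (sqrt(sum(dW^2)) / sqrt(sum(W^2)) < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warn(sprintf("InfoMax reached max_iter = %d without meeting tol = %g.", max_iter, tol))
  }
  list(W = W, bias = b, converged = converged, iterations = iter, seed = seed)
}

#' Greedy matching of components to a reference by absolute correlation
#'
#' Repeatedly assigns the remaining (component, reference) pair with the
#' largest absolute spatial correlation. Used for restart stability and for
#' comparing recovered maps against planted sources.
#'
#' @param maps k x v matrix of component maps.
#' @param reference k_ref x v matrix of reference maps.
#' @return Tibble with `component`, `reference`, `correlation` (signed, the
#'   matched value), ordered by reference index.
#' @export
match_components <- function(maps, reference) {
  cc <- stats::cor(t(reference), t(maps))   # k_ref x k
  cc[!is.finite(cc)] <- 0
  k <- min(nrow(cc), ncol(cc))
  res <- matrix(NA_real_, k, 3)
  work <- abs(cc)
  for (step in seq_len(k)) {
    idx <- arrayInd(which.max(work), dim(work))
    res[step, ] <- c(idx[2], idx[1], cc[idx[1], idx[2]])
    work[idx[1], ] <- -Inf
    work[, idx[2]] <- -Inf
  }
  tibble(component = as.integer(res[, 1]), reference = as.integer(res[, 2]),
         correlation = res[, 3]) |>
    dplyr::arrange(.data$reference)
}

#' Component stability across random restarts
#'
#' Reruns InfoMax from `n_restarts` distinct random initializations, matches
#' each run's spatial maps to the first run's by greedy absolute correlation,
#' and reports per-component stability as the mean pairwise absolute
#' correlation within each matched cluster (an ICASSO-style quality index in
#' \[0, 1\]). Restarts that diverge are excluded with a warning; if more than
#' half diverge, an error is raised.
#'
#' @param whitened n x v whitened matrix.
#' @param n_restarts Number of restarts (default 100, as in the study).
#' @param base_seed Integer; restart r uses a seed derived from it.
#' @param seeds Optional explicit seed vector overriding the derivation.
#' @param ... Passed to [infomax_unmix()].
#' @return Tibble with `component` (reference order) and `stability_index`.
#' @export
stability_restarts <- function(whitened, n_restarts = 100L, base_seed = 1L,
                               seeds = NULL, ...) {
  n_restarts <- check_count(n_restarts, "n_restarts", min = 2L)
  if (is.null(seeds)) {
    seeds <- vapply(seq_len(n_restarts), function(r) derive_seed(base_seed, r, 21L),
                    numeric(1))
  }
  runs <- vector("list", length(seeds))
  failed <- logical(length(seeds))
  for (r in seq_along(seeds)) {
    runs[[r]] <- tryCatch(infomax_unmix(whitened, seed = seeds[r], ...)$W %*% whitened,
                          error = function(e) NULL)
    failed[r] <- is.null(runs[[r]])
  }
  if (any(failed)) {
    warn(sprintf("%d restart(s) diverged and were excluded.", sum(failed)))
  }
  if (sum(failed) > length(seeds) / 2) {
    abort("More than half of the restarts diverged; the decomposition is unstable.")
  }
  runs <- runs[!failed]
  ref <- runs[[1]]
  k <- nrow(ref)
  clusters <- lapply(seq_len(k), function(c) ref[c, ])
  for (r in seq_along(runs)[-1]) {
    m <- match_components(runs[[r]], ref)
    for (j in seq_len(nrow(m))) {
      clusters[[m$reference[j]]] <- rbind(clusters[[m$reference[j]]],
                                          runs[[r]][m$component[j], ])
    }
  }
  idx <- vapply(clusters, function(cl) {
    cl <- matrix(cl, ncol = ncol(ref))
    if (nrow(cl) < 2L) return(1)
    cc <- abs(stats::cor(t(cl)))
    mean(cc[upper.tri(cc)])
  }, numeric(1))
  tibble(component = seq_len(k), stability_index = idx)
}

#' Back-project a group decomposition onto one subject
#'
#' Dual-regression-style back-reconstruction: the subject's component time
#' courses are obtained by regressing the (voxel-demeaned) data on the group
#' spatial maps, and the subject's spatial maps by regressing the data on
#' those time courses.
#'
#' @param group_maps k x v group spatial maps (in-mask voxel order).
#' @param scan A [bold4d()] on the same mask.
#' @return List with `timecourses` (t x k) and `maps` (k x v).
#' @export
back_project <- function(group_maps, scan) {
  X <- bold_matrix(scan)
  if (ncol(X) != ncol(group_maps)) {
    abort("Scan mask is incompatible with the group decomposition's voxel grid.")
  }
  Xc <- sweep(X, 2L, colMeans(X))
  G <- tcrossprod(group_maps)
  if (rcond_sym(G) < 1e-12) {
    abort("Group maps are rank deficient; the spatial regression is degenerate.")
  }
  tc <- Xc %*% t(group_maps) %*% solve(G)
  TT <- crossprod(tc)
  if (rcond_sym(TT) < 1e-12) {
    if (all(abs(tc) < 1e-12)) {
      return(list(timecourses = tc, maps = matrix(0, nrow(group_maps), ncol(group_maps))))
    }
    abort("Degenerate temporal regression in back-projection.")
  }
  maps <- solve(TT, crossprod(tc, Xc))
  list(timecourses = tc, maps = maps)
}

rcond_sym <- function(M) {
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(ev)) == 0) return(0)
  min(abs(ev)) / max(abs(ev))
}

#' Temporal-concatenation group spatial ICA
#'
#' Full group decomposition: per-subject temporal PCA, concatenation and
#' group whitening, InfoMax unmixing into `n_components` spatial components,
#' deterministic ordering (descending explained variance in the group-reduced
#' space) and sign fixing (each map's maximum-magnitude voxel positive), then
#' dual-regression back-projection giving every subject k time courses and k
#' spatial maps.
#'
#' @param scans List (>= 2) of [bold4d()] scans sharing one mask.
#' @param n_components Number of components (the study's default is 20).
#' @param seed Integer seed for the InfoMax initialization.
#' @param k_subject Subject-level retained dimension; default
#'   `ceiling(1.5 * n_components)`, truncated to each subject's temporal
#'   rank.
#' @param n_restarts If >= 2, also run [stability_restarts()] with this many
#'   restarts.
#' @param ... Passed to [infomax_unmix()].
#' @return An object of class `group_decomposition`: `group_maps`
#'   (k x v, unit-variance rows), `subject_timecourses` (list of t x k),
#'   `subject_maps` (list of k x v), `n_components`, `subject_ids`, `mask`,
#'   `stability` (tibble or NULL), `explained_variance`, `seed`.
#' @export
run_group_ica <- function(scans, n_components = 20L, seed = 1L, k_subject = NULL,
                          n_restarts = 0L, ...) {
  if (length(scans) < 2L) abort("Group ICA needs at least 2 scans.")
  n_components <- check_count(n_components, "n_components")
  masks_ok <- vapply(scans, function(s) identical(s$mask, scans[[1]]$mask), logical(1))
  if (!all(masks_ok)) {
    abort(sprintf("Scans %s do not share the mask of scan 1.",
                  paste(which(!masks_ok), collapse = ", ")))
  }
  k_subject <- k_subject %||% ceiling(1.5 * n_components)
  reduced <- lapply(scans, function(s) {
    X <- bold_matrix(s)
    Xc <- sweep(X, 2L, colMeans(X))
    ev <- pmax(eigen(tcrossprod(Xc) / ncol(Xc), symmetric = TRUE,
                     only.values = TRUE)$values, 0)
    reduce_subject(s, min(k_subject, effective_rank(ev)))$reduced
  })
  grp <- concatenate_and_reduce(reduced, n_components)
  fit <- infomax_unmix(grp$whitened, seed = seed, ...)
  S <- fit$W %*% grp$whitened + fit$bias

  # order by energy contribution in the whitened space, fix signs, unit-scale
  Winv <- solve(fit$W)
  energy <- colSums(Winv^2) * apply(S, 1L, function(r) mean(r^2))
  ord <- order(energy, decreasing = TRUE)
  S <- S[ord, , drop = FALSE]
  for (c in seq_len(nrow(S))) {
    if (S[c, which.max(abs(S[c, ]))] < 0) S[c, ] <- -S[c, ]
    S[c, ] <- S[c, ] / stats::sd(S[c, ])
  }

  bp <- lapply(scans, function(s) back_project(S, s))
  stability <- NULL
  if (n_restarts >= 2L) {
    stability <- stability_restarts(grp$whitened, n_restarts = n_restarts,
                                    base_seed = seed, ...)
  }
  structure(
    list(group_maps = S,
         subject_timecourses = lapply(bp, `[[`, "timecourses"),
         subject_maps = lapply(bp, `[[`, "maps"),
         n_components = n_components,
         subject_ids = vapply(scans, `[[`, character(1), "subject_id"),
         mask = scans[[1]]$mask,
         stability = stability,
         explained_variance = grp$model$explained_variance,
         infomax = fit[c("converged", "iterations")],
         seed = seed),
    class = "group_decomposition")
}

#' @export
print.group_decomposition <- function(x, ...) {
  cat(sprintf("<group_decomposition> %d components, %d subjects, %d in-mask voxels%s\n",
              x$n_components, length(x$subject_ids), ncol(x$group_maps),
              if (!is.null(x$stability))
                sprintf(", min stability %.3f", min(x$stability$stability_index))
              else ""))
  invisible(x)
}
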