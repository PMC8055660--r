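#' Kendall's tau-b between two measures
#'
#' Rank correlation with the standard tie correction,
#' (C - D) / sqrt((n0 - n1)(n0 - n2)), computed on pairwise-complete
#' observations only (rows missing either value are dropped, no imputation).
#' Fewer than `min_pairs` complete pairs flags the cell as missing (NA)
#' rather than erroring, so it can be excluded from group averaging.
#'
#' @param x,y Equal-length numeric vectors, possibly with NA.
#' @param min_pairs Minimum complete pairs (default 3).
#' @return tau-b in \[-1, 1\], or NA if not computable.
#' @export
kendall_tau_b <- function(x, y, min_pairs = 3L) {
  cc <- stats::complete.cases(x, y)
  if (sum(cc) < min_pairs) return(NA_real_)
  x <- x[cc]; y <- y[cc]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(NA_real_)
  stats::cor(x, y, method = "kendall")
}

tau_matrix_one <- function(mat, min_pairs = 3L) {
  p <- ncol(mat)
  tau <- diag(1, p)
  n_eff <- matrix(0L, p, p)
  for (i in seq_len(p)) {
    n_eff[i, i] <- sum(!is.na(mat[, i]))
    for (j in seq_len(p)) {
      if (j <= i) next
      tau[i, j] <- tau[j, i] <- kendall_tau_b(mat[, i], mat[, j], min_pairs)
      n_eff[i, j] <- n_eff[j, i] <- sum(stats::complete.cases(mat[, i], mat[, j]))
    }
  }
  dimnames(tau) <- dimnames(n_eff) <- list(colnames(mat), colnames(mat))
  list(tau = tau, n_effective = n_eff)
}

#' Within-group Kendall tau-b matrix, averaged across groups
#'
#' Because group sample sizes are imbalanced, pairwise tau-b is first
#' computed within each impairment group (pairwise-complete observations, no
#' imputation) and the matrices are then averaged cell-wise, unweighted,
#' over the groups where the cell is computable. Cells computable in no
#' group stay NA.
#'
#' @param data Data frame with a grouping column and numeric measure
#'   columns.
#' @param group Name of the grouping column (default `"group"`).
#' @param measures Character vector of measure columns; default every
#'   numeric column except `pre_tsm`/`post_tsm`.
#' @param min_pairs Minimum complete pairs per group cell (default 3).
#' @return Object of class `association_matrix`: `tau` (p x p, unit
#'   diagonal, symmetric), `n_effective` (summed contributing pair counts),
#'   `measures`, `groups`.
#' @export
groupwise_average_tau <- function(data, group = "group", measures = NULL,
                                  min_pairs = 3L) {
  stopifnot(is.data.frame(data))
  if (!group %in% names(data)) abort(sprintf("Grouping column '%s' not found.", group))
  if (is.null(measures)) {
    measures <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                        c("pre_tsm", "post_tsm"))
  }
  groups <- sort(unique(as.character(data[[group]])))
  per_group <- lapply(groups, function(g) {
    tau_matrix_one(as.matrix(data[data[[group]] == g, measures, drop = FALSE]),
                   min_pairs)
  })
  p <- length(measures)
  tau_sum <- matrix(0, p, p); tau_n <- matrix(0L, p, p); n_eff <- matrix(0L, p, p)
  for (gm in per_group) {
    ok <- !is.na(gm$tau)
    tau_sum[ok] <- tau_sum[ok] + gm$tau[ok]
    tau_n <- tau_n + ok
    n_eff[ok] <- n_eff[ok] + gm$n_effective[ok]
  }
  tau <- tau_sum / tau_n
  tau[tau_n == 0L] <- NA_real_
  diag(tau) <- 1
  dimnames(tau) <- dimnames(n_eff) <- list(measures, measures)
  structure(list(tau = tau, n_effective = n_eff, measures = measures,
                 groups = groups),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  off <- x$tau[upper.tri(x$tau)]
  cat(sprintf("<association_matrix> %d measures, %d group(s); median off-diagonal tau = %.2f (%d missing cells)\n",
              length(x$measures), length(x$groups),
              stats::median(off, na.rm = TRUE), sum(is.na(off))))
  invisible(x)
}

#' @rdname tidy_falffprog
#' @export
tidy.association_matrix <- function(x, ...) {
  as_tibble(x$tau, rownames = "measure_1") |>
    tidyr::pivot_longer(-"measure_1", names_to = "measure_2", values_to = "tau")
}

#' Correlation distance from an association matrix
#'
#' Distance = 1 - tau (the signed reading) or 1 - |tau| (`absolute = TRUE`);
#' zero diagonal, symmetric. Missing cells are an error: complete the matrix
#' (relax `min_pairs` or merge groups) before clustering.
#'
#' @param assoc An [groupwise_average_tau()] result, or a plain symmetric
#'   correlation matrix.
#' @param absolute Use 1 - |tau| (default FALSE).
#' @return A symmetric distance matrix with zero diagonal.
#' @export
correlation_distance <- function(assoc, absolute = FALSE) {
  tau <- if (inherits(assoc, "association_matrix")) assoc$tau else as.matrix(assoc)
  if (anyNA(tau)) {
    abort("Association matrix has missing cells; complete them (relax min_pairs or merge groups) before computing distances.")
  }
  d <- if (absolute) 1 - abs(tau) else 1 - tau
  diag(d) <- 0
  d
}

#' UPGMA hierarchical clustering
#'
#' Agglomerative clustering with unweighted-average (arithmetic mean)
#' inter-cluster distance: the closest pair of clusters merges at each step,
#' producing nondecreasing merge heights. Backed by
#' `stats::hclust(method = "average")`.
#'
#' @param distances Symmetric, nonnegative, zero-diagonal distance matrix
#'   (or a `dist`).
#' @return Object of class `upgma_tree`: `merge`, `height`, `order`,
#'   `labels`, and the underlying `hclust`.
#' @export
upgma <- function(distances) {
  if (inherits(distances, "dist")) distances <- as.matrix(distances)
  distances <- as.matrix(distances)
  if (!isSymmetric(unname(distances), tol = 1e-10)) {
    abort("`distances` must be symmetric.")
  }
  if (any(distances < 0) || any(abs(diag(distances)) > 1e-12)) {
    abort("`distances` must be nonnegative with a zero diagonal.")
  }
  if (is.null(rownames(distances))) {
    rownames(distances) <- colnames(distances) <-
      paste0("L", seq_len(nrow(distances)))
  }
  hc <- stats::hclust(stats::as.dist(distances), method = "average")
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = hc$labels, hclust = hc),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("<upgma_tree> %d leaves, merge heights %.3g-%.3g\n",
              length(x$labels), min(x$height), max(x$height)))
  invisible(x)
}

#' Cophenetic distances of an UPGMA tree
#'
#' @param tree An [upgma()] result.
#' @return Symmetric matrix of cophenetic distances.
#' @export
cophenetic_distances <- function(tree) {
  stopifnot(inherits(tree, "upgma_tree"))
  as.matrix(stats::cophenetic(tree$hclust))
}

#' Write an UPGMA tree as Newick
#'
#' Branch lengths derive from the merge heights (ultrametric tree).
#'
#' @param tree An [upgma()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(tree, path) {
  stopifnot(inherits(tree, "upgma_tree"))
  ape::write.tree(ape::as.phylo(tree$hclust), file = path)
  invisible(path)
}
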