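#' Correlation distance between two expression profiles
#'
#' `d = 1 - r(x, y)` with `r` the Pearson correlation. Two profiles are
#' close (`d -> 0`) when highly correlated and maximally far (`d -> 2`)
#' when perfectly anti-correlated, so anti-correlated genes are driven into
#' different communities.
#'
#' @param x,y Numeric profiles of equal length `>= 3` with non-zero
#'   variance.
#' @return A single number in `[0, 2]`.
#' @export
correlation_distance <- function(x, y) {
  if (length(x) != length(y)) stop("profiles must have equal length")
  if (length(x) < 3L) stop("profiles must have length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance profile")
  d <- 1 - stats::cor(x, y)
  min(max(d, 0), 2)
}

#' Partition genes into communities by k-means on the correlation distance
#'
#' A k-means-style partition of expression profiles under
#' `d = 1 - r(profile, centroid)`. Cluster centroids are mean member
#' profiles, re-standardized; each gene joins the centroid with minimal
#' correlation distance (ties to the lowest community index). The best of
#' `restarts` random initializations (total within-cluster distance) is
#' returned. A cluster emptied during iteration is re-seeded from the gene
#' farthest from its centroid.
#'
#' @param em An `expr_set`; every gene needs non-zero variance.
#' @param k Number of communities, `2 <= k <= n_genes`.
#' @param seed Integer seed; mandatory, the run is deterministic given it.
#' @param restarts Number of random initializations (default 10).
#' @param max_iter Iteration cap per restart (default 100).
#' @return A list of class `cluster_assignment`: `membership` (named
#'   integer vector, labels `1..k`), `k`, `quality` (total within-cluster
#'   correlation distance), `iterations`.
#' @export
cluster_expression <- function(em, k, seed, restarts = 10L, max_iter = 100L) {
  stopifnot(inherits(em, "expr_set"))
  ng <- n_genes(em)
  if (k < 2L || k > ng) stop("`k` must lie in [2, number of genes]")
  X <- standardize_rows(em$values)
  m <- ncol(X)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      fit <- kmeans_cordist_once(X, k, max_iter)
      if (is.null(best) || fit$quality < best$quality) best <- fit
    }
  })
  structure(list(membership = stats::setNames(best$membership, rownames(X)),
                 k = as.integer(k), quality = best$quality,
                 iterations = best$iterations),
            class = "cluster_assignment")
}

# One k-means pass on row-standardized profiles X under d = 1 - r.
# r(x, centroid) reduces to a dot product once both are standardized.
kmeans_cordist_once <- function(X, k, max_iter) {
  n <- nrow(X); m <- ncol(X)
  centres <- X[sample.int(n, k), , drop = FALSE]
  membership <- integer(n)
  for (it in seq_len(max_iter)) {
    D <- 1 - (X %*% t(centres)) / (m - 1L)       # n x k correlation distances
    new_m <- max.col(-D, ties.method = "first")  # lowest index wins ties
    # re-seed empty clusters from the points farthest from their centroids
    empties <- which(tabulate(new_m, nbins = k) == 0L)
    if (length(empties)) {
      ord <- order(D[cbind(seq_len(n), new_m)], decreasing = TRUE)
      new_m[ord[seq_along(empties)]] <- empties
    }
    if (identical(new_m, membership)) break
    membership <- new_m
    for (cl in seq_len(k)) {
      prof <- colMeans(X[membership == cl, , drop = FALSE])
      sdv <- stats::sd(prof)
      if (!is.finite(sdv) || sdv == 0) prof <- prof + stats::rnorm(m, sd = 1e-8)
      centres[cl, ] <- (prof - mean(prof)) / sqrt(sum((prof - mean(prof))^2) / (m - 1L))
    }
  }
  D <- 1 - (X %*% t(centres)) / (m - 1L)
  quality <- sum(D[cbind(seq_len(n), membership)])
  list(membership = membership, quality = quality, iterations = it)
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment> k =", x$k,
      " quality =", format(x$quality, digits = 6), "\n")
  print(table(x$membership))
  invisible(x)
}

#' Choose the number of communities by an elbow rule
#'
#' Runs [cluster_expression()] for each k in `k_range` and returns the
#' smallest k beyond which adding a community improves the total
#' within-cluster distance by less than `tol` (relative). If no elbow is
#' found the maximum of the range is returned with a warning.
#'
#' @param em An `expr_set`.
#' @param k_range Integer range of candidate k, within `[2, n_genes]`.
#' @param seed Integer seed (shared across all k for comparability).
#' @param tol Relative-improvement tolerance (default 0.05).
#' @param restarts Restarts per k (default 10).
#' @return The chosen k (integer), with the per-k quality profile attached
#'   as attribute `"quality"`.
#' @export
choose_k <- function(em, k_range, seed, tol = 0.05, restarts = 10L) {
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2L || max(k_range) > n_genes(em))
    stop("`k_range` must lie within [2, number of genes]")
  qual <- vapply(k_range, function(k)
    cluster_expression(em, k, seed = seed, restarts = restarts)$quality,
    numeric(1L))
  chosen <- NA_integer_
  for (i in seq_along(k_range)[-1L]) {
    drop_rel <- (qual[i - 1L] - qual[i]) / max(qual[i - 1L], 1e-12)
    if (drop_rel < tol) { chosen <- k_range[i - 1L]; break }
  }
  if (is.na(chosen)) {
    warning("no elbow found in k_range; returning its maximum")
    chosen <- max(k_range)
  }
  structure(chosen, quality = stats::setNames(qual, k_range))
}
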