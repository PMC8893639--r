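# Partitioning the molecule collection into homogeneous structural classes:
# k-means over folded bit fingerprints, inertia (elbow) diagnostics and a
# 2-component PCA projection for plotting. Cluster ids are 0-based.

#' Fit k-means on a fingerprint matrix
#'
#' Lloyd iterations, best of `n_init` random initializations by inertia,
#' fully deterministic given `seed`. Assignment ties break toward the lowest
#' centroid index; a centroid left empty during an iteration is re-seeded at
#' the point farthest from its current centroid.
#'
#' @param bit_matrix Numeric matrix (rows = molecules), typically the 0/1
#'   output of [folded_bit_matrix()].
#' @param k Number of clusters (`1 <= k <= nrow`).
#' @param seed Integer seed (mandatory: persisted models must reproduce
#'   cluster identities).
#' @param n_init Number of random restarts (default 10).
#' @param max_iter Iteration cap per restart.
#' @param params Optional fingerprint parameters stored with the model.
#' @return An object of class `"npek_kmeans"`: `k`, `centroids` (k x n_bits),
#'   `inertia` (sum of squared distances of samples to their closest
#'   centroid), `cluster` (0-based assignments), `sizes`, `seed`, `params`.
#' @export
fit_kmeans <- function(bit_matrix, k, seed, n_init = 10L, max_iter = 100L,
                       params = NULL) {
  x <- as.matrix(bit_matrix)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (k > n)
    npek_stop(paste0("k = ", k, " exceeds the number of samples (", n, ")"),
              "npek_param_error")
  stopifnot(k >= 1, n >= 1)
  set.seed(as.integer(seed))
  best <- NULL
  for (init in seq_len(n_init)) {
    centers <- x[sample.int(n, k), , drop = FALSE]
    fit <- .lloyd(x, centers, max_iter)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  structure(
    list(k = as.integer(k), centroids = best$centers, inertia = best$inertia,
         cluster = best$assign - 1L, sizes = tabulate(best$assign, nbins = k),
         seed = as.integer(seed), n_init = as.integer(n_init),
         params = params),
    class = "npek_kmeans"
  )
}

#' @noRd
.nearest_centroid <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(x)), rowSums(centers^2)) - 2 * x %*% t(centers)
  d2[d2 < 0] <- 0
  list(assign = max.col(-d2, ties.method = "first"),
       d2 = d2)
}

#' @noRd
.lloyd <- function(x, centers, max_iter) {
  n <- nrow(x); k <- nrow(centers)
  assign_prev <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    nc <- .nearest_centroid(x, centers)
    assign <- nc$assign
    # re-seed empty clusters at the sample farthest from its own centroid;
    # bounded retries (duplicate rows can make some centroids unfillable)
    tries <- 0L
    repeat {
      empty <- setdiff(seq_len(k), unique(assign))
      if (length(empty) == 0L || tries >= k) break
      d_own <- nc$d2[cbind(seq_len(n), assign)]
      far <- which.max(d_own)
      centers[empty[1L], ] <- x[far, ]
      nc <- .nearest_centroid(x, centers)
      assign <- nc$assign
      tries <- tries + 1L
    }
    if (identical(assign, assign_prev)) break
    assign_prev <- assign
    for (j in seq_len(k)) {
      members <- assign == j
      if (any(members)) centers[j, ] <- colMeans(x[members, , drop = FALSE])
    }
  }
  nc <- .nearest_centroid(x, centers)
  inertia <- sum(nc$d2[cbind(seq_len(n), nc$assign)])
  list(centers = centers, assign = nc$assign, inertia = inertia)
}

#' @export
print.npek_kmeans <- function(x, ...) {
  cat("<npek k-means> k = ", x$k, ", inertia = ", format(x$inertia),
      "\ncluster sizes: ", paste(x$sizes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Inertia against the number of clusters (elbow diagnostics)
#'
#' One independent best-of-`n_init` fit per requested `k`. The table is meant
#' for plotting; no automatic kink detection is attempted.
#'
#' @inheritParams fit_kmeans
#' @param k_values Ascending integer vector of cluster counts.
#' @return A data.frame with columns `k` and `inertia`.
#' @export
inertia_curve <- function(bit_matrix, k_values, seed, n_init = 10L) {
  stopifnot(!is.unsorted(k_values))
  inertia <- vapply(seq_along(k_values), function(i) {
    fit_kmeans(bit_matrix, k_values[i], seed = seed + i - 1L,
               n_init = n_init)$inertia
  }, 0)
  data.frame(k = as.integer(k_values), inertia = inertia)
}

#' Assign a fingerprint to its nearest centroid
#'
#' @param model A fitted [fit_kmeans()] model.
#' @param fp A folded bit fingerprint ([encode_folded_bits()]) or a numeric
#'   vector of matching length.
#' @return 0-based cluster id; ties break toward the lowest index.
#' @export
assign_cluster <- function(model, fp) {
  stopifnot(inherits(model, "npek_kmeans"))
  v <- if (inherits(fp, "npek_bit_fp")) fp$bits else fp
  if (length(v) != ncol(model$centroids))
    npek_stop(paste0("fingerprint length ", length(v),
                     " does not match centroid length ", ncol(model$centroids)),
              "npek_param_error")
  d2 <- rowSums(sweep(model$centroids, 2, as.numeric(v))^2)
  unname(which.min(d2)) - 1L
}

#' Two-component PCA projection of a fingerprint matrix
#'
#' @param bit_matrix Numeric matrix with at least 3 rows.
#' @return A list with `coordinates` (n x 2 scores), `explained_variance`
#'   (fractions for the two components, non-increasing) and `rotation`
#'   (loadings). Degenerate input (zero total variance) yields zero
#'   coordinates and zero fractions.
#' @export
project_pca <- function(bit_matrix) {
  x <- as.matrix(bit_matrix)
  if (nrow(x) < 3L)
    npek_stop("PCA projection needs at least 3 samples", "npek_param_error")
  total_var <- sum(apply(x, 2, stats::var))
  if (total_var == 0) {
    return(list(coordinates = matrix(0, nrow(x), 2),
                explained_variance = c(0, 0),
                rotation = matrix(0, ncol(x), 2)))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  coords <- matrix(0, nrow(x), 2)
  coords[, seq_len(k)] <- pc$x[, seq_len(k)]
  ev <- c(0, 0)
  ev[seq_len(k)] <- (pc$sdev[seq_len(k)]^2) / sum(pc$sdev^2)
  rot <- matrix(0, ncol(x), 2)
  rot[, seq_len(k)] <- pc$rotation[, seq_len(k)]
  list(coordinates = coords, explained_variance = ev, rotation = rot)
}
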