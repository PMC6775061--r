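## Mini-batch k-means discretisation of feature trajectories.

feature_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  stopifnot(is.data.frame(features))
  cols <- intersect(c("lock_distance", "y753_rmsd"), names(features))
  if (length(cols) == 0)
    cols <- names(features)[vapply(features, is.numeric, TRUE) &
                              !names(features) %in% c("traj", "frame", "time")]
  as.matrix(features[, cols, drop = FALSE])
}

#' Mini-batch k-means discretisation
#'
#' Discretises feature-space frames into k microstates with mini-batch
#' k-means (k-means++ initialisation, aggregated per-centre mini-batch
#' updates with 1/n learning rates), then assigns every frame to its
#' nearest centre by Euclidean distance. Deterministic under a fixed
#' seed.
#'
#' @param features Tibble with feature columns (`lock_distance`,
#'   `y753_rmsd`) and optionally `traj`/`frame`, or a numeric matrix.
#' @param k Number of clusters; must not exceed the number of frames.
#' @param seed RNG seed.
#' @param batch_size Mini-batch size.
#' @param n_iter Number of mini-batch iterations.
#' @return A `discretization`: list with `centers` (k x d), `assignment`
#'   (integer per frame), `k`, and `traj` (trajectory id per frame, if
#'   present in the input).
#' @export
cluster_features <- function(features, k, seed, batch_size = 2048L,
                             n_iter = 100L) {
  X <- feature_matrix(features)
  n <- nrow(X)
  k <- as.integer(k)
  if (n < k)
    stop("fewer frames (", n, ") than requested clusters (", k, ")",
         call. = FALSE)
  set.seed(as.integer(seed))
  if (k == 1L) {
    centers <- matrix(colMeans(X), 1)
  } else {
    pool <- if (n > 20000L) X[sample.int(n, 20000L), , drop = FALSE] else X
    centers <- kmeanspp_init(pool, k)
    counts <- numeric(k)
    for (it in seq_len(n_iter)) {
      idx <- sample.int(n, min(batch_size, n))
      B <- X[idx, , drop = FALSE]
      a <- nearest_center(B, centers)
      for (c in unique(a)) {
        m <- a == c
        nc <- sum(m)
        counts[c] <- counts[c] + nc
        eta <- nc / counts[c]
        centers[c, ] <- (1 - eta) * centers[c, ] + eta * colMeans(B[m, , drop = FALSE])
      }
    }
  }
  assignment <- nearest_center(X, centers)
  structure(
    list(centers = centers, assignment = assignment, k = k,
         traj = if (is.data.frame(features) && "traj" %in% names(features))
           features$traj else rep(1L, n)),
    class = "discretization")
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in 2:k) {
    prob <- d2 / sum(d2)
    centers[j, ] <- X[sample.int(n, 1L, prob = prob), ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  centers
}

## Chunked nearest-centre assignment (Euclidean).
nearest_center <- function(X, centers) {
  n <- nrow(X)
  out <- integer(n)
  cc <- rowSums(centers^2)
  chunk <- 100000L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    Xi <- X[s:e, , drop = FALSE]
    D <- -2 * Xi %*% t(centers)
    D <- sweep(D, 2, cc, "+")
    out[s:e] <- max.col(-D, ties.method = "first")
  }
  out
}

#' @export
print.discretization <- function(x, ...) {
  cat("k-means discretisation:", x$k, "microstates over",
      length(x$assignment), "frames\n")
  invisible(x)
}

#' Discrete trajectories from a discretization
#'
#' Splits the per-frame microstate assignment back into one integer
#' sequence per trajectory, preserving frame order.
#'
#' @param disc A `discretization`.
#' @return List of integer vectors.
#' @export
discrete_trajectories <- function(disc) {
  split(disc$assignment, disc$traj)
}
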