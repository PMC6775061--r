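## PCCA+ spectral coarse-graining of a reversible transition matrix.

#' PCCA+ macrostate decomposition
#'
#' Groups the microstates of a reversible Markov state model into
#' `n_macro` metastable macrostates with Perron Cluster Cluster Analysis.
#' The first `n_macro` right eigenvectors are mapped onto a probability
#' simplex with the inner-simplex vertex search (the rows most distant in
#' eigenvector space become the vertices), giving fuzzy memberships that
#' are crisped by argmax. Macrostate populations are the sums of the
#' stationary weights of their member microstates.
#'
#' @param model An `msm_model`, or a reversible transition matrix.
#' @param n_macro Number of macrostates.
#' @param pi Stationary distribution (required if `model` is a matrix).
#' @return A `macrostate_model`: list with `membership` (macrostate index
#'   per active microstate), `chi` (fuzzy memberships), `populations`,
#'   `pi_micro`, `active_set`, `n_macro`.
#' @export
pcca_macrostates <- function(model, n_macro, pi = NULL) {
  if (inherits(model, "msm_model")) {
    Tm <- model$T; pi <- model$pi; act <- model$active_set
  } else {
    Tm <- as.matrix(model)
    stopifnot(!is.null(pi))
    act <- seq_len(nrow(Tm))
  }
  n <- nrow(Tm)
  n_macro <- as.integer(n_macro)
  stopifnot(n_macro >= 1L, n_macro <= n)
  if (n_macro == 1L) {
    return(new_macrostate_model(rep(1L, n), matrix(1, n, 1), pi, act, 1L))
  }
  ## symmetrised spectral problem: S = D^1/2 T D^-1/2 with D = diag(pi)
  s <- sqrt(pi)
  S <- (s * Tm) / rep(s, each = n)
  S <- (S + t(S)) / 2                      # clean numerical asymmetry
  e <- eigen(S, symmetric = TRUE)
  gap <- abs(e$values[n_macro] - e$values[n_macro + 1])
  if (n_macro < n && gap < 1e-10)
    warning("spectral gap at n_macro is degenerate (", signif(gap, 3),
            "); macrostate definition may be ambiguous")
  X <- e$vectors[, seq_len(n_macro), drop = FALSE] / s
  X[, 1] <- 1                              # stationary eigenvector
  chi <- inner_simplex_chi(X)
  membership <- max.col(chi, ties.method = "first")
  ## re-index macrostates so every label is used, ordered by first member
  used <- sort(unique(membership))
  if (length(used) < n_macro)
    warning("PCCA produced ", length(used), " non-empty macrostates (",
            n_macro, " requested)")
  membership <- match(membership, used)
  chi <- chi[, used, drop = FALSE]
  new_macrostate_model(membership, chi, pi, act, length(used))
}

## Inner-simplex algorithm: pick the n rows of X that span the widest
## simplex, then express every row in barycentric coordinates of those
## vertices.
inner_simplex_chi <- function(X) {
  n <- nrow(X); m <- ncol(X)
  idx <- integer(m)
  ## first vertex: row furthest from the centroid
  d <- rowSums((X - rep(colMeans(X), each = n))^2)
  idx[1] <- which.max(d)
  for (k in 2:m) {
    ## residual distance from the affine span of the chosen vertices
    V <- X[idx[seq_len(k - 1)], , drop = FALSE]
    R <- sweep(X, 2, V[1, ])
    if (k > 2) {
      V0 <- sweep(V[-1, , drop = FALSE], 2, V[1, ])
      Q <- qr.Q(qr(t(V0)))
      R <- R - R %*% Q %*% t(Q)
    }
    idx[k] <- which.max(rowSums(R^2))
  }
  Lam <- X[idx, , drop = FALSE]
  chi <- X %*% solve(Lam)
  ## clip tiny negative memberships and renormalise
  chi[chi < 0] <- 0
  chi / pmax(rowSums(chi), .Machine$double.eps)
}

new_macrostate_model <- function(membership, chi, pi, active_set, n_macro) {
  pops <- vapply(seq_len(n_macro),
                 function(a) sum(pi[membership == a]), 0)
  pops <- pops / sum(pops)
  structure(
    list(membership = membership, chi = chi, populations = pops,
         pi_micro = pi, active_set = active_set, n_macro = n_macro),
    class = "macrostate_model")
}

#' @export
print.macrostate_model <- function(x, ...) {
  cat("PCCA+ macrostate model:", x$n_macro, "macrostates over",
      length(x$membership), "microstates\n")
  cat("  populations:",
      paste(sprintf("%.1f%%", 100 * x$populations), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.macrostate_model <- function(x, ...) {
  tibble::tibble(macrostate = seq_len(x$n_macro),
                 population = x$populations,
                 n_microstates = tabulate(x$membership, x$n_macro))
}

#' @export
glance.macrostate_model <- function(x, ...) {
  tibble::tibble(n_macro = x$n_macro,
                 n_micro = length(x$membership),
                 min_population = min(x$populations),
                 max_population = max(x$populations))
}
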