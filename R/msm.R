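## Markov state model estimation: lagged transition counts, reversible
## maximum-likelihood transition matrices, implied timescales.

#' Lagged transition count matrix
#'
#' Sliding-window counts \eqn{C_{ij} = \#\{t : s_t = i, s_{t+\tau} = j\}},
#' never counting across trajectory boundaries. Trajectories shorter than
#' the lag contribute nothing.
#'
#' @param dtrajs A list of integer state sequences (1-based), or a single
#'   integer vector.
#' @param lag Lag time in frames (>= 1).
#' @param n_states Number of states; defaults to the maximum observed.
#' @return A dense `n_states x n_states` count matrix.
#' @export
count_matrix <- function(dtrajs, lag, n_states = NULL) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  lag <- as.integer(lag)
  stopifnot(lag >= 1L)
  n_states <- n_states %||% max(vapply(dtrajs, max, 0L))
  if (all(vapply(dtrajs, length, 0L) <= lag))
    stop("all trajectories are shorter than the lag time", call. = FALSE)
  i_all <- integer(0); j_all <- integer(0)
  for (s in dtrajs) {
    m <- length(s) - lag
    if (m < 1L) next
    i_all <- c(i_all, s[seq_len(m)])
    j_all <- c(j_all, s[seq_len(m) + lag])
  }
  C <- Matrix::sparseMatrix(i = i_all, j = j_all, x = 1,
                            dims = c(n_states, n_states))
  as.matrix(C)
}

## Largest strongly connected component of the count graph (edges where
## C_ij > 0), returned as a sorted integer vector of state indices.
largest_connected_set <- function(C) {
  g <- igraph::graph_from_adjacency_matrix((C > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  ## among the largest components prefer the one with most counts
  sizes <- comp$csize
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1L) {
    wt <- vapply(cand, function(k) {
      idx <- which(comp$membership == k)
      sum(C[idx, idx])
    }, 0)
    cand <- cand[which.max(wt)]
  }
  sort(which(comp$membership == cand))
}

#' Reversible maximum-likelihood Markov state model
#'
#' Estimates the transition matrix maximising the likelihood of the count
#' matrix under the detailed-balance constraint
#' \eqn{\pi_i T_{ij} = \pi_j T_{ji}}, using the standard self-consistent
#' fixed-point iteration on the unnormalised flux variables
#' \eqn{x_{ij} = x_{ji}}. Estimation is restricted to the largest strongly
#' connected set of the count graph (the reversible MLE requires an
#' irreducible chain); states outside it are dropped from the model.
#'
#' @param C Transition count matrix.
#' @param tol Convergence tolerance on the max-norm change of T per sweep.
#' @param max_iter Maximum number of sweeps.
#' @param lag Lag time used to build `C` (frames); stored for timescales.
#' @param dt Physical time per frame (arbitrary units, default 1).
#' @return An `msm_model` object: list with `T` (row-stochastic,
#'   reversible), `pi`, `C`, `active_set`, `lag`, `dt`, `converged`.
#' @export
estimate_msm <- function(C, tol = 1e-10, max_iter = 10000L, lag = 1L, dt = 1) {
  C <- as.matrix(C)
  full_n <- nrow(C)
  act <- largest_connected_set(C)
  if (length(act) < 2L)
    stop("count matrix has no connected set with at least two states",
         call. = FALSE)
  Ca <- C[act, act, drop = FALSE]
  n <- nrow(Ca)
  Cs <- Ca + t(Ca)
  ci <- rowSums(Ca)
  x <- Cs / sum(Ca)            # symmetric start
  converged <- FALSE
  iter <- 0L
  Tprev <- x / rowSums(x)
  while (iter < max_iter) {
    iter <- iter + 1L
    xi <- rowSums(x)
    denom <- outer(ci / xi, ci / xi, "+")
    x <- Cs / denom
    x[Cs == 0] <- 0
    Tm <- x / rowSums(x)
    if (max(abs(Tm - Tprev)) < tol) { converged <- TRUE; break }
    Tprev <- Tm
  }
  xi <- rowSums(x)
  Tm <- x / xi
  pi <- xi / sum(xi)
  dimnames(Tm) <- list(act, act)
  structure(
    list(T = Tm, pi = pi, C = C, active_set = act, n_states_full = full_n,
         lag = lag, dt = dt, converged = converged, n_iter = iter),
    class = "msm_model")
}

#' @export
print.msm_model <- function(x, ...) {
  cat("Reversible Markov state model\n")
  cat("  states (active/total):", length(x$active_set), "/",
      x$n_states_full, "\n")
  cat("  lag:", x$lag, "frames (", x$lag * x$dt, "time units )\n")
  cat("  converged:", x$converged, "after", x$n_iter, "sweeps\n")
  invisible(x)
}

#' Implied relaxation timescales
#'
#' \eqn{t_i(\tau) = -\tau / \ln |\lambda_i(\tau)|} for the eigenvalues of
#' the transition matrix sorted by decreasing modulus, excluding the
#' stationary eigenvalue \eqn{\lambda_1 = 1}. Eigenvalues within 1e-12 of
#' one yield an infinite timescale (flagged in the output); appreciable
#' imaginary parts are reported via a warning.
#'
#' @param model An `msm_model`, or a transition matrix.
#' @param n Number of timescales to return.
#' @param lag Lag in frames (taken from the model if available).
#' @param dt Physical time per frame.
#' @return Tibble with `index`, `eigenvalue`, `timescale`, `capped`.
#' @export
implied_timescales <- function(model, n = NULL, lag = NULL, dt = NULL) {
  if (inherits(model, "msm_model")) {
    Tm <- model$T
    lag <- lag %||% model$lag
    dt <- dt %||% model$dt
  } else {
    Tm <- as.matrix(model)
    lag <- lag %||% 1L
    dt <- dt %||% 1
  }
  ev <- eigen(Tm, only.values = TRUE)$values
  if (any(abs(Im(ev)) > 1e-8))
    warning("transition matrix has complex eigenvalues beyond tolerance; ",
            "using moduli")
  lam <- Mod(ev)
  lam <- lam[order(lam, decreasing = TRUE)]
  lam <- lam[-1]                       # drop the stationary eigenvalue
  n <- n %||% length(lam)
  lam <- lam[seq_len(min(n, length(lam)))]
  capped <- lam >= 1 - 1e-12
  ts <- ifelse(capped, Inf, -lag * dt / log(pmin(lam, 1 - 1e-15)))
  tibble::tibble(index = seq_along(lam) + 1L, eigenvalue = lam,
                 timescale = ts, capped = capped)
}

#' @export
tidy.msm_model <- function(x, ...) {
  tibble::tibble(state = x$active_set, pi = as.numeric(x$pi))
}

#' @export
glance.msm_model <- function(x, ...) {
  its <- implied_timescales(x, n = 2)
  tibble::tibble(
    n_states = length(x$active_set),
    lag = x$lag,
    converged = x$converged,
    slowest_timescale = its$timescale[1],
    detailed_balance_residual = max(abs(x$pi * x$T - t(x$pi * x$T))))
}
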