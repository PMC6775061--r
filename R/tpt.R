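## Transition path theory on a discrete Markov chain.
##
## All functions work on a row-stochastic transition matrix `T` with
## stationary distribution `pi`. Source/sink sets A and B are integer state
## indices. The flux decomposition follows the usual max-bottleneck pathway
## extraction on the net flux network.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Forward and backward committor probabilities
#'
#' The forward committor \eqn{q^+_i} is the probability that the chain,
#' started in state i, reaches the sink set B before the source set A; it
#' solves the discrete boundary-value problem \eqn{q^+ = 0} on A,
#' \eqn{q^+ = 1} on B and \eqn{(Tq^+)_i = q^+_i} elsewhere. The backward
#' committor is the forward committor of the time-reversed chain with the
#' roles of A and B exchanged; for a reversible chain
#' \eqn{q^- = 1 - q^+}.
#'
#' @param tmat Row-stochastic transition matrix.
#' @param A,B Disjoint, non-empty integer vectors of source/sink states.
#' @param pi Stationary distribution; computed from `tmat` if omitted.
#' @return A list with numeric vectors `q_plus` and `q_minus`.
#' @export
committor <- function(tmat, A, B, pi = NULL) {
  tmat <- as.matrix(tmat)
  n <- nrow(tmat)
  A <- as.integer(A); B <- as.integer(B)
  stopifnot(length(A) >= 1, length(B) >= 1,
            length(intersect(A, B)) == 0,
            all(c(A, B) >= 1), all(c(A, B) <= n))
  pi <- pi %||% stationary_distribution(tmat)

  q_plus <- solve_committor(tmat, A, B)
  ## time-reversed chain: Trev_ij = pi_j T_ji / pi_i
  trev <- t(tmat * pi) / pi
  q_minus <- solve_committor(trev, B, A)
  list(q_plus = q_plus, q_minus = q_minus)
}

solve_committor <- function(tmat, A, B) {
  n <- nrow(tmat)
  q <- numeric(n)
  q[B] <- 1
  U <- setdiff(seq_len(n), c(A, B))
  if (length(U) > 0L) {
    M <- diag(length(U)) - tmat[U, U, drop = FALSE]
    b <- rowSums(tmat[U, B, drop = FALSE])
    sol <- tryCatch(solve(M, b), error = function(e)
      stop("committor system is singular: intermediate states are ",
           "disconnected from the source/sink sets", call. = FALSE))
    q[U] <- sol
  }
  pmin(pmax(q, 0), 1)
}

#' Stationary distribution of a transition matrix
#'
#' Principal left eigenvector of a row-stochastic matrix, normalised to
#' sum to one.
#'
#' @param tmat Row-stochastic transition matrix.
#' @return Numeric probability vector.
#' @export
stationary_distribution <- function(tmat) {
  tmat <- as.matrix(tmat)
  e <- eigen(t(tmat))
  i <- which.max(Re(e$values))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

#' Reactive flux network between a source and a sink set
#'
#' Computes the gross reactive flux
#' \eqn{f_{ij} = \pi_i q^-_i T_{ij} q^+_j} (off-diagonal), the net flux
#' \eqn{F_{ij} = \max(0, f_{ij} - f_{ji})} and the total A-to-B flux
#' \eqn{\sum_{i \in A, j \notin A} F_{ij}} per lag step.
#'
#' @inheritParams committor
#' @param labels Optional state labels for printing.
#' @return A `flux_network` object: list with `F` (net flux matrix),
#'   `gross`, `q_plus`, `q_minus`, `pi`, `A`, `B`, `total_flux`.
#' @export
net_flux <- function(tmat, A, B, pi = NULL, labels = NULL) {
  tmat <- as.matrix(tmat)
  pi <- pi %||% stationary_distribution(tmat)
  qq <- committor(tmat, A, B, pi = pi)
  n <- nrow(tmat)
  f <- (pi * qq$q_minus) * tmat * rep(qq$q_plus, each = n)
  diag(f) <- 0
  Fnet <- pmax(f - t(f), 0)
  total <- sum(Fnet[A, setdiff(seq_len(n), A), drop = FALSE])
  structure(
    list(F = Fnet, gross = f, q_plus = qq$q_plus, q_minus = qq$q_minus,
         pi = pi, A = A, B = B, total_flux = total,
         labels = labels %||% rownames(tmat) %||% paste0("S", seq_len(n))),
    class = "flux_network")
}

#' @export
print.flux_network <- function(x, ...) {
  cat("Reactive flux network (", length(x$pi), " states)\n", sep = "")
  cat("  source:", paste(x$labels[x$A], collapse = ", "),
      " sink:", paste(x$labels[x$B], collapse = ", "), "\n")
  cat("  total net flux per lag step:", format(x$total_flux, digits = 6), "\n")
  invisible(x)
}

#' Coarse-grain a net flux matrix onto macrostates
#'
#' Sums the microstate net flux over all pairs grouped by macrostate
#' membership, zeroing intra-macrostate flux.
#'
#' @param F Net flux matrix over microstates.
#' @param membership Integer macrostate index per microstate.
#' @return Macrostate-level flux matrix.
#' @export
coarse_flux <- function(F, membership) {
  F <- as.matrix(F)
  membership <- as.integer(membership)
  stopifnot(length(membership) == nrow(F))
  m <- max(membership)
  G <- matrix(0, m, m)
  for (a in seq_len(m)) {
    ia <- membership == a
    if (!any(ia)) next
    for (b in seq_len(m)) {
      if (a == b) next
      ib <- membership == b
      if (any(ib)) G[a, b] <- sum(F[ia, ib, drop = FALSE])
    }
  }
  G
}

#' Decompose a net flux network into pathways
#'
#' Iterative bottleneck (max-min) pathway extraction: repeatedly find the
#' A-to-B path whose minimum-flux edge is maximal, subtract that bottleneck
#' flux along the path, and record the path with its share of the total
#' flux. Ties between paths with equal bottleneck flux are broken by
#' lexicographic path order. Extraction stops once 99.9% of the total flux
#' is assigned (or no A-to-B path remains).
#'
#' @param flux A `flux_network` object, or a net flux matrix.
#' @param A,B Source/sink sets (taken from the network if omitted).
#' @param labels Optional state labels.
#' @param flux_fraction Stop once this fraction of the flux is assigned.
#' @param max_paths Safety cap on the number of extracted paths.
#' @return A tibble with columns `path` (character, states joined by
#'   " -> "), `states` (list of integer vectors), `flux`, `percent`.
#' @export
decompose_pathways <- function(flux, A = NULL, B = NULL, labels = NULL,
                               flux_fraction = 0.999, max_paths = 10000L) {
  if (inherits(flux, "flux_network")) {
    Fm <- flux$F
    A <- A %||% flux$A; B <- B %||% flux$B
    labels <- labels %||% flux$labels
    total <- flux$total_flux
  } else {
    Fm <- as.matrix(flux)
    stopifnot(!is.null(A), !is.null(B))
    total <- sum(Fm[A, setdiff(seq_len(nrow(Fm)), A), drop = FALSE])
  }
  labels <- labels %||% paste0("S", seq_len(nrow(Fm)))
  paths <- list(); fluxes <- numeric(0)
  assigned <- 0
  while (assigned < flux_fraction * total && length(paths) < max_paths) {
    p <- widest_path(Fm, A, B)
    if (is.null(p)) break
    b <- min(Fm[cbind(p[-length(p)], p[-1])])
    if (b <= 0) break
    Fm[cbind(p[-length(p)], p[-1])] <-
      Fm[cbind(p[-length(p)], p[-1])] - b
    paths[[length(paths) + 1L]] <- p
    fluxes <- c(fluxes, b)
    assigned <- assigned + b
  }
  if (length(paths) == max_paths && assigned < flux_fraction * total)
    warning("pathway decomposition did not converge within max_paths")
  tibble::tibble(
    path = vapply(paths, function(p) paste(labels[p], collapse = " -> "), ""),
    states = paths,
    flux = fluxes,
    percent = if (total > 0) 100 * fluxes / total else fluxes * NA_real_)
}

## Max-bottleneck (widest) A->B path with deterministic lexicographic
## tie-breaking: binary-search the bottleneck level over the distinct edge
## fluxes, then walk the lexicographically smallest path in the subgraph of
## edges at or above that level.
widest_path <- function(F, A, B) {
  n <- nrow(F)
  w <- sort(unique(F[F > 0]))
  if (length(w) == 0L) return(NULL)
  reach <- function(level) {
    G <- F >= level
    ## BFS from A
    seen <- logical(n); frontier <- A; seen[A] <- TRUE
    while (length(frontier) > 0L) {
      nxt <- which(colSums(G[frontier, , drop = FALSE]) > 0)
      nxt <- nxt[!seen[nxt]]
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    seen
  }
  lo <- 1L; hi <- length(w)
  if (!any(reach(w[lo])[B])) return(NULL)
  while (lo < hi) {                     # largest level with B reachable
    mid <- (lo + hi + 1L) %/% 2L
    if (any(reach(w[mid])[B])) lo <- mid else hi <- mid - 1L
  }
  level <- w[lo]
  G <- F >= level
  ## can-reach-B map on the thresholded graph
  seenB <- logical(n); frontier <- B; seenB[B] <- TRUE
  while (length(frontier) > 0L) {
    nxt <- which(rowSums(G[, frontier, drop = FALSE]) > 0)
    nxt <- nxt[!seenB[nxt]]
    seenB[nxt] <- TRUE
    frontier <- nxt
  }
  starts <- sort(A[seenB[A]])
  cur <- starts[1L]
  path <- cur
  visited <- logical(n); visited[A] <- TRUE   # never re-enter the source set
  while (!(cur %in% B)) {
    nbrs <- which(G[cur, ] & !visited)
    nbrs <- sort(nbrs[seenB[nbrs]])
    ## among viable neighbours pick the smallest index whose onward graph
    ## still reaches B without revisiting
    found <- FALSE
    for (v in nbrs) {
      if (v %in% B || reaches_B_avoiding(G, v, B, visited)) {
        path <- c(path, v); visited[v] <- TRUE; cur <- v
        found <- TRUE
        break
      }
    }
    if (!found) return(NULL)
  }
  path
}

reaches_B_avoiding <- function(G, v, B, visited) {
  n <- nrow(G)
  seen <- visited; seen[v] <- TRUE
  frontier <- v
  while (length(frontier) > 0L) {
    nxt <- which(colSums(G[frontier, , drop = FALSE]) > 0)
    nxt <- nxt[!seen[nxt]]
    if (any(nxt %in% B)) return(TRUE)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  FALSE
}

#' @export
tidy.flux_network <- function(x, ...) {
  n <- length(x$pi)
  tibble::tibble(
    state = x$labels,
    pi = x$pi,
    q_plus = x$q_plus,
    q_minus = x$q_minus,
    role = dplyr::case_when(seq_len(n) %in% x$A ~ "source",
                            seq_len(n) %in% x$B ~ "sink",
                            TRUE ~ "intermediate"))
}

#' @export
glance.flux_network <- function(x, ...) {
  tibble::tibble(n_states = length(x$pi),
                 total_flux = x$total_flux,
                 n_source = length(x$A),
                 n_sink = length(x$B))
}
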