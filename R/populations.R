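## Macrostate population estimation with bootstrap uncertainties, and the
## mapping of PCCA macrostates back onto the named landscape basins.

#' Map PCCA macrostates onto landscape basins
#'
#' Each macrostate is placed at the stationary-weighted mean feature
#' position of its member microstates and assigned greedily (closest pair
#' first, in width-scaled distance) to a distinct basin of the landscape.
#'
#' @param macro A `macrostate_model`.
#' @param msm The `msm_model` the macrostates were built from.
#' @param centers Microstate centres (k x 2) from the discretisation.
#' @param model A `landscape_model` providing the basin geometry.
#' @return Character vector: basin label per macrostate (NA if there are
#'   more macrostates than basins).
#' @export
map_macrostates <- function(macro, msm, centers, model) {
  b <- model$basins
  act <- msm$active_set
  pos <- t(vapply(seq_len(macro$n_macro), function(a) {
    m <- macro$membership == a
    w <- macro$pi_micro[m]
    colSums(centers[act[m], , drop = FALSE] * w) / sum(w)
  }, numeric(2)))
  d <- outer(seq_len(nrow(pos)), seq_len(nrow(b)), function(i, j) {
    ((pos[i, 1] - b$lock[j]) / b$sigma_l[j])^2 +
      ((pos[i, 2] - b$rmsd[j]) / b$sigma_r[j])^2
  })
  lab <- rep(NA_character_, nrow(pos))
  taken <- logical(nrow(b))
  for (step in seq_len(min(nrow(pos), nrow(b)))) {
    idx <- which(d == min(d), arr.ind = TRUE)[1, ]
    lab[idx[1]] <- b$state[idx[2]]
    d[idx[1], ] <- Inf
    d[, idx[2]] <- Inf
    taken[idx[2]] <- TRUE
  }
  lab
}

## One pass of count -> reversible MSM -> PCCA -> basin-mapped populations
## for a set of discrete trajectories over a fixed discretisation.
estimate_populations_once <- function(dtrajs, lag, n_macro, k, centers,
                                      model) {
  C <- count_matrix(dtrajs, lag = lag, n_states = k)
  msm <- estimate_msm(C, lag = lag)
  macro <- suppressWarnings(pcca_macrostates(msm, n_macro))
  lab <- map_macrostates(macro, msm, centers, model)
  pops <- setNames(rep(NA_real_, nrow(model$basins)), model$basins$state)
  ok <- !is.na(lab)
  pops[lab[ok]] <- macro$populations[ok]
  pops
}

#' Bootstrap macrostate populations
#'
#' Estimates the basin-mapped macrostate populations from the full
#' data, then resamples trajectories with replacement `n_boot` times and
#' reruns count matrix, reversible estimation and PCCA (with the
#' discretisation held fixed) on every resample. The headline
#' `population` is the bootstrap mean and the uncertainty its standard
#' deviation; the all-data point estimate is reported alongside.
#'
#' @param disc A `discretization` of the feature trajectories.
#' @param model The `landscape_model` naming the basins.
#' @param lag MSM lag time in frames.
#' @param n_macro Number of PCCA macrostates.
#' @param n_boot Number of bootstrap resamples (>= 2).
#' @param seed RNG seed for the resampling.
#' @return A `population_estimate`: list with `summary` tibble (state,
#'   population, sd, target), `boot` matrix (n_boot x basins), `n_traj`.
#' @export
bootstrap_populations <- function(disc, model, lag, n_macro = 6L,
                                  n_boot = 100L, seed = 1L) {
  stopifnot(n_boot >= 2L)
  dtrajs <- discrete_trajectories(disc)
  k <- disc$k
  point <- estimate_populations_once(dtrajs, lag, n_macro, k,
                                     disc$centers, model)
  set.seed(as.integer(seed))
  nt <- length(dtrajs)
  boot <- matrix(NA_real_, n_boot, length(point),
                 dimnames = list(NULL, names(point)))
  for (b in seq_len(n_boot)) {
    ids <- sample.int(nt, nt, replace = TRUE)
    boot[b, ] <- tryCatch(
      estimate_populations_once(dtrajs[ids], lag, n_macro, k,
                                disc$centers, model),
      error = function(e) rep(NA_real_, length(point)))
  }
  complete <- stats::complete.cases(boot)
  if (any(!complete)) {
    warning(sum(!complete), " of ", n_boot,
            " bootstrap resamples failed and were dropped")
    boot <- boot[complete, , drop = FALSE]
  }
  sds <- apply(boot, 2, sd)
  means <- colMeans(boot)
  structure(
    list(summary = tibble::tibble(
           state = names(point),
           population = as.numeric(means),
           sd = as.numeric(sds),
           point = as.numeric(point),
           target = model$basins$weight),
         boot = boot, n_traj = nt, n_boot = n_boot, lag = lag),
    class = "population_estimate")
}

#' @export
print.population_estimate <- function(x, ...) {
  cat("Macrostate populations (", x$n_boot, " bootstrap resamples over ",
      x$n_traj, " trajectories)\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %s: %5.2f%% +/- %.2f (target %.2f%%)\n", s$state[i],
                100 * s$population[i], 100 * s$sd[i], 100 * s$target[i]))
  invisible(x)
}

#' @export
tidy.population_estimate <- function(x, ...) x$summary

#' @export
glance.population_estimate <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_traj = x$n_traj, n_boot = x$n_boot, lag = x$lag,
    max_abs_error = max(abs(s$population - s$target), na.rm = TRUE),
    max_z = max(abs(s$population - s$target) / pmax(s$sd, 1e-12),
                na.rm = TRUE))
}
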