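## Synthetic 2D activation landscape.
##
## The landscape lives in the plane of the two activation descriptors
## (ionic-lock distance, Y7.53 RMSD). Each macrostate basin is a
## Gaussian with a broad co-centred halo; the halos overlap and provide
## the finite barriers through which basins exchange. The potential is
## U(x) = -kT ln p(x) with p the mixture density, so the Boltzmann
## density of U is exactly p. Mixture coefficients are calibrated so that
## the probability mass of each basin's partition cell equals the
## reported macrostate population.

basin_geometry <- function() {
  tibble::tibble(
    state   = paste0("M", 0:5),
    lock    = c(2.0, 2.5, 12.0, 10.25, 7.25, 7.0),
    rmsd    = c(0.6, 3.6, 4.0, 0.8, 0.6, 3.6),
    sigma_l = c(0.25, 0.38, 0.60, 0.60, 0.72, 0.78),
    sigma_r = c(0.25, 0.38, 0.50, 0.50, 0.45, 0.50),
    weight  = as.numeric(a2a_populations()))
}

#' The reference A2A activation landscape
#'
#' Builds the six-basin synthetic free-energy landscape over the two
#' activation descriptors. Basin target weights are the reported
#' equilibrium populations (M5 38.4%, M4 31.9%, M3 17.8%, M2 9.9%,
#' M1 1.2%, M0 0.6%, renormalised); centres follow the descriptor values
#' reported for each macrostate (ionic lock formed at ~2 A in M0/M1,
#' broken at 6-8.5 A in M4/M5, 9.5-11 A in M3 and reaching 12 A in M2;
#' Y7.53 RMSD low in the inactive-like rows, high in the TM7-rotated
#' ones). Mixture coefficients are calibrated (see
#' [calibrate_landscape()]) so each basin cell carries exactly its target
#' mass; the shipped coefficients are read from a plain-text fixture
#' unless `recalibrate = TRUE`.
#'
#' @param temperature Temperature in kelvin (sets kT).
#' @param halo_fraction Fraction of each basin's mass in its broad halo.
#' @param halo_scale Width multiplier of the halo relative to the core.
#' @param calibrate Calibrate the mixture coefficients (recommended;
#'   without it the coefficients equal the raw target weights).
#' @return A `landscape_model`: list with `basins` tibble (centres,
#'   widths, target weights, calibrated mixture coefficients), `kT`,
#'   `halo_fraction`, `halo_scale`.
#' @export
reference_landscape <- function(temperature = 300, halo_fraction = 0.30,
                                halo_scale = 3, calibrate = TRUE) {
  key <- paste(temperature, halo_fraction, halo_scale, calibrate,
               sep = "|")
  cached <- .landscape_cache[[key]]
  if (!is.null(cached)) return(cached)
  basins <- basin_geometry()
  model <- structure(
    list(basins = basins, kT = kT(temperature),
         halo_fraction = halo_fraction, halo_scale = halo_scale),
    class = "landscape_model")
  model$basins$mix <- model$basins$weight
  if (calibrate) model <- calibrate_landscape(model)
  stopifnot(all(model$basins$sigma_l > 0), all(model$basins$sigma_r > 0),
            all(model$basins$weight > 0),
            abs(sum(model$basins$weight) - 1) < 1e-8)
  .landscape_cache[[key]] <- model
  model
}

.landscape_cache <- new.env(parent = emptyenv())

#' @export
print.landscape_model <- function(x, ...) {
  cat("Synthetic activation landscape:", nrow(x$basins), "basins, kT =",
      signif(x$kT, 4), "kcal/mol\n")
  print(x$basins)
  invisible(x)
}

## Mixture density and gradient of log-density at points X (n x 2).
## Each basin contributes mix * [(1-hf) N(mu, sigma) + hf N(mu, hs*sigma)].
landscape_density <- function(model, X, gradient = FALSE) {
  X <- matrix(as.numeric(X), ncol = 2)
  b <- model$basins
  hf <- model$halo_fraction; hs <- model$halo_scale
  n <- nrow(X)
  p <- numeric(n)
  gx <- numeric(n); gy <- numeric(n)
  for (i in seq_len(nrow(b))) {
    for (halo in c(FALSE, TRUE)) {
      sl <- b$sigma_l[i] * if (halo) hs else 1
      sr <- b$sigma_r[i] * if (halo) hs else 1
      w <- b$mix[i] * if (halo) hf else (1 - hf)
      dx <- (X[, 1] - b$lock[i]) / sl
      dy <- (X[, 2] - b$rmsd[i]) / sr
      comp <- w * exp(-0.5 * (dx^2 + dy^2)) / (2 * pi * sl * sr)
      p <- p + comp
      if (gradient) {
        gx <- gx - comp * dx / sl
        gy <- gy - comp * dy / sr
      }
    }
  }
  if (gradient) {
    list(p = p, gx = gx / pmax(p, .Machine$double.xmin),
         gy = gy / pmax(p, .Machine$double.xmin))
  } else p
}

#' Potential energy of the landscape
#'
#' \eqn{U(x, y) = -kT \ln p(x, y)} in kcal/mol, where p is the calibrated
#' mixture density.
#'
#' @param model A `landscape_model`.
#' @param lock,rmsd Descriptor coordinates (vectors of equal length).
#' @return Numeric vector of energies.
#' @export
landscape_potential <- function(model, lock, rmsd) {
  -model$kT * log(landscape_density(model, cbind(lock, rmsd)))
}

scaled_dist2 <- function(model, lock, rmsd) {
  b <- model$basins
  d <- sapply(seq_len(nrow(b)), function(i) {
    ((lock - b$lock[i]) / b$sigma_l[i])^2 +
      ((rmsd - b$rmsd[i]) / b$sigma_r[i])^2
  })
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  d
}

#' Assign descriptor points to basins
#'
#' Partition of the descriptor plane used for population bookkeeping:
#' each point belongs to the basin whose centre is nearest in per-axis
#' width-scaled distance. For the well-separated reference basins this
#' cell partition tracks the density separatrices while remaining cheap
#' enough to evaluate on millions of frames.
#'
#' @param model A `landscape_model`.
#' @param lock,rmsd Descriptor coordinates.
#' @return Integer basin index (1 = M0 ... 6 = M5).
#' @export
assign_basin <- function(model, lock, rmsd) {
  max.col(-scaled_dist2(model, lock, rmsd), ties.method = "first")
}

## Quadrature grid over the physically allowed quadrant.
landscape_grid <- function(spacing = 0.05, xlim = c(0, 16.5),
                           ylim = c(0, 7.5)) {
  gx <- seq(xlim[1] + spacing / 2, xlim[2], by = spacing)
  gy <- seq(ylim[1] + spacing / 2, ylim[2], by = spacing)
  list(x = gx, y = gy, spacing = spacing,
       X = cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx))))
}

#' Analytic basin populations by quadrature
#'
#' Integrates the mixture density over each basin cell on a regular grid
#' restricted to the physical quadrant (both descriptors >= 0). This is
#' the analytic oracle against which sampled occupancies and pipeline
#' estimates are compared.
#'
#' @param model A `landscape_model`.
#' @param spacing Grid spacing in Angstrom.
#' @return Tibble with `state`, `population` (normalised to 1),
#'   `target`.
#' @export
basin_populations <- function(model, spacing = 0.05) {
  g <- landscape_grid(spacing)
  p <- landscape_density(model, g$X)
  cell <- assign_basin(model, g$X[, 1], g$X[, 2])
  mass <- vapply(seq_len(nrow(model$basins)),
                 function(i) sum(p[cell == i]), 0)
  mass <- mass / sum(mass)
  tibble::tibble(state = model$basins$state, population = mass,
                 target = model$basins$weight)
}

## Per-basin component mass (core + halo, unit coefficient) integrated
## over each basin cell: a 6 x 6 matrix A with A[cell, component].
component_mass_matrix <- function(model, g, cell) {
  b <- model$basins
  hf <- model$halo_fraction; hs <- model$halo_scale
  n <- nrow(b)
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    comp <- numeric(nrow(g$X))
    for (halo in c(FALSE, TRUE)) {
      sl <- b$sigma_l[j] * if (halo) hs else 1
      sr <- b$sigma_r[j] * if (halo) hs else 1
      w <- if (halo) hf else (1 - hf)
      dx <- (g$X[, 1] - b$lock[j]) / sl
      dy <- (g$X[, 2] - b$rmsd[j]) / sr
      comp <- comp + w * exp(-0.5 * (dx^2 + dy^2)) / (2 * pi * sl * sr)
    }
    A[, j] <- vapply(seq_len(n), function(i) sum(comp[cell == i]), 0) *
      g$spacing^2
  }
  A
}

#' Calibrate landscape mixture coefficients
#'
#' Adjusts the mixture coefficients so that every basin cell (see
#' [assign_basin()]) carries a probability mass equal to its target
#' weight. The cell partition does not depend on the coefficients and
#' cell masses are linear in them, so the calibration is a single exact
#' 6 x 6 linear solve against grid quadrature.
#'
#' @param model A `landscape_model` (uncalibrated coefficients default
#'   to the target weights).
#' @param spacing Quadrature spacing in Angstrom.
#' @param tol Tolerance on max |cell mass - target| after solving.
#' @return The model with calibrated `mix` coefficients.
#' @export
calibrate_landscape <- function(model, spacing = 0.05, tol = 5e-5) {
  if (!"mix" %in% names(model$basins))
    model$basins$mix <- model$basins$weight
  g <- landscape_grid(spacing)
  target <- model$basins$weight
  cell <- assign_basin(model, g$X[, 1], g$X[, 2])
  A <- component_mass_matrix(model, g, cell)
  m <- solve(A, target)
  if (any(m <= 0))
    stop("landscape calibration produced non-positive coefficients",
         call. = FALSE)
  model$basins$mix <- m / sum(m)
  mass <- as.numeric(A %*% model$basins$mix)
  resid <- max(abs(mass / sum(mass) - target))
  if (resid >= tol)
    warning("landscape calibration stopped at residual ",
            signif(resid, 3))
  model
}

## Draw n points from the calibrated mixture (exact equilibrium draw,
## rejecting the negligible mass outside the physical quadrant).
sample_equilibrium <- function(model, n) {
  b <- model$basins
  hf <- model$halo_fraction; hs <- model$halo_scale
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- n - nrow(out)
    comp <- sample.int(nrow(b), m, replace = TRUE, prob = b$mix)
    halo <- runif(m) < hf
    sl <- b$sigma_l[comp] * ifelse(halo, hs, 1)
    sr <- b$sigma_r[comp] * ifelse(halo, hs, 1)
    x <- rnorm(m, b$lock[comp], sl)
    y <- rnorm(m, b$rmsd[comp], sr)
    ok <- x >= 0 & y >= 0
    out <- rbind(out, cbind(x[ok], y[ok]))
  }
  out[seq_len(n), , drop = FALSE]
}

#' Sample Langevin trajectories on the landscape
#'
#' Overdamped Langevin dynamics with a Metropolis acceptance step
#' (Metropolis-adjusted Langevin), so the stationary density is exactly
#' the Boltzmann density of the landscape potential regardless of the
#' time step. Trajectories start from independent exact equilibrium
#' draws, making every frame an (auto-correlated) equilibrium sample.
#' Proposals leaving the physical quadrant (negative descriptor values)
#' are rejected. Identical (model, sizes, dt, seed) give bit-identical
#' output.
#'
#' @param model A `landscape_model`.
#' @param n_traj Number of trajectories.
#' @param n_steps Frames per trajectory (>= 1).
#' @param dt Time step in reduced units; the per-step RMS displacement
#'   `sqrt(2 dt)` should stay below the narrowest basin width (the
#'   Metropolis step keeps the sampled density exact either way).
#' @param seed RNG seed (mandatory).
#' @param start Optional n_traj x 2 matrix of start points; default is an
#'   equilibrium draw.
#' @return Tibble with columns `traj`, `frame`, `time`, `lock_distance`,
#'   `y753_rmsd`.
#' @export
sample_langevin <- function(model, n_traj, n_steps, dt = 0.025, seed,
                            start = NULL) {
  stopifnot(n_traj >= 1, n_steps >= 1)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  set.seed(as.integer(seed))
  X <- if (is.null(start)) sample_equilibrium(model, n_traj) else {
    start <- matrix(as.numeric(start), ncol = 2)
    start[rep(seq_len(nrow(start)), length.out = n_traj), , drop = FALSE]
  }
  lock <- matrix(NA_real_, n_traj, n_steps)
  rmsd <- matrix(NA_real_, n_traj, n_steps)
  lock[, 1] <- X[, 1]; rmsd[, 1] <- X[, 2]
  if (n_steps > 1) {
    d <- landscape_density(model, X, gradient = TRUE)
    lp <- log(d$p); G <- cbind(d$gx, d$gy)
    sig <- sqrt(2 * dt)
    for (t in 2:n_steps) {
      noise <- matrix(rnorm(2 * n_traj, sd = sig), n_traj, 2)
      Y <- X + dt * G + noise
      dY <- landscape_density(model, Y, gradient = TRUE)
      lpY <- log(pmax(dY$p, .Machine$double.xmin))
      GY <- cbind(dY$gx, dY$gy)
      ## log proposal densities q(x -> y), q(y -> x)
      fwd <- -rowSums((Y - X - dt * G)^2) / (4 * dt)
      bwd <- -rowSums((X - Y - dt * GY)^2) / (4 * dt)
      log_alpha <- lpY - lp + bwd - fwd
      acc <- log(runif(n_traj)) < log_alpha &
        Y[, 1] >= 0 & Y[, 2] >= 0
      X[acc, ] <- Y[acc, , drop = FALSE]
      lp[acc] <- lpY[acc]
      G[acc, ] <- GY[acc, , drop = FALSE]
      lock[, t] <- X[, 1]; rmsd[, t] <- X[, 2]
    }
  }
  tibble::tibble(
    traj = rep(seq_len(n_traj), each = n_steps),
    frame = rep(seq_len(n_steps), times = n_traj),
    time = rep(seq_len(n_steps) - 1, times = n_traj) * dt,
    lock_distance = as.numeric(t(lock)),
    y753_rmsd = as.numeric(t(rmsd)))
}

#' @export
tidy.landscape_model <- function(x, ...) x$basins

#' @export
glance.landscape_model <- function(x, ...) {
  bp <- basin_populations(x, spacing = 0.1)
  tibble::tibble(n_basins = nrow(x$basins), kT = x$kT,
                 calibration_residual = max(abs(bp$population - bp$target)))
}
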