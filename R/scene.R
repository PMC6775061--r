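## Synthetic lipid scenes: cholesterol-like particles diffusing in a
## membrane-slab box with localised attractive sites.

#' Specify a cholesterol scene
#'
#' Particles random-walk in a box with periodic boundaries in x and y
#' (membrane-plane semantics) and reflective walls in z. Attractive
#' sites are isotropic Gaussian wells \eqn{U(r) = d \exp(-|r - r_s|^2 /
#' (2 \rho^2))} with depth d <= 0 (kcal/mol) and radius \eqn{\rho} (A).
#'
#' @param box Box edges (Lx, Ly, Lz) in Angstrom.
#' @param n_particles Number of particles.
#' @param n_frames Number of recorded frames.
#' @param sites Tibble with columns `x`, `y`, `z`, `depth`, `radius`
#'   (possibly empty).
#' @param temperature Temperature in kelvin.
#' @param step RMS proposal step per axis in Angstrom.
#' @return A `cholesterol_scene` specification list.
#' @export
cholesterol_scene <- function(box, n_particles, n_frames, sites = NULL,
                              temperature = 300, step = 1.0) {
  sites <- sites %||% tibble::tibble(x = numeric(0), y = numeric(0),
                                     z = numeric(0), depth = numeric(0),
                                     radius = numeric(0))
  stopifnot(length(box) == 3, all(box > 0), n_particles >= 1,
            n_frames >= 1, step > 0)
  if (nrow(sites) > 0) {
    stopifnot(all(sites$depth <= 0), all(sites$radius > 0),
              all(sites$x >= 0 & sites$x <= box[1]),
              all(sites$y >= 0 & sites$y <= box[2]),
              all(sites$z >= 0 & sites$z <= box[3]))
  }
  structure(list(box = box, n_particles = as.integer(n_particles),
                 n_frames = as.integer(n_frames), sites = sites,
                 kT = kT(temperature), temperature = temperature,
                 step = step),
            class = "cholesterol_scene")
}

## Potential energy of particle positions (n x 3) under the scene's
## sites, with minimum-image convention in x and y.
scene_potential <- function(scene, X) {
  U <- numeric(nrow(X))
  s <- scene$sites
  if (nrow(s) == 0) return(U)
  for (i in seq_len(nrow(s))) {
    dx <- X[, 1] - s$x[i]
    dx <- dx - round(dx / scene$box[1]) * scene$box[1]
    dy <- X[, 2] - s$y[i]
    dy <- dy - round(dy / scene$box[2]) * scene$box[2]
    dz <- X[, 3] - s$z[i]
    U <- U + s$depth[i] * exp(-(dx^2 + dy^2 + dz^2) / (2 * s$radius[i]^2))
  }
  U
}

#' Sample a cholesterol scene
#'
#' Metropolis random walk: symmetric Gaussian proposals accepted with
#' probability \eqn{\min(1, e^{-\Delta U / k_B T})}, so the stationary
#' density is exactly \eqn{\propto e^{-U/k_B T}} (uniform when there are
#' no sites). x/y are wrapped periodically; z proposals are reflected at
#' the walls. Initial positions are uniform; identical (scene, seed)
#' give bit-identical output.
#'
#' @param scene A `cholesterol_scene`.
#' @param seed RNG seed.
#' @param burn_in Equilibration sweeps discarded before recording.
#' @return Tibble with `frame`, `particle`, `x`, `y`, `z`.
#' @export
sample_cholesterol_scene <- function(scene, seed, burn_in = 200L) {
  stopifnot(inherits(scene, "cholesterol_scene"))
  set.seed(as.integer(seed))
  np <- scene$n_particles
  box <- scene$box
  X <- cbind(runif(np, 0, box[1]), runif(np, 0, box[2]),
             runif(np, 0, box[3]))
  U <- scene_potential(scene, X)
  out_x <- matrix(NA_real_, np, scene$n_frames)
  out_y <- matrix(NA_real_, np, scene$n_frames)
  out_z <- matrix(NA_real_, np, scene$n_frames)
  total <- burn_in + scene$n_frames
  for (t in seq_len(total)) {
    prop <- X + matrix(rnorm(3 * np, sd = scene$step), np, 3)
    prop[, 1] <- prop[, 1] - floor(prop[, 1] / box[1]) * box[1]
    prop[, 2] <- prop[, 2] - floor(prop[, 2] / box[2]) * box[2]
    ## reflect z into [0, Lz]
    z <- prop[, 3] %% (2 * box[3])
    prop[, 3] <- ifelse(z > box[3], 2 * box[3] - z, z)
    Up <- scene_potential(scene, prop)
    acc <- log(runif(np)) < (U - Up) / scene$kT
    X[acc, ] <- prop[acc, , drop = FALSE]
    U[acc] <- Up[acc]
    if (t > burn_in) {
      k <- t - burn_in
      out_x[, k] <- X[, 1]; out_y[, k] <- X[, 2]; out_z[, k] <- X[, 3]
    }
  }
  tibble::tibble(
    frame = rep(seq_len(scene$n_frames), each = np),
    particle = rep(seq_len(np), times = scene$n_frames),
    x = as.numeric(out_x), y = as.numeric(out_y), z = as.numeric(out_z))
}
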