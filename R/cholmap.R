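## Cholesterol occupancy analysis: 3D histograms of lipid geometric
## centres, Boltzmann inversion to free energies, hotspot detection with
## minima merging and an energy cutoff.

#' 3D occupancy grid of particle positions
#'
#' Histograms per-frame particle positions into cubic bins (default 1 A)
#' spanning the simulation box. Positions are wrapped into the primary
#' cell before binning. The per-bin occupancy probability is
#' N = counts / n_frames.
#'
#' @param positions Tibble with columns `frame`, `x`, `y`, `z` (one row
#'   per particle per frame), coordinates in Angstrom.
#' @param box Length-3 box edge vector (Lx, Ly, Lz) in Angstrom.
#' @param spacing Bin edge length in Angstrom.
#' @return A `density_grid`: list with `counts` (3D array), `n_frames`,
#'   `spacing`, `box`, `origin`.
#' @export
occupancy_grid <- function(positions, box, spacing = 1) {
  stopifnot(length(box) == 3, all(box > 0), spacing > 0)
  if (nrow(positions) == 0 || length(unique(positions$frame)) == 0)
    stop("no frames to histogram", call. = FALSE)
  n_frames <- length(unique(positions$frame))
  dims <- pmax(1L, as.integer(ceiling(box / spacing - 1e-9)))
  wrap <- function(v, L) v - floor(v / L) * L
  ix <- pmin(dims[1], 1L + as.integer(wrap(positions$x, box[1]) / spacing))
  iy <- pmin(dims[2], 1L + as.integer(wrap(positions$y, box[2]) / spacing))
  iz <- pmin(dims[3], 1L + as.integer(wrap(positions$z, box[3]) / spacing))
  lin <- (iz - 1L) * dims[1] * dims[2] + (iy - 1L) * dims[1] + ix
  counts <- array(tabulate(lin, nbins = prod(dims)), dim = dims)
  structure(list(counts = counts, n_frames = n_frames, spacing = spacing,
                 box = box, origin = c(0, 0, 0)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat("Occupancy grid:", paste(dim(x$counts), collapse = " x "),
      "bins of", x$spacing, "A,", x$n_frames, "frames,",
      sum(x$counts), "counts\n")
  invisible(x)
}

#' Standard occupancy per bin under uniform mixing
#'
#' \eqn{N_0 = V_B N_A [C] / \eta_B}: the expected number of molecules per
#' bin for a homogeneous solution of concentration C in a box of volume
#' V_B gridded into \eqn{\eta_B} bins.
#'
#' @param grid A `density_grid` (supplies V_B and eta_B), or NULL if both
#'   are given explicitly.
#' @param concentration Concentration in mol/L.
#' @param volume_l Box volume in liters (overrides the grid).
#' @param n_bins Number of bins (overrides the grid).
#' @return Expected occupancy per bin (dimensionless).
#' @export
standard_occupancy <- function(grid = NULL, concentration,
                               volume_l = NULL, n_bins = NULL) {
  avogadro <- 6.02214076e23
  if (!is.null(grid)) {
    volume_l <- volume_l %||% (prod(grid$box) * 1e-27)
    n_bins <- n_bins %||% length(grid$counts)
  }
  stopifnot(volume_l > 0, n_bins > 0, concentration > 0)
  volume_l * avogadro * concentration / n_bins
}

## Concentration (mol/L) of n particles in the grid's box.
box_concentration <- function(grid, n_particles) {
  n_particles / (6.02214076e23 * prod(grid$box) * 1e-27)
}

#' Boltzmann free-energy grid from occupancies
#'
#' \eqn{\Delta G = -k_B T \ln(N / N_0)} per bin, so enrichment over the
#' uniform expectation is favourable (negative). Bins never visited are
#' returned as NA ("unobserved") rather than infinite energies.
#'
#' @param grid A `density_grid`.
#' @param n0 Standard occupancy per bin (see [standard_occupancy()]).
#' @param temperature Temperature in kelvin.
#' @return A `free_energy_grid`: list with `dG` (3D array, kcal/mol,
#'   NA = unobserved), plus the grid geometry.
#' @export
free_energy_grid <- function(grid, n0, temperature = 300) {
  stopifnot(n0 > 0)
  N <- grid$counts / grid$n_frames
  dG <- array(NA_real_, dim = dim(N))
  obs <- grid$counts > 0
  dG[obs] <- -kT(temperature) * log(N[obs] / n0)
  structure(list(dG = dG, N = N, n0 = n0, spacing = grid$spacing,
                 box = grid$box, origin = grid$origin,
                 temperature = temperature),
            class = "free_energy_grid")
}

## Coordinates (bin centres) of a set of linear bin indices.
bin_centers <- function(dims, spacing, origin, idx) {
  a <- arrayInd(idx, dims)
  sweep((a - 0.5) * spacing, 2, origin, "+")
}

#' Find, merge and filter free-energy minima
#'
#' Local minima are observed bins below the cutoff whose \eqn{\Delta G}
#' is no greater than all 26 neighbours'. Minima closer than the merge
#' radius are combined by single linkage; each merged hotspot's
#' probability is the sum of its members' occupancies, its free energy is
#' recomputed from that summed probability with the same Boltzmann
#' transform and its position is the probability-weighted centroid.
#' Hotspots at or above the cutoff after merging are dropped.
#'
#' @param fe A `free_energy_grid`.
#' @param merge_radius Merge distance in Angstrom.
#' @param cutoff Retention threshold in kcal/mol (hotspots must be
#'   strictly below it).
#' @return A `hotspot_set` tibble: `x`, `y`, `z`, `dG`, `prob`,
#'   `n_bins`, with attributes `merge_radius` and `cutoff`.
#' @export
find_hotspots <- function(fe, merge_radius = 8, cutoff = -0.22) {
  dims <- dim(fe$dG)
  dG <- fe$dG
  cand <- which(!is.na(dG) & dG < cutoff)
  minima <- integer(0)
  if (length(cand) > 0) {
    a <- arrayInd(cand, dims)
    keep <- vapply(seq_along(cand), function(i) {
      v <- dG[cand[i]]
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        p <- a[i, ] + c(dx, dy, dz)
        if (any(p < 1) || any(p > dims)) next
        w <- dG[p[1], p[2], p[3]]
        if (!is.na(w) && w < v) return(FALSE)
      }
      TRUE
    }, TRUE)
    minima <- cand[keep]
  }
  if (length(minima) == 0) {
    out <- tibble::tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                          dG = numeric(0), prob = numeric(0),
                          n_bins = integer(0))
    return(structure(out, merge_radius = merge_radius, cutoff = cutoff,
                     class = c("hotspot_set", class(out))))
  }
  pos <- bin_centers(dims, fe$spacing, fe$origin, minima)
  grp <- if (length(minima) == 1) 1L else
    cutree(hclust(dist(pos), method = "single"),
           h = merge_radius * (1 - 1e-9))
  probs <- fe$N[minima]
  rows <- lapply(sort(unique(grp)), function(g) {
    m <- grp == g
    p_tot <- sum(probs[m])
    ctr <- colSums(pos[m, , drop = FALSE] * probs[m]) / p_tot
    tibble::tibble(x = ctr[1], y = ctr[2], z = ctr[3],
                   dG = -kT(fe$temperature) * log(p_tot / fe$n0),
                   prob = p_tot, n_bins = sum(m))
  })
  out <- dplyr::bind_rows(rows)
  out <- out[out$dG < cutoff, ]
  out <- out[order(out$dG), ]
  structure(out, merge_radius = merge_radius, cutoff = cutoff,
            class = c("hotspot_set", class(out)))
}

#' Per-macrostate cholesterol hotspot maps
#'
#' Splits the frames by macrostate membership, runs the full occupancy ->
#' free energy -> merge pipeline on each macrostate's frames, and flags
#' hotspots as shared when a hotspot of another macrostate lies within
#' the merge radius.
#'
#' @param positions Tibble with `frame`, `x`, `y`, `z`.
#' @param assignments Tibble with `frame`, `macrostate`, covering all
#'   frames in `positions`.
#' @param box Box edges (Lx, Ly, Lz) in Angstrom.
#' @param concentration Bulk concentration in mol/L; defaults to the
#'   mean particle count per frame over the box volume.
#' @param spacing,merge_radius,cutoff,temperature Passed through.
#' @return Tibble of hotspots with `macrostate` and `shared` columns.
#' @export
macrostate_hotspots <- function(positions, assignments, box,
                                concentration = NULL, spacing = 1,
                                merge_radius = 8, cutoff = -0.22,
                                temperature = 300) {
  pos <- dplyr::inner_join(positions, assignments, by = "frame")
  if (nrow(pos) < nrow(positions))
    stop("macrostate assignments do not cover all frames", call. = FALSE)
  states <- unique(assignments$macrostate)
  hs <- list()
  for (s in states) {
    sub <- pos[pos$macrostate == s, ]
    if (length(unique(sub$frame)) == 0) {
      warning("macrostate ", s, " has no frames; skipped")
      next
    }
    g <- occupancy_grid(sub, box, spacing)
    conc <- concentration %||%
      box_concentration(g, sum(g$counts) / g$n_frames)
    n0 <- standard_occupancy(g, conc)
    fe <- free_energy_grid(g, n0, temperature)
    h <- find_hotspots(fe, merge_radius, cutoff)
    if (nrow(h) > 0) h$macrostate <- s
    hs[[as.character(s)]] <- h
  }
  out <- dplyr::bind_rows(hs)
  if (nrow(out) == 0)
    return(tibble::as_tibble(out))
  out$shared <- vapply(seq_len(nrow(out)), function(i) {
    other <- out[out$macrostate != out$macrostate[i], ]
    if (nrow(other) == 0) return(FALSE)
    any(sqrt((other$x - out$x[i])^2 + (other$y - out$y[i])^2 +
               (other$z - out$z[i])^2) < merge_radius)
  }, TRUE)
  tibble::as_tibble(out)
}
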