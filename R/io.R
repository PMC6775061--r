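## Artifact export: OpenDX volumetric grids, matrix-market matrices,
## hotspot pseudo-atom PDBs, provenance-stamped tables.

#' Export a 3D grid in OpenDX format
#'
#' Writes a regular-grid scalar field (counts or free energies) as an
#' OpenDX text file readable by molecular viewers. Unobserved bins (NA)
#' are written as the given fill value.
#'
#' @param grid A `density_grid` or `free_energy_grid`.
#' @param file Output path.
#' @param field `"counts"`, `"N"` or `"dG"` (depending on grid type).
#' @param na_fill Value written for unobserved bins.
#' @export
write_dx <- function(grid, file, field = NULL, na_fill = 0) {
  field <- field %||% if (inherits(grid, "free_energy_grid")) "dG" else
    "counts"
  arr <- grid[[field]]
  stopifnot(is.array(arr), length(dim(arr)) == 3)
  dims <- dim(arr)
  sp <- grid$spacing
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d",
            dims[1], dims[2], dims[3]),
    sprintf("origin %.6f %.6f %.6f",
            grid$origin[1] + sp / 2, grid$origin[2] + sp / 2,
            grid$origin[3] + sp / 2),
    sprintf("delta %.6f 0 0", sp),
    sprintf("delta 0 %.6f 0", sp),
    sprintf("delta 0 0 %.6f", sp),
    sprintf("object 2 class gridconnections counts %d %d %d",
            dims[1], dims[2], dims[3]),
    sprintf(paste("object 3 class array type double rank 0 items %d",
                  "data follows"), prod(dims))), con)
  ## OpenDX expects z fastest
  v <- as.numeric(aperm(arr, c(3, 2, 1)))
  v[is.na(v)] <- na_fill
  n <- length(v)
  pad <- (3 - n %% 3) %% 3
  m <- matrix(c(v, rep(NA_real_, pad)), ncol = 3, byrow = TRUE)
  lines <- apply(m, 1, function(r)
    paste(sprintf("%.6g", r[!is.na(r)]), collapse = " "))
  writeLines(lines, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "density" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(file)
}

#' Export a hotspot set as a PDB of pseudo-atoms
#'
#' One pseudo-atom per hotspot, with the free energy in the B-factor
#' column.
#'
#' @param hotspots A `hotspot_set` tibble.
#' @param file Output path.
#' @export
write_hotspot_pdb <- function(hotspots, file) {
  n <- nrow(hotspots)
  if (n == 0) {
    writeLines("END", file)
    return(invisible(file))
  }
  bio3d::write.pdb(
    file = file,
    xyz = as.numeric(t(as.matrix(hotspots[, c("x", "y", "z")]))),
    resno = seq_len(n), resid = rep("HSP", n), elety = rep("C", n),
    b = round(hotspots$dG, 2))
  invisible(file)
}

#' Write a count or transition matrix in matrix-market format
#'
#' @param m Matrix.
#' @param file Output path (conventionally `.mtx`).
#' @export
write_mtx <- function(m, file) {
  Matrix::writeMM(methods::as(Matrix::Matrix(as.matrix(m), sparse = TRUE),
                              "generalMatrix"), file)
  invisible(file)
}

#' Export a flux network as a DOT graph
#'
#' One node per state (labelled with its stationary weight) and one
#' edge per net-flux link above the threshold, for rendering with
#' Graphviz.
#'
#' @param flux A `flux_network`.
#' @param file Output path.
#' @param threshold Drop edges below this fraction of the total flux.
#' @export
write_dot <- function(flux, file, threshold = 0.005) {
  stopifnot(inherits(flux, "flux_network"))
  Fm <- flux$F
  idx <- which(Fm > threshold * flux$total_flux, arr.ind = TRUE)
  lines <- c("digraph flux {", "  rankdir=LR;")
  for (i in seq_along(flux$labels))
    lines <- c(lines, sprintf('  "%s" [label="%s\\npi=%.3f"];',
                              flux$labels[i], flux$labels[i],
                              flux$pi[i]))
  if (nrow(idx) > 0)
    lines <- c(lines, sprintf('  "%s" -> "%s" [label="%.3g"];',
                              flux$labels[idx[, 1]],
                              flux$labels[idx[, 2]], Fm[idx]))
  writeLines(c(lines, "}"), file)
  invisible(file)
}

#' Write a numeric table with a provenance header
#'
#' Tables carry `#`-prefixed provenance lines (stage, seed, config hash)
#' and 6-significant-digit numbers, so reruns with identical configs are
#' byte-identical.
#'
#' @param x Data frame.
#' @param file Output path.
#' @param provenance Named character vector written as `# name: value`.
#' @export
write_artifact <- function(x, file, provenance = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  for (nm in names(provenance))
    writeLines(sprintf("# %s: %s", nm, provenance[[nm]]), con)
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, TRUE)
  x[num] <- lapply(x[num], signif, digits = 6)
  utils::write.table(x, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
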