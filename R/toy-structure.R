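## Minimal pseudo-receptor structures with exactly known descriptor
## values, used for round-trip testing of the featurization.

toy_core <- function() {
  ## rigid, non-degenerate CA frame (residues 1-6)
  tibble::tibble(
    elety = "CA", resid = "GLY", resno = 1:6,
    x = c(0, 10, 0, 0, 10, 5),
    y = c(0, 0, 10, 0, 10, 2),
    z = c(0, 0, 0, 10, 3, 8))
}

toy_residue <- function(resid, resno, center, spread = 0.6) {
  ## three heavy atoms placed symmetrically about the requested centre so
  ## the (equal-mass) centre of mass equals `center` exactly
  offs <- rbind(c(spread, 0, 0), c(-spread / 2, spread, 0),
                c(-spread / 2, -spread, 0))
  tibble::tibble(
    elety = c("CB", "CG", "CD"), resid = resid, resno = resno,
    x = center[1] + offs[, 1], y = center[2] + offs[, 2],
    z = center[3] + offs[, 3])
}

#' Build a toy structure with prescribed descriptor values
#'
#' Emits a minimal pseudo-residue structure (R102, E228, Y288 plus a
#' rigid six-point CA reference frame) together with an inactive
#' reference, constructed so that [lock_distance()] returns
#' `lock` and [y753_rmsd()] returns `rmsd` exactly (up to floating
#' point): the two lock residues are placed `lock` Angstrom apart and
#' every Y288 atom is displaced from its reference position by a vector
#' of length `rmsd`.
#'
#' @param lock Target ionic-lock distance in Angstrom (> 0).
#' @param rmsd Target Y7.53 RMSD in Angstrom (>= 0).
#' @return List with atom tables `frame` and `reference`.
#' @export
toy_structure <- function(lock = 6, rmsd = 2) {
  stopifnot(lock > 0, rmsd >= 0)
  core <- toy_core()
  y_ref <- c(6, 6, 6)
  reference <- dplyr::bind_rows(
    core,
    toy_residue("ARG", 102L, c(0, -5, 0)),
    toy_residue("GLU", 228L, c(2, -5, 0)),   # reference lock = 2 A
    toy_residue("TYR", 288L, y_ref))
  frame <- dplyr::bind_rows(
    core,
    toy_residue("ARG", 102L, c(0, -5, 0)),
    toy_residue("GLU", 228L, c(lock, -5, 0)),
    toy_residue("TYR", 288L, y_ref + c(0, 0, rmsd)))
  list(frame = frame, reference = reference)
}

#' Write an atom table as a PDB file
#'
#' @param atoms Atom table.
#' @param file Output path.
#' @export
write_structure_pdb <- function(atoms, file) {
  bio3d::write.pdb(
    file = file,
    xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
    resno = atoms$resno, resid = atoms$resid, elety = atoms$elety)
  invisible(file)
}
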