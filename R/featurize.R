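## Activation descriptors computed from structures.
##
## Structures are handled as atom tables: one row per atom with columns
## elety (atom name), resid (residue name), resno (residue number) and
## x/y/z in Angstrom. PDB and DCD input is parsed with bio3d and
## converted; all descriptor math happens on the tables.

#' Convert a bio3d pdb object to an atom table
#'
#' @param pdb A `pdb` object from [bio3d::read.pdb()].
#' @return Tibble with columns `elety`, `resid`, `resno`, `x`, `y`, `z`.
#' @export
pdb_to_table <- function(pdb) {
  a <- pdb$atom
  tibble::tibble(elety = a$elety, resid = a$resid,
                 resno = as.integer(a$resno),
                 x = a$x, y = a$y, z = a$z)
}

#' Read a structure file into an atom table
#'
#' @param file Path to a PDB file.
#' @param multi Read all MODEL records; if TRUE a list is returned with
#'   the atom table of the first model plus an `xyz` coordinate matrix
#'   (one row per frame, bio3d layout).
#' @return An atom table, or a list(atoms, xyz) when `multi = TRUE`.
#' @export
read_structure <- function(file, multi = FALSE) {
  pdb <- bio3d::read.pdb(file, multi = multi)
  atoms <- pdb_to_table(pdb)
  if (multi) list(atoms = atoms, xyz = unclass(pdb$xyz)) else atoms
}

## Replace the coordinates of an atom table with one row of a bio3d xyz
## matrix (x1 y1 z1 x2 ...).
set_frame_coords <- function(atoms, xyz_row) {
  m <- matrix(xyz_row, ncol = 3, byrow = TRUE)
  stopifnot(nrow(m) == nrow(atoms))
  atoms$x <- m[, 1]; atoms$y <- m[, 2]; atoms$z <- m[, 3]
  atoms
}

is_heavy <- function(elety) !grepl("^[0-9]*H", toupper(elety))

atom_masses <- function(elety) {
  ele <- tryCatch(suppressWarnings(bio3d::atom2ele(elety)),
                  error = function(e) rep("C", length(elety)))
  tryCatch(suppressWarnings(bio3d::atom2mass(ele)),
           error = function(e) rep(12.011, length(elety)))
}

## Centre of mass of one residue.
residue_com <- function(atoms, resno, scope = c("heavy", "calpha")) {
  scope <- match.arg(scope)
  sel <- atoms$resno == resno
  if (scope == "calpha") sel <- sel & atoms$elety == "CA"
  else sel <- sel & is_heavy(atoms$elety)
  if (!any(sel))
    stop("residue ", resno, " does not resolve to any ",
         if (scope == "calpha") "CA " else "heavy ", "atom", call. = FALSE)
  sub <- atoms[sel, ]
  m <- atom_masses(sub$elety)
  c(sum(sub$x * m), sum(sub$y * m), sum(sub$z * m)) / sum(m)
}

#' Ionic-lock distance
#'
#' Distance between the centres of mass of the two ionic-lock residues,
#' R3.50 (default residue 102) and E6.30 (default residue 228). The
#' centre of mass is over side-chain-inclusive heavy atoms by default; a
#' CA-only mode is available for sensitivity checks.
#'
#' @param atoms Atom table (see [pdb_to_table()]).
#' @param residues Length-2 integer vector of residue numbers.
#' @param scope `"heavy"` (heavy-atom COM) or `"calpha"`.
#' @return Distance in Angstrom.
#' @export
lock_distance <- function(atoms, residues = c(102L, 228L),
                          scope = c("heavy", "calpha")) {
  scope <- match.arg(scope)
  stopifnot(length(residues) == 2)
  a <- residue_com(atoms, residues[1], scope)
  b <- residue_com(atoms, residues[2], scope)
  sqrt(sum((a - b)^2))
}

## Kabsch: rotation + translation mapping P (n x 3) onto Q, least squares.
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  s <- svd(crossprod(P0, Q0))
  d <- sign(det(s$u %*% t(s$v)))
  W <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(rotation = W, center_from = cp, center_to = cq)
}

apply_fit <- function(X, fit) {
  sweep(sweep(X, 2, fit$center_from) %*% fit$rotation, 2,
        fit$center_to, "+")
}

#' RMSD of Y7.53 from its inactive position
#'
#' Superposes the frame onto the inactive reference using the CA atoms of
#' a rigid core (by default every CA except the target residue's), then
#' returns the heavy-atom RMSD of residue Y7.53 (default 288). Global
#' rotations and translations of the frame therefore do not contribute.
#'
#' @param atoms Frame atom table.
#' @param reference Reference atom table with identical atom order for
#'   the target residue and the core.
#' @param residue Target residue number.
#' @param core_resnos Residue numbers forming the superposition core;
#'   default all residues with a CA atom except `residue`.
#' @return RMSD in Angstrom.
#' @export
y753_rmsd <- function(atoms, reference, residue = 288L,
                      core_resnos = NULL) {
  core_resnos <- core_resnos %||%
    setdiff(unique(reference$resno[reference$elety == "CA"]), residue)
  core_f <- atoms[atoms$elety == "CA" & atoms$resno %in% core_resnos, ]
  core_r <- reference[reference$elety == "CA" &
                        reference$resno %in% core_resnos, ]
  if (nrow(core_f) != nrow(core_r) || nrow(core_f) < 3)
    stop("superposition core must have >= 3 matching CA atoms",
         call. = FALSE)
  fit <- kabsch(as.matrix(core_f[, c("x", "y", "z")]),
                as.matrix(core_r[, c("x", "y", "z")]))
  tf <- atoms$resno == residue & is_heavy(atoms$elety)
  tr <- reference$resno == residue & is_heavy(reference$elety)
  if (sum(tf) != sum(tr) || sum(tf) == 0)
    stop("target residue atom count mismatch between frame and reference",
         call. = FALSE)
  P <- apply_fit(as.matrix(atoms[tf, c("x", "y", "z")]), fit)
  Q <- as.matrix(reference[tr, c("x", "y", "z")])
  sqrt(mean(rowSums((P - Q)^2)))
}

#' Binary CA contact map
#'
#' Symmetric zero-diagonal matrix with entry (i, j) = 1 iff the CA atoms
#' of residues i and j are closer than the threshold (default 5 A, the
#' generic adaptive-sampling metric).
#'
#' @param atoms Atom table (needs >= 2 CA atoms).
#' @param threshold Contact threshold in Angstrom.
#' @return Binary matrix with residue numbers as dimnames.
#' @export
contact_map <- function(atoms, threshold = 5) {
  ca <- atoms[atoms$elety == "CA", ]
  if (nrow(ca) < 2) stop("need at least two CA atoms", call. = FALSE)
  D <- as.matrix(dist(as.matrix(ca[, c("x", "y", "z")])))
  M <- (D < threshold) * 1L
  diag(M) <- 0L
  dimnames(M) <- list(ca$resno, ca$resno)
  M
}

#' Intracellular G-protein-site openness
#'
#' Sum of the ten distances between the cytosolic ends of TM5 and TM6 and
#' those of TM1, TM2, TM3, TM4 and TM7 (residue centres of mass), a
#' single per-frame measure of how open the intracellular G-protein
#' binding site is. The default residue set is M211 (TM5), T224 (TM6),
#' V31 (TM1), V40 (TM2), R107 (TM3), G118 (TM4) and R291 (TM7).
#'
#' @param atoms Atom table.
#' @param tm56 Residue numbers of the TM5 and TM6 probes.
#' @param others Residue numbers of the TM1/2/3/4/7 probes.
#' @param scope COM scope, `"heavy"` or `"calpha"`.
#' @return Summed distance in Angstrom (attribute `"pairs"` carries the
#'   ten individual distances).
#' @export
site_openness <- function(atoms, tm56 = c(211L, 224L),
                          others = c(31L, 40L, 107L, 118L, 291L),
                          scope = c("heavy", "calpha")) {
  scope <- match.arg(scope)
  coms <- lapply(c(tm56, others), function(r) residue_com(atoms, r, scope))
  names(coms) <- as.character(c(tm56, others))
  pairs <- expand.grid(a = as.character(tm56), b = as.character(others),
                       stringsAsFactors = FALSE)
  d <- vapply(seq_len(nrow(pairs)), function(i) {
    sqrt(sum((coms[[pairs$a[i]]] - coms[[pairs$b[i]]])^2))
  }, 0)
  structure(sum(d), pairs = setNames(d, paste(pairs$a, pairs$b, sep = "-")))
}

#' Per-macrostate summary of site openness
#'
#' @param openness Numeric vector of per-frame summed distances.
#' @param macrostate Macrostate label per frame.
#' @return Tibble with min/max/mean per macrostate.
#' @export
site_openness_summary <- function(openness, macrostate) {
  tibble::tibble(openness = openness, macrostate = macrostate) |>
    dplyr::group_by(.data$macrostate) |>
    dplyr::summarise(min = min(.data$openness), max = max(.data$openness),
                     mean = mean(.data$openness), n = dplyr::n(),
                     .groups = "drop")
}

#' Featurize a trajectory
#'
#' Applies [lock_distance()] and [y753_rmsd()] to every frame of a
#' coordinate matrix (bio3d layout, one row per frame), preserving frame
#' order.
#'
#' @param atoms Topology atom table matching the coordinate columns.
#' @param xyz Coordinate matrix (n_frames x 3 n_atoms); a DCD file read
#'   with [bio3d::read.dcd()] or a multi-model PDB via
#'   [read_structure()].
#' @param reference Inactive reference atom table for the RMSD.
#' @param dt Time per frame (ns) for the `time` column.
#' @param lock_residues,rmsd_residue,core_resnos Selector overrides.
#' @return Tibble with `frame`, `time`, `lock_distance`, `y753_rmsd`.
#' @export
featurize_trajectory <- function(atoms, xyz, reference = NULL, dt = 1,
                                 lock_residues = c(102L, 228L),
                                 rmsd_residue = 288L, core_resnos = NULL) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * nrow(atoms))
    stop("coordinate matrix does not match the topology (",
         ncol(xyz), " != 3 x ", nrow(atoms), ")", call. = FALSE)
  reference <- reference %||% set_frame_coords(atoms, xyz[1, ])
  n <- nrow(xyz)
  out <- tibble::tibble(frame = seq_len(n), time = (seq_len(n) - 1) * dt,
                        lock_distance = NA_real_, y753_rmsd = NA_real_)
  for (i in seq_len(n)) {
    fr <- set_frame_coords(atoms, xyz[i, ])
    out$lock_distance[i] <- lock_distance(fr, lock_residues)
    out$y753_rmsd[i] <- y753_rmsd(fr, reference, rmsd_residue,
                                  core_resnos)
  }
  out
}

#' Write a feature table as delimited text
#'
#' @param features Tibble from [featurize_trajectory()] or
#'   [sample_langevin()].
#' @param file Output path.
#' @param header Optional provenance comment lines (written with a
#'   leading `#`).
#' @export
write_features <- function(features, file, header = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  utils::write.table(features, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' Read a feature table written by [write_features()]
#'
#' @param file Path to the delimited file.
#' @return Tibble.
#' @export
read_features <- function(file) {
  tibble::as_tibble(utils::read.table(file, header = TRUE, sep = "\t",
                                      comment.char = "#"))
}
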