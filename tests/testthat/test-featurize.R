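# Activation descriptors on structures.

test_that("ionic-lock distance equals the hand-computed COM distance", {
  toy <- toy_structure(lock = 6)
  expect_equal(lock_distance(toy$frame), 6, tolerance = 1e-9)

  # coincident centres give zero
  atoms <- dplyr::bind_rows(
    a2amsm:::toy_residue("ARG", 102L, c(1, 2, 3)),
    a2amsm:::toy_residue("GLU", 228L, c(1, 2, 3)))
  expect_equal(lock_distance(atoms), 0, tolerance = 1e-12)

  # hand-placed carbon atoms: COM is the plain mean of equal masses
  r1 <- tibble::tibble(elety = c("CB", "CG", "CD"), resid = "ARG",
                       resno = 102L, x = c(0, 1, 2), y = c(0, 0, 0),
                       z = c(0, 3, 0))
  r2 <- tibble::tibble(elety = c("CB", "CG", "CD"), resid = "GLU",
                       resno = 228L, x = c(4, 5, 6), y = c(2, 2, 2),
                       z = c(1, 1, 1))
  com1 <- c(mean(r1$x), mean(r1$y), mean(r1$z))
  com2 <- c(mean(r2$x), mean(r2$y), mean(r2$z))
  expect_equal(lock_distance(dplyr::bind_rows(r1, r2)),
               sqrt(sum((com1 - com2)^2)), tolerance = 1e-12)

  # unresolved selector is an error
  expect_error(lock_distance(r1, residues = c(102L, 999L)),
               "does not resolve")
})

test_that("Y7.53 RMSD is zero at the reference and after rigid moves", {
  toy <- toy_structure(lock = 4, rmsd = 0)
  expect_equal(y753_rmsd(toy$reference, toy$reference), 0,
               tolerance = 1e-12)
  # rigid-body motion of the whole frame is removed by superposition
  moved <- rotate_atoms(toy$reference)
  expect_equal(y753_rmsd(moved, toy$reference), 0, tolerance = 1e-8)
  # uniform displacement of the target residue after alignment
  toy2 <- toy_structure(lock = 4, rmsd = 2)
  expect_equal(y753_rmsd(toy2$frame, toy2$reference), 2,
               tolerance = 1e-9)
  # atom-count mismatch is an error
  broken <- toy2$frame[-nrow(toy2$frame), ]
  expect_error(y753_rmsd(broken, toy2$reference), "mismatch")
})

# seven-residue pseudo-structure for the G-protein-site metric
site_atoms <- function(coords) {
  resnos <- c(211L, 224L, 31L, 40L, 107L, 118L, 291L)
  dplyr::bind_rows(lapply(seq_along(resnos), function(i)
    a2amsm:::toy_residue("ALA", resnos[i], coords[i, ])))
}

site_openness_stub <- function(atoms) as.numeric(site_openness(atoms))

test_that("features are invariant under global rotation and translation", {
  toy <- toy_structure(lock = 7.5, rmsd = 1.3)
  moved <- rotate_atoms(toy$frame, angle = 1.1, axis = c(1, 2, 0.5),
                        shift = c(-4, 9, 1))
  expect_equal(lock_distance(moved), lock_distance(toy$frame),
               tolerance = 1e-9)
  expect_equal(y753_rmsd(moved, toy$reference),
               y753_rmsd(toy$frame, toy$reference), tolerance = 1e-8)
  set.seed(17)
  sa <- site_atoms(matrix(rnorm(21, sd = 6), 7))
  expect_equal(site_openness_stub(rotate_atoms(sa)),
               site_openness_stub(sa), tolerance = 1e-9)
})

test_that("site openness sums the ten TM5/TM6-to-other distances", {
  # all residues coincident -> 0
  coords <- matrix(rep(c(1, 1, 1), 7), 7, byrow = TRUE)
  expect_equal(as.numeric(site_openness(site_atoms(coords))), 0,
               tolerance = 1e-12)

  # random coordinates match a brute-force enumeration of the 10 pairs
  set.seed(21)
  for (rep in 1:5) {
    coords <- matrix(rnorm(21, sd = 8), 7)
    so <- site_openness(site_atoms(coords))
    brute <- 0
    for (i in 1:2) for (j in 3:7)
      brute <- brute + sqrt(sum((coords[i, ] - coords[j, ])^2))
    expect_equal(as.numeric(so), brute, tolerance = 1e-9)
    # the stored pair distances sum to the reported value
    expect_equal(sum(attr(so, "pairs")), as.numeric(so),
                 tolerance = 1e-12)
    expect_length(attr(so, "pairs"), 10)
  }

  # per-macrostate aggregation
  s <- site_openness_summary(c(1, 3, 2, 10), c("a", "a", "a", "b"))
  expect_equal(s$min[s$macrostate == "a"], 1)
  expect_equal(s$max[s$macrostate == "a"], 3)
  expect_equal(s$mean[s$macrostate == "b"], 10)
})

test_that("contact map applies the 5 A threshold symmetrically", {
  atoms <- tibble::tibble(
    elety = "CA", resid = "GLY", resno = 1:3,
    x = c(0, 4.9, 10), y = 0, z = 0)
  M <- contact_map(atoms)
  expect_equal(M["1", "2"], 1L)    # 4.9 A: contact
  expect_equal(M["2", "3"], 0L)    # 5.1 A: no contact
  expect_equal(M, t(M))
  expect_true(all(diag(M) == 0))

  # monotone in the threshold on random structures
  set.seed(5)
  atoms <- tibble::tibble(elety = "CA", resid = "GLY", resno = 1:20,
                          x = runif(20, 0, 15), y = runif(20, 0, 15),
                          z = runif(20, 0, 15))
  m1 <- contact_map(atoms, threshold = 4)
  m2 <- contact_map(atoms, threshold = 7)
  expect_true(all(m2[m1 == 1] == 1))
  expect_error(contact_map(atoms[1, ]), "at least two")
})

test_that("trajectory featurization round-trips the toy generator", {
  toys <- lapply(list(c(6, 1), c(2, 4.5), c(9.5, 0.2)),
                 function(p) toy_structure(p[1], p[2]))
  atoms <- toys[[1]]$frame
  xyz <- do.call(rbind, lapply(toys, function(t)
    as.numeric(t(as.matrix(t$frame[, c("x", "y", "z")])))))
  feats <- featurize_trajectory(atoms, xyz,
                                reference = toys[[1]]$reference)
  expect_equal(feats$lock_distance, c(6, 2, 9.5), tolerance = 1e-6)
  expect_equal(feats$y753_rmsd, c(1, 4.5, 0.2), tolerance = 1e-6)
  expect_equal(feats$frame, 1:3)

  # concatenation of two trajectories is the concatenation of features
  f1 <- featurize_trajectory(atoms, xyz[1:2, , drop = FALSE],
                             reference = toys[[1]]$reference)
  f2 <- featurize_trajectory(atoms, xyz[3, , drop = FALSE],
                             reference = toys[[1]]$reference)
  expect_equal(c(f1$lock_distance, f2$lock_distance),
               feats$lock_distance)
  # mismatched topology is an error
  expect_error(featurize_trajectory(atoms, xyz[, 1:10]),
               "does not match")
})

test_that("PDB round trip preserves features", {
  toy <- toy_structure(lock = 5.5, rmsd = 2.5)
  f <- tempfile(fileext = ".pdb")
  write_structure_pdb(toy$frame, f)
  back <- read_structure(f)
  expect_equal(lock_distance(back), 5.5, tolerance = 1e-3)
  fr <- tempfile(fileext = ".pdb")
  write_structure_pdb(toy$reference, fr)
  expect_equal(y753_rmsd(back, read_structure(fr)), 2.5,
               tolerance = 1e-3)
})

test_that("feature tables round-trip through delimited text", {
  feats <- tibble::tibble(frame = 1:3, time = c(0, 1, 2),
                          lock_distance = c(2.5, 3.5, 12),
                          y753_rmsd = c(0.1, 2.2, 4.4))
  f <- tempfile(fileext = ".tsv")
  write_features(feats, f, header = c("seed: 1"))
  expect_equal(as.data.frame(read_features(f)), as.data.frame(feats))
  expect_match(readLines(f, n = 1), "^# seed")
})
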