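# Cholesterol occupancy grids, Boltzmann inversion, hotspot merging.

test_that("occupancy grid counts are conserved and located correctly", {
  # one particle fixed in one bin over 10 frames
  pos <- tibble::tibble(frame = 1:10, x = 2.5, y = 3.5, z = 4.5)
  g <- occupancy_grid(pos, box = c(10, 10, 10))
  N <- g$counts / g$n_frames
  expect_equal(N[3, 4, 5], 1)
  expect_equal(sum(g$counts), 10)

  # conservation with many particles, including wrapped positions
  set.seed(2)
  pos <- tibble::tibble(frame = rep(1:50, each = 8),
                        x = runif(400, -10, 20), y = runif(400, 0, 10),
                        z = runif(400, 0, 10))
  g <- occupancy_grid(pos, box = c(10, 10, 10))
  expect_equal(sum(g$counts), 400)
  expect_error(occupancy_grid(pos[0, ], box = c(10, 10, 10)),
               "no frames")
})

test_that("uniform positions approach the uniform per-bin expectation", {
  set.seed(8)
  n_frames <- 400; n_part <- 50
  pos <- tibble::tibble(frame = rep(seq_len(n_frames), each = n_part),
                        x = runif(n_frames * n_part, 0, 8),
                        y = runif(n_frames * n_part, 0, 8),
                        z = runif(n_frames * n_part, 0, 8))
  g <- occupancy_grid(pos, box = c(8, 8, 8))
  expect_equal(mean(g$counts / g$n_frames), n_part / length(g$counts),
               tolerance = 1e-12)  # exact identity
  # per-bin occupancies scatter as Poisson counts: 3 SE of the mean bin
  p_bin <- n_part / length(g$counts)
  se <- sqrt(p_bin / n_frames / length(g$counts) * length(g$counts))
  expect_lt(abs(max(g$counts) / n_frames - p_bin), 15 * se + p_bin)
})

test_that("standard occupancy follows the N0 closed form", {
  # V_B N_A C = 40 molecules spread over 4e5 bins -> 1e-4 per bin
  avogadro <- 6.02214076e23
  vol <- 1e-22                       # liters
  conc <- 40 / (avogadro * vol)
  expect_equal(standard_occupancy(concentration = conc, volume_l = vol,
                                  n_bins = 4e5), 1e-4)
  # doubling the bin count halves N0
  expect_equal(standard_occupancy(concentration = conc, volume_l = vol,
                                  n_bins = 8e5), 5e-5)
  # N0 * eta_B equals the expected molecule count
  expect_equal(standard_occupancy(concentration = conc, volume_l = vol,
                                  n_bins = 123) * 123, 40)
})

test_that("free energies follow the Boltzmann transform with NA gaps", {
  g <- structure(list(counts = array(c(10, 20, 0, 5), c(4, 1, 1)),
                      n_frames = 10, spacing = 1, box = c(4, 1, 1),
                      origin = c(0, 0, 0)), class = "density_grid")
  fe <- free_energy_grid(g, n0 = 1, temperature = 300)
  expect_equal(fe$dG[1, 1, 1], 0)                      # N = N0
  expect_equal(fe$dG[2, 1, 1], -kT(300) * log(2))      # N = 2 N0
  expect_equal(round(fe$dG[2, 1, 1], 3), -0.413)
  expect_true(is.na(fe$dG[3, 1, 1]))                   # unobserved
  # the -0.22 kcal/mol cutoff corresponds to ~1.446-fold enrichment
  expect_equal(exp(0.22 / kT(300)), 1.446, tolerance = 1e-3)
  # monotone: higher occupancy always means lower free energy
  o <- order(g$counts[c(1, 2, 4), 1, 1])
  expect_true(all(diff(fe$dG[c(1, 2, 4), 1, 1][o]) < 0))
})

# helper: free-energy grid built directly from a dG array
fe_from_array <- function(dG, n0 = 1e-3, temperature = 300) {
  N <- ifelse(is.na(dG), 0, n0 * exp(-dG / kT(temperature)))
  structure(list(dG = dG, N = N, n0 = n0, spacing = 1,
                 box = dim(dG), origin = c(0, 0, 0),
                 temperature = temperature),
            class = "free_energy_grid")
}

test_that("minima merging follows the 8 A single-linkage rule", {
  dims <- c(20, 5, 5)
  base <- array(0.5, dims)          # flat, above the cutoff

  # two minima 7 A apart -> one merged hotspot
  dG <- base; dG[3, 3, 3] <- -1; dG[10, 3, 3] <- -0.9
  h <- find_hotspots(fe_from_array(dG))
  expect_equal(nrow(h), 1)
  expect_equal(h$n_bins, 2)

  # two minima 9 A apart -> two hotspots
  dG <- base; dG[3, 3, 3] <- -1; dG[12, 3, 3] <- -0.9
  h2 <- find_hotspots(fe_from_array(dG))
  expect_equal(nrow(h2), 2)
  # pairwise hotspot distances respect the merge radius
  expect_gte(dist(as.matrix(h2[, c("x", "y", "z")]))[1], 8)

  # a flat grid has no hotspots
  expect_equal(nrow(find_hotspots(fe_from_array(base))), 0)

  # merged free energy comes from the summed probability
  dG <- base; dG[3, 3, 3] <- -1; dG[6, 3, 3] <- -1
  h3 <- find_hotspots(fe_from_array(dG))
  expect_equal(h3$dG, -kT(300) * log(2 * exp(1 / kT(300))),
               tolerance = 1e-9)
})

test_that("merging is idempotent", {
  set.seed(31)
  dG <- array(0.3, c(25, 25, 10))
  idx <- cbind(sample(25, 6), sample(25, 6), sample(10, 6))
  dG[idx] <- runif(6, -1.5, -0.5)
  h1 <- find_hotspots(fe_from_array(dG))
  # rebuild a grid holding only the merged hotspots and re-run
  dG2 <- array(0.3, dim(dG))
  for (i in seq_len(nrow(h1)))
    dG2[ceiling(h1$x[i]), ceiling(h1$y[i]), ceiling(h1$z[i])] <- h1$dG[i]
  h2 <- find_hotspots(fe_from_array(dG2))
  expect_equal(nrow(h2), nrow(h1))
  expect_equal(sort(h2$dG), sort(h1$dG), tolerance = 1e-9)
})

test_that("per-macrostate analysis splits and conserves the frames", {
  set.seed(12)
  box <- c(20, 20, 10)
  n_frames <- 60
  pos <- tibble::tibble(frame = rep(1:n_frames, each = 10),
                        x = runif(600, 0, 20), y = runif(600, 0, 20),
                        z = runif(600, 0, 10))
  asg <- tibble::tibble(frame = 1:n_frames,
                        macrostate = rep(c("M2", "M4"), 30))
  # all frames in one macrostate reproduces the global analysis
  asg1 <- tibble::tibble(frame = 1:n_frames, macrostate = "M2")
  h_all <- macrostate_hotspots(pos, asg1, box)
  g_all <- occupancy_grid(pos, box)
  n0 <- standard_occupancy(g_all,
                           a2amsm:::box_concentration(g_all, 10))
  h_ref <- find_hotspots(free_energy_grid(g_all, n0))
  expect_equal(nrow(h_all), nrow(h_ref))
  if (nrow(h_ref) > 0)
    expect_equal(sort(h_all$dG), sort(h_ref$dG), tolerance = 1e-9)

  # partition conservation: per-state counts add up to the global counts
  g2 <- occupancy_grid(pos[pos$frame %% 2 == 1, ], box)
  g4 <- occupancy_grid(pos[pos$frame %% 2 == 0, ], box)
  expect_equal(g2$counts + g4$counts, g_all$counts)

  # incomplete assignments are an error
  expect_error(macrostate_hotspots(pos, asg[1:10, ], box),
               "do not cover")
})

test_that("a site active only in one macrostate appears only there", {
  # dense sampling, so the 1 A bins are well occupied and the -0.22
  # cutoff is not crossed by shot noise in the uniform macrostate
  box <- c(16, 16, 8)
  n_part <- 100; n_fr <- 6000
  site <- tibble::tibble(x = 8, y = 8, z = 4, depth = -1.5, radius = 2)
  sc_site <- cholesterol_scene(box, n_part, n_fr, sites = site)
  sc_flat <- cholesterol_scene(box, n_part, n_fr)
  pos_site <- sample_cholesterol_scene(sc_site, seed = 41)
  pos_flat <- sample_cholesterol_scene(sc_flat, seed = 42)
  pos_flat$frame <- pos_flat$frame + n_fr
  pos <- dplyr::bind_rows(pos_site, pos_flat)
  asg <- tibble::tibble(frame = 1:(2 * n_fr),
                        macrostate = rep(c("M2", "M4"), each = n_fr))
  h <- macrostate_hotspots(pos, asg, box, cutoff = -0.22)
  h2 <- h[h$macrostate == "M2", ]
  expect_gte(nrow(h2), 1)
  d <- sqrt((h2$x - 8)^2 + (h2$y - 8)^2 + (h2$z - 4)^2)
  expect_lt(min(d), 2)
  expect_equal(nrow(h[h$macrostate == "M4", ]), 0)
})
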