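# Reference landscape construction, calibration and Langevin sampling.

test_that("the reference landscape carries the reported populations", {
  model <- reference_landscape()
  b <- model$basins
  expect_equal(b$weight[b$state == "M5"], 0.384, tolerance = 5e-3)
  expect_equal(sum(b$weight), 1, tolerance = 1e-12)
  # M2 sits at the largest TM3-TM6 separation
  expect_equal(b$lock[b$state == "M2"], 12, tolerance = 0.5)
  # inactive basins at a formed ionic lock
  expect_lt(b$lock[b$state == "M0"], 3)
  expect_true(all(b$sigma_l > 0 & b$sigma_r > 0))
})

test_that("calibration makes cell masses equal the target weights", {
  model <- reference_landscape()
  bp <- basin_populations(model, spacing = 0.05)
  expect_lt(max(abs(bp$population - bp$target)), 1e-4)
  # analytic populations are stable under grid refinement
  bp2 <- basin_populations(model, spacing = 0.1)
  expect_lt(max(abs(bp2$population - bp$population)), 2e-3)
})

test_that("the sampler equilibrates a single-basin landscape", {
  # M5 sits far from the physical boundaries, so the stationary mean is
  # the basin centre without truncation corrections
  model <- reference_landscape(calibrate = FALSE)
  model$basins <- model$basins[model$basins$state == "M5", ]
  model$basins$weight <- 1
  model$basins$mix <- 1
  feats <- sample_langevin(model, n_traj = 20, n_steps = 2000,
                           dt = 0.015, seed = 5)
  b <- model$basins
  # mean at the basin centre within a few standard errors
  n_eff <- 20 * 50   # generous autocorrelation discount
  expect_equal(mean(feats$lock_distance), b$lock,
               tolerance = 5 * b$sigma_l / sqrt(n_eff) + 0.05)
  expect_equal(mean(feats$y753_rmsd), b$rmsd,
               tolerance = 5 * b$sigma_r / sqrt(n_eff) + 0.05)
  # spread matches the core+halo mixture variance closed form
  sd_mix <- b$sigma_l * sqrt((1 - model$halo_fraction) +
                               model$halo_fraction * model$halo_scale^2)
  expect_equal(sd(feats$lock_distance), sd_mix, tolerance = 0.15)
})

test_that("Langevin sampling is reproducible and validates dt", {
  model <- reference_landscape()
  f1 <- sample_langevin(model, 5, 50, seed = 3)
  f2 <- sample_langevin(model, 5, 50, seed = 3)
  expect_identical(f1, f2)
  expect_error(sample_langevin(model, 5, 50, dt = 0, seed = 3),
               "dt must be positive")
  expect_true(all(f1$lock_distance >= 0 & f1$y753_rmsd >= 0))
  expect_equal(nrow(f1), 250)
})

test_that("basin occupancies match the analytic weights", {
  model <- reference_landscape()
  feats <- sample_langevin(model, n_traj = 80, n_steps = 6000,
                           seed = 23)
  cell <- assign_basin(model, feats$lock_distance, feats$y753_rmsd)
  occ <- tabulate(cell, 6) / nrow(feats)
  # per-basin standard errors from between-trajectory scatter
  per_traj <- vapply(1:6, function(i)
    sd(tapply(cell == i, feats$traj, mean)) / sqrt(80), 0)
  dev <- abs(occ - model$basins$weight)
  expect_true(all(dev < 3 * per_traj + 0.003))
})

test_that("fixed start points override the equilibrium draw", {
  model <- reference_landscape()
  st <- matrix(c(2, 0.5), 1)
  f <- sample_langevin(model, 4, 10, seed = 9, start = st)
  first <- f[f$frame == 1, ]
  expect_true(all(first$lock_distance == 2))
  expect_true(all(first$y753_rmsd == 0.5))
})
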