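# Count matrices, reversible estimation, implied timescales.

test_that("count matrix enumerates sliding-window transitions", {
  C <- count_matrix(c(1L, 1L, 2L, 2L), lag = 1)
  expect_equal(C, matrix(c(1, 0, 1, 1), 2))

  # never counts across trajectory boundaries; short ones drop out
  C2 <- count_matrix(list(c(1L, 1L, 2L, 2L), c(2L, 1L)), lag = 1)
  expect_equal(sum(C2), 4)
  expect_equal(C2[2, 1], 1)
  C3 <- count_matrix(list(c(1L, 2L), c(1L, 2L, 1L)), lag = 2,
                     n_states = 2)
  expect_equal(sum(C3), 1)   # only the length-3 trajectory contributes
  expect_error(count_matrix(c(1L, 2L), lag = 5), "shorter than the lag")

  # conservation: total counts = sum over trajectories of len - lag
  set.seed(1)
  trajs <- lapply(1:5, function(i) sample(1:3, sample(3:30, 1),
                                          replace = TRUE))
  lag <- 2
  C <- count_matrix(trajs, lag = lag, n_states = 3)
  expect_equal(sum(C),
               sum(pmax(0, vapply(trajs, length, 0L) - lag)))
})

test_that("reversible MLE satisfies its constraints and recovers chains", {
  # symmetric counts: T is the row-normalised count matrix
  C <- matrix(c(10, 4, 4, 6), 2)
  m <- estimate_msm(C)
  expect_equal(m$T, C / rowSums(C), tolerance = 1e-9,
               ignore_attr = TRUE)

  # doubly symmetric counts give a uniform stationary distribution
  C <- matrix(c(5, 2, 2, 5), 2)
  expect_equal(as.numeric(estimate_msm(C)$pi), c(0.5, 0.5),
               tolerance = 1e-9)

  # long sample from a known reversible chain is recovered
  ch <- chain_model(matrix(c(0.9, 0.1, 0.3, 0.7), 2, byrow = TRUE),
                    labels = c("a", "b"))
  trajs <- sample_chain(ch, n_traj = 20, length = 5000, seed = 5)
  C <- count_matrix(trajs, lag = 1, n_states = 2)
  m <- estimate_msm(C, lag = 1)
  # multinomial sampling error: se(T_ij) ~ sqrt(T_ij (1-T_ij) / n_i)
  n_i <- rowSums(C)
  se <- sqrt(ch$T * (1 - ch$T) / n_i)
  expect_true(all(abs(m$T - ch$T) < 3 * se + 1e-6))

  # constraints hold on every estimate from random counts
  set.seed(9)
  for (rep in 1:10) {
    C <- matrix(rpois(25, 8), 5) + 1
    m <- estimate_msm(C)
    expect_lt(max(abs(rowSums(m$T) - 1)), 1e-10)
    flux <- m$pi * m$T
    expect_lt(max(abs(flux - t(flux))), 1e-8)
    ev <- eigen(m$T, only.values = TRUE)$values
    expect_lt(abs(sort(Mod(ev), decreasing = TRUE)[1] - 1), 1e-10)
  }

  # disconnected counts are restricted to the largest connected set
  C <- matrix(0, 4, 4)
  C[1, 2] <- C[2, 1] <- 10; C[3, 4] <- C[4, 3] <- 2
  C[1, 1] <- 5
  m <- estimate_msm(C)
  expect_equal(m$active_set, c(1L, 2L))
})

test_that("implied timescales follow the eigenvalue closed form", {
  # lambda_2 = 0.5 at lag 20 -> -20 / ln 0.5 = 28.854
  Tm <- matrix(c(0.75, 0.25, 0.25, 0.75), 2)
  its <- implied_timescales(Tm, lag = 20)
  expect_equal(its$timescale[1], -20 / log(0.5), tolerance = 1e-12)
  expect_equal(round(its$timescale[1], 3), 28.854)

  # eigenvalues at 1 are capped and flagged
  its2 <- implied_timescales(diag(3), lag = 10)
  expect_true(all(its2$capped))
  expect_true(all(is.infinite(its2$timescale)))

  # deterministic for a fixed matrix
  expect_identical(implied_timescales(Tm, lag = 20),
                   implied_timescales(Tm, lag = 20))
})

test_that("PCCA recovers block structure and conserves population", {
  # two nearly uncoupled blocks {1,2} and {3,4}
  Tm <- matrix(c(0.89, 0.10, 0.005, 0.005,
                 0.10, 0.89, 0.005, 0.005,
                 0.005, 0.005, 0.79, 0.20,
                 0.005, 0.005, 0.20, 0.79), 4, byrow = TRUE)
  pi <- stationary_distribution(Tm)
  mac <- pcca_macrostates(Tm, 2, pi = pi)
  expect_equal(mac$membership[1], mac$membership[2])
  expect_equal(mac$membership[3], mac$membership[4])
  expect_false(mac$membership[1] == mac$membership[3])
  expect_equal(sum(mac$populations), 1, tolerance = 1e-10)

  # single macrostate holds everything
  mac1 <- pcca_macrostates(Tm, 1, pi = pi)
  expect_equal(mac1$populations, 1)

  # populations sum to one for random reversible inputs
  set.seed(13)
  for (rep in 1:5) {
    ch <- random_reversible_chain(8)
    mac <- suppressWarnings(pcca_macrostates(ch$T, 3, pi = ch$pi))
    expect_equal(sum(mac$populations), 1, tolerance = 1e-10)
    expect_length(mac$membership, 8)
  }
})
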