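# Transition path theory: committors, fluxes, pathway decomposition.

test_that("committor solves the boundary-value problem", {
  # 3-state symmetric chain: the middle state is undecided
  Tm <- matrix(c(0.8, 0.2, 0.0,
                 0.1, 0.8, 0.1,
                 0.0, 0.2, 0.8), 3, byrow = TRUE)
  q <- committor(Tm, A = 1, B = 3)
  expect_equal(q$q_plus, c(0, 0.5, 1))

  # random reversible chains match the absorbing-chain oracle
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(3:6, 1)
    ch <- random_reversible_chain(n)
    A <- 1
    B <- n
    q <- committor(ch$T, A, B, pi = ch$pi)
    expect_lt(max(abs(q$q_plus - committor_oracle(ch$T, A, B))), 1e-10)
    # reversibility identity
    expect_lt(max(abs(q$q_minus - (1 - q$q_plus))), 1e-10)
  }
})

test_that("net flux matches the two-state closed form and is conserved", {
  # detailed-balance two-state chain: total flux = pi_A T_AB
  Tm <- matrix(c(0.9, 0.1,
                 0.2, 0.8), 2, byrow = TRUE)
  pi <- stationary_distribution(Tm)
  fl <- net_flux(Tm, A = 1, B = 2, pi = pi)
  expect_equal(fl$total_flux, pi[1] * Tm[1, 2], tolerance = 1e-12)

  set.seed(7)
  for (rep in 1:20) {
    n <- sample(4:6, 1)
    ch <- random_reversible_chain(n)
    fl <- net_flux(ch$T, A = 1, B = n, pi = ch$pi)
    # conservation at every intermediate node
    imbalance <- rowSums(fl$F) - colSums(fl$F)
    expect_lt(max(abs(imbalance[-c(1, n)])), 1e-10)
    # flux out of A equals flux into B
    expect_equal(sum(fl$F[1, ]) - sum(fl$F[, 1]),
                 sum(fl$F[, n]) - sum(fl$F[n, ]), tolerance = 1e-10)
    # committor bounds and boundary values
    expect_true(all(fl$q_plus >= 0 & fl$q_plus <= 1))
    expect_identical(fl$q_plus[1], 0)
    expect_identical(fl$q_plus[n], 1)
    # swapping source and sink leaves the total flux unchanged
    fl2 <- net_flux(ch$T, A = n, B = 1, pi = ch$pi)
    expect_equal(fl$total_flux, fl2$total_flux, tolerance = 1e-10)
  }
})

test_that("coarse-graining the flux matrix equals the brute-force group sum", {
  set.seed(11)
  for (rep in 1:10) {
    n <- 8
    F <- matrix(runif(n * n), n); diag(F) <- 0
    mem <- sample(1:3, n, replace = TRUE)
    G <- coarse_flux(F, mem)
    for (a in 1:3) for (b in 1:3) {
      want <- if (a == b) 0 else
        sum(F[mem == a, mem == b, drop = FALSE])
      expect_equal(G[a, b], want)
    }
  }
  # identity membership leaves the matrix unchanged (up to the diagonal)
  F <- matrix(runif(16), 4); diag(F) <- 0
  expect_equal(coarse_flux(F, 1:4), F)
  # a single macrostate absorbs everything
  expect_equal(coarse_flux(F, rep(1L, 4)), matrix(0, 1, 1))
})

test_that("bottleneck pathway decomposition handles hand-solved cases", {
  # two equal parallel routes -> 50 / 50
  F <- matrix(0, 4, 4)
  F[1, 2] <- 1; F[2, 4] <- 1       # A -> I1 -> B
  F[1, 3] <- 1; F[3, 4] <- 1       # A -> I2 -> B
  d <- decompose_pathways(F, A = 1, B = 4)
  expect_equal(sort(d$percent), c(50, 50))

  # direct edge with flux 3 beats an indirect route with bottleneck 1:
  # extraction order direct (75%) then via the intermediate (25%)
  F <- matrix(0, 3, 3)
  F[1, 2] <- 1; F[2, 3] <- 1; F[1, 3] <- 3
  d <- decompose_pathways(F, A = 1, B = 3)
  expect_equal(d$percent, c(75, 25))
  expect_equal(d$path, c("S1 -> S3", "S1 -> S2 -> S3"))

  # percentages are nonincreasing and fluxes account for the total
  set.seed(3)
  for (rep in 1:15) {
    ch <- random_reversible_chain(6)
    fl <- net_flux(ch$T, A = 1, B = 6, pi = ch$pi)
    d <- decompose_pathways(fl)
    expect_true(all(diff(d$percent) <= 1e-12))
    expect_gte(sum(d$flux), 0.999 * fl$total_flux)
    expect_lte(sum(d$flux), fl$total_flux * (1 + 1e-9))
  }
})

test_that("tidy and glance summarise a flux network", {
  ch <- random_reversible_chain(5)
  fl <- net_flux(ch$T, A = 1, B = 5, pi = ch$pi)
  td <- tidy(fl)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$role[c(1, 5)], c("source", "sink"))
  expect_equal(glance(fl)$total_flux, fl$total_flux)
})
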