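test_that("gyration radius matches hand-computed configurations", {
  two <- rbind(c(0, 0, 0), c(1, 0, 0))
  three <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_equal(radius_of_gyration_sq(two), 0.25)
  expect_equal(radius_of_gyration_sq(three), 2 / 3)
  expect_equal(radius_of_gyration_sq(matrix(1, 5, 3)), 0)
})

test_that("centroid and pair-sum gyration routes agree", {
  set.seed(21)
  for (i in 1:5) {
    cf <- sample_rosette(rosette_topology(2, 1, 15))
    a <- radius_of_gyration_sq(cf, method = "centroid")
    b <- radius_of_gyration_sq(cf, method = "pairs")
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("Kirkwood sum matches hand-computed configurations", {
  two <- rbind(c(0, 0, 0), c(1, 0, 0))
  three <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_equal(inverse_hydrodynamic_radius(two), 0.5)
  expect_equal(inverse_hydrodynamic_radius(three), 5 / 9)
})

test_that("coincident beads are reported by index", {
  x <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0))
  expect_error(inverse_hydrodynamic_radius(x), "beads 2 and 3")
})

test_that("pair subsampling is unbiased and degenerates to the exact sum", {
  set.seed(22)
  cf <- sample_rosette(rosette_topology(1, 1, 60))
  exact <- inverse_hydrodynamic_radius(cf)
  M <- nrow(cf$coords)
  # full coverage short-circuits to the exact path
  expect_identical(inverse_hydrodynamic_radius(cf, pairs = M * (M - 1)),
                   exact)
  # unbiasedness: mean of repeated subsampled estimates within 3 SE
  reps <- replicate(300, inverse_hydrodynamic_radius(cf, pairs = 500))
  expect_lt(abs(mean(reps) - exact), 3 * sd(reps) / sqrt(length(reps)))
  # subsampled estimate close to exact at K = 1e4 on a larger molecule
  confs <- simulate(rosette_topology(1, 0, 800), nsim = 40, seed = 23)
  sub <- vapply(confs, inverse_hydrodynamic_radius, numeric(1), pairs = 1e4)
  exa <- vapply(confs, inverse_hydrodynamic_radius, numeric(1))
  dd <- sub - exa
  expect_lt(abs(mean(dd)), 3 * sd(dd) / sqrt(length(dd)))
})

test_that("observables are invariant under rigid motion and scale correctly", {
  set.seed(24)
  cf <- sample_rosette(rosette_topology(1, 1, 30))
  x <- cf$coords
  rg2 <- radius_of_gyration_sq(x)
  rh <- inverse_hydrodynamic_radius(x)
  rot <- random_rotation(3)
  moved <- sweep(x %*% rot, 2, c(10, -4, 2.5), "+")
  expect_equal(radius_of_gyration_sq(moved), rg2, tolerance = 1e-10)
  expect_equal(inverse_hydrodynamic_radius(moved), rh, tolerance = 1e-10)
  lam <- 3.7
  expect_equal(radius_of_gyration_sq(lam * x), lam^2 * rg2,
               tolerance = 1e-12)
  expect_equal(inverse_hydrodynamic_radius(lam * x), rh / lam,
               tolerance = 1e-12)
})

test_that("the size ratio does not depend on the step variance", {
  rhos <- vapply(c(0.25, 1, 4), function(sv) {
    top <- rosette_topology(1, 1, 25, step_var = sv)
    est <- ensemble_estimate(simulate(top, nsim = 50, seed = 31))
    est$rho
  }, numeric(1))
  # identical seed => identical normalised deviates => exact invariance
  expect_equal(rhos[1], rhos[2], tolerance = 1e-12)
  expect_equal(rhos[2], rhos[3], tolerance = 1e-12)
})

test_that("discrete chain reference evaluates its closed forms", {
  ref <- discrete_chain_reference(2)
  expect_equal(ref$rg2, 0.75)
  expect_equal(ref$rhinv, sqrt(2 / pi) / 2, tolerance = 1e-12)
  expect_equal(ref$rho, sqrt(0.75) * sqrt(2 / pi) / 2, tolerance = 1e-12)
  # approach to the asymptotic chain value from below
  r1 <- discrete_chain_reference(1000)$rho
  r2 <- discrete_chain_reference(10000)$rho
  expect_lt(r1, r2)
  expect_lt(r2, 8 / (3 * sqrt(pi)))
})

test_that("ensemble estimates combine means and jackknife errors", {
  set.seed(25)
  cf <- sample_rosette(rosette_topology(1, 0, 20))
  dup <- list(cf, cf, cf, cf, cf)
  est <- ensemble_estimate(dup)
  expect_equal(est$rho_err, 0)
  expect_equal(est$rho, sqrt(radius_of_gyration_sq(cf)) *
                 inverse_hydrodynamic_radius(cf), tolerance = 1e-12)
  # rho recombines the two means by construction
  confs <- simulate(rosette_topology(1, 0, 50), nsim = 200, seed = 26)
  est <- ensemble_estimate(confs)
  expect_equal(est$rho, sqrt(est$rg2) * est$rhinv, tolerance = 1e-12)
  # error shrinks with ensemble size
  est100 <- ensemble_estimate(confs[1:50])
  expect_lt(est$rho_err, est100$rho_err)
  # mixed topologies are refused
  other <- simulate(rosette_topology(0, 1, 50), nsim = 2, seed = 27)
  expect_error(ensemble_estimate(c(confs[1:3], other)), "mixed")
})
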