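test_that("harmonic bond forces are restoring and momentum-conserving", {
  p <- md_params()
  bonds <- matrix(c(1L, 2L), 1, 2)
  at_rest <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(bonded_forces(at_rest, bonds, p), matrix(0, 2, 3))
  stretched <- rbind(c(0, 0, 0), c(1.1, 0, 0))
  f <- bonded_forces(stretched, bonds, p)
  expect_equal(f[1, 1], p$k * 0.1, tolerance = 1e-12)
  expect_equal(f[2, 1], -p$k * 0.1, tolerance = 1e-12)
  # net internal force vanishes on a random rosette
  set.seed(41)
  top <- rosette_topology(2, 2, 8)
  cf <- sample_rosette(top)
  fr <- bonded_forces(cf, bond_list(top), p)
  expect_equal(colSums(fr), c(0, 0, 0), tolerance = 1e-10)
  # coincident bonded beads are an error
  expect_error(bonded_forces(matrix(0, 2, 3), bonds, p), "zero-length")
})

test_that("free particle equilibrates to the Maxwell velocity variance", {
  set.seed(42)
  nob <- matrix(integer(0), 0, 2)
  out <- rosette:::langevin_run_cpp(matrix(0, 1, 3), matrix(0, 1, 3), nob,
                                    200, 1, 0.5, 0.0025, 1, 1, 200000L, 10L)
  kin_T <- 2 * out$ke / 3
  # velocity decorrelation time m/zeta = 800 steps => ~250 independent frames
  n_eff <- 250
  expect_lt(abs(mean(kin_T) - 1), 3 * sqrt(2 / (3 * n_eff)))
})

test_that("a single bond samples its Boltzmann fluctuation", {
  set.seed(43)
  x0 <- rbind(c(0, 0, 0), c(1, 0, 0))
  v0 <- matrix(rnorm(6), 2, 3)
  bonds <- matrix(c(0L, 1L), 1, 2)
  out <- rosette:::langevin_run_cpp(x0, v0, bonds, 200, 1, 0.5, 0.0025,
                                    1, 1, 400000L, 40L)
  # <(l - r0)^2> = kT/k up to the small radial (entropic) correction
  expect_equal(mean(out$bond_msd), 1 / 200, tolerance = 0.05)
})

test_that("the friction substep reaches the overdamped displacement law", {
  set.seed(44)
  nob <- matrix(integer(0), 0, 2)
  zeta <- 2e5
  out <- rosette:::langevin_run_cpp(matrix(0, 1, 3), matrix(0, 1, 3), nob,
                                    0, 1, zeta, 0.0025, 1, 1, 50000L, 1L)
  x <- vapply(out$frames, function(m) m[1, 1], numeric(1))
  expect_equal(var(diff(x)), 2 * 0.0025 / zeta, tolerance = 0.05)
})

test_that("trajectories are reproducible and steps advance the state", {
  top <- rosette_topology(1, 0, 5)
  bonds <- bond_list(top)
  set.seed(45)
  st <- list(coords = sample_rosette(top)$coords,
             vel = matrix(0, total_beads(top), 3))
  set.seed(46)
  s1 <- langevin_step(st, bonds, md_params())
  set.seed(46)
  s2 <- langevin_step(st, bonds, md_params())
  expect_identical(s1$coords, s2$coords)
  expect_false(identical(s1$coords, st$coords))
  # full runs with the same seed are identical
  t1 <- run_md(top, md_params(), n_equil = 500, n_steps = 2000,
               sample_every = 500, seed = 47)
  t2 <- run_md(top, md_params(), n_equil = 500, n_steps = 2000,
               sample_every = 500, seed = 47)
  expect_identical(t1$frames[[4]]$coords, t2$frames[[4]]$coords)
})

test_that("chain MD reproduces equilibrium size and temperature", {
  top <- rosette_topology(1, 0, 30)
  tr <- run_md(top, md_params(), seed = 103)
  # kinetic temperature within 2% of the thermostat setting
  expect_equal(mean(tr$diagnostics$kinetic_T), 1, tolerance = 0.02)
  # bond fluctuation near kT/k
  expect_equal(mean(tr$diagnostics$bond_msd), 1 / 200, tolerance = 0.05)
  est <- ensemble_estimate(tr$frames, block_size = tr$block_size)
  # Rg^2 against the ideal-chain value scaled by the measured bond length
  bm <- mean(tr$diagnostics$bond_mean)
  l2 <- tr$params$r0^2 + 2 * tr$params$r0 * (bm - tr$params$r0) +
    mean(tr$diagnostics$bond_msd)
  M <- total_beads(top)
  rg2_ref <- (M^2 - 1) / (6 * M) * l2
  expect_lt(abs(est$rg2 - rg2_ref), 3 * est$rg2_err)
  # rho against the exact freely-jointed finite-M value
  expect_lt(abs(est$rho - fjc_chain_rho(M, b2 = l2)), 3 * est$rho_err)
})

test_that("ring MD maintains closure through an equilibrated closing bond", {
  top <- rosette_topology(0, 1, 30)
  tr <- run_md(top, md_params(), seed = 104)
  expect_equal(mean(tr$diagnostics$bond_msd), 1 / 200, tolerance = 0.05)
  expect_equal(mean(tr$diagnostics$kinetic_T), 1, tolerance = 0.02)
  # the closing bond specifically stays near its rest length
  closing <- vapply(tr$frames, function(cf) {
    i <- which(cf$arm == 1L)
    sqrt(sum((cf$coords[i[length(i)], ] - cf$coords[1, ])^2))
  }, numeric(1))
  expect_equal(mean((closing - 1)^2), 1 / 200, tolerance = 0.25)
})
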