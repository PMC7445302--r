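test_that("noiseless series are recovered to machine precision", {
  N <- c(100, 400, 1600)
  rho <- 1.5 * (1 + 0.3 * N^-0.5)
  fit <- fit_finite_size(N, rho)
  expect_equal(fit$rho_inf, 1.5, tolerance = 1e-10)
  expect_equal(fit$a, 0.3, tolerance = 1e-10)
  expect_lt(fit$chi2, 1e-16)
  expect_equal(unname(coef(fit)), c(1.5, 0.3), tolerance = 1e-10)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-12)
  # nonlinear refit agrees on clean data
  fit_nls <- fit_finite_size(N, rho, method = "nls")
  expect_equal(fit_nls$rho_inf, 1.5, tolerance = 1e-6)
  expect_equal(fit_nls$a, 0.3, tolerance = 1e-6)
})

test_that("degenerate designs are rejected", {
  expect_error(fit_finite_size(c(100, 200), c(1.4, 1.45)))
  expect_error(fit_finite_size(c(100, 100, 100), c(1.4, 1.41, 1.42)))
  expect_error(fit_finite_size(c(100, 200, 400), c(1.4, 1.45, 1.47),
                               rho_err = c(0.01, -0.01, 0.01)))
})

test_that("exact finite-size series extrapolate to the asymptotic ratios", {
  # chain: exact discrete values over a wide window
  M <- c(100, 200, 400, 800, 1600, 6400)
  rho_m <- vapply(M, function(m) discrete_chain_reference(m)$rho, numeric(1))
  fit <- fit_finite_size(M, rho_m)
  expect_equal(fit$rho_inf, 8 / (3 * sqrt(pi)), tolerance = 0.005)
  # ring
  n <- c(50, 100, 200, 400, 800)
  rho_n <- vapply(n, function(m) discrete_ring_reference(m)$rho, numeric(1))
  fit_r <- fit_finite_size(n, rho_n)
  expect_equal(fit_r$rho_inf, sqrt(2 * pi) / 2, tolerance = 0.005)
  # monotone approach from below with a negative correction amplitude
  expect_true(all(diff(rho_m) > 0))
  expect_true(all(diff(rho_n) > 0))
  expect_lt(fit$a, 0)
  expect_lt(fit_r$a, 0)
})

test_that("one-sigma intervals cover the truth at the nominal rate", {
  set.seed(51)
  N <- c(100, 200, 400, 800, 1600)
  err <- rep(0.005, length(N))
  truth <- 1.5045 * (1 + -1.1 * N^-0.5)
  hits <- vapply(1:100, function(i) {
    fit <- fit_finite_size(N, truth + rnorm(length(N), sd = err), err)
    abs(fit$rho_inf - 1.5045) <= fit$rho_inf_err
  }, logical(1))
  expect_gte(mean(hits), 0.6)
})

test_that("fit methods predict and summarise coherently", {
  N <- c(100, 200, 400, 800)
  rho <- 1.25 * (1 - 0.9 * N^-0.5)
  fit <- fit_finite_size(N, rho, rho_err = rep(0.003, 4))
  expect_equal(predict(fit, newdata = data.frame(N = 1e12)), 1.25,
               tolerance = 1e-5)
  expect_equal(predict(fit), rho, tolerance = 1e-10)
  ci <- confint(fit)
  expect_true(ci["rho_inf", 1] < 1.25 && 1.25 < ci["rho_inf", 2])
  expect_output(print(fit), "rho_inf")
  expect_output(summary(fit), "points")
})

test_that("the sampling pipeline assembles per-N estimates into a fit", {
  st <- rho_scaling_study(1, 0, N = c(25, 50, 100), n_conf = 60, seed = 61)
  expect_identical(nrow(st$points), 3L)
  expect_true(all(st$points$rho_err > 0))
  expect_equal(st$points$M, st$points$N + 1)
  # per-N means agree with the exact discrete chain values within 3 SE
  for (i in 1:3) {
    ref <- discrete_chain_reference(st$points$M[i])
    expect_lt(abs(st$points$rho[i] - ref$rho), 3 * st$points$rho_err[i])
  }
  expect_s3_class(st$fit, "fss_fit")
  expect_output(print(st), "Scaling study")
})
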