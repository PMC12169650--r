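test_that("inner-filter correction follows exp((A_ex + A_em)/2)", {
  expect_equal(inner_filter_correct(100, 0, 0), 100)
  expect_equal(inner_filter_correct(100, 0.1, 0.1), 100 * exp(0.1))
  a <- seq(0, 0.5, by = 0.1)
  expect_true(all(diff(inner_filter_correct(100, a, 0.2)) > 0))
  expect_error(inner_filter_correct(100, -0.1, 0), "negative")
})

test_that("titration generator hits the isotherm exactly at zero noise", {
  K <- 1.57e4
  tt <- generate_titration(K, n = 1.38, F0 = 100, F_inf = 10,
                           concentrations = c(K / 100, K, K * 1e4))
  theta <- (100 - tt$F_obs) / 90
  expect_equal(theta[2], 0.5)           # c = K gives half saturation
  expect_lt(abs(tt$F_obs[3] - 10), 0.1) # c -> infinity approaches F_inf
  expect_error(generate_titration(-1, 1, concentrations = 1), "K > 0")
})

test_that("noiseless Hill fits recover the generating parameters to 1e-6
           relative, with and without fixed endpoints", {
  conc <- sort(c(1.57e4, 10^seq(2.5, 6.5, length.out = 15)))
  tt <- generate_titration(1.57e4, 1.38, concentrations = conc)
  fit <- hill_fit(tt)
  expect_lt(abs(fit$K - 1.57e4) / 1.57e4, 1e-6)
  expect_lt(abs(fit$n - 1.38) / 1.38, 1e-6)
  expect_equal(fit$theta[conc == 1.57e4], 0.5, tolerance = 1e-6)
  fit2 <- hill_fit(tt, F0 = 100, F_inf = 10)
  expect_lt(abs(fit2$K - 1.57e4) / 1.57e4, 1e-6)
  expect_lt(abs(fit2$n - 1.38) / 1.38, 1e-6)
  expect_error(hill_fit(tt[1:3, ]), "at least 5")
})

test_that("free energies reproduce the worked dissociation examples", {
  expect_equal(delta_g(1.57e4 * 1e-9), -6.55, tolerance = 0.01 / 6.55)
  expect_equal(delta_g(3.35e5 * 1e-9), -4.74, tolerance = 0.01 / 4.74)
  expect_equal(delta_g(1), 0)
  kd <- c(1e-9, 1e-6, 1e-3, 1)
  expect_true(all(diff(delta_g(kd)) > 0))  # strictly increasing in K_D
  expect_error(delta_g(0), "positive")
})

test_that("decay generator obeys single-exponential channel ratios with a
           delta-like IRF", {
  d <- generate_decay(1, 2, irf_fwhm_ns = 1e-6, irf_t0_ns = 0,
                      dt_ns = 0.1, n_channels = 200, noise = FALSE)
  ratio <- d$counts[51] / d$counts[41]  # 1 ns apart, tau = 2 ns
  expect_equal(ratio, exp(-1 / 2), tolerance = 1e-9)
  z <- generate_decay(1, 2, total_counts = 0)
  expect_true(all(z$counts == 0))
  expect_error(generate_decay(1, -2), "lifetimes")
})

test_that("reconvolution fits recover components from noiseless and
           Poisson data", {
  d <- generate_decay(c(0.7, 0.3), c(1, 4), noise = FALSE)
  fit <- fit_decay(d, n_components = 2)
  expect_equal_tol(fit$lifetimes / c(1, 4) - 1, c(0, 0), 0.01)
  expect_equal_tol(fit$amplitudes / sum(fit$amplitudes) - c(0.7, 0.3),
                   c(0, 0), 0.01 * 0.7)
  d1 <- generate_decay(1, 2.5, noise = FALSE)
  f1 <- fit_decay(d1, n_components = 1)
  expect_lt(abs(f1$lifetimes - 2.5) / 2.5, 0.001)
  dp <- generate_decay(c(0.7, 0.3), c(1, 4), total_counts = 1e6, seed = 6)
  fp <- fit_decay(dp, n_components = 2)
  expect_lt(max(abs(fp$lifetimes / c(1, 4) - 1)), 0.05)
  expect_lt(abs(mean(fp$residuals)), 0.05)  # mean-zero standardized resid
  expect_error(fit_decay(d, n_components = 4), "identifiable")
})

test_that("mean lifetime is the amplitude-weighted average, invariant to
           rescaling", {
  expect_equal(mean_lifetime(list(amplitudes = c(1, 1),
                                  lifetimes = c(1, 3))), 2)
  expect_equal(mean_lifetime(list(amplitudes = 5, lifetimes = 2.2)), 2.2)
  expect_equal(mean_lifetime(list(amplitudes = c(7, 3) * 11,
                                  lifetimes = c(1, 4))),
               mean_lifetime(list(amplitudes = c(7, 3),
                                  lifetimes = c(1, 4))))
})
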