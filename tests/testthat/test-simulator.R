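test_that("noiseless fixed point stays on the limit cycle for 10 s", {
  p <- preset_d0("activated")
  re <- equilibrium_amplitude(p)
  rec <- simulate_single(p, sim_config(dt = 2.5e-5, duration = 10, seed = 1,
                                       initial = list(r = re, phi = 0)))
  expect_lt(max(abs(Mod(rec$analytic[, 1]) - re)), 1e-6)
})

test_that("noiseless simulation matches the closed form from off-equilibrium start", {
  p <- preset_d0("activated")
  cfg <- sim_config(dt = 1e-4, duration = 2, seed = 1,
                    initial = list(r = 0.5, phi = 0.7))
  rec <- simulate_single(p, cfg)
  cl <- deterministic_trajectory(p, 0.5, 0.7, rec$t)
  expect_lt(max(abs(Mod(rec$analytic[, 1]) - cl$r) / cl$r), 1e-4)
})

test_that("identical seeds give bit-identical recordings", {
  p <- regime_preset("activated")
  cfg <- sim_config(duration = 1, seed = 99)
  r1 <- simulate_single(p, cfg)
  r2 <- simulate_single(p, cfg)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$analytic, r2$analytic)
  r3 <- simulate_single(p, sim_config(duration = 1, seed = 100))
  expect_false(identical(r1$data, r3$data))
})

test_that("Euler-Heun improves the deterministic convergence order over Euler-Maruyama", {
  p <- oscillator_params(2, 1, 0.8, 2 * pi * 10, 0)
  endpoint_err <- function(dt, scheme) {
    cfg <- sim_config(dt = dt, duration = 1, seed = 1, scheme = scheme,
                      initial = list(r = 0.5, phi = 0))
    rec <- simulate_single(p, cfg)
    cl <- deterministic_trajectory(p, 0.5, 0, 1)
    Mod(rec$analytic[nrow(rec$analytic), 1] -
          complex(modulus = cl$r, argument = cl$phi))
  }
  e_heun <- vapply(c(1e-3, 5e-4), endpoint_err, 0, scheme = "heun")
  e_em <- vapply(c(1e-3, 5e-4), endpoint_err, 0, scheme = "euler")
  expect_gt(e_heun[1] / e_heun[2], 3.5)   # ~order 2
  expect_lt(e_em[1] / e_em[2], 3)         # ~order 1
  expect_gt(e_em[1] / e_em[2], 1.7)
})

test_that("schemes share the same noise stream and differ only through drift", {
  # nearly drift-free oscillator: trajectories under the two schemes agree
  p <- oscillator_params(0, 1e-8, 0, 0, 0.01)
  cfg_h <- sim_config(duration = 1, seed = 5, scheme = "heun",
                      initial = list(r = 1e-4, phi = 0))
  cfg_e <- sim_config(duration = 1, seed = 5, scheme = "euler",
                      initial = list(r = 1e-4, phi = 0))
  zh <- simulate_single(p, cfg_h)$analytic[, 1]
  ze <- simulate_single(p, cfg_e)$analytic[, 1]
  expect_lt(max(Mod(zh - ze)) / max(Mod(zh)), 1e-6)
})

test_that("a one-channel network reproduces simulate_single exactly", {
  p <- regime_preset("activated")
  cfg <- sim_config(duration = 1, seed = 13)
  r1 <- simulate_single(p, cfg)
  r2 <- simulate_network(network_model(list(p)), cfg)
  expect_identical(r1$analytic, r2$analytic)
})

test_that("long activated runs match the stationary amplitude statistics", {
  p <- regime_preset("activated")
  rec <- simulate_single(p, sim_config(duration = 60, seed = 21))
  burn <- 2048
  r_samp <- Mod(rec$analytic[(burn + 1):nrow(rec$analytic), 1])
  expect_equal(mean(r_samp), equilibrium_amplitude(p), tolerance = 0.05)
  dens <- stationary_density(p)
  cdf <- cumsum(dens$density) * diff(dens$r)[1]
  F <- stats::approxfun(dens$r, pmin(cdf / max(cdf), 1),
                        yleft = 0, yright = 1)
  rs <- sort(r_samp)
  ks <- max(abs(F(rs) - stats::ecdf(rs)(rs)))
  expect_lt(ks, 0.12)
})

test_that("suppressed-regime power scales linearly with noise intensity", {
  ps <- regime_preset("suppressed")
  Ds <- c(0.001, 0.005, 0.01)
  pw <- vapply(Ds, function(D) {
    p <- oscillator_params(ps$lambda, ps$zeta, ps$chi, ps$omega, D)
    rec <- simulate_single(p, sim_config(duration = 40, seed = 31))
    mean(Mod(rec$analytic[2049:nrow(rec$analytic), 1])^2)
  }, numeric(1))
  fit <- stats::lm(pw ~ Ds)
  expect_gt(summary(fit)$r.squared, 0.95)
  expect_gt(stats::coef(fit)[2], 0)
})

test_that("network coupling validation and stability guard fire", {
  p <- regime_preset("activated")
  K_bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(network_model(list(p, p), K = K_bad), "\\(2,1\\)|\\(1,2\\)")
  K_diag <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_error(network_model(list(p, p), K = K_diag), "diagonal")
  expect_error(simulate_single(p, sim_config(dt = 0.05, duration = 1, seed = 1)),
               "unstable|use dt")
})

test_that("uncoupled distinct-frequency channels show chance-level phase locking", {
  oscs <- lapply(c(8, 10, 12), function(f)
    oscillator_params(2, 1, 0.8, 2 * pi * f, 0.01))
  m <- network_model(oscs)
  rec <- simulate_network(m, sim_config(duration = 30, seed = 41,
                                        decimate_to = 256))
  zb <- analytic_band_signal(rec, c(6, 14))
  zt <- neurophonon:::.trim_rows(zb)
  p12 <- as.numeric(plv(zt[, 1], zt[, 2]))
  bound <- surrogate_bound(zt[, 1], zt[, 2], n_surrogates = 100, seed = 7)
  expect_lt(p12, max(bound, 0.3))
})

test_that("strong real coupling synchronises amplitudes of identical oscillators", {
  p <- oscillator_params(2, 1, 0.8, 2 * pi * 10, 0.001)
  K <- matrix(c(0, 5, 5, 0), 2, 2)
  m <- network_model(list(p, p), K = K)
  rec <- simulate_network(m, sim_config(duration = 10, seed = 51))
  env <- Mod(rec$analytic[2049:nrow(rec$analytic), ])
  expect_lt(mean(abs(env[, 1] - env[, 2])), 0.02)
})

test_that("make_fixture builds the requested regimes and couplings", {
  fx <- make_fixture("activated", 1, 0, seed = 3, duration = 4)
  expect_equal(ncol(fx$recording$data), 1)
  expect_equal(fx$model$oscillators[[1]]$lambda, 2.0)
  expect_equal(fx$model$oscillators[[1]]$D, 0.010)
  fx0 <- make_fixture("exploratory", 3, 0, seed = 3, duration = 2)
  expect_true(all(fx0$model$K == 0))
  fx4 <- make_fixture("suppressed", 4, 0.1, seed = 3, duration = 4)
  expect_equal(ncol(fx4$recording$data), 4)
  expect_equal(Mod(fx4$model$K[1, 2]), 0.1)
  expect_error(make_fixture("awake", 2, 0, seed = 1), "valid regimes")
})

test_that("suppressed fixtures carry far less alpha power than activated ones", {
  fa <- make_fixture("activated", 1, 0, seed = 17, duration = 20)
  fs <- make_fixture("suppressed", 1, 0, seed = 17, duration = 20)
  pa <- band_power(welch_psd(fa$recording), "alpha")
  ps <- band_power(welch_psd(fs$recording), "alpha")
  expect_gt(pa, 20 * ps)
})

test_that("decimation preserves the recording contract", {
  p <- regime_preset("activated")
  rec <- simulate_single(p, sim_config(duration = 4, seed = 61,
                                       decimate_to = 256))
  expect_equal(rec$fs, 256)
  expect_equal(nrow(rec$data), 4 * 256 + 1)
  expect_equal(diff(rec$t)[1], 1 / 256, tolerance = 1e-12)
  expect_error(sim_config(dt = 1 / 2048, duration = 1, decimate_to = 300),
               "integer multiple")
})
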