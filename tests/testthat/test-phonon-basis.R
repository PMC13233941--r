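test_that("uncoupled networks give a diagonal dynamical matrix and local modes", {
  oscs <- list(oscillator_params(2, 1, 0.8, 2 * pi * 10, 0.01),
               oscillator_params(3, 2, 0.5, 2 * pi * 11, 0.02),
               oscillator_params(1, 1, 0.2, 2 * pi * 9, 0.005))
  m <- network_model(oscs)
  b <- build_basis(m)
  expect_equal(max(abs(b$Phi - diag(diag(b$Phi)))), 0)
  omega_local <- sqrt(vapply(oscs, potential_curvature, 0, hbar = 1) /
                        (1 / (2 * vapply(oscs, `[[`, 0, "D"))))
  expect_equal(sort(b$Omega), sort(omega_local), tolerance = 1e-12)
  # modes are coordinate axes (up to ordering)
  expect_equal(sort(abs(as.vector(b$modes))), c(rep(0, 6), rep(1, 3)),
               tolerance = 1e-12)
})

test_that("single activated oscillator has the printed mode frequency", {
  b <- build_basis(network_model(list(regime_preset("activated"))))
  expect_equal(b$Omega^2, 797 / 50, tolerance = 1e-12)
  expect_equal(b$Omega, 3.9925, tolerance = 1e-4)
  expect_equal(b$M, 50)
})

test_that("two identical coupled oscillators split as {V''/m, (V''+2s)/m}", {
  p <- regime_preset("activated")
  s <- 7                       # S_12 = s requires Re K = -s
  m <- network_model(list(p, p), K = matrix(c(0, -s, -s, 0), 2, 2))
  b <- build_basis(m)
  vpp <- potential_curvature(p, 1)
  mass <- 1 / (2 * p$D)
  expect_equal(sort(b$Omega^2), sort(c(vpp / mass, (vpp + 2 * s) / mass)),
               tolerance = 1e-10)
  # basis invariants
  expect_lt(max(abs(crossprod(b$modes) - diag(2))), 1e-10)
  resid <- b$Phi %*% b$modes - b$modes %*% diag(b$Omega^2)
  expect_lt(max(abs(resid)), 1e-8)
})

test_that("mode masses: uniform noise collapses to m, trace identity in general", {
  p <- regime_preset("activated")
  m2 <- network_model(list(p, p), K = matrix(c(0, -3, -3, 0), 2, 2))
  b2 <- build_basis(m2)
  expect_equal(mode_masses(b2), rep(1 / (2 * p$D), 2), tolerance = 1e-12)
  # explicit weighted sum: m = (50, 100), v = (1, 1)/sqrt(2) -> 75
  V <- matrix(c(1, 1, 1, -1) / sqrt(2), 2)
  bs <- synthetic_basis(masses = c(50, 100), Omega = c(1, 2), modes = V)
  expect_equal(mode_masses(bs)[1], 75)
  # trace identity on random orthonormal modes with arbitrary masses
  set.seed(42)
  for (n in c(3, 5)) {
    V <- random_orthonormal(n)
    masses <- stats::runif(n, 10, 200)
    bs <- synthetic_basis(masses, Omega = seq_len(n), modes = V)
    expect_equal(sum(mode_masses(bs)), sum(masses), tolerance = 1e-10)
  }
})

test_that("isolated mode frequencies reduce to eigenfrequencies without coupling", {
  oscs <- list(oscillator_params(2, 1, 0.8, 2 * pi * 10, 0.01),
               oscillator_params(1.5, 2, 0.5, 2 * pi * 10, 0.02),
               oscillator_params(3, 1, 0.2, 2 * pi * 10, 0.03))
  b <- build_basis(network_model(oscs))
  for (l in 1:3)
    expect_equal(isolated_mode_frequency(b, l), b$Omega[l], tolerance = 1e-12)
  # homogeneous network: independent of mode index
  p <- regime_preset("activated")
  bh <- build_basis(network_model(list(p, p, p),
                                  K = matrix(c(0, -1, -1, -1, 0, -1, -1, -1, 0), 3)))
  iso <- vapply(1:3, isolated_mode_frequency, 0, basis = bh)
  expect_equal(iso, rep(sqrt(797 / 50), 3), tolerance = 1e-10)
  # heterogeneous: matches the brute-force weighted sum
  bhet <- build_basis(network_model(oscs,
                                    K = matrix(c(0, -2, 0, -2, 0, -1, 0, -1, 0), 3)))
  for (l in 1:3) {
    v <- bhet$modes[, l]
    brute <- sqrt(sum(bhet$curvatures * v^2) / sum(bhet$masses * v^2))
    expect_equal(isolated_mode_frequency(bhet, l), brute, tolerance = 1e-12)
  }
})

test_that("projection is the exact inverse of mode superposition", {
  p <- regime_preset("activated")
  m <- network_model(list(p, p, p),
                     K = matrix(c(0, -2, -1, -2, 0, -3, -1, -3, 0), 3))
  b <- build_basis(m)
  set.seed(7)
  q_true <- matrix(stats::rnorm(50 * 3, sd = 0.1), 50, 3)
  r_mat <- reconstruct_amplitudes(b, m, q_true)
  rec <- multichannel_recording(data = r_mat, fs = 100, channels = m$channels,
                                analytic = r_mat + 0i)
  traj <- project_recording(b, m, rec)
  expect_lt(max(abs(traj$q - q_true)), 1e-10)
  # zero fluctuation -> zero displacement
  re <- vapply(m$oscillators, equilibrium_amplitude, 0)
  flat <- matrix(rep(re, each = 20), 20, 3)
  rec0 <- multichannel_recording(flat, 100, m$channels, analytic = flat + 0i)
  expect_lt(max(abs(project_recording(b, m, rec0)$q)), 1e-12)
  # fluctuation along a single mass-scaled mode excites only that mode
  v1 <- b$modes[, 1] / sqrt(b$masses)
  one <- sweep(outer(sin(1:40 / 5), v1), 2, re, `+`)
  rec1 <- multichannel_recording(one, 100, m$channels, analytic = one + 0i)
  q1 <- project_recording(b, m, rec1)$q
  expect_lt(max(abs(q1[, 2:3])), 1e-10)
  expect_gt(stats::sd(q1[, 1]), 0)
  # channel mismatch is refused
  bad <- multichannel_recording(flat, 100, c("a", "b", "c"))
  expect_error(project_recording(b, m, bad), "channels")
})

test_that("occupation estimator recovers the analytic harmonic value", {
  p <- regime_preset("activated")
  m <- network_model(list(p))
  b <- build_basis(m)
  Om <- b$Omega; M <- b$M
  fs <- 512
  tt <- seq(0, 200, by = 1 / fs)
  A <- 0.05
  q <- matrix(A * cos(Om * tt), ncol = 1)
  pmat <- matrix(M * neurophonon:::.central_diff(q[, 1], 1 / fs) , ncol = 1)
  occ <- mode_occupation(list(q = q, p = pmat), b, hbar = 1)
  E_true <- 0.5 * M * Om^2 * A^2
  expect_equal(attr(occ, "raw"), E_true / Om - 0.5, tolerance = 1e-3)
  # doubling the amplitude quadruples the energy
  q2 <- 2 * q; p2 <- 2 * pmat
  occ2 <- mode_occupation(list(q = q2, p = p2), b, hbar = 1)
  E1 <- (attr(occ, "raw") + 0.5) * Om
  E2 <- (attr(occ2, "raw") + 0.5) * Om
  expect_equal(E2 / E1, 4, tolerance = 1e-3)
  # silent trajectory sits at the ground-state floor
  occ0 <- mode_occupation(list(q = 0 * q, p = 0 * pmat), b, hbar = 1)
  expect_equal(as.numeric(occ0), 0)
  expect_equal(attr(occ0, "raw"), -0.5)
})

test_that("energy report: coupling term switches with Im K and phases", {
  p <- regime_preset("activated")
  re <- equilibrium_amplitude(p)
  # real coupling only -> zero coupling energy
  m_re <- network_model(list(p, p), K = matrix(c(0, -2, -2, 0), 2, 2))
  b_re <- build_basis(m_re)
  n_t <- 600
  z <- matrix(complex(modulus = re, argument = 2 * pi * 10 * (1:n_t) / 256),
              n_t, 2)
  rec <- multichannel_recording(Re(z), 256, m_re$channels, analytic = z)
  er <- energy_report(m_re, b_re, rec)
  expect_equal(er$coupling_term, 0)
  expect_equal(er$total, er$amplitude_term + er$phase_term + er$coupling_term)
  # imaginary coupling with identical phases: coupling = -sum J (cos 0 = 1)
  K_im <- matrix(c(0, -4i, -4i, 0), 2, 2)
  m_im <- network_model(list(p, p), K = K_im)
  er2 <- energy_report(m_im, build_basis(m_im), rec)
  J12 <- -0.5 * re * re * Im(K_im[1, 2])
  expect_gt(J12, 0)
  expect_equal(er2$coupling_term, -J12, tolerance = 1e-12)
  # ground-state-like amplitude term is bounded below by zero-point energy
  expect_gte(er$amplitude_term, 0.999 * sum(b_re$Omega / 2))
})

test_that("energy total is invariant under channel relabelling", {
  oscs <- list(oscillator_params(2, 1, 0.8, 2 * pi * 10, 0.01),
               oscillator_params(1.5, 1, 0.5, 2 * pi * 10, 0.02),
               oscillator_params(2.5, 2, 0.3, 2 * pi * 10, 0.015))
  K <- matrix(c(0, -1 - 2i, -0.5i,
                -1 - 2i, 0, -2,
                -0.5i, -2, 0), 3, 3)
  m <- network_model(oscs, K = K)
  rec <- simulate_network(m, sim_config(duration = 5, seed = 71))
  er <- energy_report(m, build_basis(m), rec)
  perm <- c(3, 1, 2)
  m_p <- network_model(oscs[perm], K = K[perm, perm],
                       channels = m$channels[perm])
  rec_p <- multichannel_recording(rec$data[, perm], rec$fs,
                                  m$channels[perm], t = rec$t,
                                  analytic = rec$analytic[, perm])
  er_p <- energy_report(m_p, build_basis(m_p), rec_p)
  expect_equal(er_p$total, er$total, tolerance = 1e-8)
})

test_that("destabilising coupling is flagged as unstable, not dropped", {
  p <- regime_preset("activated")
  m <- network_model(list(p, p), K = matrix(c(0, 400, 400, 0), 2, 2))
  expect_warning(b <- build_basis(m), "unstable")
  expect_length(b$Omega, 2)
  expect_true(any(b$unstable))
  expect_true(all(b$Omega >= 0))
})

test_that("guards: no limit cycle and zero noise are refused with channel names", {
  p <- regime_preset("activated")
  ps <- regime_preset("suppressed")
  expect_error(build_basis(network_model(list(p, ps))), "ch2")
  expect_error(build_basis(network_model(list(p, preset_d0("activated")))),
               "mass|D")
})

test_that("empirical mode fluctuation spectrum rolls off near the mode frequency", {
  # the projected displacement of a single SL oscillator relaxes at a rate
  # ~= Omega; its Lorentzian PSD should reach half power near Omega/2pi
  p <- regime_preset("activated")
  m <- network_model(list(p))
  b <- build_basis(m)
  rec <- simulate_single(p, sim_config(duration = 60, seed = 81,
                                       decimate_to = 256))
  traj <- project_recording(b, m, rec)
  ps <- welch_psd(matrix(traj$q[, 1]), window_s = 8, fs = 256)
  plateau <- mean(ps[ps$freq > 0 & ps$freq <= 0.25, 2])
  f_half <- ps$freq[ps$freq > 0.25][which(ps[ps$freq > 0.25, 2] <
                                            plateau / 2)[1]]
  expect_gt(f_half, 0.3 * b$Omega / (2 * pi))
  expect_lt(f_half, 3 * b$Omega / (2 * pi))
})
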