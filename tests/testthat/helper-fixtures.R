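# shared fixtures and independent oracles

# noiseless copy of a preset (for deterministic-limit checks)
preset_d0 <- function(name, omega_hz = 10) {
  p <- regime_preset(name, omega_hz = omega_hz)
  oscillator_params(p$lambda, p$zeta, p$chi, p$omega, D = 0)
}

# independent oracle: adaptive ODE integration of the polar equations
# dr/dt = lambda r - zeta r^3, dphi/dt = omega - chi r^2 at D = 0
ode_polar_oracle <- function(params, r0, phi0, times) {
  rhs <- function(t, y, parms) {
    list(c(params$lambda * y[1] - params$zeta * y[1]^3,
           params$omega - params$chi * y[1]^2))
  }
  out <- deSolve::ode(c(r = r0, phi = phi0), times, rhs, NULL,
                      method = "lsoda", rtol = 1e-12, atol = 1e-12)
  data.frame(t = out[, "time"], r = out[, "r"], phi = out[, "phi"])
}

# random orthonormal matrix (QR of a Gaussian matrix, deterministic signs)
random_orthonormal <- function(n) {
  q <- qr.Q(qr(matrix(stats::rnorm(n * n), n)))
  for (l in seq_len(n)) if (q[which.max(abs(q[, l])), l] < 0)
    q[, l] <- -q[, l]
  q
}

# synthetic phonon basis from explicit parts (no dynamical matrix check)
synthetic_basis <- function(masses, Omega, modes,
                            curvatures = masses * Omega^2) {
  phonon_basis(curvatures = curvatures, masses = masses,
               S = matrix(0, length(masses), length(masses)),
               Phi = NULL, modes = modes, Omega = Omega,
               M = as.vector(crossprod(modes^2, masses)))
}

# the two-channel heterogeneous-amplitude pair used for the phase-locking
# prediction: Im K only enters the phase-difference dynamics when the
# equilibrium amplitudes differ
plv_pair_model <- function(k_im) {
  o1 <- oscillator_params(2.0, 1, 0.8, 2 * pi * 10, 0.01)
  o2 <- oscillator_params(0.5, 1, 0.8, 2 * pi * 10, 0.01)
  K <- matrix(c(0, k_im * 1i, k_im * 1i, 0), 2, 2)
  network_model(list(o1, o2), K = K)
}
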