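#' Construct a phonon (normal-mode) basis by hand
#'
#' Low-level constructor used by [build_basis()] and by tests that need a
#' synthetic basis.  Checks orthonormality of the mode matrix and the
#' eigen-residual of the dynamical matrix when one is supplied.
#'
#' @param curvatures Per-channel potential curvatures \eqn{V''(r_e)}.
#' @param masses Per-channel effective masses \eqn{m_j = \hbar/2D_j} (s).
#' @param S Symmetric amplitude-coupling matrix \eqn{S_{jk} = -Re K_{jk}}
#'   (1/s).
#' @param Phi Dynamical matrix (1/s^2).
#' @param modes Orthonormal eigenvector matrix, columns are modes.
#' @param Omega Eigenfrequencies (rad/s), ascending, `>= 0`.
#' @param M Mode masses (s).
#' @param unstable Logical per mode: `TRUE` where the underlying
#'   eigenvalue of `Phi` is negative (imaginary frequency); `Omega` then
#'   holds `sqrt(|eigenvalue|)`.
#' @return An object of class `"phonon_basis"`.
#' @export
phonon_basis <- function(curvatures, masses, S, Phi, modes, Omega, M,
                         unstable = rep(FALSE, length(Omega))) {
  n <- length(curvatures)
  stopifnot(length(masses) == n, all(dim(modes) == c(n, n)),
            length(Omega) == n, length(M) == n)
  orth <- crossprod(modes) - diag(n)
  if (max(abs(orth)) > 1e-10)
    stop("mode matrix is not orthonormal (max deviation ",
         format(max(abs(orth))), ")", call. = FALSE)
  if (!is.null(Phi)) {
    ev <- Omega^2 * ifelse(unstable, -1, 1)
    resid <- Phi %*% modes - modes %*% diag(ev, n)
    if (max(abs(resid)) > 1e-8)
      stop("modes do not diagonalise Phi (residual ",
           format(max(abs(resid))), ")", call. = FALSE)
  }
  structure(list(curvatures = curvatures, masses = masses, S = S,
                 Phi = Phi, modes = modes, Omega = Omega, M = M,
                 unstable = unstable),
            class = "phonon_basis")
}

#' @export
print.phonon_basis <- function(x, ...) {
  cat(sprintf("<phonon_basis> %d mode(s); Omega = %s rad/s%s\n",
              length(x$Omega),
              paste(signif(x$Omega, 5), collapse = ", "),
              if (any(x$unstable)) sprintf(" (%d unstable)",
                                           sum(x$unstable)) else ""))
  invisible(x)
}

#' Build the neural-phonon basis of a network model
#'
#' Expands the effective amplitude Hamiltonian to second order about the
#' limit-cycle amplitudes and diagonalises the mass-weighted dynamical
#' matrix
#' \deqn{\Phi_{jj} = \frac{1}{m_j}\Big(V''(r_j^e) + \sum_{k\ne j} S_{jk}\Big),
#'   \qquad \Phi_{jk} = -\frac{S_{jk}}{\sqrt{m_j m_k}},}
#' with site masses \eqn{m_j = \hbar/2D_j} and amplitude coupling
#' \eqn{S_{jk} = -\mathrm{Re}\,K_{jk}}.  Eigenpairs
#' \eqn{\Phi v^{(\ell)} = \Omega_\ell^2 v^{(\ell)}} define the phonon
#' modes: spatial patterns \eqn{v^{(\ell)}}, eigenfrequencies
#' \eqn{\Omega_\ell} (sorted ascending) and mode masses
#' \eqn{M_\ell = \sum_j m_j (v_j^{(\ell)})^2}.  The number of modes always
#' equals the number of channels.  Negative eigenvalues (possible when the
#' coupling destabilises the harmonic expansion) are flagged as unstable
#' modes with \eqn{\Omega = \sqrt{|\Omega^2|}}, not dropped.
#'
#' Eigenvectors are sign-fixed deterministically: the first component of
#' each mode exceeding 1e-8 in magnitude is made positive.
#'
#' @param model A [network_model()] in which every oscillator has
#'   `lambda > 0` (a limit cycle at every site) and `D > 0`.
#' @return A [phonon_basis()].
#' @export
build_basis <- function(model) {
  stopifnot(inherits(model, "network_model"))
  pv <- .param_vectors(model)
  n <- length(model$oscillators)
  bad <- which(pv$lambda <= 0)
  if (length(bad) > 0)
    stop("no limit cycle at channel(s) ",
         paste(model$channels[bad], collapse = ", "),
         ": the harmonic expansion requires lambda > 0 everywhere",
         call. = FALSE)
  if (any(pv$D <= 0))
    stop("infinite effective mass: D must be > 0 at every channel",
         call. = FALSE)
  hbar <- model$hbar
  curv <- vapply(model$oscillators, potential_curvature, 0, hbar = hbar)
  m <- hbar / (2 * pv$D)
  S <- -Re(model$K)
  Phi <- -S / sqrt(outer(m, m))
  diag(Phi) <- (curv + rowSums(S) - diag(S)) / m
  Phi <- (Phi + t(Phi)) / 2  # symmetrise against rounding
  eig <- eigen(Phi, symmetric = TRUE)
  ord <- order(eig$values)
  ev <- eig$values[ord]
  V <- eig$vectors[, ord, drop = FALSE]
  # deterministic sign convention
  for (l in seq_len(n)) {
    first <- which(abs(V[, l]) > 1e-8)[1]
    if (!is.na(first) && V[first, l] < 0) V[, l] <- -V[, l]
  }
  unstable <- ev < 0
  if (any(unstable))
    warning(sum(unstable), " unstable mode(s): negative eigenvalue of the ",
            "dynamical matrix (imaginary frequency)", call. = FALSE)
  Omega <- sqrt(abs(ev))
  M <- as.vector(crossprod(V^2, m))
  phonon_basis(curvatures = curv, masses = m, S = S, Phi = Phi,
               modes = V, Omega = Omega, M = M, unstable = unstable)
}

#' Mode masses of a phonon basis
#'
#' \eqn{M_\ell = \sum_j m_j (v_j^{(\ell)})^2}: the collective inertia of
#' mode \eqn{\ell}, a polarisation-weighted sum of the site masses.  When
#' all site masses are equal to `m`, orthonormality forces
#' \eqn{M_\ell = m} for every mode.
#'
#' @param basis A [phonon_basis()].
#' @return Numeric vector of mode masses (s).
#' @export
mode_masses <- function(basis) {
  stopifnot(inherits(basis, "phonon_basis"))
  as.vector(crossprod(basis$modes^2, basis$masses))
}

#' Isolated (curvature-weighted) mode frequency
#'
#' \eqn{\Omega_\ell^2 = M_\ell^{-1} \sum_j V''(r_j^e)(v_j^{(\ell)})^2},
#' the frequency a mode would have from local curvature alone.  Equals
#' the eigenfrequency exactly when the coupling matrix `S` is zero.
#'
#' @param basis A [phonon_basis()].
#' @param ell Mode index (1-based).
#' @return Frequency in rad/s.
#' @export
isolated_mode_frequency <- function(basis, ell) {
  stopifnot(inherits(basis, "phonon_basis"),
            ell >= 1, ell <= length(basis$Omega))
  v <- basis$modes[, ell]
  sqrt(sum(basis$curvatures * v^2) / basis$M[ell])
}

# amplitude envelope of a recording: simulator state if retained,
# otherwise the magnitude of the full-band analytic transform
.envelope_matrix <- function(recording) {
  if (!is.null(recording$analytic)) return(Mod(recording$analytic))
  apply(recording$data, 2, function(x) Mod(.analytic(x)))
}

#' Project a recording onto the phonon modes
#'
#' Inverts the mode-superposition relation
#' \eqn{r_j(t) = r_j^e + \sum_\ell v_j^{(\ell)} m_j^{-1/2} q_\ell(t)} to
#' recover the mode displacements
#' \eqn{q_\ell(t) = \sum_j v_j^{(\ell)} \sqrt{m_j}\,\delta r_j(t)} from
#' the amplitude-envelope fluctuations \eqn{\delta r_j = r_j - r_j^e}.
#' Conjugate momenta are estimated as \eqn{p_\ell = M_\ell \dot q_\ell}
#' (central differences).  By orthonormality the round trip
#' project-then-reconstruct is exact to numerical precision.
#'
#' @param basis A [phonon_basis()] built from `model`.
#' @param model The [network_model()].
#' @param recording A `multichannel_recording` whose channels match the
#'   model.
#' @return An object of class `"mode_trajectory"`: matrices `q` and `p`
#'   (T x N_modes), `fs`, and per-mode occupations `occupation` (clipped
#'   at 0) with the raw estimates in `occupation_raw`.
#' @export
project_recording <- function(basis, model, recording) {
  stopifnot(inherits(basis, "phonon_basis"),
            inherits(model, "network_model"),
            inherits(recording, "multichannel_recording"))
  if (!identical(recording$channels, model$channels))
    stop("recording channels do not match model channels", call. = FALSE)
  pv <- .param_vectors(model)
  re <- ifelse(pv$lambda > 0, sqrt(pv$lambda / pv$zeta), 0)
  env <- .envelope_matrix(recording)
  dr <- sweep(env, 2, re)
  q <- dr %*% sweep(basis$modes, 1, sqrt(basis$masses), `*`)
  p <- apply(q, 2, .central_diff, dx = 1 / recording$fs)
  p <- sweep(p, 2, basis$M, `*`)
  occ <- mode_occupation_qp(q, p, basis, model$hbar)
  structure(list(q = q, p = p, fs = recording$fs,
                 occupation = pmax(occ, 0), occupation_raw = occ),
            class = "mode_trajectory")
}

.central_diff <- function(x, dx) {
  n <- length(x)
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / dx
  d[n] <- (x[n] - x[n - 1]) / dx
  if (n > 2) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dx)
  d
}

#' Reconstruct channel amplitude envelopes from mode displacements
#'
#' Inverse of [project_recording()]: returns
#' \eqn{r_j(t) = r_j^e + \sum_\ell v_j^{(\ell)} m_j^{-1/2} q_\ell(t)}.
#'
#' @param basis A [phonon_basis()].
#' @param model The matching [network_model()].
#' @param q T x N_modes matrix of mode displacements.
#' @return T x N matrix of amplitudes.
#' @export
reconstruct_amplitudes <- function(basis, model, q) {
  pv <- .param_vectors(model)
  re <- ifelse(pv$lambda > 0, sqrt(pv$lambda / pv$zeta), 0)
  dr <- q %*% t(sweep(basis$modes, 1, sqrt(basis$masses), `/`))
  sweep(dr, 2, re, `+`)
}

# classical energy estimator per mode from (q, p) series
mode_occupation_qp <- function(q, p, basis, hbar) {
  E <- colMeans(p^2) / (2 * basis$M) +
    0.5 * basis$M * basis$Omega^2 * colMeans(q^2)
  n <- E / (hbar * basis$Omega) - 0.5
  n[basis$Omega <= 0] <- NA_real_
  n
}

#' Estimate phonon occupations from a mode trajectory
#'
#' Classical estimator: each mode's mean energy
#' \eqn{E_\ell = \langle p^2\rangle/2M_\ell +
#' \tfrac12 M_\ell \Omega_\ell^2 \langle q^2\rangle} is converted to an
#' occupation \eqn{n_\ell = E_\ell/\hbar\Omega_\ell - 1/2}.  Raw values
#' can fall below 0 for fluctuations below the zero-point level; the
#' clipped value is reported with the raw estimate attached.  Modes with
#' \eqn{\Omega_\ell = 0} are excluded with a warning.
#'
#' @param mode_traj A `"mode_trajectory"` from [project_recording()], or a
#'   list with matrices `q` and `p`.
#' @param basis The [phonon_basis()].
#' @param hbar Fluctuation scale (uV s).
#' @return Numeric vector of occupations (clipped at 0), with attribute
#'   `"raw"`.
#' @export
mode_occupation <- function(mode_traj, basis, hbar) {
  stopifnot(inherits(basis, "phonon_basis"))
  raw <- mode_occupation_qp(mode_traj$q, mode_traj$p, basis, hbar)
  if (anyNA(raw))
    warning("mode(s) with Omega = 0 excluded from occupation estimate",
            call. = FALSE)
  structure(pmax(raw, 0), raw = raw)
}

#' Energy accounting for a recording under the neural Hamiltonian
#'
#' Splits the total energy of a recording into the three additive terms
#' of the neural Hamiltonian:
#' \itemize{
#'   \item `amplitude_term`: \eqn{\sum_\ell \hbar\Omega_\ell
#'     (\langle n_\ell\rangle + 1/2)} over the phonon modes, using the
#'     clipped occupation estimates (\eqn{n \ge 0}) so the term is bounded
#'     below by the zero-point energy \eqn{\sum_\ell \hbar\Omega_\ell/2};
#'   \item `phase_term`: \eqn{\sum_j \langle p_{\phi_j}\rangle^2/2I_j -
#'     f_\phi(r_j^e)\langle p_{\phi_j}\rangle} with moment of inertia
#'     \eqn{I_j = m_j r_{e,j}^2} evaluated at equilibrium and
#'     \eqn{\langle p_{\phi_j}\rangle = I_j \langle\dot\phi_j\rangle}
#'     estimated from unwrapped phase differences;
#'   \item `coupling_term`: \eqn{-\sum_{j<k} J_{jk}
#'     \langle\cos(\phi_j-\phi_k)\rangle} with Josephson strengths
#'     \eqn{J_{jk} = -\tfrac12 r_{e,j} r_{e,k}\,\mathrm{Im}\,K_{jk}}
#'     evaluated at the equilibrium amplitudes.  The time-averaged cosine
#'     equals the real part of the pairwise phase-locking statistic.
#' }
#'
#' @param model A [network_model()] (all `lambda > 0`).
#' @param basis The matching [phonon_basis()].
#' @param recording A `multichannel_recording` with analytic phases
#'   available (simulated recordings retain them; otherwise the full-band
#'   analytic transform is used).
#' @return A list of class `"energy_report"` with the three terms and
#'   their `total`.
#' @export
energy_report <- function(model, basis, recording) {
  stopifnot(inherits(model, "network_model"),
            inherits(basis, "phonon_basis"),
            inherits(recording, "multichannel_recording"))
  pv <- .param_vectors(model)
  hbar <- model$hbar
  re <- ifelse(pv$lambda > 0, sqrt(pv$lambda / pv$zeta), 0)

  traj <- project_recording(basis, model, recording)
  amp <- sum(hbar * basis$Omega * (traj$occupation + 0.5), na.rm = TRUE)

  za <- if (!is.null(recording$analytic)) recording$analytic else
    apply(recording$data, 2, .analytic)
  phases <- apply(Arg(za), 2, .unwrap_phase)
  phidot <- apply(phases, 2, .central_diff, dx = 1 / recording$fs)
  m <- basis$masses
  I <- m * re^2
  p_phi <- I * colMeans(phidot)
  f_phi <- pv$omega - pv$chi * re^2
  phase <- sum(p_phi^2 / (2 * I) - f_phi * p_phi)

  J <- -0.5 * outer(re, re) * Im(model$K)
  coupling <- 0
  n <- length(re)
  if (n > 1) {
    for (j in seq_len(n - 1)) for (k in (j + 1):n) {
      if (J[j, k] != 0) {
        coupling <- coupling -
          J[j, k] * mean(cos(phases[, j] - phases[, k]))
      }
    }
  }
  structure(list(amplitude_term = amp, phase_term = phase,
                 coupling_term = coupling,
                 total = amp + phase + coupling),
            class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf(paste0("<energy_report> amplitude=%.6g  phase=%.6g  ",
                     "coupling=%.6g  total=%.6g\n"),
              x$amplitude_term, x$phase_term, x$coupling_term, x$total))
  invisible(x)
}

.unwrap_phase <- function(phi) {
  d <- diff(phi)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(phi[1], d))
}
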