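#' Default spectral damping for a model
#'
#' The undamped Green's-function spectrum has non-integrable poles at the
#' mode frequencies; a per-mode damping `gamma` regularises it.  The
#' default is the linearised amplitude relaxation rate \eqn{2\lambda} of
#' the site-averaged oscillator.
#'
#' @param model A [network_model()].
#' @return Damping rate (1/s).
#' @export
default_gamma <- function(model) {
  pv <- .param_vectors(model)
  2 * mean(pv$lambda)
}

#' Closed-form phonon mode power spectra
#'
#' Each phonon mode responds to the projected noise as a driven harmonic
#' oscillator with Green's function \eqn{G_\ell(\omega) =
#' (\Omega_\ell^2 - \omega^2)^{-1}} and flat noise floor \eqn{2\hbar},
#' giving the regularised spectrum
#' \deqn{S_{q_\ell}(\omega) = \frac{2\hbar}
#'   {(\Omega_\ell^2 - \omega^2)^2 + \gamma^2\omega^2}.}
#' The undamped form is recovered pointwise away from resonance as
#' \eqn{\gamma \to 0}; at resonance the regularised value is
#' \eqn{2\hbar/(\gamma^2\Omega_\ell^2)}.
#'
#' @param basis A [phonon_basis()].
#' @param hbar Fluctuation scale (uV s).
#' @param freq_hz Positive frequency grid (Hz); converted to rad/s
#'   internally.
#' @param gamma Damping rate(s), 1/s; scalar or one per mode; must be
#'   positive (the undamped spectrum diverges at resonance).
#' @return Matrix `length(freq_hz)` x N_modes of spectral densities.
#' @export
mode_psd <- function(basis, hbar, freq_hz, gamma) {
  stopifnot(inherits(basis, "phonon_basis"), all(freq_hz >= 0))
  if (any(gamma <= 0))
    stop("gamma must be > 0: the undamped spectrum diverges at resonance",
         call. = FALSE)
  n <- length(basis$Omega)
  gamma <- rep_len(gamma, n)
  w <- 2 * pi * freq_hz
  out <- matrix(NA_real_, length(w), n)
  for (l in seq_len(n)) {
    out[, l] <- 2 * hbar /
      ((basis$Omega[l]^2 - w^2)^2 + gamma[l]^2 * w^2)
  }
  colnames(out) <- paste0("mode", seq_len(n))
  out
}

#' Closed-form cross-spectral matrix
#'
#' Superposes the mode spectra through the eigenvector loadings and site
#' masses:
#' \deqn{S_{jk}(\omega) = \sum_\ell
#'   \frac{v_j^{(\ell)} v_k^{(\ell)}}{\sqrt{m_j m_k}}
#'   S_{q_\ell}(\omega).}
#' The result is real-symmetric and positive semidefinite at every
#' frequency (it is a nonnegative mixture of rank-1 terms).
#'
#' @inheritParams mode_psd
#' @param model The matching [network_model()] (provides site masses).
#' @return A 3-d array N x N x `length(freq_hz)`, with `dimnames` on the
#'   frequency axis.
#' @export
cross_spectrum <- function(basis, model, hbar, freq_hz, gamma) {
  stopifnot(inherits(model, "network_model"))
  sq <- mode_psd(basis, hbar, freq_hz, gamma)
  m <- basis$masses
  V <- sweep(basis$modes, 1, sqrt(m), `/`)   # v_j / sqrt(m_j)
  n <- nrow(V)
  out <- array(0, dim = c(n, n, length(freq_hz)),
               dimnames = list(model$channels, model$channels,
                               signif(freq_hz, 8)))
  for (f in seq_along(freq_hz)) {
    out[, , f] <- V %*% (sq[f, ] * t(V))
  }
  out
}

#' Analytic magnitude-squared coherence from a cross-spectral array
#'
#' \eqn{\rho_{jk}(\omega) = |S_{jk}|^2 / (S_{jj} S_{kk})}, bounded in
#' `[0, 1]` by Cauchy-Schwarz, with unit diagonal wherever the
#' autospectrum is positive.  Entries whose autospectra vanish are masked
#' as `NA` rather than propagated as `NaN`.
#'
#' @param S N x N x F cross-spectral array from [cross_spectrum()].
#' @return Array of the same shape with coherences.
#' @export
analytic_coherence <- function(S) {
  stopifnot(length(dim(S)) == 3)
  n <- dim(S)[1]
  out <- S
  for (f in seq_len(dim(S)[3])) {
    auto <- diag(S[, , f])
    denom <- outer(auto, auto)
    rho <- abs(S[, , f])^2 / denom
    rho[denom <= 0] <- NA_real_
    out[, , f] <- rho
  }
  out
}

#' Analytic amplitude-envelope correlation matrix
#'
#' Envelope co-modulation predicted from shared mode loadings:
#' the raw quantity is
#' \deqn{\mathrm{AAC}_{jk} = \sum_\ell
#'   \frac{v_j^{(\ell)} v_k^{(\ell)}}{m_j m_k} \langle q_\ell^2\rangle,}
#' with \eqn{\langle q_\ell^2\rangle} defaulting to the zero-point value
#' \eqn{\hbar/2M_\ell\Omega_\ell} unless mode displacement variances are
#' supplied (e.g. from a [project_recording()] trajectory).  Because a
#' correlation must lie in `[-1, 1]`, the raw matrix is also normalised
#' symmetrically to unit diagonal; both forms are returned.
#'
#' @param basis A [phonon_basis()].
#' @param model The matching [network_model()].
#' @param q2 Optional per-mode displacement variances
#'   \eqn{\langle q_\ell^2\rangle}.
#' @return A list with `raw` (the mode-sum) and `corr` (normalised to
#'   diagonal 1).
#' @export
analytic_aac <- function(basis, model, q2 = NULL) {
  stopifnot(inherits(basis, "phonon_basis"),
            inherits(model, "network_model"))
  hbar <- model$hbar
  if (is.null(q2)) {
    q2 <- hbar / (2 * basis$M * basis$Omega)
    q2[basis$Omega <= 0] <- 0
  }
  m <- basis$masses
  V <- sweep(basis$modes, 1, m, `/`)   # v_j / m_j
  raw <- V %*% (q2 * t(V))
  d <- diag(raw)
  denom <- sqrt(outer(d, d))
  corr <- raw / denom
  corr[denom <= 0] <- NA_real_
  dimnames(raw) <- dimnames(corr) <- list(model$channels, model$channels)
  list(raw = raw, corr = corr)
}

#' First-order phase-amplitude coupling strength
#'
#' Linearising the amplitude-modulated phase velocity
#' \eqn{\dot\phi \approx \omega - \chi r_e^2 - 2\chi r_e\, q(t)} about the
#' limit cycle gives the coefficient \eqn{2\chi r_e} coupling amplitude
#' fluctuations to phase velocity; PAC strength is proportional to it and
#' vanishes iff \eqn{\chi = 0}.
#'
#' @param params An [oscillator_params()] with `lambda > 0`.
#' @return Modulation slope \eqn{2\chi r_e}.
#' @export
pac_strength <- function(params) {
  stopifnot(inherits(params, "oscillator_params"))
  if (params$lambda <= 0)
    stop("pac_strength requires a limit cycle (lambda > 0)", call. = FALSE)
  2 * params$chi * equilibrium_amplitude(params)
}

#' 1/f spectral background
#'
#' Additive broadband background `amplitude / omega` (with
#' \eqn{\omega = 2\pi f}) modelling the high-temperature occupation of an
#' ensemble of incoherent modes.  `amplitude = 0` disables the term; a
#' 0 Hz bin is masked as `NA`.
#'
#' @param amplitude Nonnegative background scale.
#' @param freq_hz Frequency grid (Hz).
#' @return Vector of background spectral values.
#' @export
one_over_f_background <- function(amplitude, freq_hz) {
  stopifnot(amplitude >= 0)
  out <- amplitude / (2 * pi * freq_hz)
  out[freq_hz == 0] <- NA_real_
  out
}
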