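#' Network of coupled Stuart-Landau oscillators
#'
#' A network model is a list of per-channel [oscillator_params()] plus a
#' complex coupling matrix `K` (1/s) entering each oscillator as the
#' diffusive term \eqn{\sum_k K_{jk}(z_k - z_j)}, and a shared fluctuation
#' scale `hbar`.  Bidirectional equivalence of the coupling is assumed:
#' `K` must be (complex-) symmetric, `K[j,k] == K[k,j]`, with zero
#' diagonal.  The real part of `K` exchanges amplitude between sites; the
#' imaginary part couples the phases (Josephson-like cosine interaction
#' with strength \eqn{J_{jk} = -\tfrac12 r_j r_k \,\mathrm{Im}\,K_{jk}}).
#'
#' @param oscillators A list of `oscillator_params`, one per channel.
#' @param K Complex (or real) N x N coupling matrix, 1/s.  Defaults to the
#'   zero matrix (uncoupled network).
#' @param hbar Fluctuation scale (uV s), default 1.
#' @param channels Optional channel names; default `"ch1" ... "chN"`.
#' @return An object of class `"network_model"`.
#' @export
network_model <- function(oscillators, K = NULL, hbar = 1,
                          channels = NULL) {
  if (inherits(oscillators, "oscillator_params"))
    oscillators <- list(oscillators)
  stopifnot(length(oscillators) >= 1,
            all(vapply(oscillators, inherits, TRUE, "oscillator_params")))
  n <- length(oscillators)
  if (is.null(K)) K <- matrix(0, n, n)
  K <- as.matrix(K)
  if (!all(dim(K) == c(n, n)))
    stop("K must be ", n, " x ", n, call. = FALSE)
  storage.mode(K) <- "complex"
  bad <- which(abs(K - t(K)) > 1e-12, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("K must be symmetric (K[j,k] == K[k,j]); offending entries: ",
         paste(sprintf("(%d,%d)", bad[, 1], bad[, 2]), collapse = ", "),
         call. = FALSE)
  if (any(abs(diag(K)) > 0)) stop("K must have zero diagonal", call. = FALSE)
  if (hbar <= 0) stop("hbar must be > 0", call. = FALSE)
  if (is.null(channels)) channels <- paste0("ch", seq_len(n))
  stopifnot(length(channels) == n)
  structure(list(oscillators = oscillators, K = K, hbar = hbar,
                 channels = channels),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("<network_model> %d channel(s), hbar=%g uV s, mean|K|=%g /s\n",
              length(x$oscillators), x$hbar,
              mean(abs(x$K[upper.tri(x$K)]))))
  invisible(x)
}

# per-oscillator parameter vectors, for vectorised drift evaluation
.param_vectors <- function(model) {
  list(lambda = vapply(model$oscillators, `[[`, 0, "lambda"),
       zeta   = vapply(model$oscillators, `[[`, 0, "zeta"),
       chi    = vapply(model$oscillators, `[[`, 0, "chi"),
       omega  = vapply(model$oscillators, `[[`, 0, "omega"),
       D      = vapply(model$oscillators, `[[`, 0, "D"))
}

#' Simulation configuration
#'
#' @param dt Integration step (s).  Default 1/2048 s.
#' @param duration Total simulated time (s).
#' @param seed Integer seed; all randomness (initial phases and noise
#'   increments) is drawn from one stream seeded here, so identical
#'   `(model, config)` pairs reproduce identical recordings.
#' @param scheme `"heun"` (Euler-Heun, Stratonovich-consistent; default)
#'   or `"euler"` (Euler-Maruyama).  For the additive noise used here the
#'   two schemes share the same noise treatment and differ only in the
#'   drift update.
#' @param decimate_to Optional output rate (Hz).  When given, channels are
#'   low-pass filtered (4th-order Butterworth at 0.8x the target Nyquist,
#'   applied forward and backward with `signal::filtfilt`, i.e. an
#'   8th-order zero-phase magnitude response) and subsampled; `1/dt` must
#'   be an integer multiple of the target rate.
#' @param initial Optional list with elements `r` and `phi` (vectors, one
#'   per channel) overriding the defaults: amplitudes start at the
#'   equilibrium amplitude (0.1 uV where no limit cycle exists) and phases
#'   are drawn uniformly on `[0, 2*pi)` from the seeded stream.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(dt = 1 / 2048, duration = 10, seed = 1L,
                       scheme = c("heun", "euler"), decimate_to = NULL,
                       initial = NULL) {
  scheme <- match.arg(scheme)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (duration < dt) stop("duration must be >= dt", call. = FALSE)
  if (!is.null(decimate_to)) {
    fac <- (1 / dt) / decimate_to
    if (abs(fac - round(fac)) > 1e-9 || fac < 1)
      stop("1/dt must be an integer multiple of decimate_to", call. = FALSE)
  }
  structure(list(dt = dt, duration = duration, seed = as.integer(seed),
                 scheme = scheme, decimate_to = decimate_to,
                 initial = initial),
            class = "sim_config")
}

# fastest local relaxation rate; coupling row sums added so that strongly
# coupled networks tighten the step bound too
.stability_rate <- function(model) {
  pv <- .param_vectors(model)
  re2 <- ifelse(pv$lambda > 0, pv$lambda / pv$zeta, 0)
  max(abs(pv$lambda) + 3 * pv$zeta * re2 + rowSums(abs(model$K)))
}

#' Simulate a network of coupled stochastic Stuart-Landau oscillators
#'
#' Integrates
#' \deqn{dz_j = \left[(\lambda_j + i\omega_j) z_j -
#'   (\zeta_j + i\chi_j)|z_j|^2 z_j + \sum_k K_{jk}(z_k - z_j)\right] dt
#'   + dW_j}
#' in Cartesian complex coordinates (avoiding the 1/r singularity of the
#' polar noise term), with independent complex Wiener increments whose
#' real and imaginary parts each have variance \eqn{D_j\,dt} per step
#' (the convention \eqn{\langle\eta\eta^*\rangle = 2D\delta}).  The
#' default Euler-Heun scheme is Stratonovich-consistent; for additive
#' noise it coincides with Euler-Maruyama in the noise term.
#'
#' @param model A [network_model()].
#' @param config A [sim_config()].  The step is refused (with a suggested
#'   value) if `dt` exceeds one tenth of the fastest relaxation time
#'   \eqn{\max_j(|\lambda_j| + 3\zeta_j r_{e,j}^2 + \sum_k |K_{jk}|)^{-1}}.
#' @return A `multichannel_recording`: real voltages `data` (T x N matrix,
#'   `Re z`), the complex states in `analytic`, sampling rate `fs`, time
#'   vector `t`, channel names, and provenance in `meta`.
#' @seealso [simulate_single()], [make_fixture()]
#' @export
simulate_network <- function(model, config) {
  stopifnot(inherits(model, "network_model"), inherits(config, "sim_config"))
  pv <- .param_vectors(model)
  n <- length(model$oscillators)
  dt <- config$dt
  dt_max <- 0.1 / .stability_rate(model)
  if (dt > dt_max)
    stop(sprintf("dt = %g s is unstable for this model; use dt <= %g s",
                 dt, dt_max), call. = FALSE)
  n_steps <- round(config$duration / dt)

  K <- model$K
  coupled <- any(abs(K) > 0)
  k_rows <- rowSums(K)

  ab <- complex(real = pv$lambda, imaginary = pv$omega)
  cd <- complex(real = pv$zeta, imaginary = pv$chi)
  drift <- function(z) {
    f <- ab * z - cd * (Re(z)^2 + Im(z)^2) * z
    if (coupled) f <- f + as.vector(K %*% z) - k_rows * z
    f
  }

  set.seed(config$seed)
  # draw order is part of the contract: initial phases first, then one
  # block of 2N Gaussian deviates per step
  if (is.null(config$initial)) {
    re <- ifelse(pv$lambda > 0, sqrt(pv$lambda / pv$zeta), 0.1)
    phi0 <- stats::runif(n, 0, 2 * pi)
    z <- complex(modulus = re, argument = phi0)
  } else {
    stopifnot(length(config$initial$r) == n,
              length(config$initial$phi) == n)
    z <- complex(modulus = config$initial$r,
                 argument = config$initial$phi)
  }

  sig <- sqrt(pv$D * dt)
  noise <- matrix(stats::rnorm(2L * n * n_steps), nrow = 2L * n)
  heun <- config$scheme == "heun"

  out <- matrix(NA_complex_, nrow = n_steps + 1L, ncol = n)
  out[1L, ] <- z
  idx_re <- seq_len(n); idx_im <- n + seq_len(n)
  for (s in seq_len(n_steps)) {
    dw <- complex(real = sig * noise[idx_re, s],
                  imaginary = sig * noise[idx_im, s])
    f0 <- drift(z)
    if (heun) {
      zp <- z + f0 * dt + dw
      z <- z + 0.5 * dt * (f0 + drift(zp)) + dw
    } else {
      z <- z + f0 * dt + dw
    }
    out[s + 1L, ] <- z
  }

  t_grid <- seq.int(0L, n_steps) * dt
  fs <- 1 / dt
  if (!is.null(config$decimate_to)) {
    dec <- .decimate_complex(out, fs, config$decimate_to)
    out <- dec
    fac <- as.integer(round(fs / config$decimate_to))
    keep <- seq.int(1L, n_steps + 1L, by = fac)
    t_grid <- t_grid[keep]
    fs <- config$decimate_to
  }

  multichannel_recording(
    data = Re(out), fs = fs, channels = model$channels, t = t_grid,
    analytic = out,
    meta = list(seed = config$seed, dt = dt, scheme = config$scheme,
                duration = config$duration,
                decimate_to = config$decimate_to,
                model_hash = model_hash(model)))
}

# zero-phase Butterworth low-pass + subsample, applied to Re and Im parts
.decimate_complex <- function(x, fs, target_fs) {
  fac <- as.integer(round(fs / target_fs))
  bf <- signal::butter(4, 0.8 * target_fs / fs, type = "low")
  keep <- seq.int(1L, nrow(x), by = fac)
  res <- matrix(NA_complex_, nrow = length(keep), ncol = ncol(x))
  for (j in seq_len(ncol(x))) {
    fr <- signal::filtfilt(bf, Re(x[, j]))
    fi <- signal::filtfilt(bf, Im(x[, j]))
    res[, j] <- complex(real = fr[keep], imaginary = fi[keep])
  }
  res
}

#' Simulate a single stochastic Stuart-Landau oscillator
#'
#' Degenerate single-channel case of [simulate_network()]; the same seeded
#' stream is used, so an N = 1 network with zero coupling produces
#' bit-identical samples.
#'
#' @param params An [oscillator_params()].
#' @param config A [sim_config()].
#' @param hbar Fluctuation scale recorded with the model (uV s).
#' @return A `multichannel_recording` with one channel.
#' @export
simulate_single <- function(params, config, hbar = 1) {
  simulate_network(network_model(list(params), hbar = hbar), config)
}

#' Multichannel recording container
#'
#' @param data T x N real matrix of voltages (uV).
#' @param fs Sampling rate (Hz).
#' @param channels Channel names (length N).
#' @param t Optional time vector (s); defaults to `(0:(T-1))/fs`.
#' @param analytic Optional T x N complex matrix of analytic samples.
#' @param meta Provenance list (model hash, seed, config).
#' @return An object of class `"multichannel_recording"`.
#' @export
multichannel_recording <- function(data, fs, channels, t = NULL,
                                   analytic = NULL, meta = list()) {
  data <- as.matrix(data)
  stopifnot(fs > 0, length(channels) == ncol(data))
  if (is.null(t)) t <- (seq_len(nrow(data)) - 1L) / fs
  stopifnot(length(t) == nrow(data))
  colnames(data) <- channels
  structure(list(data = data, fs = fs, channels = channels, t = t,
                 analytic = analytic, meta = meta),
            class = "multichannel_recording")
}

#' @export
print.multichannel_recording <- function(x, ...) {
  cat(sprintf("<multichannel_recording> %d channel(s) x %d samples @ %g Hz (%.3g s)\n",
              ncol(x$data), nrow(x$data), x$fs, nrow(x$data) / x$fs))
  invisible(x)
}

#' Build a seeded test fixture for a named regime
#'
#' Constructs an N-channel network in which every oscillator carries the
#' named regime's parameters, couples the channels on a ring lattice with
#' complex coupling \eqn{K = c\,(1 + i)/\sqrt 2} (so `coupling_strength`
#' is the modulus `|K|` on each ring edge), and returns the model together
#' with a seeded recording.
#'
#' @param regime_name One of [regime_names()].
#' @param n_channels Number of channels (N >= 1).
#' @param coupling_strength Ring-edge coupling modulus, 1/s; 0 gives the
#'   zero matrix.
#' @param seed Integer seed.
#' @param duration Recording length (s), default 10.
#' @param omega_hz Intrinsic frequency (Hz), default 10.
#' @param decimate_to Output rate (Hz), default 256.
#' @return A list with elements `model` (a `network_model`) and
#'   `recording` (a `multichannel_recording`).
#' @export
make_fixture <- function(regime_name, n_channels, coupling_strength, seed,
                         duration = 10, omega_hz = 10, decimate_to = 256) {
  if (!regime_name %in% regime_names())
    stop("unknown regime '", regime_name, "'; valid regimes: ",
         paste(regime_names(), collapse = ", "), call. = FALSE)
  params <- regime_preset(regime_name, omega_hz = omega_hz)
  oscs <- rep(list(params), n_channels)
  K <- matrix(0 + 0i, n_channels, n_channels)
  if (coupling_strength != 0 && n_channels > 1) {
    kval <- coupling_strength * complex(real = 1, imaginary = 1) / sqrt(2)
    edges <- cbind(seq_len(n_channels),
                   c(seq_len(n_channels)[-1], 1L))
    if (n_channels == 2) edges <- edges[1, , drop = FALSE]
    for (e in seq_len(nrow(edges))) {
      i <- edges[e, 1]; j <- edges[e, 2]
      K[i, j] <- K[i, j] + kval
      K[j, i] <- K[j, i] + kval
    }
  }
  model <- network_model(oscs, K = K)
  rec <- simulate_network(model, sim_config(duration = duration, seed = seed,
                                            decimate_to = decimate_to))
  list(model = model, recording = rec)
}

#' Stable hash of a model or config object
#'
#' MD5 of the object's canonical serialisation; used in recording
#' provenance and run manifests.
#' @param x Any R object.
#' @return Character MD5 hash.
#' @export
model_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}
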