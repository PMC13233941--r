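# FFT-based analytic signal (Hilbert transform) of a real series
.analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Conventional EEG frequency bands
#'
#' delta 1-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-80 Hz.
#'
#' @return Named list of `c(f_lo, f_hi)` pairs (Hz).
#' @export
default_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), gamma = c(30, 80))
}

#' Band definition
#'
#' @param name Band label.
#' @param f_lo,f_hi Band edges (Hz), `0 < f_lo < f_hi`.
#' @return A named numeric vector of class `"band_definition"`.
#' @export
band_definition <- function(name, f_lo, f_hi) {
  if (!(f_lo > 0 && f_hi > f_lo))
    stop("band edges must satisfy 0 < f_lo < f_hi", call. = FALSE)
  structure(c(f_lo = f_lo, f_hi = f_hi), name = name,
            class = "band_definition")
}

.as_band <- function(band) {
  if (inherits(band, "band_definition")) return(unname(band))
  if (is.character(band)) {
    b <- default_bands()[[band]]
    if (is.null(b)) stop("unknown band '", band, "'", call. = FALSE)
    return(b)
  }
  stopifnot(is.numeric(band), length(band) == 2)
  unname(band)
}

#' Band-limited analytic signal
#'
#' Zero-phase band-pass (4th-order Butterworth, applied forward and
#' backward with `signal::filtfilt`) followed by the FFT Hilbert
#' transform.  The modulus of the result is the band envelope and the
#' argument the band phase.  The attribute `"trim"` gives the number of
#' edge samples (`6 * fs / f_lo`, six periods of the lower band edge,
#' which bounds the zero-phase filter transient below 0.5% for the
#' default bands) that metric summaries should discard on each side.
#'
#' @param recording A `multichannel_recording`, or a numeric matrix/vector
#'   (then `fs` must be given).
#' @param band Band name from [default_bands()], a `c(f_lo, f_hi)` pair,
#'   or a [band_definition()].
#' @param fs Sampling rate (Hz) when `recording` is a bare matrix.
#' @return Complex T x N matrix with attribute `"trim"`.
#' @export
analytic_band_signal <- function(recording, band, fs = NULL) {
  if (inherits(recording, "multichannel_recording")) {
    x <- recording$data; fs <- recording$fs
  } else {
    x <- as.matrix(recording)
    if (is.null(fs)) stop("fs required for matrix input", call. = FALSE)
  }
  b <- .as_band(band)
  if (b[2] >= fs / 2)
    stop(sprintf("band upper edge %g Hz is at or above Nyquist (%g Hz)",
                 b[2], fs / 2), call. = FALSE)
  bf <- signal::butter(2, b / (fs / 2), type = "pass")
  out <- matrix(NA_complex_, nrow(x), ncol(x))
  for (j in seq_len(ncol(x))) {
    out[, j] <- .analytic(signal::filtfilt(bf, x[, j]))
  }
  colnames(out) <- colnames(x)
  structure(out, trim = ceiling(6 * fs / b[1]), band = b)
}

.trim_rows <- function(z, trim = attr(z, "trim")) {
  if (is.null(trim) || trim <= 0) return(z)
  n <- NROW(z)
  if (2 * trim >= n)
    stop("recording too short to trim filter edges", call. = FALSE)
  if (is.matrix(z)) z[(trim + 1):(n - trim), , drop = FALSE]
  else z[(trim + 1):(n - trim)]
}

#' Welch power spectral density
#'
#' One-sided PSD from Hann-windowed, mean-detrended, 50%-overlapping
#' segments.  Density normalisation: the integral of the PSD over
#' frequency approximates the signal variance.
#'
#' @param recording A `multichannel_recording`, or numeric matrix/vector
#'   with `fs` given.
#' @param window_s Segment length (s), default 2.
#' @param overlap Fractional overlap, default 0.5.
#' @param fs Sampling rate for matrix input.
#' @return A data frame with column `freq` (Hz) and one PSD column per
#'   channel (uV^2/Hz).
#' @export
welch_psd <- function(recording, window_s = 2, overlap = 0.5, fs = NULL) {
  if (inherits(recording, "multichannel_recording")) {
    x <- recording$data; fs <- recording$fs
  } else {
    x <- as.matrix(recording)
    if (is.null(fs)) stop("fs required for matrix input", call. = FALSE)
  }
  L <- round(window_s * fs)
  step <- max(1L, round(L * (1 - overlap)))
  n <- nrow(x)
  if (n < L + step)
    stop(sprintf("recording too short for Welch PSD: need >= %d samples (%.3g s)",
                 L + step, (L + step) / fs), call. = FALSE)
  starts <- seq.int(1L, n - L + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / L))
  scale <- 1 / (fs * sum(w^2))
  nf <- floor(L / 2) + 1L
  psd <- matrix(0, nf, ncol(x))
  for (j in seq_len(ncol(x))) {
    acc <- numeric(nf)
    for (s in starts) {
      seg <- x[s:(s + L - 1L), j]
      seg <- (seg - mean(seg)) * w
      P <- Mod(stats::fft(seg))^2 * scale
      acc <- acc + P[seq_len(nf)]
    }
    acc <- acc / length(starts)
    acc[2:(nf - 1L)] <- 2 * acc[2:(nf - 1L)]  # fold negative frequencies
    psd[, j] <- acc
  }
  out <- data.frame(freq = (seq_len(nf) - 1L) * fs / L)
  ch <- colnames(x)
  if (is.null(ch)) ch <- paste0("ch", seq_len(ncol(x)))
  out[ch] <- split(psd, col(psd))
  out
}

#' Integrated band power
#'
#' Trapezoidal integral of a PSD over a band.
#'
#' @param psd Data frame from [welch_psd()] (`freq` plus channel columns).
#' @param band Band specification as in [analytic_band_signal()].
#' @return Named vector of band powers per channel (uV^2).
#' @export
band_power <- function(psd, band) {
  b <- .as_band(band)
  sel <- psd$freq >= b[1] & psd$freq <= b[2]
  if (!any(sel)) stop("band outside PSD frequency grid", call. = FALSE)
  chans <- setdiff(names(psd), "freq")
  vapply(chans, function(ch) pracma::trapz(psd$freq[sel], psd[[ch]][sel]),
         numeric(1))
}

#' Amplitude-amplitude coupling between two band signals
#'
#' The pointwise envelope product \eqn{|z_j^{(b)}(t)|\,|z_k^{(b')}(t)|}
#' together with the Pearson correlation of the two envelopes as the
#' association summary.
#'
#' @param z1,z2 Complex band signals of equal length (vectors).
#' @return List with `series` and `correlation`.
#' @export
aac <- function(z1, z2) {
  stopifnot(length(z1) == length(z2))
  a1 <- Mod(z1); a2 <- Mod(z2)
  # envelopes constant to numerical precision are treated as degenerate
  const1 <- stats::sd(a1) <= 1e-12 * mean(a1)
  const2 <- stats::sd(a2) <= 1e-12 * mean(a2)
  corr <- if (const1 || const2) {
    if (const1 && const2) 1 else NA_real_
  } else stats::cor(a1, a2)
  list(series = a1 * a2, correlation = corr)
}

#' Phase-amplitude coupling between a slow and a fast band signal
#'
#' The coupling series \eqn{|z^{(b')}(t)| \cos[\arg z^{(b)}(t)]} (slow
#' phase modulating fast amplitude), plus two summaries: `mean`, the time
#' average of the series, and `correlation`, the Pearson correlation
#' between the fast envelope and the phase velocity of the slow signal
#' (unwrapped phase, central differences).  The correlation summary is
#' the model-relevant index: amplitude fluctuations shift the
#' instantaneous frequency in proportion to the amplitude-phase coupling
#' \eqn{\chi}, so its magnitude grows with \eqn{\chi} and vanishes when
#' amplitude and phase dynamics are decoupled.
#'
#' @param z_low Complex band signal providing the phase (lower band).
#' @param z_high Complex band signal providing the envelope (higher band).
#' @param fs Sampling rate (Hz), required for the phase velocity.
#' @param f_low,f_high Optional band centre/edge frequencies; when both
#'   are given, `f_low < f_high` is enforced.
#' @param smooth_s Optional moving-average window (s) applied to both the
#'   envelope and the phase-velocity series before correlating.  The raw
#'   per-sample phase velocity is dominated by the white phase noise,
#'   which dilutes the correlation at high sampling rates; smoothing is
#'   linear in both series, so it sharpens the estimate without biasing
#'   its sign.  Default 0 (no smoothing).
#' @return List with `series`, `mean` and `correlation`.
#' @export
pac <- function(z_low, z_high, fs, f_low = NULL, f_high = NULL,
                smooth_s = 0) {
  stopifnot(length(z_low) == length(z_high))
  if (!is.null(f_low) && !is.null(f_high) && f_low >= f_high)
    stop("band order violation: the phase band must be lower-frequency ",
         "than the amplitude band", call. = FALSE)
  series <- Mod(z_high) * cos(Arg(z_low))
  phi <- .unwrap_phase(Arg(z_low))
  phidot <- .central_diff(phi, dx = 1 / fs)
  env <- Mod(z_high)
  if (smooth_s > 0) {
    k <- max(1L, round(smooth_s * fs))
    env <- as.numeric(stats::filter(env, rep(1 / k, k), sides = 2))
    phidot <- as.numeric(stats::filter(phidot, rep(1 / k, k), sides = 2))
    ok <- !is.na(env) & !is.na(phidot)
    env <- env[ok]; phidot <- phidot[ok]
  }
  corr <- if (stats::sd(env) == 0 || stats::sd(phidot) == 0) 0
          else stats::cor(env, phidot)
  list(series = series, mean = mean(series), correlation = corr)
}

#' Phase-locking value
#'
#' \eqn{\mathrm{PLV} = |\langle e^{i(\arg z_j - \arg z_k)}\rangle_t|},
#' ranging from 0 (no locking) to 1 (perfect synchrony).  Samples where
#' either signal has zero amplitude carry no phase and are excluded; the
#' number of excluded samples is attached as attribute `"excluded"`.
#'
#' @param z1,z2 Complex analytic signals of equal length.
#' @return PLV in `[0, 1]`.
#' @export
plv <- function(z1, z2) {
  stopifnot(length(z1) == length(z2))
  ok <- Mod(z1) > 0 & Mod(z2) > 0
  if (!any(ok)) stop("no samples with defined phase", call. = FALSE)
  val <- Mod(mean(exp(1i * (Arg(z1[ok]) - Arg(z2[ok])))))
  structure(val, excluded = sum(!ok))
}

#' Pairwise phase-locking matrix
#'
#' @param zb Complex T x N matrix of band signals.
#' @return Symmetric N x N matrix with unit diagonal.
#' @export
plv_matrix <- function(zb) {
  n <- ncol(zb)
  out <- diag(1, n)
  if (n > 1) {
    for (j in seq_len(n - 1)) for (k in (j + 1):n) {
      out[j, k] <- out[k, j] <- as.numeric(plv(zb[, j], zb[, k]))
    }
  }
  dimnames(out) <- list(colnames(zb), colnames(zb))
  out
}

#' Empirical coherence matrix of band signals
#'
#' \eqn{\rho_{ij} = |\langle z_i z_j^*\rangle| /
#' \sqrt{\langle|z_i|^2\rangle\langle|z_j|^2\rangle}} with whole-epoch
#' time averages.  Zero-power channels are masked (`NA` row/column).
#'
#' @param zb Complex T x N matrix of band signals (N >= 2).
#' @return Symmetric N x N matrix in `[0, 1]` with unit diagonal.
#' @export
coherence_matrix <- function(zb) {
  stopifnot(ncol(zb) >= 2)
  n <- ncol(zb)
  pow <- colMeans(Mod(zb)^2)
  cross <- crossprod(Conj(zb), zb) / nrow(zb)  # <z_i* z_j>
  out <- Mod(t(cross)) / sqrt(outer(pow, pow))
  out[pow == 0, ] <- NA_real_
  out[, pow == 0] <- NA_real_
  diag(out)[pow > 0] <- 1
  dimnames(out) <- list(colnames(zb), colnames(zb))
  out
}

#' Coherence entropy
#'
#' Shannon entropy (nats) of the normalised pairwise-coherence
#' distribution \eqn{\tilde\rho = \rho / \sum\rho}: low entropy means
#' synchrony concentrated on few pairs, high entropy a dispersed network.
#' By default the sum runs over off-diagonal unordered pairs (the unit
#' self-coherences would otherwise dominate); `pairs = "all"` gives the
#' literal all-entries reading.  Maximum is `log(#pairs)` for a uniform
#' distribution.
#'
#' @param rho Coherence matrix (e.g. from [coherence_matrix()]).
#' @param pairs `"offdiag"` (default) or `"all"`.
#' @return Entropy in nats.
#' @export
coherence_entropy <- function(rho, pairs = c("offdiag", "all")) {
  pairs <- match.arg(pairs)
  vals <- if (pairs == "offdiag") rho[upper.tri(rho)] else as.vector(rho)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0 || sum(vals) <= 0)
    stop("coherence entropy undefined: no positive entries", call. = FALSE)
  p <- vals / sum(vals)
  -sum(ifelse(p > 0, p * log(p), 0))
}

#' Surrogate null bound for a pairwise statistic
#'
#' Circular time-shift surrogates: channel 2 is rotated by a random
#' offset (at least a tenth of the series length) and the statistic is
#' recomputed; the bound is the requested quantile of the surrogate
#' distribution.  Used for "no coupling" claims about PLV, coherence and
#' envelope correlations.
#'
#' @param z1,z2 Complex signals of equal length.
#' @param stat Function of `(z1, z2)` returning a scalar; default [plv()].
#' @param n_surrogates Number of draws (default 200).
#' @param probs Quantile of the null distribution (default 0.95).
#' @param seed Seed for the surrogate offsets.
#' @return The null-bound quantile, with the surrogate values as
#'   attribute `"surrogates"`.
#' @export
surrogate_bound <- function(z1, z2, stat = function(a, b) as.numeric(plv(a, b)),
                            n_surrogates = 200, probs = 0.95, seed = 1L) {
  n <- length(z1)
  set.seed(seed)
  shifts <- sample(seq.int(floor(n / 10), n - floor(n / 10)), n_surrogates,
                   replace = TRUE)
  vals <- vapply(shifts, function(s) {
    z2s <- c(z2[(s + 1):n], z2[1:s])
    stat(z1, z2s)
  }, numeric(1))
  structure(unname(stats::quantile(vals, probs)), surrogates = vals)
}
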