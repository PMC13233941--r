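# numeric formatting used for all CSV output: 17 significant digits,
# '.' decimal, no grouping -- round-trips float64 losslessly
.fmt17 <- function(x) formatC(x, digits = 17, format = "g")

#' Write a recording as CSV plus JSON sidecar
#'
#' The CSV holds a `time_s` column followed by one column per channel
#' (uV), written with 17 significant digits so that a write-read round
#' trip is bit-exact.  The sidecar `<path>.json` records
#' `{fs_hz, channels, units, seed, model_hash}`.
#'
#' @param recording A `multichannel_recording`.
#' @param path Output CSV path; the sidecar is written next to it.
#' @return Invisibly, the two file paths.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "multichannel_recording"))
  df <- data.frame(time_s = .fmt17(recording$t))
  for (ch in recording$channels)
    df[[ch]] <- .fmt17(recording$data[, ch])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  meta <- list(fs_hz = recording$fs, channels = recording$channels,
               units = "uV",
               seed = recording$meta$seed,
               model_hash = recording$meta$model_hash)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(csv = path, sidecar = sidecar))
}

#' Read a recording written by [write_recording()]
#'
#' Requires the JSON sidecar; the sampling rate it declares is
#' cross-checked against the median time step of the CSV to 1 ppm.
#'
#' @param path CSV path.
#' @return A `multichannel_recording` (without analytic samples).
#' @export
read_recording <- function(path) {
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (!file.exists(sidecar))
    stop("missing JSON sidecar: ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "numeric")
  if (names(df)[1] != "time_s")
    stop("first CSV column must be time_s", call. = FALSE)
  chans <- as.character(meta$channels)
  if (!all(chans %in% names(df)))
    stop("sidecar channels missing from CSV: ",
         paste(setdiff(chans, names(df)), collapse = ", "), call. = FALSE)
  t <- df$time_s
  fs_file <- 1 / stats::median(diff(t))
  if (abs(fs_file - meta$fs_hz) / meta$fs_hz > 1e-6)
    stop(sprintf("fs mismatch: sidecar says %g Hz, time column implies %g Hz",
                 meta$fs_hz, fs_file), call. = FALSE)
  multichannel_recording(data = as.matrix(df[chans]), fs = meta$fs_hz,
                         channels = chans, t = t,
                         meta = list(seed = meta$seed,
                                     model_hash = meta$model_hash))
}

#' Read a network model from a YAML or JSON config
#'
#' The config holds a list `oscillators` of blocks
#' `{lambda, zeta, chi, omega_hz, D}` (frequency in Hz at the interface,
#' converted to rad/s internally), optional `hbar` (default 1), optional
#' `channels`, and optional coupling `K` given as parallel real/imaginary
#' matrices `K_re` and `K_im` (row-major lists of rows).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [network_model()].
#' @export
read_model <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  oscs <- lapply(cfg$oscillators, function(o)
    oscillator_params(lambda = o$lambda, zeta = o$zeta, chi = o$chi,
                      omega = 2 * pi * o$omega_hz, D = o$D))
  n <- length(oscs)
  K <- NULL
  if (!is.null(cfg$K_re)) {
    K_re <- matrix(unlist(cfg$K_re), n, n, byrow = TRUE)
    K_im <- if (!is.null(cfg$K_im))
      matrix(unlist(cfg$K_im), n, n, byrow = TRUE) else 0 * K_re
    K <- K_re + 1i * K_im
  }
  network_model(oscs, K = K,
                hbar = if (is.null(cfg$hbar)) 1 else cfg$hbar,
                channels = cfg$channels)
}

#' Write a network model config
#'
#' Inverse of [read_model()]; format chosen by file extension.
#'
#' @param model A [network_model()].
#' @param path Output `.yaml` or `.json` path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  cfg <- list(
    oscillators = lapply(model$oscillators, function(o)
      list(lambda = o$lambda, zeta = o$zeta, chi = o$chi,
           omega_hz = o$omega / (2 * pi), D = o$D)),
    hbar = model$hbar,
    channels = model$channels,
    K_re = apply(Re(model$K), 1, as.list, simplify = FALSE),
    K_im = apply(Im(model$K), 1, as.list, simplify = FALSE))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(cfg, path)
  else jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Personality-map coordinates of a model
#'
#' Summarises a network on the five axes of the cognitive "personality
#' map": the growth/damping ratio \eqn{\lambda/\zeta} (equilibrium
#' amplitude squared), the phonon eigenfrequency summary, the noise
#' intensity `D`, the amplitude-phase coupling \eqn{\chi}, and coupling
#' statistics of `K` (mean off-diagonal `|Re K|`, `|Im K|`, spectral
#' radius).  Multi-channel values are averaged.
#'
#' @param model A [network_model()].
#' @param basis Optional [phonon_basis()]; computed when possible if
#'   missing (requires `lambda > 0` everywhere), otherwise the frequency
#'   summary is `NA`.
#' @return A list of class `"personality_coordinates"`.
#' @export
personality_coordinates <- function(model, basis = NULL) {
  pv <- .param_vectors(model)
  if (is.null(basis) && all(pv$lambda > 0) && all(pv$D > 0))
    basis <- suppressWarnings(build_basis(model))  # unstable flags kept
  n <- length(pv$lambda)
  off <- upper.tri(model$K) | lower.tri(model$K)
  k_abs <- if (n > 1) abs(model$K[off]) else 0
  coords <- list(
    ratio = mean(pv$lambda / pv$zeta),
    omega_mean = if (!is.null(basis)) mean(basis$Omega) else NA_real_,
    omega_spread = if (!is.null(basis)) stats::sd(basis$Omega) else NA_real_,
    D = mean(pv$D),
    chi = mean(pv$chi),
    k_mean_re = if (n > 1) mean(abs(Re(model$K)[off])) else 0,
    k_mean_im = if (n > 1) mean(abs(Im(model$K)[off])) else 0,
    k_mean = mean(k_abs),
    k_spectral_radius = if (n > 1) max(abs(eigen(model$K,
                                                only.values = TRUE)$values))
                        else 0)
  structure(coords, class = "personality_coordinates")
}

#' Classify a model into an archetypal cognitive regime
#'
#' Deterministic rule-based mapping from [personality_coordinates()] to a
#' regime label.  The qualitative low/high descriptors of the personality
#' map are made operational with documented thresholds: "high
#' \eqn{\lambda/\zeta}" means `ratio >= 1` uV^2, "low D" means
#' `D < 0.02` uV^2/s, "very low D" `D < 0.005`, "high chi" `chi >= 0.5`,
#' "very high chi" `chi >= 1.5`, and "strong K" a mean off-diagonal
#' `|K| >= 0.5` 1/s.  These defaults separate the three archetypal
#' presets; all are configurable.  First matching rule wins:
#' \enumerate{
#'   \item `ratio < 0` (no limit cycle) -> `"suppressed"`
#'   \item very low `D` and very high `chi` -> `"hypercoherent/overload"`
#'   \item `ratio >= 1`, low `D`, high `chi` -> `"activated"`
#'   \item `0 < ratio < 1`, `D` high, high `chi` -> `"exploratory"`
#'   \item `0 < ratio < 1`, `D` high, low `chi` -> `"fragmented"`
#'   \item `0 < ratio < 1`, `D` low -> `"drowsy/transitional"`
#'   \item otherwise -> `"unclassified"`.
#' }
#'
#' @param coords A `personality_coordinates` object (or a
#'   [network_model()], which is summarised first).
#' @param thresholds Named list overriding `ratio_high` (1), `d_low`
#'   (0.02), `d_very_low` (0.005), `chi_high` (0.5), `chi_very_high`
#'   (1.5), `k_strong` (0.5).
#' @return A regime label (character scalar).
#' @export
classify_personality <- function(coords, thresholds = list()) {
  if (inherits(coords, "network_model"))
    coords <- personality_coordinates(coords)
  th <- utils::modifyList(
    list(ratio_high = 1, d_low = 0.02, d_very_low = 0.005,
         chi_high = 0.5, chi_very_high = 1.5, k_strong = 0.5),
    thresholds)
  r <- coords$ratio; D <- coords$D; chi <- coords$chi
  if (r < 0) return("suppressed")
  if (D > 0 && D < th$d_very_low && chi >= th$chi_very_high)
    return("hypercoherent/overload")
  if (r >= th$ratio_high && D > 0 && D < th$d_low && chi >= th$chi_high)
    return("activated")
  if (r > 0 && r < th$ratio_high && D >= th$d_low && chi >= th$chi_high)
    return("exploratory")
  if (r > 0 && r < th$ratio_high && D >= th$d_low && chi < th$chi_high)
    return("fragmented")
  if (r > 0 && r < th$ratio_high && D > 0 && D < th$d_low)
    return("drowsy/transitional")
  "unclassified"
}

# tidy long-format export of a symmetric metric matrix
.tidy_matrix <- function(mat, band, metric) {
  n <- nrow(mat)
  idx <- which(upper.tri(mat, diag = TRUE), arr.ind = TRUE)
  data.frame(band = band,
             channel_i = rownames(mat)[idx[, 1]],
             channel_j = colnames(mat)[idx[, 2]],
             metric = metric,
             value = mat[idx])
}

#' Full analysis report for a model + recording
#'
#' Runs the complete pipeline -- phonon basis, analytic spectra, empirical
#' band metrics, energy accounting, personality classification -- and
#' writes the results into one output directory:
#' `basis.json`, `modes.csv` (eigenvector matrix), `spectra.csv` (tidy
#' analytic spectra and coherences), `metrics.csv` (tidy empirical
#' metrics), `energy.json`, `personality.json` and `manifest.json`.
#' All numeric outputs are deterministic functions of the inputs, so a
#' rerun on the same recording reproduces them bit-identically (the
#' manifest carries the only timestamp).
#'
#' @param model A [network_model()] with `lambda > 0` everywhere.
#' @param recording A matching `multichannel_recording`.
#' @param out_dir Output directory (created if needed).
#' @param bands Bands for the empirical metrics; default alpha only.
#' @param freq_hz Frequency grid for the analytic spectra.
#' @param gamma Spectral damping; default [default_gamma()].
#' @return Invisibly, a list with the in-memory results.
#' @export
run_report <- function(model, recording, out_dir,
                       bands = list(alpha = c(8, 13)),
                       freq_hz = seq(0.25, 30, by = 0.25),
                       gamma = default_gamma(model)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  basis <- build_basis(model)
  hbar <- model$hbar

  jsonlite::write_json(
    list(Omega = basis$Omega, M = basis$M, curvatures = basis$curvatures,
         masses = basis$masses, unstable = basis$unstable),
    file.path(out_dir, "basis.json"), digits = NA)
  modes_df <- as.data.frame(basis$modes)
  names(modes_df) <- paste0("mode", seq_along(basis$Omega))
  utils::write.csv(cbind(channel = model$channels,
                         as.data.frame(lapply(modes_df, .fmt17))),
                   file.path(out_dir, "modes.csv"), row.names = FALSE,
                   quote = FALSE)

  S <- cross_spectrum(basis, model, hbar, freq_hz, gamma)
  rho <- analytic_coherence(S)
  sp <- do.call(rbind, lapply(seq_along(freq_hz), function(f) {
    rbind(.tidy_matrix(S[, , f], band = freq_hz[f], "cross_spectrum"),
          .tidy_matrix(rho[, , f], band = freq_hz[f], "coherence_analytic"))
  }))
  names(sp)[names(sp) == "band"] <- "freq_hz"
  sp$value <- .fmt17(sp$value)
  utils::write.csv(sp, file.path(out_dir, "spectra.csv"),
                   row.names = FALSE, quote = FALSE)

  met <- list()
  for (bn in names(bands)) {
    zb <- analytic_band_signal(recording, bands[[bn]])
    zt <- .trim_rows(zb)
    met[[length(met) + 1]] <- .tidy_matrix(plv_matrix(zt), bn, "plv")
    co <- coherence_matrix(zt)
    met[[length(met) + 1]] <- .tidy_matrix(co, bn, "coherence")
    if (ncol(zt) > 1)
      met[[length(met) + 1]] <- data.frame(
        band = bn, channel_i = "*", channel_j = "*",
        metric = "coherence_entropy", value = coherence_entropy(co))
  }
  met <- do.call(rbind, met)
  met$value <- .fmt17(as.numeric(met$value))
  utils::write.csv(met, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE, quote = FALSE)

  energy <- energy_report(model, basis, recording)
  jsonlite::write_json(unclass(energy), file.path(out_dir, "energy.json"),
                       digits = NA, auto_unbox = TRUE)

  coords <- personality_coordinates(model, basis)
  label <- classify_personality(coords)
  jsonlite::write_json(c(unclass(coords), list(label = label)),
                       file.path(out_dir, "personality.json"),
                       digits = NA, auto_unbox = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("neurophonon")),
    model_hash = model_hash(model),
    recording_meta = recording$meta,
    bands = bands, gamma = gamma,
    files = c("basis.json", "modes.csv", "spectra.csv", "metrics.csv",
              "energy.json", "personality.json"),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(basis = basis, cross_spectrum = S, coherence = rho,
                 metrics = met, energy = energy, coords = coords,
                 label = label))
}
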