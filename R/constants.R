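#' Loudness model constants bundle
#'
#' Builds the full set of constants for the excitation / specific-loudness
#' model: the ERB-spaced channel grid, per-channel cochlear gain `G`,
#' compressive exponent `alpha`, additive constant `A`, peak excitation at
#' absolute threshold `E_THRQ`, signal-to-noise ratio at masked threshold `K`,
#' the loudness scaling constant `C`, the fixed partial-loudness exponent
#' (0.3), the binaural-inhibition exponent `P` (1.598), and the attack/release
#' time constants of the temporal-integration stages.
#'
#' The frequency-dependent tables follow the Moore--Glasberg loudness-model
#' lineage: cochlear gain is maximal and constant for channels at and above
#' 500 Hz and falls smoothly (to -25 dB at 50 Hz) below; `alpha` and `A`
#' co-vary with the gain; the absolute-threshold excitation is 2.31 dB where
#' gain is maximal. The tables here are smooth parameterizations of that
#' model's published behaviour, not verbatim standard tables; all of them can
#' be overridden. `C` is calibrated so that a 1-kHz pure tone at 40 dB SPL,
#' presented diotically in free field, has a loudness of 1 sone (the model's
#' calibration anchor).
#'
#' @param cam_min,cam_max,cam_step Channel grid on the ERB-rate (Cam) scale.
#'   Defaults span roughly 50 Hz to 15 kHz at 0.25-Cam spacing.
#' @param C Loudness scaling constant (sones); default is the 1-sone anchor
#'   calibration for this package's tables.
#' @param P_binaural Binaural inhibition exponent; default 1.598.
#' @param partial_exponent Exponent of the masked-threshold ratio in the
#'   partial-loudness formula; fixed at 0.3 in the model.
#' @param agc List of AGC time constants in seconds:
#'   `attack_st`, `release_st` (short-term stage) and `attack_lt`,
#'   `release_lt` (long-term stage).
#' @param smooth_width Width (Cams) of the two-sided exponential smoother
#'   applied to specific-loudness patterns before the binaural inhibition
#'   ratio is formed.
#' @return An object of class `loudness_constants`: a list with per-channel
#'   vectors `cam`, `freq`, `G` (linear), `A`, `alpha`, `E_THRQ` (linear),
#'   `K` (linear), `p51`, and scalars `C`, `P_binaural`, `partial_exponent`,
#'   `p51_1k`, `cam_step`, `smooth_width`, plus the `agc` list.
#' @export
#' @examples
#' cst <- loudness_constants()
#' range(cst$freq)
loudness_constants <- function(cam_min = 1.75, cam_max = 39, cam_step = 0.25,
                               C = 0.042575198,
                               P_binaural = 1.598,
                               partial_exponent = 0.3,
                               agc = list(attack_st = 0.022, release_st = 0.050,
                                          attack_lt = 0.099, release_lt = 2.000),
                               smooth_width = 2) {
  stopifnot(cam_min > 0, cam_max > cam_min, cam_step > 0,
            C > 0, partial_exponent == 0.3)
  cam <- seq(cam_min, cam_max, by = cam_step)
  freq <- erb_to_freq(cam)

  G_db <- cochlear_gain_db(freq)
  alpha <- 0.2 - 0.00225 * G_db          # 0.2 at full gain, larger at low CFs
  A <- 4.72 - 0.1632 * G_db              # grows as gain is reduced
  E_thrq_db <- 2.31 - G_db               # threshold excitation rises at low CFs
  K_db <- masked_snr_db(freq)

  stopifnot(all(alpha > 0 & alpha < 1), all(A > 0))

  cst <- list(
    cam = cam, freq = freq, cam_step = cam_step,
    G = 10^(G_db / 10), G_db = G_db,
    A = A, alpha = alpha,
    E_THRQ = 10^(E_thrq_db / 10), E_THRQ_db = E_thrq_db,
    K = 10^(K_db / 10), K_db = K_db,
    p51 = 4 * freq / erb_bandwidth(freq),
    p51_1k = 4000 / erb_bandwidth(1000),
    C = C,
    P_binaural = P_binaural,
    partial_exponent = partial_exponent,
    agc = agc,
    smooth_width = smooth_width
  )
  class(cst) <- "loudness_constants"
  cst
}

# Cochlear amplifier gain in dB relative to its maximum: 0 dB at and above
# 500 Hz, falling linearly on a log-frequency axis to -25 dB at 50 Hz.
cochlear_gain_db <- function(f) {
  g <- -25 * log10(500 / pmax(f, 1e-6))
  pmin(0, pmax(g, -25))
}

# Signal-to-noise ratio K (dB) at masked threshold as a function of channel
# frequency: large at low frequencies, about -3 dB at 2 kHz and above.
masked_snr_db <- function(f) {
  kx <- log10(c(50, 100, 200, 500, 1000, 2000))
  ky <- c(13, 6, 2, -1, -2, -3)
  stats::approx(kx, ky, xout = log10(pmax(f, 1)), rule = 2)$y
}

# Free-field threshold of hearing (minimum audible field), dB SPL.
# Interpolated on a log-frequency axis from standard audiometric values.
minimum_audible_field_db <- function(f) {
  tf <- c(20, 25, 31.5, 40, 50, 63, 80, 100, 125, 160, 200, 250, 315, 400,
          500, 630, 800, 1000, 1250, 1600, 2000, 2500, 3150, 4000, 5000,
          6300, 8000, 10000, 12500, 14000)
  tl <- c(78.1, 68.7, 59.5, 51.1, 44.0, 37.5, 31.5, 26.5, 22.1, 17.9, 14.4,
          11.4, 8.6, 6.2, 4.4, 3.0, 2.2, 2.4, 3.5, 2.4, -1.3, -4.2, -5.8,
          -5.4, -1.5, 6.0, 12.6, 13.9, 12.3, 18.4)
  stats::approx(log10(tf), tl, xout = log10(pmax(f, 1)), rule = 2)$y
}

# Diffuse-field minus free-field presentation correction, dB (approximate).
diffuse_field_correction_db <- function(f) {
  dx <- log10(c(250, 500, 1000, 2000, 3150, 4000, 5000, 8000, 12500))
  dy <- c(0, 0.2, 0.4, 1.2, 1.8, 0.8, -1.0, -2.0, -2.5)
  stats::approx(dx, dy, xout = log10(pmax(f, 1)), rule = 2)$y
}

# Combined outer+middle-ear / cochlear input transfer, dB: converts a
# free-field SPL at frequency f into the effective excitation level scale.
# Built so that a tone at the threshold of hearing produces exactly the
# absolute-threshold excitation E_THRQ of the channel at its frequency.
ear_transfer_db <- function(f, field = c("free", "diffuse")) {
  field <- match.arg(field)
  t <- (2.31 - cochlear_gain_db(f)) - minimum_audible_field_db(f)
  if (field == "diffuse") t <- t - diffuse_field_correction_db(f)
  t
}

#' @export
print.loudness_constants <- function(x, ...) {
  cat("Loudness model constants\n")
  cat(sprintf("  channels: %d (%.2f-%.2f Cams, step %.2f; %.0f Hz-%.0f Hz)\n",
              length(x$cam), min(x$cam), max(x$cam), x$cam_step,
              min(x$freq), max(x$freq)))
  cat(sprintf("  C = %.6f, alpha(1 kHz) = %.3f, P_binaural = %.3f\n",
              x$C, x$alpha[which.min(abs(x$freq - 1000))], x$P_binaural))
  invisible(x)
}

#' Write / read a constants bundle
#'
#' Serializes the scalar constants and per-channel tables to a structured JSON
#' file so a calculation can be reproduced with frozen constants, and reads
#' such a file back.
#'
#' @param constants A `loudness_constants` object.
#' @param path File path.
#' @return `constants_to_file` returns `path` invisibly;
#'   `constants_from_file` returns a `loudness_constants` object.
#' @export
constants_to_file <- function(constants, path) {
  stopifnot(inherits(constants, "loudness_constants"))
  x <- unclass(constants)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname constants_to_file
#' @export
constants_from_file <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$agc <- as.list(x$agc)
  class(x) <- "loudness_constants"
  stopifnot(length(x$cam) == length(x$freq), x$C > 0)
  x
}
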