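#' Calibrated binaural audio
#'
#' Container for two-channel (left/right ear) PCM audio with an absolute
#' calibration. The calibration `cal_db` is the sound pressure level in dB SPL
#' that corresponds to an RMS sample amplitude of 1.0, so a sine of amplitude
#' `a` has level `cal_db + 20*log10(a) - 3.01` dB SPL.
#'
#' @param left,right Numeric sample vectors of equal length.
#' @param fs Sample rate in Hz (> 8000).
#' @param cal_db Calibration: dB SPL at RMS amplitude 1.0. `NA` marks
#'   uncalibrated audio, which the loudness chain rejects.
#' @return Object of class `binaural_audio`.
#' @export
binaural_audio <- function(left, right = left, fs, cal_db = NA_real_) {
  if (length(left) != length(right))
    stop("left and right channels must have equal length")
  if (fs <= 8000) stop("sample rate must exceed 8 kHz")
  structure(list(left = as.numeric(left), right = as.numeric(right),
                 fs = fs, cal_db = cal_db),
            class = "binaural_audio")
}

#' @export
print.binaural_audio <- function(x, ...) {
  cat(sprintf("Binaural audio: %.2f s at %d Hz, calibration %s\n",
              length(x$left) / x$fs, x$fs,
              if (is.na(x$cal_db)) "none" else sprintf("%.1f dB SPL @ RMS 1", x$cal_db)))
  invisible(x)
}

# 1/3-octave band mean-square power of a sample vector (optionally windowed
# segment). Normalization is exact in total energy (Parseval), so both tones
# (with leakage summed within the band) and broadband noise come out right.
band_mean_square <- function(x, fs, window = NULL) {
  n <- length(x)
  if (is.null(window)) window <- rep(1, n)
  xw <- x * window
  X <- stats::fft(xw)
  k <- seq_len(floor(n / 2))              # positive-frequency bins
  p <- 2 * Mod(X[k + 1])^2 / (n * sum(window^2))
  f <- k * fs / n
  centers <- third_octave_centers()
  lo <- centers / 2^(1 / 6)
  hi <- centers * 2^(1 / 6)
  ms <- vapply(seq_along(centers), function(i)
    sum(p[f >= lo[i] & f < hi[i]]), numeric(1))
  ms
}

# band levels (dB SPL) of one channel of calibrated audio
audio_band_levels <- function(samples, fs, cal_db, window = NULL) {
  ms <- band_mean_square(samples, fs, window)
  lev <- rep(-Inf, length(ms))
  pos <- ms > 0
  lev[pos] <- 10 * log10(ms[pos]) + cal_db
  lev
}

# long-term 1/3-octave spectrum of calibrated audio, averaged over ears
audio_spectrum <- function(audio) {
  stopifnot(inherits(audio, "binaural_audio"))
  if (is.na(audio$cal_db)) stop("audio has no dB SPL calibration")
  msl <- band_mean_square(audio$left, audio$fs)
  msr <- band_mean_square(audio$right, audio$fs)
  ms <- (msl + msr) / 2
  lev <- rep(-Inf, length(ms))
  lev[ms > 0] <- 10 * log10(ms[ms > 0]) + audio$cal_db
  third_octave_spectrum(third_octave_centers(), lev)
}

#' @export
a_weighted_level.binaural_audio <- function(x, ...) {
  a_weighted_level(audio_spectrum(x))
}

#' @export
calibrate_level.binaural_audio <- function(x, target_dba, ...) {
  cur <- a_weighted_level(x)
  if (!is.finite(cur)) stop("silent input cannot be calibrated")
  g <- 10^((target_dba - cur) / 20)
  x$left <- x$left * g
  x$right <- x$right * g
  x
}

#' Read / write a stereo WAV file
#'
#' Minimal RIFF/WAVE support for 16-bit integer and 32-bit float PCM, enough
#' to exchange binaural stimuli. WAV carries no absolute level, so the
#' calibration (dB SPL at RMS amplitude 1.0) is supplied as a sidecar value on
#' read.
#'
#' @param path File path.
#' @param cal_db Calibration applied to the audio read (dB SPL at RMS 1.0).
#' @param audio A `binaural_audio` object.
#' @param bits 16 (integer PCM, samples clipped to \[-1, 1\]) or 32 (float).
#' @return `wav_read` returns a `binaural_audio`; `wav_write` returns `path`
#'   invisibly.
#' @export
wav_read <- function(path, cal_db = NA_real_) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file")
  fmt <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "raw", sz)
    } else if (id == "data") {
      dat <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))
    if (!is.null(fmt) && !is.null(dat)) break
  }
  if (is.null(fmt) || is.null(dat)) stop("malformed WAV: missing fmt or data chunk")
  fmt_tag <- readBin(fmt[1:2], "integer", 1, 2, endian = "little")
  n_chan <- readBin(fmt[3:4], "integer", 1, 2, endian = "little")
  fs <- readBin(fmt[5:8], "integer", 1, 4, endian = "little")
  bits <- readBin(fmt[15:16], "integer", 1, 2, endian = "little")
  if (n_chan != 2) stop("expected 2-channel (binaural) WAV")
  if (fmt_tag == 1 && bits == 16) {
    x <- readBin(dat, "integer", length(dat) / 2, 2, signed = TRUE,
                 endian = "little") / 32768
  } else if (fmt_tag == 3 && bits == 32) {
    x <- readBin(dat, "double", length(dat) / 4, 4, endian = "little")
  } else {
    stop("unsupported WAV encoding (need 16-bit PCM or 32-bit float)")
  }
  binaural_audio(left = x[seq(1, length(x), by = 2)],
                 right = x[seq(2, length(x), by = 2)],
                 fs = fs, cal_db = cal_db)
}

#' @rdname wav_read
#' @export
wav_write <- function(audio, path, bits = 16) {
  stopifnot(inherits(audio, "binaural_audio"), bits %in% c(16, 32))
  n <- length(audio$left)
  inter <- numeric(2 * n)
  inter[seq(1, 2 * n, by = 2)] <- audio$left
  inter[seq(2, 2 * n, by = 2)] <- audio$right
  con <- file(path, "wb")
  on.exit(close(con))
  bytes_per <- bits / 8
  data_sz <- 2 * n * bytes_per
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_sz), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(as.integer(if (bits == 16) 1 else 3), con, 2, endian = "little")
  writeBin(2L, con, 2, endian = "little")
  writeBin(as.integer(audio$fs), con, 4, endian = "little")
  writeBin(as.integer(audio$fs * 2 * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(2 * bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, 4, endian = "little")
  if (bits == 16) {
    writeBin(as.integer(round(pmax(pmin(inter, 1), -1) * 32767)), con, 2,
             endian = "little")
  } else {
    writeBin(inter, con, 4, endian = "little")
  }
  invisible(path)
}
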