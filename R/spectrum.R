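#' Stationary 1/3-octave band spectrum
#'
#' The canonical description of a stationary stimulus: sound pressure levels
#' in standard 1/3-octave bands. Band centers must belong to the standard
#' series ([third_octave_centers()]); levels are dB SPL (`-Inf` marks a silent
#' band).
#'
#' @param freq_hz Numeric vector of band center frequencies (Hz), strictly
#'   increasing, drawn from the standard series.
#' @param level_db Numeric vector of band levels in dB SPL (may be `-Inf`).
#' @return An object of class `third_octave_spectrum` (a data frame with
#'   columns `freq_hz`, `level_db`).
#' @export
#' @examples
#' tone <- third_octave_spectrum(1000, 40)
#' a_weighted_level(tone)
third_octave_spectrum <- function(freq_hz, level_db) {
  if (length(freq_hz) == 0) stop("spectrum must contain at least one band")
  if (length(freq_hz) != length(level_db))
    stop("freq_hz and level_db must have the same length")
  std <- third_octave_centers()
  bad <- freq_hz[!freq_hz %in% std]
  if (length(bad) > 0)
    stop(sprintf("non-standard 1/3-octave band center(s): %s Hz",
                 paste(bad, collapse = ", ")))
  if (any(diff(freq_hz) <= 0))
    stop("band center frequencies must be strictly increasing")
  if (any(is.na(level_db)) || any(level_db == Inf))
    stop("band levels must be finite or -Inf")
  out <- data.frame(freq_hz = as.numeric(freq_hz),
                    level_db = as.numeric(level_db))
  class(out) <- c("third_octave_spectrum", "data.frame")
  out
}

#' @export
print.third_octave_spectrum <- function(x, ...) {
  cat(sprintf("1/3-octave spectrum: %d bands, %.0f-%.0f Hz, %.1f dBA\n",
              nrow(x), min(x$freq_hz), max(x$freq_hz), a_weighted_level(x)))
  invisible(x)
}

#' A-weighted level
#'
#' Overall A-weighted sound pressure level of a band spectrum (per-band
#' weighting, energetic summation) or of calibrated binaural audio (via its
#' long-term band spectrum, averaged over ears).
#'
#' @param x A `third_octave_spectrum` or `binaural_audio` object.
#' @param ... Unused.
#' @return Level in dBA (scalar; `-Inf` for silence).
#' @export
a_weighted_level <- function(x, ...) UseMethod("a_weighted_level")

#' @export
a_weighted_level.third_octave_spectrum <- function(x, ...) {
  combine_levels_db(x$level_db + a_weight_db(x$freq_hz))
}

#' Scale a stimulus to a target A-weighted level
#'
#' Applies a uniform gain so that [a_weighted_level()] of the result equals
#' `target_dba`; the spectral shape is preserved.
#'
#' @param x A `third_octave_spectrum` or `binaural_audio` object.
#' @param target_dba Target level in dBA.
#' @param ... Unused.
#' @return Object of the same class as `x`.
#' @export
calibrate_level <- function(x, target_dba, ...) UseMethod("calibrate_level")

#' @export
calibrate_level.third_octave_spectrum <- function(x, target_dba, ...) {
  cur <- a_weighted_level(x)
  if (!is.finite(cur)) stop("silent input cannot be calibrated")
  x$level_db <- x$level_db + (target_dba - cur)
  x
}

#' Read / write a 1/3-octave spectrum CSV
#'
#' The file dialect is two named columns `freq_hz,level_db_spl` with a header
#' row. On read, rows may be in any order and are sorted by frequency.
#'
#' @param path File path.
#' @param spectrum A `third_octave_spectrum` object.
#' @return `read_spectrum` returns a `third_octave_spectrum`;
#'   `write_spectrum` returns `path` invisibly.
#' @export
read_spectrum <- function(path) {
  df <- utils::read.csv(path)
  need <- c("freq_hz", "level_db_spl")
  if (!all(need %in% names(df)))
    stop("spectrum CSV must have header columns freq_hz,level_db_spl")
  df <- df[order(df$freq_hz), ]
  third_octave_spectrum(df$freq_hz, df$level_db_spl)
}

#' @rdname read_spectrum
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "third_octave_spectrum"))
  utils::write.csv(
    data.frame(freq_hz = spectrum$freq_hz, level_db_spl = spectrum$level_db),
    path, row.names = FALSE)
  invisible(path)
}
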