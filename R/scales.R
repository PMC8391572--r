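#' Auditory frequency scales and standard weightings
#'
#' Helpers for the ERB-rate (Cam) scale of auditory-filter channels, the
#' standard 1/3-octave band series, and IEC A-weighting. These underpin the
#' excitation-pattern and loudness computations.
#'
#' @name scales
NULL

#' ERB-rate (Cam) value of a frequency
#'
#' Number of equivalent rectangular bandwidths below `f`, i.e. the position of
#' `f` on the Cam scale.
#'
#' @param f Frequency in Hz.
#' @return ERB-rate in Cams.
#' @export
#' @examples
#' erb_rate(1000) # about 15.6 Cams
erb_rate <- function(f) {
  21.366 * log10(0.004368 * f + 1)
}

#' Frequency at a given ERB-rate
#'
#' Inverse of [erb_rate()].
#'
#' @param cam ERB-rate in Cams.
#' @return Frequency in Hz.
#' @export
erb_to_freq <- function(cam) {
  (10^(cam / 21.366) - 1) / 0.004368
}

#' Equivalent rectangular bandwidth at a frequency
#'
#' @param f Frequency in Hz.
#' @return Bandwidth in Hz.
#' @export
erb_bandwidth <- function(f) {
  24.673 * (0.004368 * f + 1)
}

#' Standard 1/3-octave band center frequencies
#'
#' The nominal preferred series from 25 Hz to 12.5 kHz used for stationary
#' band-spectrum input.
#'
#' @return Numeric vector of 28 center frequencies in Hz.
#' @export
third_octave_centers <- function() {
  c(25, 31.5, 40, 50, 63, 80, 100, 125, 160, 200, 250, 315, 400, 500,
    630, 800, 1000, 1250, 1600, 2000, 2500, 3150, 4000, 5000, 6300,
    8000, 10000, 12500)
}

#' A-weighting in dB at given frequencies
#'
#' Standard IEC 61672 A-weighting curve; 0 dB at 1 kHz by construction.
#'
#' @param f Frequency in Hz (vectorized).
#' @return Weight in dB to be added to an SPL at `f`.
#' @export
#' @examples
#' a_weight_db(1000) # 0
#' a_weight_db(100)  # about -19.1
a_weight_db <- function(f) {
  f2 <- f^2
  ra <- (12194^2 * f2^2) /
    ((f2 + 20.6^2) * sqrt((f2 + 107.7^2) * (f2 + 737.9^2)) * (f2 + 12194^2))
  20 * log10(ra) + 2.000297
}

#' Combine sound levels energetically
#'
#' Power (energetic) summation of decibel levels: two equal incoherent sources
#' add 3.01 dB.
#'
#' @param levels Numeric vector of levels in dB; `-Inf` allowed (silent).
#' @return Combined level in dB.
#' @export
combine_levels_db <- function(levels) {
  levels <- levels[is.finite(levels) | levels == -Inf]
  if (all(levels == -Inf)) return(-Inf)
  10 * log10(sum(10^(levels[is.finite(levels)] / 10)))
}
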