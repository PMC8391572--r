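#' Time-varying loudness of binaural audio
#'
#' Frame-based loudness analysis: each analysis frame is reduced to per-ear
#' 1/3-octave band levels, passed through the stationary chain (excitation,
#' specific loudness, binaural inhibition) to give instantaneous loudness,
#' which is then smoothed twice by attack/release automatic-gain-control
#' stages: a short-term stage (attack 22 ms, release 50 ms by default) and a
#' long-term stage (attack 99 ms, release 2 s). Attack is always faster than
#' release, so loudness rises quickly after an onset and decays slowly. The
#' maximum of the long-term series is the representative single-number
#' loudness of a nonstationary sound such as an aircraft flyover.
#'
#' @param audio A calibrated [binaural_audio()] object.
#' @param constants A [loudness_constants()] bundle.
#' @param window Analysis window length in seconds (Hann window).
#' @param hop Frame hop in seconds.
#' @param field Presentation field, `"free"` or `"diffuse"`.
#' @return Object of class `loudness_trace`: list with `time_step` (s),
#'   `instantaneous`, `short_term`, `long_term` (sones per frame) and
#'   `max_long_term` (sones).
#' @export
time_varying_loudness <- function(audio, constants = loudness_constants(),
                                  window = 0.050, hop = 0.010,
                                  field = "free") {
  stopifnot(inherits(audio, "binaural_audio"))
  if (is.na(audio$cal_db)) stop("audio has no dB SPL calibration")
  n_win <- round(window * audio$fs)
  n_hop <- round(hop * audio$fs)
  n <- length(audio$left)
  if (n < n_win) stop("audio shorter than one analysis frame")
  starts <- seq(1, n - n_win + 1, by = n_hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n_win) / (n_win + 1))
  centers <- third_octave_centers()

  inst <- numeric(length(starts))
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + n_win - 1)
    ll <- audio_band_levels(audio$left[idx], audio$fs, audio$cal_db, w)
    lr <- audio_band_levels(audio$right[idx], audio$fs, audio$cal_db, w)
    el <- excitation_core(centers, ll, field, constants)
    er <- excitation_core(centers, lr, field, constants)
    sl <- specific_loudness(el, constants)
    sr <- specific_loudness(er, constants)
    pair <- binaural_inhibition(sl, sr, constants)
    inst[i] <- integrate_loudness(pair$left) + integrate_loudness(pair$right)
  }

  st <- agc_smooth(inst, hop, constants$agc$attack_st, constants$agc$release_st)
  lt <- agc_smooth(st, hop, constants$agc$attack_lt, constants$agc$release_lt)

  structure(list(time_step = hop, instantaneous = inst, short_term = st,
                 long_term = lt, max_long_term = max(lt)),
            class = "loudness_trace")
}

# one-pole attack/release smoother (AGC): coefficient depends on whether the
# input is above (attack) or below (release) the current state
agc_smooth <- function(x, dt, tau_attack, tau_release) {
  a_a <- 1 - exp(-dt / tau_attack)
  a_r <- 1 - exp(-dt / tau_release)
  out <- numeric(length(x))
  s <- 0
  for (i in seq_along(x)) {
    a <- if (x[i] > s) a_a else a_r
    s <- s + a * (x[i] - s)
    out[i] <- s
  }
  out
}

#' @export
print.loudness_trace <- function(x, ...) {
  cat(sprintf("Loudness trace: %d frames at %.0f ms, max long-term %.2f sones\n",
              length(x$long_term), 1000 * x$time_step, x$max_long_term))
  invisible(x)
}
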