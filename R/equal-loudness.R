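#' Predict the equal-loudness level match under background noise
#'
#' Finds the level at which a target sound presented together with a
#' background is judged as loud as the same target at a reference level in
#' quiet: the returned level `x` satisfies
#' `partial_loudness(target at x | background) = loudness(target at reference)`.
#' Because partial masking can only reduce loudness, the match is at or above
#' the reference level. The equation is solved by bisection on the target
#' level; the matching statistic is the integrated stationary partial loudness
#' of the target (with binaural inhibition, diotic presentation).
#'
#' For a time-varying target such as a flyover, the representative loudness is
#' the maximum of the long-term loudness series, which occurs at the envelope
#' peak where the target momentarily exceeds its own LAeq while a steady
#' background does not. `target_crest_db` expresses this: the stationary
#' matching objective is evaluated with the target raised by that amount above
#' the nominal LAeq on both sides of the match. It is 0 for a steady target
#' and [flyover_crest_db()] (about 4.26 dB) for the synthetic raised-cosine
#' flyover envelope.
#'
#' @param target A [third_octave_spectrum()] giving the target's spectral
#'   shape (it is recalibrated internally).
#' @param background A [third_octave_spectrum()] for the masker, or `NULL`
#'   for quiet.
#' @param reference_dba Reference level of the target in quiet, dBA.
#' @param background_dba Level of the background, dBA (ignored when
#'   `background` is `NULL`).
#' @param tolerance Bisection tolerance in dB.
#' @param target_crest_db Level by which the target's long-term-loudness
#'   maximum exceeds its LAeq (see Details).
#' @param constants A [loudness_constants()] bundle.
#' @return Matched level in dBA (on the LAeq scale of `reference_dba`).
#' @export
predict_equal_level <- function(target, background = NULL,
                                reference_dba, background_dba = NULL,
                                tolerance = 0.05, target_crest_db = 0,
                                constants = loudness_constants()) {
  stopifnot(reference_dba >= 0, reference_dba <= 120, tolerance > 0,
            target_crest_db >= 0)
  if (is.null(background) || is.null(background_dba) ||
      !is.finite(background_dba))
    return(reference_dba)

  bg <- calibrate_level(background, background_dba)
  l_quiet <- loudness_stationary(
    calibrate_level(target, reference_dba + target_crest_db),
    constants = constants)
  objective <- function(x)
    partial_loudness_stationary(calibrate_level(target, x + target_crest_db),
                                bg, constants = constants) - l_quiet

  lo <- max(reference_dba - 5, 0)
  # ceiling: highest target level keeping every band below 120 dB SPL
  shape_off <- max(target$level_db) - a_weighted_level(target)
  hi <- 119.9 - target_crest_db - max(shape_off, 0)
  if (hi <= lo || objective(hi) < 0)
    stop("target stays below the loudness match even at the search ceiling; ",
         "background too intense")
  f_lo <- objective(lo)
  if (f_lo >= 0) return(lo)
  while (hi - lo > tolerance) {
    mid <- (lo + hi) / 2
    if (objective(mid) < 0) lo <- mid else hi <- mid
  }
  max((lo + hi) / 2, reference_dba)
}

#' Crest of the synthetic flyover envelope
#'
#' Level difference between the peak and the energy mean of the raised-cosine
#' (squared-sine) flyover envelope: `10 log10(8/3)`, about 4.26 dB. At the
#' long-term loudness maximum a synthetic flyover exceeds its own LAeq by this
#' amount.
#'
#' @return Crest in dB.
#' @export
flyover_crest_db <- function() 10 * log10(8 / 3)

#' Simulate an adaptive up-down loudness-matching track
#'
#' Emulates the adaptive staircase used to measure equal-loudness matches: a
#' simulated subject repeatedly compares the target-with-background against
#' the target at the reference level in quiet, the presented level moves
#' opposite to the response ("louder" lowers it, "quieter" raises it), and the
#' step size shrinks from 5 dB down to 1 dB at each reversal. The subject's
#' internal comparison perturbs the presented level with Gaussian noise
#' (`subject_noise_sd`, dB) and declares "same" when the loudness difference
#' falls below a just-noticeable fraction of the reference loudness. If the
#' track is still oscillating at the 1-dB step after `max_final_trials`
#' further trials, it is closed with a "same" at the current level (which is
#' then within one final step of the match).
#'
#' @inheritParams predict_equal_level
#' @param subject_noise_sd Response-noise standard deviation in dB (>= 0).
#' @param seed Integer seed; fixes the whole track.
#' @param jnd_frac "Same" criterion: fraction of the reference loudness below
#'   which a difference is not noticeable (default 2 %).
#' @param steps_db Step-size schedule, advanced one entry per reversal;
#'   non-increasing from 5 to 1 dB.
#' @param max_final_trials Failsafe trial budget at the final step size.
#' @return Object of class `staircase_track`: data frame `trials` with
#'   columns `level_db`, `response`, plus fields `converged_level`, `seed`.
#' @export
simulate_staircase <- function(target, background, reference_dba,
                               background_dba, subject_noise_sd = 1,
                               seed = 1, jnd_frac = 0.02,
                               steps_db = c(5, 3, 2, 1),
                               max_final_trials = 40, target_crest_db = 0,
                               constants = loudness_constants()) {
  stopifnot(subject_noise_sd >= 0, all(diff(steps_db) < 0),
            steps_db[1] == 5, steps_db[length(steps_db)] == 1)
  set.seed(seed)
  bg <- calibrate_level(background, background_dba)
  l_quiet <- loudness_stationary(
    calibrate_level(target, reference_dba + target_crest_db),
    constants = constants)
  perceived <- function(x)
    partial_loudness_stationary(
      calibrate_level(target, x + target_crest_db +
                        stats::rnorm(1, 0, subject_noise_sd)),
      bg, constants = constants)

  level <- reference_dba
  step_i <- 1
  last_dir <- 0L
  trials <- list()
  final_count <- 0
  repeat {
    d <- perceived(level) - l_quiet
    if (abs(d) <= jnd_frac * l_quiet) {
      trials[[length(trials) + 1]] <- list(level_db = level, response = "same")
      break
    }
    resp <- if (d > 0) "louder" else "quieter"
    trials[[length(trials) + 1]] <- list(level_db = level, response = resp)
    dir <- if (d > 0) -1L else 1L          # louder -> reduce level
    if (last_dir != 0L && dir != last_dir && step_i < length(steps_db))
      step_i <- step_i + 1
    last_dir <- dir
    if (step_i == length(steps_db)) {
      final_count <- final_count + 1
      if (final_count >= max_final_trials) {
        trials[[length(trials) + 1]] <- list(level_db = level, response = "same")
        break
      }
    }
    level <- min(max(level + dir * steps_db[step_i], 0), 119)
  }
  tr <- do.call(rbind, lapply(trials, function(t)
    data.frame(level_db = t$level_db, response = t$response)))
  structure(list(trials = tr,
                 converged_level = tr$level_db[nrow(tr)],
                 steps_db = steps_db, seed = seed),
            class = "staircase_track")
}

#' @export
print.staircase_track <- function(x, ...) {
  cat(sprintf("Staircase track: %d trials, converged at %.1f dBA (seed %d)\n",
              nrow(x$trials), x$converged_level, x$seed))
  invisible(x)
}

#' Equal-loudness match table over level grids
#'
#' Predicted matched level and shift for every combination of target reference
#' level and background level (the experiment's scenario grid: three aircraft
#' levels crossed with three road-traffic levels gives nine rows).
#'
#' @inheritParams predict_equal_level
#' @param reference_levels Vector of target reference levels, dBA.
#' @param background_levels Vector of background levels, dBA; if empty, an
#'   identity table (no masking) is returned.
#' @return Data frame with columns `target_db`, `background_db`,
#'   `predicted_db`, `shift_db`.
#' @export
equal_loudness_table <- function(target, background, reference_levels,
                                 background_levels, tolerance = 0.05,
                                 target_crest_db = 0,
                                 constants = loudness_constants()) {
  stopifnot(length(reference_levels) > 0)
  if (length(background_levels) == 0) {
    return(data.frame(target_db = reference_levels,
                      background_db = NA_real_,
                      predicted_db = reference_levels,
                      shift_db = 0))
  }
  grid <- expand.grid(background_db = background_levels,
                      target_db = reference_levels)[, 2:1]
  grid$predicted_db <- mapply(function(ref, bgl)
    predict_equal_level(target, background, ref, bgl,
                        tolerance = tolerance,
                        target_crest_db = target_crest_db,
                        constants = constants),
    grid$target_db, grid$background_db)
  grid$shift_db <- grid$predicted_db - grid$target_db
  rownames(grid) <- NULL
  grid
}
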