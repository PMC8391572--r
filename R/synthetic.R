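#' Synthetic stimulus spectra for aircraft and road traffic
#'
#' Deterministic template spectra emulating the qualitative character of the
#' recorded stimuli: aircraft flyover noise carries pronounced high-frequency
#' (1--8 kHz) energy, while road-traffic noise is broadband with a
#' low-frequency emphasis. Templates are fixed shapes; only the overall level
#' is adjusted (uniform gain) to the requested A-weighted level.
#'
#' @param level_dba Target A-weighted level; aircraft templates accept
#'   40--100 dBA.
#' @return A [third_octave_spectrum()] calibrated to `level_dba`.
#' @export
#' @examples
#' a_weighted_level(aircraft_spectrum(68)) # 68
aircraft_spectrum <- function(level_dba) {
  stopifnot(level_dba >= 40, level_dba <= 100)
  calibrate_level(aircraft_template(), level_dba)
}

#' @rdname aircraft_spectrum
#' @export
road_spectrum <- function(level_dba) {
  stopifnot(level_dba >= 30, level_dba <= 100)
  calibrate_level(road_template(), level_dba)
}

#' @rdname aircraft_spectrum
#' @details `aircraft_template()` and `road_template()` return the fixed
#'   spectral shapes (relative dB, arbitrary overall level); they are
#'   versioned data, not random draws, so downstream results are stable.
#' @export
aircraft_template <- function() {
  # broadband flyover shape: jet noise keeps substantial low-frequency energy
  # while its character relative to road traffic is the broad 1-8 kHz
  # plateau (fan/jet mixing noise)
  third_octave_spectrum(third_octave_centers(), c(
    -6, -5, -4, -3, -2, -2, -2, -2, -2, -2,             # 25..200 Hz
    -2, -2, -1.5, -1, -1, -0.5, 0, 0, 0, 0,             # 250..2000 Hz
    0, 0, 0, -0.5, -1.5, -3, -4.5, -6))                 # 2500..12500 Hz
}

#' @rdname aircraft_spectrum
#' @export
road_template <- function() {
  # steady traffic shape: low-frequency plateau (engine/tyre noise), steady
  # decline toward high frequencies, within a 15-dB window over 100 Hz-5 kHz
  third_octave_spectrum(third_octave_centers(), c(
    -3, -2, -1, 0, 0, 0, 0, -0.5, -1, -1.5,             # 25..200 Hz
    -2, -2.5, -3, -3.5, -4, -5, -6, -7, -8, -9,         # 250..2000 Hz
    -10, -11, -12, -13, -14.5, -16, -18, -20))          # 2500..12500 Hz
}

#' Synthetic binaural aircraft flyover waveform
#'
#' Shaped noise with the aircraft template spectrum and a smooth raised-cosine
#' rise--fall envelope peaking at the middle of the file, emulating a single
#' overhead flyover. The two ear channels share the template shape but are
#' partially decorrelated with seeded independent noise. The result is
#' calibrated so its A-weighted equivalent level over the file equals
#' `level_dba`.
#'
#' @param level_dba Target LAeq over the file, dBA.
#' @param duration File length in seconds (>= 5; the recordings being
#'   emulated were 20 s).
#' @param fs Sample rate, Hz.
#' @param seed Integer seed; fixes the waveform exactly.
#' @param decorrelation Fraction (0--1) of independent noise power in the
#'   second ear.
#' @return A calibrated [binaural_audio()] object.
#' @export
flyover_waveform <- function(level_dba, duration = 20, fs = 32000, seed = 1,
                             decorrelation = 0.1) {
  stopifnot(duration >= 5, fs > 8000)
  set.seed(seed)
  n <- round(duration * fs)
  shape_db <- aircraft_template()

  shaped_noise <- function() {
    x <- stats::rnorm(n)
    X <- stats::fft(x)
    f <- (seq_len(n) - 1) * fs / n
    f <- pmin(f, fs - f)                      # two-sided -> frequency
    amp_db <- stats::approx(log10(shape_db$freq_hz), shape_db$level_db,
                            xout = log10(pmax(f, 1)), rule = 2)$y
    amp_db[f < 20 | f > 16000] <- -80
    Re(stats::fft(X * 10^(amp_db / 20), inverse = TRUE)) / n
  }

  base <- shaped_noise()
  extra <- shaped_noise()
  left <- base
  right <- sqrt(1 - decorrelation) * base + sqrt(decorrelation) * extra

  t <- seq_len(n) / n
  env <- sin(pi * t)^2                        # rise-fall, peak mid-file
  audio <- binaural_audio(left * env, right * env, fs = fs, cal_db = 94)
  calibrate_level(audio, level_dba)
}

#' The 85-condition jury-test design
#'
#' The full laboratory design: 5 aircraft-alone conditions, 5 road-alone
#' conditions, 25 aircraft-with-road combinations (aircraft rated), 25
#' road-with-aircraft combinations (road rated) and 25 combined conditions
#' (total rated). Aircraft levels are 63--83 dBA in 5-dB steps; road levels
#' 55--75 dBA in 5-dB steps.
#'
#' @return Data frame with 85 rows: `condition`, `type`, `aircraft_db`,
#'   `road_db`, `rated`.
#' @export
jury_design <- function() {
  air <- c(63, 68, 73, 78, 83)
  road <- c(55, 60, 65, 70, 75)
  combos <- expand.grid(aircraft_db = air, road_db = road)
  d <- rbind(
    data.frame(type = "aircraft_alone", aircraft_db = air, road_db = NA_real_,
               rated = "aircraft"),
    data.frame(type = "road_alone", aircraft_db = NA_real_, road_db = road,
               rated = "road"),
    data.frame(type = "aircraft_with_road", aircraft_db = combos$aircraft_db,
               road_db = combos$road_db, rated = "aircraft"),
    data.frame(type = "road_with_aircraft", aircraft_db = combos$aircraft_db,
               road_db = combos$road_db, rated = "road"),
    data.frame(type = "combined", aircraft_db = combos$aircraft_db,
               road_db = combos$road_db, rated = "total"))
  cbind(condition = seq_len(nrow(d)), d)
}

# loudness of one jury condition (sones), with memoized excitation patterns
jury_condition_loudness <- function(design, constants = loudness_constants()) {
  memo <- new.env(parent = emptyenv())
  exc <- function(src, level) {
    key <- paste(src, level)
    if (!is.null(memo[[key]])) return(memo[[key]])
    spec <- if (src == "air") aircraft_spectrum(level) else road_spectrum(level)
    memo[[key]] <- excitation_from_spectrum(spec, constants = constants)
    memo[[key]]
  }
  diotic <- function(S) {
    pair <- binaural_inhibition(S, S, constants)
    integrate_loudness(pair$left) + integrate_loudness(pair$right)
  }
  vapply(seq_len(nrow(design)), function(i) {
    row <- design[i, ]
    switch(as.character(row$type),
      aircraft_alone = diotic(specific_loudness(exc("air", row$aircraft_db),
                                                constants)),
      road_alone = diotic(specific_loudness(exc("road", row$road_db),
                                            constants)),
      aircraft_with_road = diotic(partial_specific_loudness(
        exc("air", row$aircraft_db), exc("road", row$road_db), constants)),
      road_with_aircraft = diotic(partial_specific_loudness(
        exc("road", row$road_db), exc("air", row$aircraft_db), constants)),
      combined = diotic(specific_loudness(
        add_excitation(exc("air", row$aircraft_db), exc("road", row$road_db)),
        constants)))
  }, numeric(1))
}

#' Simulate individual annoyance ratings around a generating curve
#'
#' For each loudness value the mean rating is taken from the short-term
#' exposure--response model; each simulated subject adds Gaussian response
#' noise, and ratings are optionally rounded to the 11-point integer scale
#' and clipped to \[0, 10\].
#'
#' @param loudness Vector of loudness values, sones.
#' @param n_subjects Subjects per stimulus (>= 1).
#' @param noise_sd Response-noise SD in scale points.
#' @param seed Integer seed.
#' @param round_scale Round ratings to integers (the jury procedure) or keep
#'   them continuous.
#' @param params Generating [logistic_params()]; defaults to the fitted
#'   short-term model.
#' @return Matrix `n_subjects x length(loudness)` of ratings.
#' @export
simulate_ratings <- function(loudness, n_subjects = 50, noise_sd = 0.5,
                             seed = 1, round_scale = TRUE,
                             params = short_term_params()) {
  stopifnot(n_subjects >= 1, noise_sd >= 0)
  set.seed(seed)
  mu <- logistic(loudness, params)
  r <- matrix(stats::rnorm(n_subjects * length(loudness), 0, noise_sd),
              nrow = n_subjects)
  r <- sweep(r, 2, mu, "+")
  if (round_scale) r <- round(r)
  pmin(pmax(r, 0), 10)
}

#' Simulate the jury experiment
#'
#' Computes the (partial/total) loudness of every condition in the design via
#' the loudness chain, then simulates subject ratings from the short-term
#' model with Gaussian response noise, rounded to the 11-point scale.
#'
#' @param design Design table from [jury_design()].
#' @param n_subjects Subjects (>= 1).
#' @param noise_sd Response-noise SD in scale points.
#' @param seed Integer seed.
#' @param constants A [loudness_constants()] bundle.
#' @return Data frame with one row per condition x subject: design columns
#'   plus `loudness`, `subject`, `rating`.
#' @export
simulate_jury <- function(design = jury_design(), n_subjects = 50,
                          noise_sd = 0.5, seed = 1,
                          constants = loudness_constants()) {
  loud <- jury_condition_loudness(design, constants)
  ratings <- simulate_ratings(loud, n_subjects, noise_sd, seed)
  out <- design[rep(seq_len(nrow(design)), each = n_subjects), ]
  out$loudness <- rep(loud, each = n_subjects)
  out$subject <- rep(seq_len(n_subjects), times = nrow(design))
  out$rating <- as.vector(ratings)
  rownames(out) <- NULL
  out
}

#' Simulate a long-term field survey over an exposure grid
#'
#' Draws survey respondents from the cells of an exposure grid: indoor levels
#' follow from the outdoor levels by the source-specific corrections, partial
#' and total loudness are computed with the loudness chain, the
#' highly-annoyed indicator is Bernoulli with probability given by the
#' long-term exposure--response model at the respondent's total loudness, and
#' the exposure group follows the combined outdoor level.
#'
#' @param grid An [receiver_grid()] exposure grid.
#' @param n_subjects Number of respondents drawn (cells sampled uniformly
#'   with replacement).
#' @param seed Integer seed.
#' @param constants A [loudness_constants()] bundle.
#' @param params Generating long-term [logistic_params()].
#' @return Data frame with `receiver`, `x`, `y`, `aircraft_db`, `road_db`,
#'   `aircraft_indoor_db`, `road_indoor_db`, `loud_aircraft`, `loud_road`,
#'   `loud_total`, `highly_annoyed`, `group`.
#' @export
simulate_survey <- function(grid, n_subjects = 1000, seed = 1,
                            constants = loudness_constants(),
                            params = long_term_params()) {
  stopifnot(inherits(grid, "exposure_grid"), n_subjects >= 1)
  set.seed(seed)
  ny <- nrow(grid$aircraft); nx <- ncol(grid$aircraft)
  cell <- sample.int(nx * ny, n_subjects, replace = TRUE)
  row <- (cell - 1) %% ny + 1
  col <- (cell - 1) %/% ny + 1
  air <- grid$aircraft[cbind(row, col)]
  road <- grid$road[cbind(row, col)]

  # loudness per unique exposure pair (many respondents share a cell)
  key <- paste(air, road)
  uk <- !duplicated(key)
  tri <- t(mapply(cell_loudness, air[uk], road[uk],
                  MoreArgs = list(constants = constants)))
  rownames(tri) <- key[uk]
  tri <- tri[key, , drop = FALSE]

  p <- logistic(tri[, "total"], params) / 100
  ha <- stats::runif(n_subjects) < p
  combined <- mapply(function(a, r) combine_levels_db(c(a, r)), air, road)

  data.frame(receiver = seq_len(n_subjects),
             x = grid$origin[1] + (col - 0.5) * grid$cellsize,
             y = grid$origin[2] + (row - 0.5) * grid$cellsize,
             aircraft_db = air, road_db = road,
             aircraft_indoor_db = indoor_level(air, "aircraft"),
             road_indoor_db = indoor_level(road, "road"),
             loud_aircraft = tri[, "aircraft"], loud_road = tri[, "road"],
             loud_total = tri[, "total"],
             highly_annoyed = ha,
             group = exposure_group(combined),
             row.names = NULL)
}

#' Simulate binned highly-annoyed proportions from the long-term model
#'
#' Draws Bernoulli highly-annoyed indicators in 5-sone loudness groups with
#' the success probability given by the long-term model at each bin midpoint,
#' and tabulates the empirical %HA per bin — the self-consistency simulation
#' used to check parameter recovery of the survey model.
#'
#' @param n_per_bin Respondents per bin.
#' @param n_bins Number of bins (default 9, covering 0--45 sones).
#' @param width Bin width in sones.
#' @param seed Integer seed.
#' @param params Generating [logistic_params()].
#' @return Data frame with `lower`, `upper`, `mid`, `n`, `pct_ha`,
#'   `p_true` (generating %).
#' @export
simulate_survey_bins <- function(n_per_bin = 2000, n_bins = 9, width = 5,
                                 seed = 1, params = long_term_params()) {
  set.seed(seed)
  lower <- (seq_len(n_bins) - 1) * width
  mid <- lower + width / 2
  p <- logistic(mid, params) / 100
  pct <- vapply(p, function(pi)
    100 * mean(stats::runif(n_per_bin) < pi), numeric(1))
  data.frame(lower = lower, upper = lower + width, mid = mid,
             n = n_per_bin, pct_ha = pct, p_true = 100 * p)
}

#' Toy exposure grid: a line-source road and an overhead flight track
#'
#' Builds a rectangular 10-m receiver grid with a road running horizontally
#' and an aircraft flight track running vertically. Each source's outdoor
#' level decays by a fixed number of dB per doubling of distance from its
#' axis beyond a reference distance, giving smooth, bounded fields. A toy
#' stand-in for the prediction-model noise maps the survey was based on.
#'
#' @param nx,ny Grid dimensions (cells).
#' @param cellsize Cell size in m (default 10).
#' @param road_level,air_level Source levels on the respective axes, dBA.
#' @param road_frac,air_frac Position of the road (fraction of the y extent)
#'   and the flight track (fraction of the x extent).
#' @param road_decay,air_decay dB per doubling of distance.
#' @param d_ref Reference distance in m.
#' @return Object of class `exposure_grid`: list with matrices `aircraft`,
#'   `road` (rows = y, columns = x, row 1 at the south edge), `origin`,
#'   `cellsize`.
#' @export
receiver_grid <- function(nx = 30, ny = 30, cellsize = 10,
                          road_level = 75, air_level = 80,
                          road_frac = 0.25, air_frac = 0.5,
                          road_decay = 4, air_decay = 6, d_ref = 25) {
  x <- (seq_len(nx) - 0.5) * cellsize
  y <- (seq_len(ny) - 0.5) * cellsize
  road_y <- road_frac * ny * cellsize
  air_x <- air_frac * nx * cellsize
  road <- matrix(distance_attenuation(road_level, abs(rep(y, nx) - road_y),
                                      d_ref, road_decay), nrow = ny)
  air <- matrix(distance_attenuation(air_level,
                                     abs(rep(x, each = ny) - air_x),
                                     d_ref, air_decay), nrow = ny)
  structure(list(aircraft = air, road = road,
                 origin = c(0, 0), cellsize = cellsize),
            class = "exposure_grid")
}

#' @export
print.exposure_grid <- function(x, ...) {
  cat(sprintf(
    "Exposure grid: %d x %d cells at %g m; aircraft %.1f-%.1f dBA, road %.1f-%.1f dBA\n",
    ncol(x$aircraft), nrow(x$aircraft), x$cellsize,
    min(x$aircraft), max(x$aircraft), min(x$road), max(x$road)))
  invisible(x)
}
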