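#' Specific loudness of an unmasked excitation pattern
#'
#' Converts excitation to loudness density (sones per Cam) per channel with
#' the compressive transform `N' = C[(E G + A)^alpha - A^alpha]`, using the
#' low-level branch `N' = C (2E/(E + E_THRQ))^1.5 [(E G + A)^alpha - A^alpha]`
#' below the absolute-threshold excitation and the high-level branch
#' `N' = C (E / 1.04e6)^0.5` above an excitation of 10^10.
#'
#' @param E An `excitation_pattern`.
#' @param constants A [loudness_constants()] bundle (must match the grid the
#'   pattern was computed on).
#' @param role Role tag stored on the result: `"total"`, `"target_partial"`
#'   or `"background"`.
#' @return An object of class `specific_loudness_pattern`: list with `cam`,
#'   `n_prime` (sones per Cam), `cam_step` and `role`.
#' @export
specific_loudness <- function(E, constants = loudness_constants(),
                              role = "total") {
  stopifnot(inherits(E, "excitation_pattern"))
  if (length(E$cam) != length(constants$cam) || any(E$cam != constants$cam))
    stop("excitation pattern grid does not match the constants grid")
  n <- n_prime_unmasked(E$excitation, constants)
  structure(list(cam = E$cam, n_prime = n, cam_step = E$cam_step, role = role),
            class = "specific_loudness_pattern")
}

# vectorized unmasked specific loudness over channels
n_prime_unmasked <- function(e, cst) {
  G <- cst$G; A <- cst$A; al <- cst$alpha; Et <- cst$E_THRQ; C <- cst$C
  core <- (e * G + A)^al - A^al
  n <- C * core
  low <- e < Et
  if (any(low)) {
    fac <- (2 * e[low] / (e[low] + Et[low]))^1.5
    n[low] <- C * fac * core[low]
  }
  high <- e > 1e10
  if (any(high)) n[high] <- C * (e[high] / 1.04e6)^0.5
  n[e <= 0] <- 0
  pmax(n, 0)
}

#' Partial specific loudness of a target under a background
#'
#' Loudness density of a target sound in the presence of a masking background,
#' per channel. The masked-threshold excitation is
#' `E_THRN = K E_bg + E_THRQ`. For a target at or above its masked threshold,
#' `N' = C[((E_sig + E_bg) G + A)^alpha - A^alpha]
#'  - C[((E_bg (1+K) + E_THRQ) G + A)^alpha - (E_THRQ G + A)^alpha]
#'    (E_THRN / E_sig)^0.3`;
#' below the masked threshold the value falls with the factor
#' `(2 E_sig / (E_sig + E_THRN))^1.5` and is continuous at the threshold,
#' where the partial loudness equals the loudness of a tone at the absolute
#' threshold in quiet. With a silent background in a channel, the unmasked
#' formula is used in that channel, so the no-masker case reproduces
#' [specific_loudness()] exactly. Values are clamped to
#' `[0, unmasked target N']` (partial masking cannot increase loudness).
#'
#' @param E_target,E_background `excitation_pattern` objects on the same grid.
#' @param constants A [loudness_constants()] bundle.
#' @return A `specific_loudness_pattern` with role `"target_partial"`.
#' @export
partial_specific_loudness <- function(E_target, E_background,
                                      constants = loudness_constants()) {
  stopifnot(inherits(E_target, "excitation_pattern"),
            inherits(E_background, "excitation_pattern"))
  check_same_grid(E_target, E_background)
  if (length(E_target$cam) != length(constants$cam) ||
      any(E_target$cam != constants$cam))
    stop("excitation pattern grid does not match the constants grid")

  cst <- constants
  es <- E_target$excitation
  eb <- E_background$excitation
  G <- cst$G; A <- cst$A; al <- cst$alpha
  Et <- cst$E_THRQ; K <- cst$K; C <- cst$C; q <- cst$partial_exponent

  n <- numeric(length(es))
  quiet <- eb <= 0
  n[quiet] <- n_prime_unmasked(es[quiet], sub_channels(cst, quiet))

  m <- !quiet & es > 0
  if (any(m)) {
    ethrn <- K[m] * eb[m] + Et[m]
    above <- es[m] >= ethrn
    idx <- which(m)
    thr_quiet <- (Et[m] * G[m] + A[m])^al[m] - A[m]^al[m]  # threshold-in-quiet core
    corr <- ((eb[m] * (1 + K[m]) + Et[m]) * G[m] + A[m])^al[m] -
            (Et[m] * G[m] + A[m])^al[m]
    tot <- ((es[m] + eb[m]) * G[m] + A[m])^al[m] - A[m]^al[m]
    val <- numeric(sum(m))
    # target at or above its masked threshold
    va <- C * tot[above] - C * corr[above] * (ethrn[above] / es[m][above])^q
    val[above] <- va
    # target below its masked threshold: continuous at E_sig = E_THRN
    if (any(!above)) {
      b <- !above
      base <- (eb[m][b] * (1 + K[m][b])) * G[m][b] + A[m][b]
      num <- (base + es[m][b] * G[m][b])^al[m][b] - base^al[m][b]
      den <- (base + ethrn[b] * G[m][b])^al[m][b] - base^al[m][b]
      fac <- (2 * es[m][b] / (es[m][b] + ethrn[b]))^1.5
      val[b] <- C * fac * thr_quiet[b] * num / den
    }
    n[idx] <- val
  }

  unmasked <- n_prime_unmasked(es, cst)
  n <- pmin(pmax(n, 0), unmasked)

  structure(list(cam = E_target$cam, n_prime = n,
                 cam_step = E_target$cam_step, role = "target_partial"),
            class = "specific_loudness_pattern")
}

# internal: subset per-channel constants vectors
sub_channels <- function(cst, idx) {
  out <- cst
  for (f in c("cam", "freq", "G", "G_db", "A", "alpha", "E_THRQ", "E_THRQ_db",
              "K", "K_db", "p51"))
    out[[f]] <- cst[[f]][idx]
  out
}

#' @export
print.specific_loudness_pattern <- function(x, ...) {
  cat(sprintf("Specific loudness (%s): %d channels, integral %.3f sones\n",
              x$role, length(x$cam), integrate_loudness(x)))
  invisible(x)
}

#' Integrate a specific-loudness pattern to total loudness
#'
#' Sum of the loudness density over the Cam scale (density times channel
#' spacing). Linear: the integral of a channel-wise sum of patterns is the sum
#' of the integrals.
#'
#' @param pattern A `specific_loudness_pattern`.
#' @return Loudness in sones (scalar, >= 0).
#' @export
integrate_loudness <- function(pattern) {
  stopifnot(inherits(pattern, "specific_loudness_pattern"))
  sum(pattern$n_prime) * pattern$cam_step
}

#' Binaural inhibition of left/right specific-loudness patterns
#'
#' The signal at each ear reduces the internal response at the other ear.
#' Each ear's specific loudness is divided channel-wise by its effective
#' factor `INH = 2 / (1 + sech(S_contra / S_ipsi))^P` with `P = 1.598`, where
#' the ratio is formed from patterns smoothed across the Cam axis by a
#' two-sided exponential kernel. With a silent contralateral ear the factor is
#' `2^(1 - P)` (about 0.661, raising the ipsilateral loudness by about 1.51);
#' for identical ears it is about 0.900, so diotic loudness is about 1.5 times
#' monaural rather than double. Channels where the ipsilateral smoothed
#' pattern is zero stay zero.
#'
#' @param S_left,S_right `specific_loudness_pattern` objects on the same grid.
#' @param constants A [loudness_constants()] bundle.
#' @return List with inhibited patterns `left` and `right`.
#' @export
binaural_inhibition <- function(S_left, S_right,
                                constants = loudness_constants()) {
  stopifnot(inherits(S_left, "specific_loudness_pattern"),
            inherits(S_right, "specific_loudness_pattern"))
  check_same_grid(S_left, S_right)
  if (any(S_left$n_prime < 0) || any(S_right$n_prime < 0))
    stop("specific loudness must be non-negative")

  sl <- smooth_pattern(S_left$n_prime, constants)
  sr <- smooth_pattern(S_right$n_prime, constants)
  p <- constants$P_binaural

  inh_for <- function(ipsi_s, contra_s) {
    r <- rep(Inf, length(ipsi_s))            # silent ipsi: factor irrelevant
    pos <- ipsi_s > 0
    r[pos] <- contra_s[pos] / ipsi_s[pos]
    2 / (1 + sech(r))^p
  }

  out_l <- S_left
  out_r <- S_right
  fl <- inh_for(sl, sr)
  fr <- inh_for(sr, sl)
  out_l$n_prime <- ifelse(sl > 0, S_left$n_prime / fl, 0)
  out_r$n_prime <- ifelse(sr > 0, S_right$n_prime / fr, 0)
  list(left = out_l, right = out_r)
}

# hyperbolic secant, with sech(Inf) = 0
sech <- function(x) {
  out <- 1 / cosh(x)
  out[!is.finite(x)] <- 0
  out
}

# two-sided exponential smoothing across the Cam axis, unit-sum kernel
smooth_pattern <- function(n_prime, constants) {
  w <- constants$smooth_width
  if (is.null(w) || w <= 0) return(n_prime)
  half <- ceiling(10 * w / constants$cam_step)
  lag <- (-half):half
  k <- exp(-abs(lag) * constants$cam_step / w)
  k <- k / sum(k)
  as.numeric(stats::filter(c(rep(0, half), n_prime, rep(0, half)),
                           k, sides = 2))[(half + 1):(half + length(n_prime))]
}

#' Stationary loudness of a spectrum with binaural inhibition
#'
#' Full chain for a stationary stimulus: excitation pattern, specific
#' loudness, binaural inhibition, integration over channels and summation
#' across ears.
#'
#' @param spectrum A [third_octave_spectrum()] (presented to both ears for
#'   `ears = "diotic"`, to one ear for `ears = "monaural"`).
#' @param field Presentation field, `"free"` or `"diffuse"`.
#' @param ears `"diotic"` or `"monaural"`.
#' @param constants A [loudness_constants()] bundle.
#' @return Loudness in sones.
#' @export
#' @examples
#' loudness_stationary(third_octave_spectrum(1000, 40)) # about 1 sone
loudness_stationary <- function(spectrum, field = "free",
                                ears = c("diotic", "monaural"),
                                constants = loudness_constants()) {
  ears <- match.arg(ears)
  E <- excitation_from_spectrum(spectrum, field, constants)
  S <- specific_loudness(E, constants)
  S0 <- S
  S0$n_prime <- numeric(length(S$n_prime))
  pair <- if (ears == "diotic") binaural_inhibition(S, S, constants)
          else binaural_inhibition(S, S0, constants)
  integrate_loudness(pair$left) + integrate_loudness(pair$right)
}

#' Stationary partial loudness of a target under a background
#'
#' Diotic partial loudness of the target stimulus with the background as
#' masker, including binaural inhibition.
#'
#' @param target,background [third_octave_spectrum()] objects; `background`
#'   may be `NULL` (no masker).
#' @param field Presentation field.
#' @param constants A [loudness_constants()] bundle.
#' @return Partial loudness in sones.
#' @export
partial_loudness_stationary <- function(target, background = NULL,
                                        field = "free",
                                        constants = loudness_constants()) {
  Et <- excitation_from_spectrum(target, field, constants)
  Eb <- if (is.null(background)) zero_excitation(constants)
        else excitation_from_spectrum(background, field, constants)
  S <- partial_specific_loudness(Et, Eb, constants)
  pair <- binaural_inhibition(S, S, constants)
  integrate_loudness(pair$left) + integrate_loudness(pair$right)
}

#' Stationary total loudness of two combined sources
#'
#' Diotic loudness of the power sum of two stimuli (incoherent combination of
#' their excitation patterns).
#'
#' @param spec_a,spec_b [third_octave_spectrum()] objects (`spec_b` may be
#'   `NULL`).
#' @param field Presentation field.
#' @param constants A [loudness_constants()] bundle.
#' @return Loudness in sones.
#' @export
total_loudness_stationary <- function(spec_a, spec_b = NULL, field = "free",
                                      constants = loudness_constants()) {
  Ea <- excitation_from_spectrum(spec_a, field, constants)
  E <- if (is.null(spec_b)) Ea
       else add_excitation(Ea, excitation_from_spectrum(spec_b, field, constants))
  S <- specific_loudness(E, constants)
  pair <- binaural_inhibition(S, S, constants)
  integrate_loudness(pair$left) + integrate_loudness(pair$right)
}
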