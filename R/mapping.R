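#' Partial and total loudness of a receiver cell
#'
#' The per-cell computation behind the annoyance map: outdoor levels are
#' corrected to indoor levels (aircraft -15.0 dBA, road -15.8 dBA, slightly
#' opened window), the source template spectra are calibrated to the indoor
#' levels, and three stationary loudness values are computed — the partial
#' loudness of the aircraft with the road as masker, the partial loudness of
#' the road with the aircraft as masker, and the total loudness of the
#' combination. Indoor levels below 0 dBA (or `-Inf`/`NA` exposure) are
#' treated as silent. An absent source leaves the other source's loudness
#' exactly equal to its single-source value.
#'
#' @param aircraft_dba,road_dba Outdoor exposure levels, dBA (may be `-Inf`
#'   or `NA` for no source).
#' @param constants A [loudness_constants()] bundle.
#' @param indoor Apply the outdoor-to-indoor corrections (default TRUE).
#' @return Named numeric vector `c(aircraft=, road=, total=)`, sones.
#' @export
#' @examples
#' cell_loudness(70, 65)
cell_loudness <- function(aircraft_dba, road_dba,
                          constants = loudness_constants(), indoor = TRUE) {
  lv <- function(outdoor, source) {
    if (is.na(outdoor) || !is.finite(outdoor)) return(-Inf)
    if (indoor) indoor_level(outdoor, source) else outdoor
  }
  la <- lv(aircraft_dba, "aircraft")
  lr <- lv(road_dba, "road")
  # audibility floor: indoor levels below 0 dBA contribute no excitation
  ea <- if (la >= 0) excitation_from_spectrum(aircraft_spectrum(la),
                                              constants = constants)
        else zero_excitation(constants)
  er <- if (lr >= 0) excitation_from_spectrum(road_spectrum(lr),
                                              constants = constants)
        else zero_excitation(constants)

  diotic <- function(S) {
    pair <- binaural_inhibition(S, S, constants)
    integrate_loudness(pair$left) + integrate_loudness(pair$right)
  }
  c(aircraft = diotic(partial_specific_loudness(ea, er, constants)),
    road = diotic(partial_specific_loudness(er, ea, constants)),
    total = diotic(specific_loudness(add_excitation(ea, er), constants)))
}

#' Annoyance surfaces from an exposure grid
#'
#' Applies [cell_loudness()] to every cell of a paired aircraft/road exposure
#' grid and converts each loudness layer to a percentage-highly-annoyed layer
#' with the long-term exposure--response model. The three %HA layers show
#' each source with the other as background plus the combined surface; cells
#' near a strong road suppress the aircraft %HA relative to equally exposed
#' cells far from it — the background-noise effect absent from ordinary noise
#' maps.
#'
#' @param grid An `exposure_grid` (see [receiver_grid()], [read_grid()]).
#' @param model An `annoyance_model`, [logistic_params()] object, or `NULL`
#'   for the default long-term model.
#' @param constants A [loudness_constants()] bundle.
#' @param indoor Apply indoor corrections before the loudness computation.
#' @return Object of class `annoyance_grid`: list with `origin`, `cellsize`
#'   and `layers` — matrices `loud_aircraft`, `loud_road`, `loud_total`,
#'   `pct_ha_aircraft`, `pct_ha_road`, `pct_ha_total`.
#' @export
annoyance_surface <- function(grid, model = NULL,
                              constants = loudness_constants(),
                              indoor = TRUE) {
  stopifnot(inherits(grid, "exposure_grid"))
  if (is.null(grid$aircraft) || is.null(grid$road))
    stop("grid must carry both an aircraft and a road exposure layer")
  params <- annoyance_params(model)
  ny <- nrow(grid$aircraft); nx <- ncol(grid$aircraft)
  la <- lr <- lt <- matrix(NA_real_, ny, nx)
  for (j in seq_len(nx)) {
    for (i in seq_len(ny)) {
      tri <- cell_loudness(grid$aircraft[i, j], grid$road[i, j],
                           constants, indoor)
      la[i, j] <- tri["aircraft"]; lr[i, j] <- tri["road"]
      lt[i, j] <- tri["total"]
    }
  }
  structure(list(origin = grid$origin, cellsize = grid$cellsize,
                 layers = list(loud_aircraft = la, loud_road = lr,
                               loud_total = lt,
                               pct_ha_aircraft = logistic(la, params),
                               pct_ha_road = logistic(lr, params),
                               pct_ha_total = logistic(lt, params))),
            class = "annoyance_grid")
}

# accept an annoyance_model, logistic_params, or NULL (default long-term)
annoyance_params <- function(model) {
  if (is.null(model)) return(long_term_params())
  if (inherits(model, "annoyance_model")) return(model$params)
  if (inherits(model, "logistic_params")) return(model)
  stop("model must be an annoyance_model or logistic_params object")
}

#' @export
print.annoyance_grid <- function(x, ...) {
  cat(sprintf("Annoyance grid: %d x %d cells at %g m; total %%HA %.1f-%.1f\n",
              ncol(x$layers[[1]]), nrow(x$layers[[1]]), x$cellsize,
              min(x$layers$pct_ha_total), max(x$layers$pct_ha_total)))
  invisible(x)
}

#' Exposure group of an outdoor level
#'
#' The four survey exposure groups: below 50 dBA, 50--60 dBA, 60--70 dBA and
#' over 70 dBA. Boundaries are half-open with ties assigned upward (60 dBA
#' falls in the 60--70 group).
#'
#' @param level_dba Outdoor level(s), dBA.
#' @return Factor with levels `"less than 50 dBA"`, `"50-60 dBA"`,
#'   `"60-70 dBA"`, `"over 70 dBA"`.
#' @export
#' @examples
#' exposure_group(c(45, 60, 75))
exposure_group <- function(level_dba) {
  stopifnot(all(is.finite(level_dba)))
  cut(level_dba, breaks = c(-Inf, 50, 60, 70, Inf), right = FALSE,
      labels = c("less than 50 dBA", "50-60 dBA", "60-70 dBA", "over 70 dBA"))
}
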