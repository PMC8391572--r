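#' RLS-90 idealized road-traffic emission level
#'
#' Mean emission level at 25 m from the lane under idealized conditions
#' (100/80 km/h light/heavy vehicles, gradient below 5 %, smooth asphalt):
#' `Lm_E = 37.3 + 10 log10(Q (1 + 0.082 P))`.
#'
#' @param Q Traffic volume, vehicles per hour (> 0).
#' @param P_trucks Percentage of heavy trucks (> 2.8 t), 0--100.
#' @return Emission level in dB.
#' @export
#' @examples
#' rls90_emission_level(1000, 10) # about 69.9 dB
rls90_emission_level <- function(Q, P_trucks) {
  if (any(Q <= 0)) stop("emission level undefined for zero traffic volume (Q = 0)")
  if (any(P_trucks < 0 | P_trucks > 100)) stop("P_trucks must lie in [0, 100]")
  37.3 + 10 * log10(Q * (1 + 0.082 * P_trucks))
}

#' RLS-90 speed-limit correction
#'
#' Correction of the emission level for posted speed limits:
#' `R_SL = L_car - 37.3 + 10 log10((100 + (10^(0.1 D) - 1) P) / (100 + 8.23 P))`
#' with `L_car = 27.7 + 10 log10(1 + (0.02 v_car)^3)`,
#' `L_truck = 23.1 + 12.5 log10(v_truck)` and `D = L_truck - L_car`.
#' At the reference speeds (100 km/h cars, 80 km/h trucks) the correction is
#' within 0.1 dB of zero for any truck percentage.
#'
#' @param v_car,v_truck Speed limits in km/h, each within \[30, 130\].
#' @param P_trucks Percentage of heavy trucks, 0--100.
#' @return Correction `R_SL` in dB.
#' @export
rls90_speed_correction <- function(v_car, v_truck, P_trucks) {
  if (any(v_car < 30 | v_car > 130) || any(v_truck < 30 | v_truck > 130))
    stop("speed limits must lie within [30, 130] km/h")
  if (any(P_trucks < 0 | P_trucks > 100)) stop("P_trucks must lie in [0, 100]")
  l_car <- 27.7 + 10 * log10(1 + (0.02 * v_car)^3)
  l_truck <- 23.1 + 12.5 * log10(v_truck)
  d <- l_truck - l_car
  l_car - 37.3 +
    10 * log10((100 + (10^(0.1 * d) - 1) * P_trucks) / (100 + 8.23 * P_trucks))
}

#' RLS-90 road-gradient correction
#'
#' `R_RG = 0.6 g - 3` dB for gradients above 5 %, zero otherwise (continuous
#' at g = 5).
#'
#' @param g Road gradient in percent (>= 0).
#' @return Correction in dB.
#' @export
rls90_gradient_correction <- function(g) {
  if (any(g < 0)) stop("gradient must be non-negative")
  ifelse(g > 5, 0.6 * g - 3, 0)
}

#' Road segment description for the RLS-90 chain
#'
#' @param Q Traffic volume, vehicles/hour.
#' @param P_trucks Percentage of heavy trucks (> 2.8 t).
#' @param v_car,v_truck Speed limits, km/h, in \[30, 130\].
#' @param g Road gradient, percent.
#' @param R_RS,R_E,R_DA,R_GA,R_TB User-supplied corrections in dB (road
#'   surface, building absorption, distance/air, ground/atmosphere,
#'   topography/buildings); the guideline defines these from geometry and are
#'   accepted here as inputs, defaulting to 0.
#' @param K Surcharge for light-controlled intersections, dB.
#' @return A `road_segment` list.
#' @export
road_segment <- function(Q, P_trucks = 0, v_car = 100, v_truck = 80, g = 0,
                         R_RS = 0, R_E = 0, R_DA = 0, R_GA = 0, R_TB = 0,
                         K = 0) {
  stopifnot(Q >= 0, P_trucks >= 0, P_trucks <= 100)
  structure(list(Q = Q, P_trucks = P_trucks, v_car = v_car, v_truck = v_truck,
                 g = g, R_RS = R_RS, R_E = R_E, R_DA = R_DA, R_GA = R_GA,
                 R_TB = R_TB, K = K),
            class = "road_segment")
}

#' RLS-90 receiver level for a road segment
#'
#' Chains the emission level, the speed and gradient corrections and the
#' user-supplied corrections into the mean emission level
#' `Lm = Lm_E + R_SL + R_RS + R_RG + R_E + R_DA + R_GA + R_TB` and the
#' receiver level `Lr = Lm + K`. All intermediates are reported.
#'
#' @param segment A [road_segment()].
#' @return List of class `emission_result` with `Lm_E`, `R_SL`, `R_RG`,
#'   `L_car`, `L_truck`, `D`, `Lm`, `Lr`.
#' @export
rls90_receiver_level <- function(segment) {
  stopifnot(inherits(segment, "road_segment"))
  lm_e <- rls90_emission_level(segment$Q, segment$P_trucks)
  r_sl <- rls90_speed_correction(segment$v_car, segment$v_truck,
                                 segment$P_trucks)
  r_rg <- rls90_gradient_correction(segment$g)
  l_car <- 27.7 + 10 * log10(1 + (0.02 * segment$v_car)^3)
  l_truck <- 23.1 + 12.5 * log10(segment$v_truck)
  lm <- lm_e + r_sl + segment$R_RS + r_rg + segment$R_E + segment$R_DA +
    segment$R_GA + segment$R_TB
  structure(list(Lm_E = lm_e, R_SL = r_sl, R_RG = r_rg,
                 L_car = l_car, L_truck = l_truck, D = l_truck - l_car,
                 Lm = lm, Lr = lm + segment$K),
            class = "emission_result")
}

#' @export
print.emission_result <- function(x, ...) {
  cat(sprintf(
    "RLS-90: Lm_E = %.1f, R_SL = %.2f, R_RG = %.1f -> Lm = %.1f, Lr = %.1f dB\n",
    x$Lm_E, x$R_SL, x$R_RG, x$Lm, x$Lr))
  invisible(x)
}

#' Combine per-lane receiver levels energetically
#'
#' Multi-lane receiver level as the power sum of the per-lane levels: two
#' identical lanes add 3.01 dB.
#'
#' @param levels_db Vector of per-lane receiver levels, dB.
#' @return Combined level in dB.
#' @export
rls90_combine_lanes <- function(levels_db) combine_levels_db(levels_db)

#' Read road segments from CSV and compute receiver levels
#'
#' The CSV dialect is one row per lane/segment with header columns
#' `q_veh_h,p_trucks_pct,v_car,v_truck,gradient_pct,r_rs,r_e,r_da,r_ga,r_tb,k`
#' (missing correction columns default to 0). The output mirrors the
#' `emission_result` fields per row.
#'
#' @param path CSV file path.
#' @return Data frame of inputs plus `Lm_E`, `R_SL`, `R_RG`, `Lm`, `Lr`.
#' @export
rls90_from_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("q_veh_h", "p_trucks_pct", "v_car", "v_truck", "gradient_pct")
  if (!all(need %in% names(df)))
    stop("road CSV must have columns ", paste(need, collapse = ","))
  for (cn in c("r_rs", "r_e", "r_da", "r_ga", "r_tb", "k"))
    if (!cn %in% names(df)) df[[cn]] <- 0
  res <- lapply(seq_len(nrow(df)), function(i) {
    seg <- road_segment(df$q_veh_h[i], df$p_trucks_pct[i], df$v_car[i],
                        df$v_truck[i], df$gradient_pct[i], df$r_rs[i],
                        df$r_e[i], df$r_da[i], df$r_ga[i], df$r_tb[i],
                        df$k[i])
    unlist(rls90_receiver_level(seg)[c("Lm_E", "R_SL", "R_RG", "Lm", "Lr")])
  })
  cbind(df, do.call(rbind, res))
}

#' Free-field distance attenuation helper for toy grids
#'
#' Simple level decay with distance from a source for constructing synthetic
#' exposure grids: `decay_db` per doubling of distance beyond `d_ref`. This
#' helper is a convenience beyond the emission formulas; it does not implement
#' the guideline's geometric propagation.
#'
#' @param level_db Source level at the reference distance, dB.
#' @param distance_m Distance(s) in m.
#' @param d_ref Reference distance in m.
#' @param decay_db Level decrease per doubling of distance, dB.
#' @return Attenuated level(s) in dB.
#' @export
distance_attenuation <- function(level_db, distance_m, d_ref = 25,
                                 decay_db = 4) {
  level_db - decay_db * log2(pmax(distance_m, d_ref) / d_ref)
}
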