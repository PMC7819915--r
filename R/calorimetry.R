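# Steady-state open-flow calorimetry: mass-balance inversion of excurrent
# gas fractions into whole-animal exchange rates, and the standard unit
# conversions (oxyjoule equivalent, latent heat, allometric surface area,
# dry thermal conductance).
#
# Conventions used throughout:
#   * O2/CO2 fractions (FeO2, FeCO2, FiO2, FiCO2) are dry-basis, i.e.
#     fractions of the gas stream after water removal, as read by analyzers
#     placed downstream of a drying column.
#   * Water is carried as a partial pressure (kPa) on the wet stream;
#     the wet mole fraction is PH2O/BP.
#   * FR is the metered flow (ml min^-1 STP) of DRY gas at the metering
#     position, which the `mode` determines:
#       push_chamber - metered upstream on the dry incurrent supply;
#       pull_mask / pull_chamber - metered downstream, after drying.

#' Milligrams of water per ml of water vapour at STP
#' @keywords internal
.MG_H2O_PER_ML <- 0.803

#' Construct a gas sample record
#'
#' A `gas_sample` bundles the excurrent readings of one steady-state
#' measurement (or a vector of them) together with the flow, barometric
#' pressure, incurrent composition and measurement configuration, ready for
#' [gas_exchange_rates()].
#'
#' @param feo2,feco2 excurrent dry-basis O2 and CO2 fractions (0-1).
#' @param ph2o excurrent water-vapour partial pressure (kPa).
#' @param fr metered dry flow rate (ml min^-1 STP); position set by `mode`.
#' @param mode one of `"push_chamber"`, `"pull_mask"`, `"pull_chamber"`.
#' @param fio2,fico2 incurrent dry-basis fractions (defaults 0.2095, 0).
#' @param pih2o incurrent water-vapour pressure (kPa, default 0: dried air).
#' @param bp barometric pressure (kPa, default 101.325).
#' @return A data frame of class `gas_sample`, one row per reading.
#' @export
gas_sample <- function(feo2, feco2, ph2o, fr,
                       mode = c("push_chamber", "pull_mask", "pull_chamber"),
                       fio2 = 0.2095, fico2 = 0, pih2o = 0, bp = 101.325) {
  mode <- match.arg(mode)
  s <- data.frame(feo2 = feo2, feco2 = feco2, ph2o = ph2o, fr = fr,
                  mode = mode, fio2 = fio2, fico2 = fico2,
                  pih2o = pih2o, bp = bp)
  validate_gas_sample(s)
  class(s) <- c("gas_sample", class(s))
  s
}

#' Validate a gas sample against its physical invariants
#'
#' Fractions must lie in \[0, 1\], flows must be positive and water-vapour
#' pressure must be below barometric pressure. Chamber runs with PH2O above
#' 2.5 kPa (the humidity ceiling the push-chamber protocol is designed to
#' respect) draw a warning, not an error.
#'
#' @param s a data frame with `gas_sample` columns.
#' @return `s`, invisibly. Errors on violation.
#' @export
validate_gas_sample <- function(s) {
  need <- c("feo2", "feco2", "ph2o", "fr", "mode", "fio2", "fico2",
            "pih2o", "bp")
  miss <- setdiff(need, names(s))
  if (length(miss))
    stop("gas sample is missing column(s): ", paste(miss, collapse = ", "))
  frac <- c("feo2", "feco2", "fio2", "fico2")
  for (f in frac)
    if (any(s[[f]] < 0 | s[[f]] > 1, na.rm = TRUE))
      stop("fraction '", f, "' outside [0, 1]")
  if (any(s$fr <= 0, na.rm = TRUE)) stop("flow rate must be positive")
  if (any(s$ph2o >= s$bp | s$pih2o >= s$bp, na.rm = TRUE))
    stop("water-vapour pressure at or above barometric pressure")
  if (any(s$ph2o < 0 | s$pih2o < 0, na.rm = TRUE))
    stop("negative water-vapour pressure")
  bad_mode <- setdiff(unique(as.character(s$mode)),
                      c("push_chamber", "pull_mask", "pull_chamber"))
  if (length(bad_mode)) stop("unknown mode: ", paste(bad_mode, collapse = ", "))
  if (any(s$mode == "push_chamber" & s$ph2o > 2.5, na.rm = TRUE))
    warning("chamber water-vapour pressure exceeds 2.5 kPa; ",
            "humidity ceiling for valid chamber runs violated")
  invisible(s)
}

#' Invert the steady-state mass balance to gas-exchange rates
#'
#' Recovers whole-animal oxygen consumption, carbon dioxide production
#' (both ml min^-1 STP) and evaporative water loss (mg min^-1) from
#' excurrent readings, by exact inversion of the steady-state species
#' balance of the measurement configuration.
#'
#' For `push_chamber` the metered flow is the dry incurrent supply
#' \eqn{F_i}; nitrogen conservation gives the dry excurrent flow
#' \eqn{F_e = F_i (1 - FiO_2 - FiCO_2) / (1 - FeO_2 - FeCO_2)} and then
#' \deqn{\dot{V}O_2 = F_i FiO_2 - F_e FeO_2, \quad
#'       \dot{V}CO_2 = F_e FeCO_2 - F_i FiCO_2.}
#' For the pull modes the metered flow is the dry excurrent \eqn{F_e} and
#' the same balance is solved for \eqn{F_i}. Water is recovered on the wet
#' stream from the vapour mole fraction \eqn{PH_2O/BP}:
#' \eqn{\dot{V}H_2O = F_e w_e/(1-w_e) - F_i w_i/(1-w_i)} ml min^-1 of
#' vapour, converted at 0.803 mg ml^-1.
#'
#' Small negative computed rates (|rate| below `tol`, analyzer noise) are
#' zeroed with a warning; larger negatives are kept and flagged in the
#' `flag` column rather than silently clamped.
#'
#' @param sample a [gas_sample()] (or data frame with the same columns).
#' @param tol noise tolerance for negative rates, ml min^-1 (water:
#'   mg min^-1). Default 0.01.
#' @return A data frame with columns `vo2`, `vco2` (ml min^-1), `ewl`
#'   (mg min^-1) and `flag` (logical: non-physical negative rate).
#' @export
gas_exchange_rates <- function(sample, tol = 0.01) {
  validate_gas_sample(sample)
  s <- as.data.frame(sample)
  pull <- s$mode %in% c("pull_mask", "pull_chamber")

  inert_i <- 1 - s$fio2 - s$fico2
  inert_e <- 1 - s$feo2 - s$feco2
  if (any(inert_e <= 0)) stop("excurrent O2 + CO2 fractions reach 1")

  # dry flows on both sides of the animal via N2 (inert) conservation
  fi <- ifelse(pull, s$fr * inert_e / inert_i, s$fr)
  fe <- ifelse(pull, s$fr, s$fr * inert_i / inert_e)

  vo2  <- fi * s$fio2  - fe * s$feo2
  vco2 <- fe * s$feco2 - fi * s$fico2

  we <- s$ph2o / s$bp
  wi <- s$pih2o / s$bp
  vh2o <- fe * we / (1 - we) - fi * wi / (1 - wi)
  ewl <- vh2o * .MG_H2O_PER_ML

  out <- data.frame(vo2 = vo2, vco2 = vco2, ewl = ewl, flag = FALSE)
  small <- function(r) r < 0 & r > -tol
  noisy <- small(out$vo2) | small(out$vco2) | small(out$ewl)
  out$vo2[small(out$vo2)] <- 0
  out$vco2[small(out$vco2)] <- 0
  out$ewl[small(out$ewl)] <- 0
  if (any(noisy))
    warning(sum(noisy), " record(s) had small negative rates (< ", tol,
            " in magnitude) zeroed as analyzer noise")
  out$flag <- out$vo2 < 0 | out$vco2 < 0 | out$ewl < 0
  if (any(out$flag))
    warning(sum(out$flag), " record(s) flagged: negative rate beyond the ",
            tol, " noise tolerance")
  out
}

#' Respiratory exchange ratio
#'
#' @param vo2,vco2 rates in ml min^-1; `vo2` must be positive.
#' @return `vco2 / vo2`.
#' @export
respiratory_exchange_ratio <- function(vo2, vco2) {
  if (any(vo2 <= 0)) stop("RER undefined for non-positive VO2")
  vco2 / vo2
}

#' Metabolic rate from oxygen consumption (oxyjoule equivalent)
#'
#' Converts oxygen consumption to metabolic heat production using the
#' RER-dependent oxyjoule equivalent (16 + 5.164 RER) J per ml O2:
#' \deqn{MR (W) = \dot{V}O_2 (16 + 5.164\,RER) / 60.}
#'
#' @param vo2 oxygen consumption, ml min^-1 (>= 0).
#' @param rer respiratory exchange ratio; values outside the physiological
#'   band 0.6-1.1 draw a warning.
#' @return metabolic rate in W.
#' @export
metabolic_rate <- function(vo2, rer) {
  if (any(vo2 < 0)) stop("negative VO2")
  if (any(rer < 0.6 | rer > 1.1))
    warning("RER outside the physiological range 0.6-1.1")
  vo2 * (16 + 5.164 * rer) / 60
}

#' Evaporative heat loss from evaporative water loss
#'
#' Latent heat of vaporization 2.4 J per mg H2O.
#'
#' @param ewl evaporative water loss, mg min^-1 (>= 0).
#' @return evaporative heat loss in W (`ewl * 2.4 / 60`).
#' @export
ehl_from_ewl <- function(ewl) {
  if (any(ewl < 0)) stop("negative EWL")
  ewl * 2.4 / 60
}

#' Allometric body surface area
#'
#' \eqn{A_s (cm^2) = 10\, m_b^{0.667}} with body mass in g.
#'
#' @param mb body mass, g (> 0).
#' @return surface area in cm^2.
#' @export
surface_area <- function(mb) {
  if (any(mb <= 0)) stop("body mass must be positive")
  10 * mb^0.667
}

#' Dry thermal conductance
#'
#' Surface-specific dry heat-transfer coefficient
#' \eqn{C = (MR - EHL) / ((T_b - T_a) A_s)}, meaningful only below the
#' lower critical temperature where the body-air gradient is positive.
#'
#' @param mr metabolic rate, W.
#' @param ehl evaporative heat loss, W; `mr < ehl` draws a warning.
#' @param tb,ta body and ambient temperature, degrees C; requires `tb > ta`.
#' @param mb body mass, g.
#' @return conductance in W per degree C per cm^2 (multiply by 1000 for the
#'   mW-scale display convention).
#' @export
thermal_conductance <- function(mr, ehl, tb, ta, mb) {
  if (any(tb <= ta))
    stop("thermal conductance requires tb > ta (below the lower critical ",
         "temperature)")
  if (any(mr < ehl))
    warning("MR below EHL: negative dry heat loss")
  (mr - ehl) / ((tb - ta) * surface_area(mb))
}
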