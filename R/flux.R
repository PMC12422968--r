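# Wanninkhof (2014) 4th-order Schmidt number polynomials for CH4,
# Sc = A + B*t + C*t^2 + D*t^3 + E*t^4, t in degC, valid -2..40 degC.
.SC_CH4 <- list(
  seawater  = c(2101.2, -131.54, 4.4931, -0.08676, 0.00070663),  # S = 35
  freshwater = c(1909.4, -120.78, 4.1555, -0.080578, 0.00065777) # S = 0
)

#' Schmidt number for methane
#'
#' Schmidt number (kinematic viscosity over gas diffusivity) for CH4 from
#' the Wanninkhof (2014) polynomial fits. The seawater (S = 35) and
#' freshwater (S = 0) polynomials are interpolated linearly in salinity for
#' brackish water.
#'
#' @param temp_c temperature, degrees Celsius, within the fit range
#'   \[-2, 40\].
#' @param salinity practical salinity (ppt).
#' @return dimensionless Schmidt number, vectorized.
#' @export
schmidt_number <- function(temp_c, salinity = 35) {
  if (any(temp_c < -2) || any(temp_c > 40)) {
    stop("temperature outside Schmidt polynomial validity [-2, 40] degC",
         call. = FALSE)
  }
  .check_conditions(temp_c, salinity)
  poly_eval <- function(cf) {
    cf[1] + cf[2] * temp_c + cf[3] * temp_c^2 + cf[4] * temp_c^3 +
      cf[5] * temp_c^4
  }
  sc_sw <- poly_eval(.SC_CH4$seawater)
  sc_fw <- poly_eval(.SC_CH4$freshwater)
  sc_fw + (sc_sw - sc_fw) * salinity / 35
}

#' Gas transfer velocity
#'
#' Wind-speed parameterization of the gas transfer (piston) velocity,
#' \eqn{k = 0.251 \, g(U_{10}) \, (Sc/660)^{-1/2}} in cm h^-1. The default
#' \code{"as-printed"} mode uses \eqn{g(U) = U} (the linear form as used in
#' the source calculation chain); \code{"quadratic"} uses
#' \eqn{g(U) = U^2}, the form in which the 0.251 coefficient was originally
#' fitted (Wanninkhof 2014). The discrepancy is deliberate and documented,
#' not silently resolved.
#'
#' @param u10 wind speed at 10 m, m s^-1.
#' @param sc Schmidt number (e.g. from [schmidt_number()]).
#' @param mode \code{"as-printed"} or \code{"quadratic"}.
#' @return k in cm h^-1.
#' @export
gas_transfer_velocity <- function(u10, sc, mode = c("as-printed", "quadratic")) {
  mode <- match.arg(mode)
  if (any(u10 < 0)) stop("u10 must be non-negative", call. = FALSE)
  if (any(sc <= 0)) stop("Schmidt number must be positive", call. = FALSE)
  g <- if (mode == "as-printed") u10 else u10^2
  0.251 * g * (sc / 660)^-0.5
}

#' Sea-air gas flux
#'
#' Diffusive sea-air flux \eqn{F = k \, \Delta C} where \eqn{\Delta C} is
#' the air-sea concentration disequilibrium \eqn{C - C_{eq}}. With
#' \code{form = "partial-pressure"} the algebraically equivalent
#' \eqn{F = k \, K_0 \, \Delta p} route is used (the two agree at
#' equilibrium by construction because K0 is derived from the same Bunsen
#' coefficient). Positive flux means outgassing.
#'
#' @param conc dissolved concentration, mol L^-1.
#' @param temp_c,salinity seawater conditions.
#' @param u10 wind speed at 10 m, m s^-1.
#' @param atm an [atmosphere_spec()].
#' @param mode gas-transfer-velocity mode, see [gas_transfer_velocity()].
#' @param form \code{"concentration"} or \code{"partial-pressure"}.
#' @param molar_mass_g molar mass used for the mass flux, g mol^-1.
#' @return data.frame with \code{k_cm_h}, \code{c_eq_mol_l},
#'   \code{delta_c_mol_l} and \code{flux_mg_m2_d}.
#' @export
sea_air_flux <- function(conc, temp_c, salinity, u10,
                         atm = atmosphere_spec(),
                         mode = "as-printed",
                         form = c("concentration", "partial-pressure"),
                         molar_mass_g = 16.04) {
  form <- match.arg(form)
  if (any(conc < 0)) stop("conc must be non-negative", call. = FALSE)
  sc <- schmidt_number(temp_c, salinity)
  k_cm_h <- gas_transfer_velocity(u10, sc, mode)
  k_m_s <- k_cm_h / 100 / 3600
  c_eq <- equilibrium_concentration(temp_c, salinity, atm$f_gas)
  if (form == "concentration") {
    delta_c <- conc - c_eq
    flux_mol_m2_s <- k_m_s * delta_c * 1000 # mol L^-1 -> mol m^-3
  } else {
    k0 <- k0_solubility(temp_c, salinity) # mol L^-1 atm^-1
    p_dry <- 1 - seawater_vapor_pressure(temp_c, salinity)
    p_water <- conc / k0
    p_air <- atm$f_gas * p_dry
    delta_c <- k0 * (p_water - p_air)
    flux_mol_m2_s <- k_m_s * k0 * (p_water - p_air) * 1000
  }
  data.frame(
    k_cm_h = k_cm_h,
    c_eq_mol_l = c_eq,
    delta_c_mol_l = delta_c,
    flux_mg_m2_d = flux_mol_m2_s * molar_mass_g * 1000 * 86400
  )
}

#' Flux bounds from survey concentrations and wind quartiles
#'
#' Low / mid / high sea-air flux scenarios pairing the lowest, mean and
#' highest surveyed concentrations with the first quartile, median and
#' third quartile of the wind record (quantile type 7; the convention is
#' recorded in the output so results are reproducible across
#' implementations). The low and high scenarios use the temperature and
#' salinity of the records holding the extreme concentrations; the mid
#' scenario uses survey means.
#'
#' @param survey data.frame with columns \code{ch4_nM}, \code{temp_C},
#'   \code{salinity}.
#' @param wind numeric vector of U10 wind speeds, m s^-1.
#' @param atm an [atmosphere_spec()].
#' @param mode gas-transfer-velocity mode.
#' @return data.frame with one row per scenario (\code{low}, \code{mid},
#'   \code{high}): the concentration and wind used and the flux in
#'   mg m^-2 d^-1; attribute \code{quantile_type} documents the wind
#'   quantile convention.
#' @export
flux_bounds <- function(survey, wind, atm = atmosphere_spec(),
                        mode = "as-printed") {
  stopifnot(is.data.frame(survey),
            all(c("ch4_nM", "temp_C", "salinity") %in% names(survey)))
  if (nrow(survey) == 0) stop("survey is empty", call. = FALSE)
  if (length(wind) == 0) stop("wind record is empty", call. = FALSE)
  qs <- quantile(wind, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  i_min <- which.min(survey$ch4_nM)
  i_max <- which.max(survey$ch4_nM)
  pick <- data.frame(
    scenario = c("low", "mid", "high"),
    ch4_nM = c(survey$ch4_nM[i_min], mean(survey$ch4_nM),
               survey$ch4_nM[i_max]),
    temp_C = c(survey$temp_C[i_min], mean(survey$temp_C),
               survey$temp_C[i_max]),
    salinity = c(survey$salinity[i_min], mean(survey$salinity),
                 survey$salinity[i_max]),
    u10_m_s = qs
  )
  fl <- sea_air_flux(pick$ch4_nM * 1e-9, pick$temp_C, pick$salinity,
                     pick$u10_m_s, atm = atm, mode = mode)
  out <- cbind(pick, fl)
  attr(out, "quantile_type") <- 7L
  out
}

#' Radon-222 decay correction
#'
#' Corrects a measured 222Rn activity back to collection time:
#' \eqn{A_0 = A \, e^{\lambda t}} with \eqn{\lambda = \ln 2 / 3.8235}
#' d^-1. Salinity/temperature partitioning corrections are instrument-side
#' and not applied here.
#'
#' @param activity measured activity, Bq m^-3.
#' @param elapsed_days days between collection and counting.
#' @return decay-corrected activity, Bq m^-3.
#' @export
radon_decay_correct <- function(activity, elapsed_days) {
  if (any(elapsed_days < 0)) {
    stop("elapsed_days must be non-negative", call. = FALSE)
  }
  activity * exp(log(2) / .RN222_HALF_LIFE_D * elapsed_days)
}

#' Methane-radon association
#'
#' Paired Pearson correlation between dissolved methane and radon
#' activity, used to test whether methane co-varies with the groundwater
#' tracer (no relationship argues against a groundwater methane source).
#'
#' @param ch4 dissolved methane (any consistent unit).
#' @param radon radon activity (any consistent unit).
#' @return list with \code{r}, \code{n} and the two-sided \code{p_value}
#'   from [stats::cor.test()].
#' @export
ch4_radon_correlation <- function(ch4, radon) {
  stopifnot(length(ch4) == length(radon), length(ch4) >= 3)
  ct <- stats::cor.test(ch4, radon, method = "pearson")
  list(r = unname(ct$estimate), n = length(ch4), p_value = ct$p.value)
}
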