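#' Headspace vial geometry
#'
#' Geometry and conditions of a two-phase (water + headspace) sample vial,
#' e.g. a 12 mL exetainer in which 5 mL of sample was replaced by helium
#' before shaking to equilibrium.
#'
#' @param total_mL total vial volume, mL.
#' @param headspace_mL headspace (gas phase) volume, mL.
#' @param temp_c equilibration temperature, degrees Celsius.
#' @param salinity sample salinity, ppt.
#' @param pressure_atm total pressure, atm.
#' @return an object of class \code{vial_geometry}.
#' @export
vial_geometry <- function(total_mL = 12, headspace_mL = 5, temp_c = 20,
                          salinity = 35, pressure_atm = 1) {
  if (total_mL <= 0 || headspace_mL <= 0 || headspace_mL >= total_mL) {
    stop("need 0 < headspace_mL < total_mL", call. = FALSE)
  }
  .check_conditions(temp_c, salinity, pressure_atm)
  structure(list(total_mL = total_mL, headspace_mL = headspace_mL,
                 liquid_mL = total_mL - headspace_mL, temp_c = temp_c,
                 salinity = salinity, pressure_atm = pressure_atm),
            class = "vial_geometry")
}

# Two-phase partition coefficients for a vial: moles of gas held in each
# phase per unit (dry) mole fraction in the headspace. Dry-gas partial
# pressures are (P - Pvp); dissolved concentration follows Henry's law via
# the Bunsen coefficient.
.phase_moles_per_x <- function(geom, constants) {
  tk <- celsius_to_kelvin(geom$temp_c)
  p_dry <- geom$pressure_atm - seawater_vapor_pressure(geom$temp_c,
                                                       geom$salinity)
  beta <- bunsen_coefficient(geom$temp_c, geom$salinity, constants)
  list(
    gas = p_dry * (geom$headspace_mL / 1000) / (.R_L_ATM * tk),
    aq  = beta * p_dry / .STP_MOLAR_VOLUME * (geom$liquid_mL / 1000)
  )
}

#' Forward headspace partitioning
#'
#' Given the original dissolved concentration of a water sample, compute the
#' headspace mixing ratio (ppm, dry) after a headspace is introduced and the
#' vial is shaken to equilibrium. Total moles are conserved; the
#' dissolved/gas split is fixed by the Bunsen coefficient and the phase
#' volumes. This is the forward model whose exact inverse is
#' [dissolved_from_headspace()].
#'
#' @param dissolved_mol_l original dissolved concentration, mol L^-1.
#' @param geom a [vial_geometry()].
#' @param constants Bunsen constants, see [solubility_constants()].
#' @return headspace mixing ratio in ppm (dry mole fraction x 1e6).
#' @export
partition_forward <- function(dissolved_mol_l, geom,
                              constants = solubility_constants("ch4", "bunsen")) {
  if (any(dissolved_mol_l < 0)) {
    stop("dissolved concentration must be non-negative", call. = FALSE)
  }
  ph <- .phase_moles_per_x(geom, constants)
  n_total <- dissolved_mol_l * (geom$liquid_mL / 1000)
  n_total / (ph$gas + ph$aq) * 1e6
}

#' Back-calculate dissolved concentration from a headspace measurement
#'
#' Inverts the equilibrium mole balance of [partition_forward()]: from the
#' measured headspace mixing ratio, reconstruct the dissolved gas
#' concentration of the original (pre-equilibration) water sample.
#'
#' @param ppm measured headspace mixing ratio, ppm (dry).
#' @inheritParams partition_forward
#' @return original dissolved concentration, mol L^-1.
#' @export
dissolved_from_headspace <- function(ppm, geom,
                                     constants = solubility_constants("ch4", "bunsen")) {
  if (any(ppm < 0)) stop("ppm must be non-negative", call. = FALSE)
  ph <- .phase_moles_per_x(geom, constants)
  (ppm / 1e6) * (ph$gas + ph$aq) / (geom$liquid_mL / 1000)
}

#' Slurry vial description
#'
#' A sediment slurry incubation vial: sediment plus seawater in a crimped
#' serum vial. The headspace volume is derived from the vial volume minus
#' the seawater volume minus the solids displacement (sediment mass over
#' grain density; quartz-sand default 2.65 g cm^-3).
#'
#' @param vial_mL serum vial volume, mL.
#' @param sediment_g wet sediment mass, g.
#' @param seawater_mL seawater volume, mL.
#' @param grain_density_g_cm3 sediment grain density, g cm^-3.
#' @param temp_c,salinity,pressure_atm incubation conditions.
#' @return an object of class \code{slurry_vial} (a \code{vial_geometry}
#'   with sediment fields).
#' @export
slurry_vial <- function(vial_mL = 160, sediment_g = 30, seawater_mL = 70,
                        grain_density_g_cm3 = 2.65, temp_c = 20,
                        salinity = 35, pressure_atm = 1) {
  if (grain_density_g_cm3 <= 0) stop("grain density must be positive",
                                     call. = FALSE)
  solids_mL <- sediment_g / grain_density_g_cm3
  headspace_mL <- vial_mL - seawater_mL - solids_mL
  if (headspace_mL <= 0) {
    stop("derived headspace volume is non-positive; check vial geometry",
         call. = FALSE)
  }
  g <- vial_geometry(total_mL = seawater_mL + headspace_mL,
                     headspace_mL = headspace_mL, temp_c = temp_c,
                     salinity = salinity, pressure_atm = pressure_atm)
  g$vial_mL <- vial_mL
  g$sediment_g <- sediment_g
  g$solids_mL <- solids_mL
  class(g) <- c("slurry_vial", class(g))
  g
}

#' Slurry headspace inventory across repeated sampling
#'
#' Reconstructs the total methane inventory of a slurry vial (headspace gas
#' plus dissolved gas at equilibrium) at each sampling event, accounting for
#' the helium-injection dilution and the gas withdrawn at each event. At an
#' event, \code{injected_mL} of He is added to the sealed headspace (the
#' mixing ratio is diluted by Vhs / (Vhs + inj) while the methane partial
#' pressure is unchanged) and \code{removed_mL} of the mixed gas is
#' withdrawn at 1 atm at the measured mixing ratio.
#'
#' Two cumulative series are reported: \code{cumulative_umol}, corrected for
#' all prior withdrawals (the production series), and \code{naive_umol},
#' which ignores injection and removal bookkeeping, since field protocols
#' do not always state whether they correct for sampling dilution.
#'
#' @param events data.frame with columns \code{time_h}, \code{ppm}
#'   (measured post-injection mixing ratio) and optionally
#'   \code{injected_mL}, \code{removed_mL} (default 2 each).
#' @param vial a [slurry_vial()] (or any [vial_geometry()]).
#' @param constants Bunsen constants.
#' @return data.frame per event: \code{time_h}, \code{ppm},
#'   \code{total_umol} (inventory present in the vial),
#'   \code{removed_umol}, \code{cumulative_umol}, \code{naive_umol}.
#' @export
slurry_inventory <- function(events, vial,
                             constants = solubility_constants("ch4", "bunsen")) {
  stopifnot(is.data.frame(events), all(c("time_h", "ppm") %in% names(events)))
  if (is.null(events$injected_mL)) events$injected_mL <- 2
  if (is.null(events$removed_mL)) events$removed_mL <- 2
  if (is.unsorted(events$time_h, strictly = TRUE)) {
    stop("sampling events must be strictly time-ordered", call. = FALSE)
  }
  if (any(events$ppm < 0)) stop("ppm must be non-negative", call. = FALSE)
  if (any(events$removed_mL > vial$headspace_mL + events$injected_mL)) {
    stop("removed gas volume exceeds available headspace", call. = FALSE)
  }
  ph <- .phase_moles_per_x(vial, constants)
  tk <- celsius_to_kelvin(vial$temp_c)
  p_dry <- vial$pressure_atm - seawater_vapor_pressure(vial$temp_c,
                                                       vial$salinity)
  vhs <- vial$headspace_mL
  # pre-injection equilibrium mixing ratio; injection leaves partial
  # pressure, hence phase inventories, unchanged
  x_pre <- events$ppm * 1e-6 * (vhs + events$injected_mL) / vhs
  total_mol <- x_pre * (ph$gas + ph$aq)
  removed_mol <- events$ppm * 1e-6 * p_dry *
    (events$removed_mL / 1000) / (.R_L_ATM * tk)
  prior_removed <- c(0, cumsum(removed_mol)[-length(removed_mol)])
  naive_mol <- events$ppm * 1e-6 * (ph$gas + ph$aq)
  data.frame(
    time_h = events$time_h,
    ppm = events$ppm,
    total_umol = total_mol * 1e6,
    removed_umol = removed_mol * 1e6,
    cumulative_umol = (total_mol + prior_removed) * 1e6,
    naive_umol = naive_mol * 1e6
  )
}
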