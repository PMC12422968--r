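#' Gas solubility constants
#'
#' Loads the empirical constants of the natural-log solubility fits shipped
#' with the package (see \code{inst/extdata/gas_solubility_constants.yaml}).
#' Two unit conventions are available per gas: \code{"bunsen"} (the
#' dimensionless Bunsen coefficient) and \code{"nmol_per_l"} (direct
#' atmospheric equilibrium concentration in nmol per litre, which folds the
#' moist-atmosphere correction into the fit and needs a fourth A constant).
#'
#' @param gas gas identifier, e.g. \code{"ch4"}.
#' @param convention \code{"bunsen"} or \code{"nmol_per_l"}.
#' @param file optional path to an alternative constants file.
#' @return a list with elements \code{gas}, \code{convention}, \code{A}
#'   (length 3 or 4) and \code{B} (length 3).
#' @export
solubility_constants <- function(gas = "ch4",
                                 convention = c("bunsen", "nmol_per_l"),
                                 file = NULL) {
  convention <- match.arg(convention)
  if (is.null(file)) {
    file <- system.file("extdata", "gas_solubility_constants.yaml",
                        package = "sandch4", mustWork = TRUE)
  }
  tab <- yaml::read_yaml(file)
  if (is.null(tab[[gas]])) {
    stop("no solubility constants for gas '", gas, "' in ", file,
         call. = FALSE)
  }
  entry <- tab[[gas]][[convention]]
  if (is.null(entry)) {
    stop("no '", convention, "' constants for gas '", gas, "'", call. = FALSE)
  }
  a_names <- intersect(c("A1", "A2", "A3", "A4"), names(entry))
  consts <- list(gas = gas, convention = convention,
                 A = unlist(entry[a_names], use.names = FALSE),
                 B = unlist(entry[c("B1", "B2", "B3")], use.names = FALSE))
  if (!all(is.finite(consts$A)) || !all(is.finite(consts$B)) ||
      length(consts$A) < 3 || length(consts$B) != 3) {
    stop("incomplete or non-finite solubility constants for '", gas, "'",
         call. = FALSE)
  }
  consts
}

# Evaluate the natural-log solubility fit at temperature tk (kelvin) and
# salinity S. A[4], when present, multiplies (T/100).
.ln_solubility_fit <- function(tk, salinity, consts) {
  t100 <- tk / 100
  v <- consts$A[1] + consts$A[2] * (100 / tk) + consts$A[3] * log(t100) +
    salinity * (consts$B[1] + consts$B[2] * t100 + consts$B[3] * t100^2)
  if (length(consts$A) >= 4) v <- v + consts$A[4] * t100
  v
}

#' Bunsen solubility coefficient
#'
#' The Bunsen coefficient \eqn{\beta(T, S)}: the volume of gas at STP
#' absorbed per volume of solution when the gas partial pressure is 1 atm.
#' For methane it decreases with both temperature and salinity
#' (salting-out).
#'
#' @param temp_c temperature in degrees Celsius (accepted range corresponds
#'   to 270-320 K).
#' @param salinity practical salinity, 0-45 ppt.
#' @param constants a constants list from [solubility_constants()] with
#'   convention \code{"bunsen"}.
#' @return dimensionless Bunsen coefficient(s), vectorized over inputs.
#' @examples
#' bunsen_coefficient(20, 35)
#' @export
bunsen_coefficient <- function(temp_c, salinity,
                               constants = solubility_constants("ch4", "bunsen")) {
  tk <- .check_conditions(temp_c, salinity)
  if (!identical(constants$convention, "bunsen")) {
    stop("constants have convention '", constants$convention,
         "'; bunsen_coefficient() requires 'bunsen'", call. = FALSE)
  }
  exp(.ln_solubility_fit(tk, salinity, constants))
}

#' Vapour pressure of seawater
#'
#' Weiss & Price (1980) formulation: an Antoine-type pure-water term with a
#' linear salinity depression, returning the solution vapour pressure in
#' atm. Increases with temperature, decreases with salinity.
#'
#' @inheritParams bunsen_coefficient
#' @return vapour pressure in atm.
#' @export
seawater_vapor_pressure <- function(temp_c, salinity = 35) {
  tk <- .check_conditions(temp_c, salinity)
  exp(24.4543 - 67.4509 * (100 / tk) - 4.8489 * log(tk / 100) -
        0.000544 * salinity)
}

#' Aqueous-phase solubility K0
#'
#' Converts the Bunsen coefficient to a Henry-law solubility in
#' mol L^-1 atm^-1 of gas partial pressure (K0 = beta / 22.414).
#'
#' @inheritParams bunsen_coefficient
#' @return solubility in mol L^-1 atm^-1.
#' @export
k0_solubility <- function(temp_c, salinity,
                          constants = solubility_constants("ch4", "bunsen")) {
  bunsen_coefficient(temp_c, salinity, constants) / .STP_MOLAR_VOLUME
}

#' Atmospheric specification
#'
#' Dry-air mole fraction of the gas and its uncertainty, with per-hemisphere
#' marine-boundary-layer methane defaults (ppb). The uncertainty default
#' reflects reported interannual variation of the atmospheric baseline.
#'
#' @param ppb dry-air mole fraction in parts per billion; if \code{NULL},
#'   taken from \code{hemisphere}.
#' @param ppb_sd 1-sigma uncertainty, ppb.
#' @param hemisphere \code{"south"}, \code{"north"} or \code{"global"}.
#' @return list with \code{f_gas} and \code{f_gas_sd} as dimensionless mole
#'   fractions, plus the provenance fields.
#' @export
atmosphere_spec <- function(ppb = NULL, ppb_sd = 30,
                            hemisphere = c("south", "north", "global")) {
  hemisphere <- match.arg(hemisphere)
  if (is.null(ppb)) {
    ppb <- switch(hemisphere, south = 1870, north = 1940, global = 1900)
  }
  if (ppb <= 0 || ppb >= 1e9) stop("ppb must be in (0, 1e9)", call. = FALSE)
  if (ppb_sd < 0) stop("ppb_sd must be non-negative", call. = FALSE)
  list(f_gas = ppb * 1e-9, f_gas_sd = ppb_sd * 1e-9,
       hemisphere = hemisphere, ppb = ppb)
}

#' Equilibrium concentration against the atmosphere
#'
#' Concentration of dissolved gas in equilibrium with a moist atmosphere at
#' 1 atm total pressure: \eqn{C_{eq} = \beta (1 - P_{vp}) f_G / 22.414}
#' (mol L^-1), or, with \code{method = "direct"}, the literature fit that
#' returns nmol L^-1 directly (converted to mol L^-1 here). The two routes
#' agree to well under 0.5 percent and serve as mutual cross-checks.
#'
#' @inheritParams bunsen_coefficient
#' @param f_gas dry-air mole fraction of the gas (dimensionless), or an
#'   [atmosphere_spec()] list.
#' @param method \code{"bunsen"} (default) or \code{"direct"}.
#' @return equilibrium concentration in mol L^-1.
#' @export
equilibrium_concentration <- function(temp_c, salinity, f_gas,
                                      method = c("bunsen", "direct"),
                                      constants = NULL) {
  method <- match.arg(method)
  if (is.list(f_gas)) f_gas <- f_gas$f_gas
  if (any(f_gas < 0) || any(f_gas >= 1)) {
    stop("f_gas must be a mole fraction in [0, 1)", call. = FALSE)
  }
  tk <- .check_conditions(temp_c, salinity)
  if (method == "bunsen") {
    if (is.null(constants)) constants <- solubility_constants("ch4", "bunsen")
    if (!identical(constants$convention, "bunsen")) {
      stop("method 'bunsen' requires constants with convention 'bunsen'",
           call. = FALSE)
    }
    beta <- exp(.ln_solubility_fit(tk, salinity, constants))
    pvp <- seawater_vapor_pressure(temp_c, salinity)
    beta * (1 - pvp) * f_gas / .STP_MOLAR_VOLUME
  } else {
    if (is.null(constants)) constants <- solubility_constants("ch4", "nmol_per_l")
    if (!identical(constants$convention, "nmol_per_l")) {
      stop("method 'direct' requires constants with convention 'nmol_per_l'",
           call. = FALSE)
    }
    # ln C = ln f_G + fit, i.e. C is linear in f_G (zero-safe)
    f_gas * exp(.ln_solubility_fit(tk, salinity, constants)) * 1e-9
  }
}

#' Percent saturation with respect to the atmosphere
#'
#' Saturation is 100 x C / C_eq; 100 percent is air equilibrium and values
#' above it mark the water as a methane source to the atmosphere. Two
#' uncertainty components are propagated first-order and reported
#' separately: the replicate (analytical) relative uncertainty of C and the
#' atmospheric-baseline relative uncertainty of f_G (hence of C_eq); the
#' combined column adds them in quadrature.
#'
#' @param conc dissolved concentration, mol L^-1 (vectorized).
#' @param temp_c,salinity seawater conditions per sample.
#' @param atm an [atmosphere_spec()] list.
#' @param conc_sd 1-sigma replicate uncertainty of \code{conc}, mol L^-1.
#' @param method passed to [equilibrium_concentration()].
#' @return data.frame with columns \code{conc_mol_l}, \code{c_eq_mol_l},
#'   \code{saturation_pct}, \code{saturation_pct_sd_rep},
#'   \code{saturation_pct_sd_atm} and \code{saturation_pct_sd}.
#' @export
percent_saturation <- function(conc, temp_c, salinity,
                               atm = atmosphere_spec(), conc_sd = 0,
                               method = "bunsen") {
  if (any(conc < 0)) stop("conc must be non-negative", call. = FALSE)
  c_eq <- equilibrium_concentration(temp_c, salinity, atm$f_gas,
                                    method = method)
  if (any(c_eq == 0)) {
    stop("equilibrium concentration is zero (f_gas = 0); ",
         "percent saturation undefined", call. = FALSE)
  }
  sat <- 100 * conc / c_eq
  rel_rep <- ifelse(conc > 0, conc_sd / conc, 0)
  rel_atm <- atm$f_gas_sd / atm$f_gas
  data.frame(
    conc_mol_l = conc,
    c_eq_mol_l = c_eq,
    saturation_pct = sat,
    saturation_pct_sd_rep = sat * rel_rep,
    saturation_pct_sd_atm = sat * rel_atm,
    saturation_pct_sd = sat * sqrt(rel_rep^2 + rel_atm^2)
  )
}
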