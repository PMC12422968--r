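#' Methyl-group stoichiometry table
#'
#' Methyl groups per molecule for methylated metabolites that can feed
#' methylotrophic methanogenesis (TMA, TMAO and choline carry 3; DMSP and
#' DMS carry 2; methylamine 1; ...). Shipped as data
#' (\code{inst/extdata/methyl_groups.yaml}) so users can extend the
#' osmolyte list without code changes.
#'
#' @param file optional alternative YAML file.
#' @return named integer vector, methyl groups per molecule.
#' @export
methyl_groups_table <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "methyl_groups.yaml",
                        package = "sandch4", mustWork = TRUE)
  }
  tab <- unlist(yaml::read_yaml(file))
  if (any(tab < 1) || any(tab != round(tab))) {
    stop("methyl group counts must be positive integers", call. = FALSE)
  }
  tab
}

#' Methyl-group equivalents of a metabolite panel
#'
#' Sums metabolite concentrations weighted by the stoichiometric number of
#' methyl groups per molecule; replicate uncertainties are propagated in
#' quadrature.
#'
#' @param panel data.frame with columns \code{metabolite}, \code{conc_uM}
#'   and optionally \code{sd_uM}.
#' @param groups named vector from [methyl_groups_table()].
#' @return list with \code{methyl_uM} and \code{methyl_sd_uM}.
#' @export
methyl_equivalents <- function(panel, groups = methyl_groups_table()) {
  stopifnot(is.data.frame(panel),
            all(c("metabolite", "conc_uM") %in% names(panel)))
  if (nrow(panel) == 0) return(list(methyl_uM = 0, methyl_sd_uM = 0))
  if (any(panel$conc_uM < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  unknown <- setdiff(panel$metabolite, names(groups))
  if (length(unknown) > 0) {
    stop("no methyl-group stoichiometry for: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  g <- groups[panel$metabolite]
  sds <- if (!is.null(panel$sd_uM)) panel$sd_uM else rep(0, nrow(panel))
  list(methyl_uM = sum(panel$conc_uM * g),
       methyl_sd_uM = sqrt(sum((sds * g)^2)))
}

#' Theoretical methane yield from methyl groups
#'
#' Converts a methyl-group pool to the methane it could yield. The default
#' yield factor 0.75 assumes methylotrophic disproportionation
#' (4 CH3 -> 3 CH4 + 1 CO2); a factor of 1 represents complete reduction of
#' every methyl group to methane. Neither is privileged: which one an
#' observed closure corresponds to depends on the electron balance of the
#' system, so both are exposed.
#'
#' @param methyl_uM methyl-group concentration (or supply rate), µM (or
#'   µmol h^-1).
#' @param yield_factor CH4 produced per methyl group, in (0, 1].
#' @return theoretical methane, same units as the input.
#' @export
theoretical_methane_yield <- function(methyl_uM, yield_factor = 0.75) {
  if (yield_factor <= 0 || yield_factor > 1) {
    stop("yield_factor must be in (0, 1]", call. = FALSE)
  }
  if (any(methyl_uM < 0)) stop("methyl pool must be non-negative",
                               call. = FALSE)
  methyl_uM * yield_factor
}

#' Methyl-substrate supply rate to an FTR
#'
#' Converts a metabolite panel measured in a macrophyte extract to the
#' methyl-group delivery rate at the reactor inlet, given the
#' extract:seawater dilution of the feed (20:1 or 50:1 in typical runs) and
#' the flow rate.
#'
#' @param panel metabolite panel data.frame, see [methyl_equivalents()].
#' @param dilution extract dilution factor of the feed (e.g. 20 means
#'   1 part extract in 20 parts feed).
#' @param flow_mL_h reactor flow, mL h^-1.
#' @param groups methyl stoichiometry table.
#' @return list with \code{methyl_umol_h} and \code{methyl_sd_umol_h}.
#' @export
metabolite_supply_rate <- function(panel, dilution = 20, flow_mL_h = 45,
                                   groups = methyl_groups_table()) {
  if (dilution < 1) stop("dilution factor must be >= 1", call. = FALSE)
  if (flow_mL_h <= 0) stop("flow must be positive", call. = FALSE)
  eq <- methyl_equivalents(panel, groups)
  scale <- flow_mL_h / 1000 / dilution # µM x L h^-1 = µmol h^-1
  list(methyl_umol_h = eq$methyl_uM * scale,
       methyl_sd_umol_h = eq$methyl_sd_uM * scale)
}

#' Substrate closure fraction
#'
#' Percentage of an observed maximum methane production rate that the
#' theoretical methane yield of the measured substrate supply can account
#' for. Values above 100 percent are permitted (supply exceeding observed
#' production) and flagged; the unexplained remainder is reported as a
#' line item, never imputed to any substrate.
#'
#' @param theoretical theoretical methane supply rate (µmol h^-1, or any
#'   unit shared with \code{observed}).
#' @param observed observed maximum production rate, same units, > 0.
#' @return list with \code{closure_pct}, \code{unexplained_pct} (zero when
#'   closure exceeds 100) and logical \code{exceeds_observed}.
#' @export
closure_fraction <- function(theoretical, observed) {
  if (observed <= 0) {
    stop("observed production rate must be positive", call. = FALSE)
  }
  if (theoretical < 0) stop("theoretical supply must be non-negative",
                            call. = FALSE)
  pct <- 100 * theoretical / observed
  list(closure_pct = pct,
       unexplained_pct = max(0, 100 - pct),
       exceeds_observed = pct > 100)
}
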