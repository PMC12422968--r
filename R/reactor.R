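#' Flow-through reactor configuration
#'
#' Geometry and flow of a sand-packed flow-through reactor (FTR): a bed of
#' cross-sectional area \code{area_cm2} and length \code{length_cm}
#' percolated at \code{flow_mL_h} without recirculation.
#'
#' @param volume_cm3 bulk bed volume, cm^3.
#' @param area_cm2 cross-sectional area, cm^2.
#' @param flow_mL_h default volumetric flow rate, mL h^-1.
#' @return object of class \code{ftr_config}; \code{length_cm} is derived
#'   as volume / area.
#' @export
ftr_config <- function(volume_cm3 = 50, area_cm2 = 25, flow_mL_h = 45) {
  if (volume_cm3 <= 0 || area_cm2 <= 0) {
    stop("volume and area must be positive", call. = FALSE)
  }
  if (any(flow_mL_h <= 0)) stop("flow rate must be positive", call. = FALSE)
  structure(list(volume_cm3 = volume_cm3, area_cm2 = area_cm2,
                 length_cm = volume_cm3 / area_cm2, flow_mL_h = flow_mL_h),
            class = "ftr_config")
}

#' Volumetric production rate from an FTR time series
#'
#' Plug-flow mass balance at each timepoint:
#' \eqn{x(t) = Q(t) (C_{out} - C_{in}) / V_{FTR}}, in
#' µmol cm^-3 h^-1 of bulk sand volume (no porosity division unless
#' \code{porosity} is supplied, in which case rates are per pore volume).
#' Negative rates (consumption) are permitted and flagged.
#'
#' @param ts data.frame with columns \code{time_h}, \code{c_in_uM},
#'   \code{c_out_uM} and optionally \code{q_mL_h} (per-timepoint flow; the
#'   config default is used otherwise — time-varying flow is supported
#'   because experiments may raise the flow mid-run).
#' @param cfg an [ftr_config()].
#' @param porosity optional porosity in (0, 1] to express rates per pore
#'   volume; default \code{NULL} keeps bulk-volume rates.
#' @return data.frame with \code{time_h}, \code{q_mL_h},
#'   \code{rate_umol_cm3_h} and logical \code{consumption}.
#' @export
volumetric_rate <- function(ts, cfg, porosity = NULL) {
  stopifnot(is.data.frame(ts),
            all(c("time_h", "c_in_uM", "c_out_uM") %in% names(ts)))
  if (is.unsorted(ts$time_h)) stop("time series must be time-ordered",
                                   call. = FALSE)
  if (any(ts$c_in_uM < 0) || any(ts$c_out_uM < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  q <- if (!is.null(ts$q_mL_h)) ts$q_mL_h else rep(cfg$flow_mL_h[1], nrow(ts))
  if (length(q) != nrow(ts)) stop("flow series length mismatch", call. = FALSE)
  # mL h^-1 x µmol L^-1 = 1e-3 µmol h^-1
  x <- q * (ts$c_out_uM - ts$c_in_uM) * 1e-3 / cfg$volume_cm3
  if (!is.null(porosity)) {
    if (porosity <= 0 || porosity > 1) stop("porosity must be in (0, 1]",
                                            call. = FALSE)
    x <- x / porosity
  }
  data.frame(time_h = ts$time_h, q_mL_h = q, rate_umol_cm3_h = x,
             consumption = x < 0)
}

#' Depth-integrated areal flux from a volumetric rate
#'
#' Integrates a volumetric production rate over a sediment depth (the depth
#' of advective pore-water penetration, 0.5 cm by default) and converts to
#' areal units: µmol cm^-2 h^-1, mmol m^-2 h^-1 and g m^-2 h^-1.
#'
#' @param rate_umol_cm3_h volumetric rate, µmol cm^-3 h^-1.
#' @param depth_cm integration depth, cm (> 0).
#' @param molar_mass_g molar mass for the mass flux, g mol^-1
#'   (CH4 = 16.04).
#' @return data.frame with \code{umol_cm2_h}, \code{mmol_m2_h} and
#'   \code{g_m2_h}.
#' @examples
#' areal_flux(48, depth_cm = 0.5) # 24 µmol cm^-2 h^-1 = 240 mmol m^-2 h^-1
#' @export
areal_flux <- function(rate_umol_cm3_h, depth_cm = 0.5,
                       molar_mass_g = 16.04) {
  if (any(depth_cm <= 0)) stop("integration depth must be positive",
                               call. = FALSE)
  umol_cm2_h <- rate_umol_cm3_h * depth_cm
  mmol_m2_h <- umol_cm2_h * 10 # 1e4 cm^2 m^-2 / 1e3 µmol mmol^-1
  data.frame(umol_cm2_h = umol_cm2_h, mmol_m2_h = mmol_m2_h,
             g_m2_h = mmol_m2_h * molar_mass_g / 1000)
}

#' CH4:CO2 carbon remineralization ratio
#'
#' Per-timepoint ratio of methane to DIC production rates in an FTR,
#' reported as 1:n with n = x_DIC / x_CH4. The DIC series is linearly
#' interpolated onto the CH4 timestamps when the two series are not
#' co-registered. Timepoints with non-positive CH4 rate get \code{NA} ratio
#' and are flagged \code{undefined}, not dropped.
#'
#' @param ch4,dic data.frames as accepted by [volumetric_rate()].
#' @param cfg an [ftr_config()].
#' @return data.frame with \code{time_h}, \code{x_ch4}, \code{x_dic},
#'   \code{ratio_n} (the n of 1:n) and logical \code{undefined}.
#' @export
ch4_co2_ratio <- function(ch4, dic, cfg) {
  r_ch4 <- volumetric_rate(ch4, cfg)
  r_dic <- volumetric_rate(dic, cfg)
  x_dic <- if (identical(r_ch4$time_h, r_dic$time_h)) {
    r_dic$rate_umol_cm3_h
  } else {
    approx(r_dic$time_h, r_dic$rate_umol_cm3_h, xout = r_ch4$time_h,
           rule = 2)$y
  }
  undefined <- r_ch4$rate_umol_cm3_h <= 0
  data.frame(
    time_h = r_ch4$time_h,
    x_ch4 = r_ch4$rate_umol_cm3_h,
    x_dic = x_dic,
    ratio_n = ifelse(undefined, NA_real_,
                     x_dic / r_ch4$rate_umol_cm3_h),
    undefined = undefined
  )
}

#' Slurry production rate by linear regression
#'
#' Ordinary least-squares slope of cumulative methane against time over a
#' window, with standard error; optionally normalized per gram of wet
#' sediment.
#'
#' @param time_h sampling times, h.
#' @param cumulative_umol cumulative methane series, µmol (e.g. from
#'   [slurry_inventory()]).
#' @param window numeric length-2 \code{c(t0, t1)} in hours; default is the
#'   full series.
#' @param sediment_g optional wet sediment mass for per-gram rates.
#' @return list with \code{rate_umol_h}, \code{se_umol_h}, \code{n} and,
#'   when \code{sediment_g} is given, \code{rate_umol_g_h}.
#' @export
slurry_rate <- function(time_h, cumulative_umol, window = range(time_h),
                        sediment_g = NULL) {
  stopifnot(length(time_h) == length(cumulative_umol))
  keep <- time_h >= window[1] & time_h <= window[2]
  if (sum(keep) < 3) {
    stop("need at least 3 points in the fitting window", call. = FALSE)
  }
  fit <- lm(cumulative_umol[keep] ~ time_h[keep])
  # a perfectly linear series is legitimate here; its SE is just 0
  sm <- suppressWarnings(summary(fit))$coefficients
  out <- list(rate_umol_h = unname(coef(fit)[2]),
              se_umol_h = unname(sm[2, 2]),
              n = sum(keep))
  if (!is.null(sediment_g)) out$rate_umol_g_h <- out$rate_umol_h / sediment_g
  out
}

#' Maximum production rate of a reactor run
#'
#' The "maximum rate" of a run is reported two ways, since a single noisy
#' timepoint and a sustained plateau answer different questions: the
#' single-timepoint maximum and the maximum of a centred rolling mean.
#'
#' @param rates data.frame from [volumetric_rate()].
#' @param window_pts odd window width for the rolling mean (default 3).
#' @return list with \code{max_pointwise}, \code{max_windowed} and the
#'   times at which each occurs.
#' @export
max_rate <- function(rates, window_pts = 3) {
  x <- rates$rate_umol_cm3_h
  if (window_pts %% 2 == 0 || window_pts < 1) {
    stop("window_pts must be odd and positive", call. = FALSE)
  }
  half <- (window_pts - 1) / 2
  n <- length(x)
  roll <- vapply(seq_len(n), function(i) {
    mean(x[max(1, i - half):min(n, i + half)])
  }, numeric(1))
  list(max_pointwise = max(x), time_pointwise = rates$time_h[which.max(x)],
       max_windowed = max(roll), time_windowed = rates$time_h[which.max(roll)])
}
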