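# One global seed fans out to fixed per-stream child seeds, so adding a
# generator never perturbs the draws of an existing one.
.child_seed <- function(seed, stream) {
  offsets <- c(survey = 101L, wind = 211L, reactor = 307L, slurry = 401L,
               counts = 503L)
  if (!stream %in% names(offsets)) stop("unknown seed stream: ", stream,
                                        call. = FALSE)
  (as.integer(seed) * 1009L + offsets[[stream]]) %% 2147483647L
}

#' Survey scenario
#'
#' Parameters of a synthetic multi-site surface-water survey. The defaults
#' emulate a shallow sandy-beach survey in which methane saturation spans
#' about four orders of magnitude (the programmed endpoints 380 and
#' 189,000 percent are assigned to the first and last site exactly, with
#' interior sites log-uniform between them), replicate variability is
#' lognormal at ~8 percent CV, and radon is uncorrelated with methane
#' under the \code{"no-groundwater"} regime.
#'
#' @param n_sites number of sites (>= 2 when both endpoints are pinned).
#' @param sat_range_pct length-2 saturation range, percent.
#' @param replicate_cv lognormal replicate coefficient of variation.
#' @param n_replicates replicate bottles per site.
#' @param temp_range_c,sal_range temperature (degC) and salinity ranges.
#' @param radon_regime \code{"no-groundwater"} (radon independent of
#'   methane) or \code{"groundwater"} (radon proportional to methane with
#'   noise).
#' @param radon_mean_bq_m3 mean radon activity.
#' @param atm an [atmosphere_spec()].
#' @return list of class \code{survey_scenario}.
#' @export
survey_scenario <- function(n_sites = 12, sat_range_pct = c(380, 189000),
                            replicate_cv = 0.08, n_replicates = 3,
                            temp_range_c = c(12, 24), sal_range = c(30, 36),
                            radon_regime = c("no-groundwater", "groundwater"),
                            radon_mean_bq_m3 = 50,
                            atm = atmosphere_spec()) {
  radon_regime <- match.arg(radon_regime)
  if (n_sites < 2) stop("n_sites must be >= 2", call. = FALSE)
  if (any(sat_range_pct <= 0) || sat_range_pct[2] < sat_range_pct[1]) {
    stop("saturation range must be positive and ordered", call. = FALSE)
  }
  structure(list(n_sites = n_sites, sat_range_pct = sat_range_pct,
                 replicate_cv = replicate_cv, n_replicates = n_replicates,
                 temp_range_c = temp_range_c, sal_range = sal_range,
                 radon_regime = radon_regime,
                 radon_mean_bq_m3 = radon_mean_bq_m3, atm = atm),
            class = "survey_scenario")
}

#' Generate a synthetic field survey
#'
#' Draws per-site conditions, sets each site's true dissolved methane from
#' its programmed percent saturation via the solubility chain (so the
#' analysis pipeline recovers the programmed saturations by construction),
#' and adds lognormal replicate noise and a radon activity per site.
#'
#' @param scenario a [survey_scenario()].
#' @param seed integer seed; generation is a pure function of
#'   (scenario, seed).
#' @return data.frame with columns \code{site}, \code{replicate},
#'   \code{temp_C}, \code{salinity}, \code{ch4_nM}, \code{radon_Bq_m3},
#'   \code{true_saturation_pct}; attribute \code{seed} records provenance.
#' @export
generate_survey <- function(scenario, seed) {
  stopifnot(inherits(scenario, "survey_scenario"))
  set.seed(.child_seed(seed, "survey"))
  n <- scenario$n_sites
  lsat <- log(scenario$sat_range_pct)
  sat <- exp(c(lsat[1], sort(runif(n - 2, lsat[1], lsat[2])), lsat[2]))
  temp <- runif(n, scenario$temp_range_c[1], scenario$temp_range_c[2])
  sal <- runif(n, scenario$sal_range[1], scenario$sal_range[2])
  c_eq <- equilibrium_concentration(temp, sal, scenario$atm$f_gas)
  true_nM <- sat / 100 * c_eq * 1e9
  radon <- switch(scenario$radon_regime,
    "no-groundwater" = rlnorm(n, log(scenario$radon_mean_bq_m3), 0.5),
    "groundwater" = scenario$radon_mean_bq_m3 * (true_nM / mean(true_nM)) *
      rlnorm(n, 0, 0.2))
  cv <- scenario$replicate_cv
  sdlog <- sqrt(log(1 + cv^2))
  reps <- scenario$n_replicates
  out <- data.frame(
    site = rep(sprintf("site_%02d", seq_len(n)), each = reps),
    replicate = rep(seq_len(reps), times = n),
    temp_C = rep(temp, each = reps),
    salinity = rep(sal, each = reps),
    ch4_nM = rep(true_nM, each = reps) *
      rlnorm(n * reps, -sdlog^2 / 2, sdlog),
    radon_Bq_m3 = rep(radon, each = reps),
    true_saturation_pct = rep(sat, each = reps)
  )
  attr(out, "seed") <- seed
  attr(out, "package_version") <- as.character(packageVersion("sandch4"))
  out
}

#' Generate a synthetic wind record
#'
#' Twice-daily wind observations over a year (the sampling scheme used for
#' flux bounding): Weibull-distributed U10, a standard model for wind-speed
#' climatology.
#'
#' @param seed integer seed.
#' @param n_days days of record.
#' @param per_day observations per day.
#' @param shape,scale Weibull parameters (defaults give mean U10 of about
#'   5.5 m s^-1, typical of an exposed coastal station).
#' @return data.frame with \code{day}, \code{obs} and \code{u10_m_s}.
#' @export
generate_wind <- function(seed, n_days = 365, per_day = 2, shape = 2,
                          scale = 6.2) {
  set.seed(.child_seed(seed, "wind"))
  n <- n_days * per_day
  data.frame(day = rep(seq_len(n_days), each = per_day),
             obs = rep(seq_len(per_day), times = n_days),
             u10_m_s = rweibull(n, shape, scale))
}

#' Reactor scenario
#'
#' Programmed behaviour of a synthetic FTR run: methanogenesis onset after
#' an anoxia lag (~20 h), logistic growth of the volumetric rate to a
#' programmed maximum, a CH4:DIC carbon ratio trajectory that tightens to
#' a programmed terminal value (1:9 at 44 h by default), optional repeated
#' oxygen pulses during which production stops and then recovers within a
#' programmed lag, and multiplicative measurement noise.
#'
#' @param onset_h hours before methane production starts.
#' @param max_rate_umol_cm3_h programmed maximum volumetric rate.
#' @param growth_h logistic e-folding timescale, h.
#' @param ratio_n0,ratio_n_final,ratio_t_final_h CH4:DIC ratio trajectory:
#'   n decays exponentially from \code{ratio_n0} (at onset) to
#'   \code{ratio_n_final} at \code{ratio_t_final_h}.
#' @param noise_cv multiplicative lognormal noise CV on outlet
#'   concentrations (0 disables noise).
#' @param o2_pulses optional data.frame with \code{start_h}, \code{end_h},
#'   \code{recovery_h}: production is zero during a pulse and ramps back
#'   linearly over \code{recovery_h} (1-2 h is realistic).
#' @param c_in_ch4_uM,c_in_dic_uM inlet concentrations.
#' @return list of class \code{reactor_scenario}.
#' @export
reactor_scenario <- function(onset_h = 20, max_rate_umol_cm3_h = 48,
                             growth_h = 4, ratio_n0 = 100,
                             ratio_n_final = 9, ratio_t_final_h = 44,
                             noise_cv = 0.02, o2_pulses = NULL,
                             c_in_ch4_uM = 0.005, c_in_dic_uM = 2000) {
  if (onset_h < 0) stop("onset lag must be non-negative", call. = FALSE)
  if (max_rate_umol_cm3_h <= 0) stop("max rate must be positive",
                                     call. = FALSE)
  structure(list(onset_h = onset_h,
                 max_rate_umol_cm3_h = max_rate_umol_cm3_h,
                 growth_h = growth_h, ratio_n0 = ratio_n0,
                 ratio_n_final = ratio_n_final,
                 ratio_t_final_h = ratio_t_final_h, noise_cv = noise_cv,
                 o2_pulses = o2_pulses, c_in_ch4_uM = c_in_ch4_uM,
                 c_in_dic_uM = c_in_dic_uM),
            class = "reactor_scenario")
}

# Programmed volumetric CH4 rate at time t (no noise): logistic growth
# after onset, gated by the oxygen-pulse schedule.
.programmed_rate <- function(t, scen) {
  x <- ifelse(t < scen$onset_h, 0,
              scen$max_rate_umol_cm3_h /
                (1 + exp(-(t - scen$onset_h - 3 * scen$growth_h) /
                           scen$growth_h)))
  if (!is.null(scen$o2_pulses)) {
    for (i in seq_len(nrow(scen$o2_pulses))) {
      p <- scen$o2_pulses[i, ]
      x <- ifelse(t >= p$start_h & t <= p$end_h, 0, x)
      ramp <- (t - p$end_h) / p$recovery_h
      x <- ifelse(t > p$end_h & ramp < 1, x * pmax(0, ramp), x)
    }
  }
  x
}

# Programmed CH4:DIC ratio n(t): exponential decay to the terminal value.
.programmed_ratio_n <- function(t, scen) {
  a <- log(scen$ratio_n0 / scen$ratio_n_final) /
    (scen$ratio_t_final_h - scen$onset_h)
  pmax(scen$ratio_n_final,
       scen$ratio_n0 * exp(-a * pmax(0, t - scen$onset_h)))
}

#' Generate a synthetic FTR time series pair
#'
#' Forward-simulates outlet concentrations for CH4 and DIC from the
#' programmed volumetric rates through the plug-flow mass balance
#' \eqn{C_{out} = C_{in} + x V / Q}, with multiplicative lognormal noise.
#' The programmed trajectories are attached as attributes so tests can use
#' the generator's own schedule as an oracle.
#'
#' @param scenario a [reactor_scenario()].
#' @param cfg an [ftr_config()].
#' @param seed integer seed.
#' @param times_h sampling times, h.
#' @return list with data.frames \code{ch4} and \code{dic} (columns
#'   \code{time_h}, \code{c_in_uM}, \code{c_out_uM}, \code{q_mL_h}) and
#'   the programmed \code{rate_ch4}, \code{rate_dic} vectors.
#' @export
generate_reactor <- function(scenario, cfg, seed,
                             times_h = seq(0, 48, by = 2)) {
  stopifnot(inherits(scenario, "reactor_scenario"),
            inherits(cfg, "ftr_config"))
  set.seed(.child_seed(seed, "reactor"))
  q <- rep(cfg$flow_mL_h[1], length(times_h))
  x_ch4 <- .programmed_rate(times_h, scenario)
  x_dic <- x_ch4 * .programmed_ratio_n(times_h, scenario)
  sdlog <- sqrt(log(1 + scenario$noise_cv^2))
  noise <- function(n) if (sdlog == 0) rep(1, n) else
    rlnorm(n, -sdlog^2 / 2, sdlog)
  mk <- function(c_in, x) {
    c_out <- (c_in + x * cfg$volume_cm3 / q * 1000) * noise(length(times_h))
    data.frame(time_h = times_h, c_in_uM = c_in, c_out_uM = c_out,
               q_mL_h = q)
  }
  list(ch4 = mk(scenario$c_in_ch4_uM, x_ch4),
       dic = mk(scenario$c_in_dic_uM, x_dic),
       rate_ch4 = x_ch4, rate_dic = x_dic)
}

#' Generate a synthetic slurry sampling record
#'
#' Forward-simulates a slurry incubation with constant methane production:
#' between sampling events the vial inventory grows at the programmed
#' rate; at each event the inventory partitions between water and
#' headspace via the Bunsen coefficient, helium injection dilutes the
#' headspace mixing ratio by Vhs/(Vhs+inj), the diluted ratio is read
#' (with optional Gaussian instrument noise) and a gas sample is
#' withdrawn at that ratio. The physics is identical to
#' [slurry_inventory()]'s bookkeeping, which makes the generator the
#' oracle for rate-recovery tests.
#'
#' @param rate_umol_h programmed production rate, µmol h^-1.
#' @param vial a [slurry_vial()].
#' @param times_h sampling times, h (first event defines time zero
#'   inventory = initial dissolved load, default 0).
#' @param seed integer seed.
#' @param injected_mL,removed_mL per-event He injection and sample volume.
#' @param initial_umol methane present at the first event.
#' @param noise_rel relative Gaussian noise on the ppm reading (0
#'   disables).
#' @return data.frame of events (\code{time_h}, \code{ppm},
#'   \code{injected_mL}, \code{removed_mL}) with attribute
#'   \code{true_total_umol}.
#' @export
generate_slurry <- function(rate_umol_h, vial, times_h = seq(0, 48, by = 6),
                            seed = 1, injected_mL = 2, removed_mL = 2,
                            initial_umol = 0.05, noise_rel = 0) {
  stopifnot(inherits(vial, "vial_geometry"))
  set.seed(.child_seed(seed, "slurry"))
  ph <- .phase_moles_per_x(vial, solubility_constants("ch4", "bunsen"))
  tk <- celsius_to_kelvin(vial$temp_c)
  p_dry <- vial$pressure_atm - seawater_vapor_pressure(vial$temp_c,
                                                       vial$salinity)
  vhs <- vial$headspace_mL
  n <- initial_umol * 1e-6
  ppm <- numeric(length(times_h))
  true_total <- numeric(length(times_h))
  for (i in seq_along(times_h)) {
    if (i > 1) n <- n + rate_umol_h * 1e-6 * (times_h[i] - times_h[i - 1])
    true_total[i] <- n * 1e6
    x_pre <- n / (ph$gas + ph$aq)
    x_meas <- x_pre * vhs / (vhs + injected_mL)
    if (noise_rel > 0) x_meas <- x_meas * (1 + rnorm(1, 0, noise_rel))
    ppm[i] <- x_meas * 1e6
    removed <- x_meas * p_dry * (removed_mL / 1000) / (.R_L_ATM * tk)
    n <- n - removed
  }
  out <- data.frame(time_h = times_h, ppm = ppm,
                    injected_mL = injected_mL, removed_mL = removed_mL)
  attr(out, "true_total_umol") <- true_total
  attr(out, "seed") <- seed
  out
}

#' Generate a synthetic metagenomic count table
#'
#' Simulates read counts for a community in which a programmed fraction of
#' genome abundance carries the target gene (mcrA) and every genome
#' carries one copy of each single-copy ribosomal marker. Reads are drawn
#' from a single multinomial over gene categories plus a rest-of-genome
#' category — the exact aggregated marginal of a genome-by-gene multinomial
#' proportional to genome abundance times gene length, since markers are
#' single-copy in all genomes.
#'
#' @param seed integer seed.
#' @param mcra_fraction fraction of community (genome abundance) carrying
#'   mcrA, in \[0, 1\].
#' @param depth library size (total reads).
#' @param genome_bp effective genome length, bp.
#' @param mcra_bp,marker_bp gene lengths (markers recycled across the 14
#'   ids).
#' @param n_samples samples to simulate; \code{enrichment} scales the
#'   carrier fraction per sample (e.g. \code{c(1, 6)} for a programmed
#'   6-fold enrichment).
#' @param enrichment per-sample multipliers on \code{mcra_fraction}.
#' @return long data.frame with columns \code{sample}, \code{gene_id},
#'   \code{reads}, \code{length_bp}, \code{library_size}.
#' @export
generate_counts <- function(seed, mcra_fraction = 0.002, depth = 1e7,
                            genome_bp = 3e6, mcra_bp = 1650,
                            marker_bp = c(830, 650, 620, 540, 530, 370,
                                          410, 350, 330, 700, 400, 310,
                                          260, 280),
                            n_samples = 1, enrichment = rep(1, n_samples)) {
  if (mcra_fraction < 0 || mcra_fraction > 1) {
    stop("carrier fraction must be in [0, 1]", call. = FALSE)
  }
  stopifnot(length(enrichment) == n_samples)
  set.seed(.child_seed(seed, "counts"))
  markers <- default_marker_genes()
  marker_bp <- rep_len(marker_bp, length(markers))
  out <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    f <- mcra_fraction * enrichment[s]
    if (f > 1) stop("enriched carrier fraction exceeds 1", call. = FALSE)
    p_markers <- marker_bp / genome_bp      # every genome carries one copy
    p_mcra <- f * mcra_bp / genome_bp       # carriers only
    p <- c(p_markers, p_mcra)
    reads <- as.vector(rmultinom(1, size = depth, prob = c(p, 1 - sum(p))))
    out[[s]] <- data.frame(
      sample = sprintf("sample_%02d", s),
      gene_id = c(markers, "mcrA"),
      reads = reads[seq_len(length(markers) + 1)],
      length_bp = c(marker_bp, mcra_bp),
      library_size = depth
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "seed") <- seed
  res
}
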