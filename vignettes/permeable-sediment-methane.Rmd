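---
title: "Quantifying methane production and emission from permeable sandy sediments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying methane production and emission from permeable sandy sediments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sandch4)
```

Shallow sandy (permeable) coastal sediments are usually considered poor
methane producers: they are well flushed with oxygenated seawater, and
methanogenesis is an obligately anaerobic metabolism. Yet surface waters
over sandy beaches can be strongly methane-oversaturated, especially where
drifting macroalgae and seagrass wrack accumulate. The working model behind
this package is that macrophyte-derived methylated osmolytes (trimethylamine,
TMAO, choline, DMSP, DMS) fuel *methylotrophic* methanogenesis — a pathway
that does not compete with sulfate reduction for H~2~ or acetate and that is
carried out by aerotolerant Methanosarcinaceae — so that methane production
can switch on within hours of anoxia even in sediments that are oxic most of
the time.

`sandch4` implements the complete calculation chain needed to quantify that
picture from raw measurements: dissolved-gas chemistry, sea–air exchange,
reactor and slurry rate computation, substrate stoichiometry, and
marker-gene normalization. Because the package is exercised entirely on
synthetic data, every generator is itself a first-class, seeded, tested
component whose programmed truths are the oracles for the analysis code.

## Dissolved methane and percent saturation

The equilibrium concentration of methane in seawater against a moist
atmosphere at 1 atm follows

$$C_{eq} = \beta \,(1 - P_{vp})\, f_G \,/\, V_m,$$

where $\beta(T,S)$ is the Bunsen solubility coefficient, $P_{vp}$ the
vapour pressure of the solution (atm), $f_G$ the dry-air mole fraction of
methane and $V_m = 22.414$ L mol^-1^ the molar volume at STP. $\beta$ uses
the classical natural-log fit
$\ln\beta = A_1 + A_2(100/T) + A_3\ln(T/100) + S\,[B_1 + B_2(T/100) + B_3(T/100)^2]$
with the methane constants of the Yamamoto/Wiesenburg–Guinasso lineage,
shipped as data (`inst/extdata/gas_solubility_constants.yaml`) so other
gases can be added. Two unit conventions are stored: the Bunsen fit above
and the direct atmospheric-equilibrium fit in nmol L^-1^ (which carries a
fourth $A$ constant). The two were transcribed independently and agree to
better than 0.1% over the 0–30 °C, 0–35 ppt range; the test suite holds
them to 0.5% as mutual transcription checks, and uses the ideal molar
volume throughout (the ~0.2% real-gas correction for CH~4~ is far below
field measurement uncertainty).

Vapour pressure uses the Weiss & Price (1980) seawater formulation — an
Antoine-type pure-water term with a linear salinity depression — verified
against the steam table at 25 °C. Temperatures cross the user boundary in
°C and are converted to kelvin immediately; accepted ranges (270–320 K,
S 0–45) are enforced with errors naming the offending field.

Percent saturation is $100\,C/C_{eq}$. Its uncertainty has two logically
distinct sources that field papers do not always separate: replicate
(analytical) scatter in $C$ and the atmospheric-baseline uncertainty in
$f_G$. `percent_saturation()` propagates both first-order and reports them
separately plus combined in quadrature, so either convention can be read
off. The atmospheric baseline is configurable per hemisphere
(`atmosphere_spec()`, defaults 1870/1940 ppb south/north with a 30 ppb
1-sigma interannual variation); nothing is hard-coded.

## Headspace equilibration

Dissolved methane is measured by introducing a helium headspace into a
sealed sample vial (e.g. replacing 5 mL of a 12 mL exetainer), shaking to
equilibrium, and measuring the headspace mixing ratio. The mole balance is
linear: total moles split between the gas phase
($x\,(P-P_{vp})V_{hs}/RT$) and the water ($x\,(P-P_{vp})\beta/V_m\,V_{liq}$),
so the back-calculation `dissolved_from_headspace()` is the exact algebraic
inverse of the forward model `partition_forward()`; the round-trip is exact
to machine precision across the whole $T\times S$ grid and the tests hold
it below 10^-9^. Full re-equilibration is assumed before each measurement
(vials are shaken); no kinetic mass-transfer model is attempted, and the
~50 µL of HgCl~2~ preservative is treated as volume-neutral.

Slurry incubations add bookkeeping: at each sampling event, helium is
injected into the sealed headspace (at constant vial volume this raises
total pressure and dilutes the *mixing ratio* by $V_{hs}/(V_{hs}+V_{inj})$
while leaving the methane partial pressure unchanged) and an equal gas
volume is withdrawn at 1 atm at the measured ratio. `slurry_inventory()`
reconstructs the vial's total methane at each event and accumulates the
withdrawn moles, yielding a production series exactly conserved under zero
production (held to 10^-12^ relative in tests). Because protocols do not
always state whether reported concentrations correct for cumulative
sampling dilution, both the corrected and the naive series are always
returned — on the default geometry the naive series understates a constant
production rate by roughly 10%. Headspace volume is derived from vial
volume minus seawater minus solids displacement at a configurable grain
density (quartz default 2.65 g cm^-3^); dissolved methane in the slurry
porewater uses the free-seawater $\beta$ (no sorption term).

## Sea–air flux

Flux uses the piston-velocity form $F = k\,\Delta C$ with
$k = 0.251\,U_{10}\,(Sc/660)^{-1/2}$ in cm h^-1^. Two deliberate
ambiguities are exposed rather than resolved silently:

* The 0.251 coefficient and the 660 normalization come from a
  parameterization that is quadratic in $U_{10}$; the linear form is
  nevertheless the default (`mode = "as-printed"`) because that is how the
  calculation chain this package implements writes it, and
  `mode = "quadratic"` restores the original fit. At the ~4–7 m s^-1^ wind
  speeds typical of the application the two differ by a factor of a few —
  users comparing against literature fluxes should check which convention
  a source used.
* Whether $\Delta C$ is a concentration difference (making the solubility
  $K_0$ redundant) or a partial-pressure difference multiplied by $K_0$:
  both forms are implemented behind one interface
  (`form = "concentration"` / `"partial-pressure"`), and because $K_0$ is
  derived from the same Bunsen coefficient they agree identically — a
  property the tests assert.

Schmidt numbers come from the Wanninkhof (2014) fourth-order polynomials
for CH~4~ in seawater (S = 35) and freshwater, interpolated linearly in
salinity for brackish sites and range-checked to the fits' −2–40 °C
validity. Flux bounding follows the survey convention of pairing the
lowest/mean/highest concentrations with the Q1/median/Q3 of a year of
twice-daily wind observations; the quartile convention (type 7) is recorded
as an attribute of the output because quartile conventions differ across
software. Radon, the groundwater tracer, gets only the decay-time
correction $A_0 = A\,e^{\lambda t}$ ($t_{1/2}$ = 3.8235 d); instrument-side
salinity/temperature partition corrections are out of scope and this
narrowing is deliberate.

## Reactor and slurry rates

A flow-through reactor (FTR) percolates seawater through a sand bed at
flow $Q$ (45 mL h^-1^ default, ~1 h residence time for the 50 cm^3^ bed).
At steady state between samplings the volumetric production rate is the
plug-flow balance $x(t) = Q(t)\,(C_{out}-C_{in})/V_{FTR}$, per *bulk* sand
volume — no porosity division, though a porosity option exists — with
per-timepoint $Q$ because oxygen-pulse experiments raise the flow mid-run.
Outlet lag is not deconvolved. Negative rates (consumption) are allowed
and flagged.

Areal fluxes integrate $x$ over a sediment depth, default 0.5 cm — a
conservative depth of advective penetration of substrate-rich surface
water under wave pumping, which is a *user parameter justified by
literature*, not a fitted quantity. The conversion chain for the maximum
observed rate (48 µmol cm^-3^ h^-1^) is
24.0 µmol cm^-2^ h^-1^ → 240 mmol m^-2^ h^-1^ → 3.8 g m^-2^ h^-1^
(×16.04/1000), reproduced exactly in tests and by the acceptance script.
Because a "maximum rate" can mean a single noisy timepoint or a sustained
plateau, `max_rate()` reports both the pointwise maximum and a centred
rolling-mean maximum. The CH~4~:CO~2~ carbon remineralization ratio is
reported per timepoint as 1:n with $n = x_{DIC}/x_{CH_4}$ (linear
interpolation onto shared timestamps; zero methane rates flagged, not
thrown), attributing DIC change wholly to remineralization. Slurry rates
are OLS slopes of the cumulative series over a window, with standard
errors, per vial and per gram wet sediment.

## Metabolite closure

The methyl-group pool of a measured panel is
$\sum_i c_i \, m_i$ with $m_i$ the methyl groups per molecule (TMA,
TMAO, choline, glycine betaine: 3; DMSP, DMS: 2; methylamine: 1), shipped
as editable data. The supply rate to an FTR is panel concentration ×
feed dilution (20:1 or 50:1) × flow. The methyl→CH~4~ yield is genuinely
ambiguous: methylotrophic disproportionation (4 CH~3~ → 3 CH~4~ + 1 CO~2~)
gives 0.75, complete reduction gives 1.0. Both modes are shipped and
neither is labelled canonical; the closure fraction
(100 × theoretical/observed) flags values above 100% and reports the
unexplained remainder as a line item rather than imputing it to unmeasured
compounds.

## Marker-gene normalization

Functional-gene abundance in metagenomes is normalized as RPKM
(reads / kb / million library reads) and divided by the mean RPKM of 14
single-copy ribosomal marker genes, whose mean estimates "one genome's
worth" of sequence — making the ratio the fraction of the community
encoding the gene. The marker identities shipped
(`default_marker_genes()`) are placeholder ribosomal-protein ids; the
arithmetic, not the database, is the contract, and upstream
identity/coverage filtering is assumed done. Fold changes between samples
are ratios of these fractions, with a zero baseline flagged infinite
rather than erroring.

## What the generators emulate — and what they do not

Each generator is a pure function of (scenario, seed), with one global
seed fanned out to fixed per-stream child seeds so adding a generator
never perturbs existing draws.

* **Survey** (`generate_survey()`): 12 sites × 3 replicates; per-site
  percent saturation log-uniform over 380–189,000% with the endpoints
  pinned to the first and last site so the programmed range is always
  realized; lognormal replicate noise at 8% CV (matching the relative
  errors typical of low-concentration field replicates); temperatures
  12–24 °C, salinities 30–36; radon lognormal and independent of methane
  in the default no-groundwater regime. The truth concentrations are
  computed *backwards* through the same solubility chain the analysis
  runs forwards, so recovery is exact up to noise by construction — the
  closed loop validates plumbing, not nature.
* **Wind** (`generate_wind()`): 365 days × 2 observations of Weibull
  (shape 2, scale 6.2 m s^-1^, mean ≈ 5.5) U10 — a standard wind
  climatology shape for an exposed coastal station, with no seasonality
  or diel structure.
* **Reactor** (`generate_reactor()`): logistic rate growth after a 20 h
  anoxia onset to a programmed 48 µmol cm^-3^ h^-1^ maximum; a CH~4~:DIC
  ratio trajectory decaying exponentially to 1:9 at 44 h; optional oxygen
  pulses that zero production and ramp it back over a 1–2 h recovery lag;
  2% multiplicative lognormal measurement noise. Outlet concentrations
  follow the same plug-flow balance the analysis inverts. The programmed
  maximum implies outlet concentrations far above bubble-free solubility —
  the generator reproduces reported magnitudes, not two-phase transport.
* **Slurry** (`generate_slurry()`): forward simulation with the identical
  partitioning/dilution physics as `slurry_inventory()` — deliberately,
  because the bookkeeping identities (conservation, event splitting) are
  the thing under test; optional Gaussian ppm reading noise.
* **Counts** (`generate_counts()`): one multinomial draw per sample over
  gene categories plus a rest-of-genome category — the exact aggregated
  marginal of multinomial read allocation proportional to genome
  abundance × gene length with single-copy markers — at 10^7^ reads,
  3 Mb genomes, a 1650 bp target gene and a 0.2% carrier fraction
  (≈11 expected target reads, so single libraries carry ~30% sampling
  error; Monte-Carlo means over seeded replicates are used wherever
  precision is claimed).

Passing tests therefore demonstrate that the calculation chain is
self-consistent, exactly invertible where it claims to be, and unbiased
under the programmed statistical structure. They do not validate the
solubility fits beyond their literature check points, nor hydrodynamics,
bubble ebullition, carbonate-system effects on DIC, or any property of
real sequence data.

## Numerical and design notes

* Problem sizes: the default test and acceptance runs use a 12-site
  survey, 730 wind observations, 26–31 reactor timepoints, 9 slurry
  events and 500 count-table replicates — sizes chosen so the full suite
  exercises every code path in seconds while Monte-Carlo standard errors
  stay near 1%.
* Quantiles: type 7 everywhere, recorded in output metadata.
* The closure round-trip scenario is run with measurement noise disabled:
  it is an arithmetic consistency check of the
  panel → methyl → yield → closure chain against a programmed 86%, not a
  noise study.
* Degenerate inputs: zero atmosphere ($f_G = 0$) makes saturation
  undefined and raises an explicit error; zero methane rate makes the
  CH~4~:CO~2~ ratio undefined and is flagged `NA`; a zero fold-change
  baseline is flagged infinite.
* Ties and windows: `max_rate()` breaks ties by first occurrence;
  `slurry_rate()` requires ≥3 points in its window.

## Worked example

```{r example}
# the printed areal-flux chain
areal_flux(48, depth_cm = 0.5, molar_mass_g = 16.04)

# a survey record: 100 nM methane at 20 degC, S = 35
percent_saturation(100e-9, 20, 35)[, c("c_eq_mol_l", "saturation_pct")]

# sea-air flux at 4 m/s wind
sea_air_flux(100e-9, 20, 35, u10 = 4)$flux_mg_m2_d
```

The `analysis/` directory chains these stages as numbered scripts
(simulate → saturation/flux → reactor rates → slurry rates → closure →
marker normalization), writing tables under `results/`.
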