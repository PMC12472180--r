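---
title: "Methods and design notes for the dielpond pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for the dielpond pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dielpond)
```

`dielpond` analyses one diel cycle of a shallow, high-altitude pond: light
attenuation, mat photophysiology, dissolved greenhouse gases and their
air–water exchange, and inhibitor-resolved nitrification. This vignette
records the models, the parameters that matter, the numerical choices, and
what the synthetic-data validation does and does not demonstrate.

## Light attenuation

Downwelling PAR follows the Beer–Lambert law
$E_d(z) = E_d(0)\,e^{-K_d z}$, with $z$ in cm and $K_d$ in cm⁻¹. The
centimetre scale is deliberate: in turbid mat ponds only a few centimetres
deep, metre-based coefficients obscure the relevant gradient (a $K_d$ of
0.32 cm⁻¹ removes 20% of PAR within 0.7 cm).

`fit_kd()` fits the linearised model by ordinary least squares on
$\ln E_d$ versus $z$ with a free intercept, which is the standard
limnological estimator: it is closed-form, stable on short profiles, and
unbiased under multiplicative (lognormal) sensor noise because that noise
is additive Gaussian in log space. A nonlinear refit of the untransformed
exponential is available (`nonlinear = TRUE`) for profiles where additive
noise dominates; on clean data the two agree to numerical precision.

Degenerate inputs are handled explicitly rather than left to `lm()`:
non-positive irradiance readings are dropped with a warning (they have no
logarithm and usually mean the sensor bottomed out); a fit requires at
least three surviving points — a floor we impose because two points always
fit an exponential exactly and provide no error estimate; a perfectly
constant profile returns $K_d = 0$ with an undefined $r^2$ (the log
response has zero variance, so the usual coefficient of determination has
no meaning).

## PAM photophysiology

Effective quantum yield $\Delta F/F_m' = (F_m' - F)/F_m'$, maximal quantum
yield $F_v/F_m = (F_m - F_o)/F_m$, and $rETR = \Delta F/F_m' \times
E\text{-PAR}$ use incident irradiance with no absorptance factor, i.e. the
"relative" ETR convention, appropriate when the mat's absorption cross
section is not measured.

Instrument noise can produce $F > F_m'$ and hence a negative yield. Such
records are retained in the index table but carry `qc_valid = FALSE` and
are excluded from the diel statistics, so a single noisy saturating pulse
cannot drive the apparent yield minimum.

The diel summary quantifies photoinhibition as
`1 − min(Fv/Fm in noon window) / max(Fv/Fm before the window)` and
recovery as the last afternoon value over the same morning maximum. The
noon window defaults to 11:00–15:00 local — the interval in which midday
minima of benthic phototrophs are typically observed — and is
configurable.

## Dissolved gases, saturation and chamber fluxes

Headspace equilibration is inverted by mole balance. After a vial of
volume $V$ with headspace $V_h$ equilibrates at temperature $T$ and
pressure $P$, the measured mole fraction $x$ gives a partial pressure
$p = xP$; the original dissolved concentration referenced to the water
volume $V_w = V - V_h$ is

$$C_0 = \frac{pV_h/(RT) + K_0(T,S)\,p\,V_w}{V_w},$$

with $K_0$ the Henry-law solubility. The model is linear in $x$, and the
forward partitioning (`simulate_headspace()`) is its exact inverse — a
property the test suite exercises across a grid of temperatures,
salinities and headspace fractions.

Solubilities come from the standard seawater coefficient polynomials
(Weiss-type, $\ln K_0$ as a polynomial in $100/T$, $\ln(T/100)$ and
salinity): the CO₂ and N₂O sets give mol L⁻¹ atm⁻¹ directly; the CH₄ set
gives a Bunsen coefficient divided by 22.414 L mol⁻¹. All three are
checked in the tests against an independent re-evaluation of the
polynomials and against the qualitative monotonicities (colder and fresher
water holds more gas). Outside $T \in [-2, 40]$ °C or $S \in [0, 40]$ the
functions warn and extrapolate.

Percent saturation compares the dissolved concentration with air
equilibrium **at in situ conditions**: if the vial table carries a
`water_temp_c` column, that temperature (not the lab equilibration
temperature) sets the reference solubility. Two defaults deserve
attention:

- **Ambient pressure 0.64 atm.** At ~3800 m a.s.l. the atmospheric partial
  pressure of every gas is roughly two thirds of its sea-level value;
  saturation computed against 1 atm would misclassify. The default is
  configurable, and the saturation status of gases near equilibrium (N₂O
  especially) depends on it — a caveat to keep in mind when comparing
  against studies that do not state their pressure correction.
- **Atmospheric mole fractions** default to modern global means (CO₂ 420,
  CH₄ 1.9, N₂O 0.336 ppm) and should be replaced by local air
  measurements when available.

Saturation status uses the 100% threshold with a $10^{-9}$ numerical guard
so that an exactly-at-equilibrium input is not tipped to either side by
floating-point rounding. Dissolved CO₂ here is the gas-chromatographic
CO₂ signal only: above pH ~9 most dissolved inorganic carbon is
carbonate/bicarbonate, and no carbonate-system speciation is attempted.

Chamber fluxes are the OLS slope of mole fraction versus time converted
with the ideal-gas molar density: flux $= b\,P V_c\,60 / (R T A)$ in
µmol m⁻² h⁻¹ for slope $b$ in ppm min⁻¹, chamber volume $V_c$ (L) and
area $A$ (m²). A slope not distinguishable from zero at the configured
level ($\alpha = 0.05$) is reported as "no-trend"; an exactly constant
series short-circuits to zero flux rather than relying on `lm()`'s
degenerate standard error. Exponential (saturating) chamber models and
wind-based $k_{600}$ transfer-velocity models are intentionally out of
scope: the supported design is a short deployment with a handful of
samples, where the linear fit is the defensible choice.

## Endpoint nutrient rates and nitrification partitioning

Endpoint incubations yield one rate per flask,
$R = (C_{final} - C_{initial}) / \Delta t$ in µM h⁻¹. Treatment summaries
use the mean across replicate flasks with a spread of: SD for $n > 2$;
half the range for duplicates (which equals the standard error of a
duplicate mean); 0, flagged, for singletons.

The partition of the net nitrite rate is a set of differences against the
control: azide+GC7 isolates the bacterial ammonia-oxidiser (AOB)
contribution, azide+ATU the archaeal (AOA) one, and azide alone the
remaining production/consumption processes. Negative contributions are
reported as-is — net consumption is real information, not an error.
Treatment labels are configurable (`equations` argument) because inhibitor
panels differ between studies.

Uncertainty design: operand spreads combine in quadrature (replicate
flasks are independent). With duplicates, however, a ±1·u interval built
from two half-ranges covers the true value only ~58% of the time — the
error of a difference of duplicate means divided by that quadrature
estimate is exactly Student-t with 2 degrees of freedom. The partition
therefore also reports a 95% expanded interval, $\pm t_{0.975,\nu}\,u$
with Welch–Satterthwaite effective degrees of freedom $\nu$; it is this
interval whose coverage the validation suite checks (observed ~95% over
500 simulated duplicate experiments at σ = 0.05 µM).

Inhibitor concentrations are experiment metadata, not model inputs; the
inhibitor-efficacy matrix belongs to the *generator* (below), where it
exists to probe how imperfect inhibition distorts the partition.

## The statistical decision tree

`compare_groups()` reproduces the common field-study protocol: Shapiro–
Wilk on the pooled within-group residuals and a median-centred Levene
(Brown–Forsythe, via `car::leveneTest`) on the raw values; if both pass at
$\alpha = 0.05$ the comparison is a one-way ANOVA, otherwise
Kruskal–Wallis. The routing is deterministic given the two assumption
p-values and is reported alongside the result. Constant data, where both
pre-tests are undefined, fall through to Kruskal–Wallis with a
`constant_data` flag. The median-centred Levene variant was chosen as the
robust default among the variants in circulation. No multiple-testing
correction is applied by default (single planned contrasts);
Benjamini–Hochberg is available in `compare_many()`.

A pre-test-then-test procedure does not inherit the nominal error rate of
either branch automatically, so the suite measures the realised type-I
error of the full tree on null Gaussian data (2000 seeded replicates,
n = 10 per group) and requires it to sit within Monte-Carlo error of 5%.

`spearman_matrix()` uses pairwise-complete observations, average ranks for
ties and two-sided p-values; entries with fewer than 4 complete pairs are
set to missing and flagged rather than estimated from 3 points.

## The synthetic field day

The generator emulates the statistical structure the analysis assumes, so
every stage can be tested against known truth:

- **Forcing**: half-sine radiation curves peaking at solar noon (defaults:
  PAR 1100 µmol m⁻² s⁻¹, UVA 165 and UVB 58 W m⁻²), an air-temperature
  half-sine lagged 1 h between −5 and 18 °C, and a step-ramp wind increase
  from 1 to 6 m s⁻¹ at noon — the radiation extremes characteristic of
  high-altitude wetlands. The sensor log itself is noiseless.
- **PAM trace**: Yield II = baseline·(1 − c·E/E_peak) + Gaussian noise, so
  the yield minimum coincides with the irradiance maximum by construction
  (defaults: baseline 0.78, coupling 0.23, giving a midday minimum near
  0.6). Fv/Fm carries a fractional midday depression (default 0.0625:
  0.80 → 0.75) shaped by irradiance plus a linearly accruing recovery
  shortfall (default recovery 0.98). Fluorescence pairs are back-solved at
  an F_m′ scale of 1000.
- **Gases**: dissolved concentrations follow signed diel sinusoids around
  means of 23.4 µM CO₂, 163.1 nM CH₄ and 7.3 nM N₂O (CH₄ rising towards
  evening, CO₂/N₂O higher in the morning), forward-partitioned into vial
  headspace mole fractions at lab temperature (20 °C) with 1%
  multiplicative measurement noise; in situ water temperature (8 °C) is
  carried separately for the saturation reference. Chamber series are
  linear (CH₄ +0.05, CO₂ −0.5, N₂O 0 ppm min⁻¹) plus Gaussian noise over
  five samples 20 min apart.
- **Incubations**: duplicate flasks per treatment, 5.5 h, Gaussian
  endpoint noise σ = 0.05 µM. Treatment rates follow a linear signal
  model: azide-combination flasks deviate from the control by the guild
  signal the second inhibitor isolates, with leak terms for imperfect
  GC7/ATU, and single-inhibitor flasks subtract the suppressed guild.
  Under the ideal efficacy matrix (azide 1, GC7 1, ATU-on-AOB 1,
  ATU-on-AOA 0) the difference equations recover the configured rates
  exactly — the algebraic round trip the tests assert. Morning truth
  (control 0.3, AOB 0.4, AOA 0.2, other −0.05 µM h⁻¹) exceeds afternoon
  truth by design.

Noise magnitudes (lognormal σ = 0.05 for irradiance, 0.01 for
fluorescence yields, 1% for headspace readings, 0.05 µM for endpoints)
are assumptions — realistic for the respective instruments, but not
derived from any error model of real data. Reproducibility: one integer
seed; each table draws from a sub-stream at `seed + fixed offset`, so the
same seed yields a bit-identical bundle.

What passing the synthetic suite shows: the estimators are correct
inverses of the generating models and unbiased at realistic noise. What it
does not show: robustness to structure the generator omits — non-linear
chamber accumulation, drifting baselines, ebullition spikes in CH₄,
heteroscedastic nutrient chemistry, partial inhibitor specificity in real
communities (the efficacy matrix lets you *probe* that sensitivity, but
the default scenario is ideal), and any spatial heterogeneity.

## Pipeline and problem sizes

`run_pipeline()` only orchestrates: validation, then light → PAM → gases
→ rates → stats, each number traceable to a stage function; a missing
input skips that stage and is recorded. Reports are deterministic for
fixed inputs.

The validation suite runs at deliberately modest problem sizes — 200
profiles for the $K_d$ recovery Monte Carlo, 500 chamber series and 500
incubation experiments, 2000 replicates for the type-I calibration —
chosen so the full suite completes in well under a minute while keeping
Monte-Carlo standard errors a factor of a few below the tolerances being
asserted.

## Known limitations

- Endpoint (two-point) rates only; multi-timepoint kinetic fits are out of
  scope, as are isotope-tracer methods.
- The saturation call for near-equilibrium gases depends on the assumed
  ambient pressure and atmospheric mole fractions; both are explicit,
  configurable assumptions.
- The CO₂ interpretation ignores the carbonate system; at pH > 9 treat
  dissolved CO₂ and its saturation as a lower bound on DIC disequilibrium.
- The statistics module implements two-group (morning/afternoon) designs;
  k-group use works but is untested beyond k = 2, and community-ecology
  statistics (PERMANOVA, ordination) are intentionally absent.
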