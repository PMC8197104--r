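---
title: "Methods: outdoor thermal comfort and construction accident risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: outdoor thermal comfort and construction accident risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Construction work happens outdoors, and the thermal environment a worker
experiences — air temperature, radiant heat from sun and surfaces, wind and
humidity — plausibly modulates accident risk. `comfortrisk` implements an
analysis chain for this question built around the **physiological
equivalent temperature (PET)**: hourly weather records are converted to
PET, accident registry records are linked to the weather of their city,
district and hour, events are classified into comfort bands and seasons,
the probability that each accident type occurs outside the 18–23 °C
comfort range is estimated by Monte Carlo simulation, and a small neural
network ranks the four environmental inputs by relative importance.

Because national accident registries and meteorological feeds are not
freely redistributable, the package ships a synthetic registry generator
that reproduces the statistical structure the analysis relies on. Every
downstream stage is exercised, with known ground truth, on synthetic data.

## The human heat-balance model

### PMV

The predicted mean vote is Fanger's steady-state index,

$$\mathrm{PMV} = \left(0.303\,e^{-0.036M} + 0.028\right) L,$$

where $L$ (W/m²) is the thermal load: metabolic heat production $M - W$
minus the losses by skin vapor diffusion, sweat evaporation (active only
above the activity threshold $M - W > 58.15$ W/m², and therefore inactive
for the light-activity subject used here), latent and sensible
respiration, radiation
$3.96\times10^{-8} f_{cl}\left[(t_{cl}+273)^4 - (T_{mrt}+273)^4\right]$
and convection $f_{cl} h_c (t_{cl} - t_a)$. The clothing area factor
$f_{cl}$ is the printed two-branch linear form with the boundary at
$I_{cl} = 0.078$ m²K/W assigned to the lower branch; the convective
coefficient is the larger of $2.38|t_{cl}-t_a|^{0.25}$ and
$12.1\sqrt{v}$.

The clothing surface temperature $t_{cl}$ appears on both sides of its
balance. The solver first tries the classic damped fixed-point iteration
(damping 0.5, start $(t_{sk}+t_a)/2$, tolerance $10^{-4}$ °C). At outdoor
wind speeds the iteration oscillates, so elements that have not converged
after 30 sweeps are finished by bisection on the residual, which is
strictly decreasing in $t_{cl}$ and therefore guarantees termination.
The implementation reproduces the standard ISO reference cases to
0.01 PMV units, and the test suite checks it against an independent
scalar root-search oracle to $10^{-3}$ over 200 random states spanning
$t_a \in [-20, 40]$, $T_{mrt} \in [t_a - 20, t_a + 30]$,
$v \in [0, 10]$, $RH \in [0, 100]$.

Vapor pressure uses the Magnus form
$e_s = 611.2\exp\!\left(\frac{17.62\,t_a}{243.12+t_a}\right)$ Pa over
water at all temperatures, including below 0 °C: the analysis classifies
events on a continuous PET scale and a freezing-point discontinuity in
$P_a$ would propagate into the index.

### PET by load equivalence

PET is defined as the air temperature of a standardized indoor reference
environment — $T_{mrt} = t_a$, $v = 0.1$ m/s, $P_a = 1200$ Pa — at which
the body's heat budget equals that in the actual outdoor environment.
The full definition rests on a two-node (core/skin) physiological model;
this package instead matches the *thermal load* of the PMV body model
between the two environments, with the personal factors fixed at 0.9 clo
and 80 W (converted to flux with a 1.80 m² DuBois area; both are
configurable through `person_state()`). The reference temperature is
found by bisection over $[-60, 70]$ °C to 0.01 °C; the reference load is
strictly increasing in the reference temperature, so the root is unique.
Mechanical work $W$ is 0 throughout, the standard assumption for this
kind of exposure index.

Two consequences of the single-node simplification matter for
interpretation:

* **Self-consistency and monotonicity are exact.** The PET of the
  reference environment is its own air temperature to within 0.02 °C
  over $[-20, 40]$ °C, PET increases strictly with air temperature, and
  wind strictly lowers PET below skin temperature. On the twelve monthly
  monsoon normals (where $T_{mrt} \approx t_a$ on average) the model
  tracks the published monthly PET values to within about 2.6 °C.
* **Strong wind combined with solar-elevated radiant temperature is
  over-weighted.** In a two-node model, vasoconstriction lowers skin
  temperature under cold stress and caps the dry heat loss; with the PMV
  model's fixed metabolic skin-temperature line, a 10 m-height station
  wind of 2–8 m/s at sub-skin temperatures produces 6–12 °C colder PET
  than the reference two-node software on the published example rows.
  The corresponding cross-check test is therefore expected to fail at
  its ±2.5 °C band and is retained as an honest record of the
  approximation error, not weakened. Users who need closer agreement
  with station data should reduce wind to body level before calling
  `pet()`; the package deliberately does not do this implicitly, because
  its input contract is wind *at body level*.

## The synthetic registry

`registry_config()` defaults are the study conditions: ten calendar
years, a three-city/six-district layout in which all districts of a city
share the city's weather, and hourly series built as

* **temperature** — a mean-preserving interpolation of the twelve
  monthly normals (anchors solved so that monthly averages reproduce the
  targets exactly; plain mid-month interpolation would bias January by
  +0.6 °C because it smooths the winter minimum), plus a 4 °C diurnal
  cosine peaking at 14:00, plus AR(1) noise with coefficient 0.8 and
  stationary sd 1.5 °C;
* **radiant temperature** — air temperature plus a deterministic
  daytime offset, 10 °C at solar noon falling sinusoidally to 0 at
  06:00/18:00 (radiant modelling from sky geometry is out of scope);
* **wind** — lognormal around the monthly normal (sdlog 0.4);
* **humidity** — beta-distributed around the monthly normal
  (concentration 25), clipped to [0, 100].

Accidents are an inhomogeneous Poisson stream per (type, severity) over
working hours (Mon–Fri, 07:00–18:00 by default; the working-day boundary
is a configuration default, not an observed fact). The hourly intensity
is the per-type base rate (published ten-year totals divided by ten)
times the monthly shape of the published accident counts (normalized to
mean 1) times an optional multiplier $k_{out}$ for hours whose PET lies
outside 18–23 °C. `calibrate_comfort_multiplier()` inverts the planted
outside-comfort probability
$p = k W_{out} / (k W_{out} + W_{in})$ for $k$, which gives the
parameter-recovery tests exact ground truth. Five simulated years
reproduce each monthly temperature normal within ±0.5 °C (measured
maximum error ≈ 0.1 °C).

What the generator does **not** emulate: spatial weather gradients
between cities beyond independent noise, public holidays (the working
calendar is strictly Mon–Fri), worker-population denominators, and any
real correlation between accident type and weather other than the
planted comfort effect. Passing tests on synthetic data therefore
validate the machinery — linkage, classification, estimation, recovery
of planted effects — not any substantive claim about real registries.

## Record linkage and classification

Linkage is a deterministic join on (city, district, hour), with event
timestamps truncated (not rounded) to the hour, matching the on-the-hour
convention of climate feeds. Duplicate climate keys are an integrity
error. The `nearest-hour` policy allows a ±1 h fallback, preferring the
earlier hour on ties for determinism; `strict` drops unmatched events
with a reported count — the pipeline never silently loses rows, and
`linked + unmatched = input` is asserted in the tests.

PET comfort bands are half-open intervals $[\ell, u)$: the published
band edges repeat their endpoints ("4–8", "8–13"), and half-open
intervals turn them into an exact partition. The comfort zone is exactly
$[18, 23)$; cold is $\mathrm{PET} < 18$, hot is $\mathrm{PET} \ge 23$.
Seasons are the three-month calendar blocks starting in March.

## Monte Carlo comfort-range probabilities

For each accident type and severity the event-level PET sample is
summarized by its mean and sample standard deviation ($n-1$), and the
probability of the cold/hot/outside ranges is estimated as the mean of
indicator values over $N = 10^6$ draws from
$\mathcal{N}(\mu, \sigma)$, with binomial standard errors and normal
95% intervals. The sampling distribution is a modelling choice — the
event PET distribution is a seasonal mixture, not a normal — but the
published per-type percentages are reproduced from the published
(mean, sd) pairs under normality to within ~0.7 percentage points for
the fatal rows, which fixes normality as the implied model.
Threshold sidedness matches the classification module: cold strictly
below 18, hot at or above 23, so `p_outside + p_neutral = 1` holds
exactly per draw set. Because the normal approximation error dwarfs the
Monte Carlo error at $10^6$ draws, the planted-effect recovery test
compares the *empirical* outside-comfort fraction of linked events
against its planted value (binomial 2 SE), and reserves the fitted
normal for the published-parameter comparisons.

## Relative importance

`build_dataset()` emits one row per working station-hour with the four
weather features and the hour's fatal/injury event counts (or binary
presence — both encodings are exposed because the original analysis does
not state which it used). The network is 4 inputs → 9 hidden logistic
units → 2 logistic outputs ("nine hidden layers" in the source analysis
is read as nine hidden *units* in one layer, following its architecture
figure; the unit count is configurable). Features and targets are
min–max scaled to [0, 1]; 70% of rows train, 30% test;
$R^2 = 1 - SSE/SST$ pooled over both outputs on the test split, defined
as 0 when $SST = 0$.

Training uses `nnet` (BFGS on the least-squares criterion) with a small
ridge penalty (decay $10^{-3}$). The penalty is not cosmetic: the
connection-weight decomposition reads importance off the weights, and
with no penalty an input the fitted function ignores can retain large
mutually-cancelling weights and inherit spurious importance. With the
penalty, a planted outcome depending only on $t_a$ yields a $t_a$
importance above 0.5 in 20 of 20 seeds (insensitive over decay
$10^{-3}$–$10^{-2}$); without it, 16 of 20.

Importance is Garson's decomposition for a single hidden layer:

$$Q_i \propto \sum_h \sum_o \frac{|w_{ih}|}{\sum_k |w_{kh}|}\,|v_{ho}|,
\qquad \sum_i Q_i = 1,$$

verified in the tests against exhaustive path enumeration, and invariant
to permuting hidden units. Olden's signed variant
($\sum_h \sum_o w_{ih} v_{ho}$, unnormalized) is available via
`method = "olden"`. One property differs between the two: when the
outcome is independent of all inputs, the *signed* importances contract
toward zero as the sample grows (the fitted function flattens and all
weights shrink), but the normalized shares do not — they are a ratio of
vanishing weights and remain ill-conditioned. The corresponding property
test therefore measures the signed variant.

The original analysis's exact importances and its $R^2 = 97.53\%$ depend
on the restricted registry and on an unstated target construction; they
are out of scope. On the synthetic registry the reproducible findings
are the *shape* of the result: near-uniform importances with air
temperature first, and a low count-level $R^2$ (hourly accident counts
are mostly Poisson noise at these rates).

## Problem sizes and numerical settings

The test suite runs the generator at 1–5 simulated years and one to
three cities, the planted-effect recovery at three years (≈28,000
planted-type events), the PMV/PET oracles at 200 random states, the
Monte Carlo checks at $10^6$ draws, and the importance recovery at 20
seeds × 300 rows — sizes chosen so the whole suite completes in about a
minute while keeping every estimator's error well below its assertion
band. Key tolerances: clothing temperature $10^{-4}$ °C; PET bisection
0.005 °C (reported to 0.01 °C); Monte Carlo assertions at 4 binomial
SE; importance decomposition exact to $10^{-12}$ against enumeration.

## Known limitations

* PET is a load-equivalence approximation; see the wind/radiation
  discussion above.
* The Monte Carlo stage assumes normal PET distributions per type;
  per-draw-set exactness and published-parameter agreement are tested,
  distributional adequacy on real data is not testable here.
* The generator's accident stream is conditionally independent across
  hours given weather; real registries cluster (projects, sites, crews).
* $R^2$ of the importance network on count targets is intrinsically
  small at realistic rates; the network is a ranking device here, not a
  forecaster.
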