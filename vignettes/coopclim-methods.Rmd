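---
title: "Methods: the layer-house heat-balance model and its controllers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the layer-house heat-balance model and its controllers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopclim)
```

## The plant: a lumped heat balance under combined ventilation

`coopclim` models a multi-tier caged layer house as a single well-mixed air
volume. The indoor temperature $T_i$ obeys

$$\rho V c_p \frac{dT_i}{dt} = Q_s + Q_c - Q_v - Q_g - Q_w,$$

with air density $\rho$ (kg/m³), house volume $V$ (m³) and specific heat
$c_p$ (J/(kg·°C)). The terms, each in watts:

* **Solar gain** $Q_s = P_s S_w I$: irradiance $I$ on the effective
  envelope area $S_w$, attenuated by a radiation conversion coefficient
  $P_s \in [0,1]$ (`solar_gain()`).
* **Flock sensible heat** $Q_c$: total metabolic production follows the
  CIGR-style expression
  $Q_t = (6.28\,M^{0.75} + 25\,Y)\,(4\times10^{-5}(20-T_i)^3 + 1)$ with
  live weight $M$ (kg) and egg output $Y$ (kg/day), multiplied by the
  sensible fraction
  $0.67(1-0.02(20-T_i)) - 9.8\times10^{-11}T_i^6$
  (`total_heat_production()`, `sensible_heat()`). Both temperature
  polynomials equal their reference values at 20 °C. The fraction is
  clamped to $[0,1]$ because the polynomial leaves the physical range at
  extreme temperatures.
* **Ventilation loss** $Q_v$: see below.
* **Floor exchange** $Q_g = h_g S_g (T_i - t_g)$ against the floor /
  manure-pit temperature $t_g$ (`floor_heat_loss()`); the sign follows the
  temperature difference, so a warm pit heats the room.
* **Envelope loss** $Q_w = k_s F_s (t_n - t_w)$ between the inner and
  outer surface temperatures of the enclosure (`envelope_heat_loss()`).
  When a driver supplies no surface measurements, the inner surface
  defaults to the current indoor temperature and the outer surface to the
  outdoor dry-bulb — a quasi-steady approximation.

Heat from lighting and equipment and infiltration leakage are deliberately
omitted: they are small against the hundreds of kilowatts moved by
ventilation at this scale. There is no humidity, gas or spatial state; the
well-mixed assumption is the model's central simplification.

### Per-bird evaluation of the flock heat

The CIGR expression is defined per animal (metabolic mass scales as
$M^{0.75}$ within one bird, not across a flock). Applying it to the summed
flock weight of ~93 t would yield only ~100 kW for 48,000 hens — about
2 W per bird, an order of magnitude below any published measurement, and
far too little to hold a 25–27.5 °C setpoint against the minimum
ventilation rate. The house-level budget therefore evaluates

$$Q_c = n \cdot \mathrm{sensible}(M/n,\, Y/n,\, T_i)$$

with the bird count $n$ (default 48,000). The scalar operations remain
pure functions of whatever mass you pass them; setting `n_birds = 1` in
`house_config()` recovers the literal total-mass reading.

## Combined positive- and negative-pressure ventilation

Exhaust fans remove a total flow $L_-$ (m³/s internally; m³/min at the
actuator and configuration boundary). Continuity splits the intake into a
positive-pressure-fan stream $L_+ = \lambda L_-$ and a guide-plate stream
$L_d = (1-\lambda) L_-$, with face velocities $v_+ = \lambda L_-/A_+$ and
$v_d = (1-\lambda)L_-/A_d$ (`split_velocities()`; conservation
$A_+v_+ + A_dv_d = L_-$ is tested to 1e-9).

Each stream is cooled by the evaporative pad. The outlet temperature is

$$t_c = t_s + (t_0 - t_s)\,e^{-12.28305\, v^{-0.30078} H},$$

between the outdoor wet-bulb $t_s$ and dry-bulb $t_0$, with pad thickness
$H$ (m). Slower air spends longer in the pad, so the outlet approaches the
wet-bulb as $v \to 0$; below a 1e-6 m/s velocity floor the outlet is set to
$t_s$ exactly (the associated mass flow is then also ~0, so no flux is
affected and no NaN can arise). With $H = 0.15$ m this decay law gives
saturation efficiencies in the 60–90 % range documented for pads of this
class. An alternative reading that multiplies the exponent by
$\rho c_p$ is selectable (`pad_exponent_rho_cp`), but it drives the decay
factor to 0 and turns the pad into a perfect wet-bulb cooler, which
contradicts its role as a partial cooler; it is off by default. When the
pad is closed (autumn and winter operation) the intake is at the dry-bulb
temperature.

The ventilation loss is then
$Q_v = \rho \lambda L_- c_p (T_i - t_{c+}) + \rho(1-\lambda)L_- c_p (T_i - t_{cd})$
(`ventilation_heat_loss()`).

Because the positive-pressure fans concentrate their share of the flow
through a small total area (≈6.7 m² against ≈45 m² of guide-plate
cross-section), raising $\lambda$ raises the pad-face velocity and thus
*reduces* the evaporative cooling of that stream. In this lumped model
$\lambda$ is therefore an air-distribution knob, not a cooling booster;
its value is scheduled by the controller's rule base from the temperature
error, and its thermal effect is secondary.

### Geometry and parameter defaults

Defaults in `house_config()` describe a 100 m × 15 m × 4 m house:
$V = 6375$ m³, floor $S_g = 1500$ m², envelope $F_s = 920$ m²
(230 m perimeter × 4 m), irradiated area $S_w = 1491$ m², $P_s = 0.64$,
$h_g = 6$ and $k_s = 0.93$ W/(m²·°C), $\rho = 1.2$ kg/m³,
$c_p = 1006$ J/(kg·°C), pad thickness 0.15 m. The fan and guide-plate
areas are derived from the installed hardware: 95 positive-pressure fans
of 0.30 m diameter give $A_+ \approx 6.7$ m²; the guide-plate openings
below the pad sets (2.13 m × 21 m per side) give $A_d \approx 45$ m².
The flock defaults are 48,000 birds at 92,900 kg total — the mass implied
by the seasonal ventilation limits of 0.08 and 0.02 m³/(min·kg) against
7435 and 1858 m³/min — and 2700 kg of eggs per day (~92 % lay at 62 g).
Three auxiliary coefficients (roof heat exchange 5.4 W/(m²·K), insulation
conductivity 0.042 W/(m²·K), pad area 1504 m²) are carried in the
configuration for completeness but enter no default flux.

### Integration

The state advances by explicit Euler with $dt = 60$ s, matching the 1-min
cadence of the drivers (`plant_step()`). At the maximum flow the discrete
eigenvalue $dt \cdot m c_p / (\rho V c_p) \approx 1.2$ stays inside the
stability region, and the fixed point of the Euler map is exactly the root
of the net heat budget, so constant-input trajectories converge to the
equilibrium found independently by bisection
(`equilibrium_temperature()`; tested to 0.01 °C on 20 random scenarios).
A classical Runge–Kutta stepper is available for convergence checks only.

## The controller family

All controllers run on the same 60 s cadence as the plant. The discrete
PID law is

$$u_k = (K_P + \Delta K_P) e_k + (K_I + \Delta K_I)\textstyle\sum_j e_j +
 (K_D + \Delta K_D)(e_k - e_{k-1}),$$

with $e = T_{set} - T_i$. The integral and derivative are per control
step: this keeps the error-change universe $[-1.5, 1.5]$ °C/step
meaningful and makes the gains per-step quantities. The integral is
clamped so the integral term alone can never exceed the actuator span
(anti-windup); the first step uses $e_{k-1} = e_k$ (zero derivative).

Seasonal presets (`season_preset()`): setpoints 27.5 / 27 / 25.5 °C and
base gains 23/15/3, 17/13/8, 13/12/4 for summer, autumn and winter; pad
open only in summer. Ventilation is bounded in every season by
[1858, 7435] m³/min — the winter physiological minimum applies year-round
and the summer hardware maximum is a property of the installation, so the
pair is used as a common saturation band.

**Actuation.** The controller output maps reverse-actingly onto flow:
$L_- = \mathrm{clip}(L_{min} + \max(0, -g\,u))$, since $u < 0$ signals a
cooling demand. The actuator gain $g$ (m³/min per output unit) is not
fixed by the control law itself; the default $g = 25$ is sized by loop
shaping so that the proportional loop gain is near 0.5 per step (well
damped) and the integral winds to full actuator authority in roughly
15 minutes, the response-time scale this controller family operates at.
Both $g$ and the band are configurable per preset.

**Fuzzy gain scheduling.** The fuzzy PID adds a dual-input, quad-output
Mamdani layer: inputs $e$ (universe $[-3, 3]$ °C) and $e_c$
($[-1.5, 1.5]$ °C/step), outputs $\Delta K_P, \Delta K_I, \Delta K_D$
(shared universe $[-5, 5]$) and the split coefficient $\lambda$
($[0, 1]$). Seven triangular membership functions (NB…PB) with evenly
spaced centers and 50 % overlap cover each universe; inputs beyond a
universe are clipped to its bounds. The 7×7 rule base (49 rules, four
output terms per cell) is shipped as a plain CSV
(`system.file("extdata", "fuzzy_rules.csv", package = "coopclim")`) and
follows the usual expert heuristics: large errors raise $K_P$ and cut
$K_I$; near the setpoint $K_I$ rises to kill steady-state error; and a hot
house (negative $e$) drives $\lambda$ up while a cold one drives it to
zero. Inference is min–max, defuzzification is the centroid of the
clipped-and-aggregated output sets, evaluated on a fixed 601-point grid —
fine enough that the symmetric cases used in the tests are exact to
1e-12, while the centroid ripple between adjacent cells stays below ~0.01
on the $\lambda$ channel.

The $\lambda$ channel is defuzzified on $[0, 1]$ and mapped affinely so
that a pure NB output lands exactly at 0 and a pure PB output at 1, using
the centroids of the edge triangles as anchors; this makes the mapping
independent of how the edge triangles are clipped by the universe bounds.

**Variable universe.** The variable-universe controller contracts the
$e$, $e_c$ and $\Delta K$ universes online with
proportional-exponential factors

$$\alpha(x) = (|x|/E)^P + \theta, \qquad
 \beta = \tfrac{1}{2}(\alpha_e + \alpha_{ec}) + \theta,$$

sharing one adaptive exponent
$P = E_1/(|e|(E_1{+}E_2)+v) + E_2/(|e_c|(E_1{+}E_2)+v)$, capped at 1. As
the error shrinks, $P$ caps and the universes contract towards their
$\theta$-floors, refining the rule grid exactly where the loop is close
to the setpoint; at large errors the universes stay near full width. The
offsets default to $\theta = 10^{-4}$ and $v = 10^{-6}$ — "sufficiently
small positive" guards against degenerate universes and division by zero —
and universes are rescaled every control step before fuzzification, with
inputs clipped to the contracted bounds so $\alpha \le 1 + \theta$ always
bounds the effective ratio. Contraction commutes exactly with input
rescaling for triangular families
($\mathrm{fuzzify}(x, \alpha U) = \mathrm{fuzzify}(x/\alpha, U)$), which
the tests use as an identity oracle.

Two readings were open in the scaling design. First, the exponent formula
is taken with $|e|$ in the *denominator*: only that form grows beyond 1 as
the errors vanish, which is the stated behaviour the cap exists for.
Second, only the $\Delta K$ channels see the contracted universes; the
$\lambda$ channel is inferred on the base universes. $\lambda$'s $[0,1]$
universe has no stated contraction law, and feeding the contracted inputs
to its rules would make any ±0.05 °C error saturate the error term to
NB/PB and bang-bang $\lambda$ between 0 and 1 every minute — a ±0.4 °C
flux oscillation that defeats the purpose of the refinement.

**Degeneracies.** With the scaling factors frozen at 1 the
variable-universe controller is bit-identical to the fuzzy PID; with the
fuzzy corrections zeroed the fuzzy PID is bit-identical to the plain PID
(at the same fixed $\lambda$). Both identities are structural — the same
code path with switches — and are asserted in the tests.

**On–off baseline.** A two-level thermostat with a symmetric ±0.5 °C
hysteresis band toggling between $L_{min}$ and $L_{max}$
(`onoff_step()`); the staged multi-fan cycling of a real installation is
out of scope.

## Synthetic weather

`synth_day()` emulates the monitored seasonal days at 1-min cadence:

* outdoor temperature follows a piecewise-cosine diurnal curve hitting
  the daily minimum at 05:00 and the maximum at 15:00 exactly (a single
  sinusoid cannot place extremes 10 h apart);
* seasonal extremes default to the monitored days: 19.3–35.0 °C
  (summer), 13.2–27.4 °C (autumn), −10.5–1.4 °C (winter);
* irradiance is a half-sine between sunrise and sunset (peaks 850, 600
  and 420 W/m² — clear-sky magnitudes for the respective seasons at this
  latitude);
* relative humidity is anti-correlated with temperature
  (−1.5 %/°C about the seasonal mean of ~45 %), clipped to [5, 100] %;
* wet-bulb temperature comes from a single-expression psychrometric fit,
  clamped to never exceed the dry-bulb, and validated in the tests
  against an iterative saturation-vapour-pressure solver to 1 °C;
* the floor/pit temperature is the daily mean outdoor temperature plus a
  seasonal offset (1, 4 and 20 °C) keeping the pit near its typical
  28 / 24 / 15 °C;
* AR(1) noise (lag-1 correlation 0.98, marginal σ 0.3 °C; 5× for
  humidity) is added under an explicit seed, and the generator restores
  the caller's RNG state.

The generator reproduces diurnal shape, seasonal range and
humidity–temperature coupling; it does **not** emulate weather fronts,
rain (the monitored farm saw pad-off rain days), multi-day trends, or
measured wall-surface series. Passing tests on these drivers therefore
demonstrate correct model mechanics and controller ranking under clean
seasonal forcing, not predictive accuracy on farm data.

## Problem sizes and test design

The test suite and the acceptance script run closed loops of one or two
synthetic days (1440 or 2880 steps) per controller, a ten-day seeded
summer battery for the controller ranking, 20 random constant-input
scenarios for the equilibrium oracle, and a few hundred randomized draws
for the bounded-output properties — sizes chosen so the whole suite
completes in well under a minute of simulation per controller while still
exercising every regime (saturated hot midday, interior tracking,
minimum-flow nights).

On the ten-day battery the mean tracking MAE orders as
VFPID ≤ FPID ≤ on–off and the mean oscillation index of the
variable-universe controller stays far below the thermostat's limit
cycle; the mean $\lambda$ over hot summer drivers exceeds that over cold
winter drivers, where the error is persistently positive and the rule
base holds $\lambda \approx 0$. These are the qualitative rankings the
controller family is designed to show; exact magnitudes depend on the
driver and are computed fresh by the tests.

## Known limitations

* Single-zone model: no stratification, no along-house gradients, although
  monitored houses show several degrees of spatial spread on hot days.
* No humidity or CO₂ state, so pad operation feeds back on temperature
  only.
* The envelope quasi-steady closure ($t_n = T_i$, $t_w = t_0$) ignores
  wall thermal mass; measured surface temperatures override it when
  supplied.
* Summer middays with full solar gain exceed the cooling capacity at the
  maximum flow, so every controller saturates and tracking error there is
  plant-limited — visible in the traces as a common afternoon excursion.
* The on–off baseline is a single two-level stage, not the staged fan
  banks of a real installation, so its limit-cycle amplitude is an upper
  bound on what staged cycling would show.
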