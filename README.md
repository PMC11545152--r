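# coopclim

Heat-balance simulation and variable-universe fuzzy PID ventilation control
for multi-tier layer houses.

Modern caged layer houses hold tens of thousands of hens whose welfare and
egg production depend on a stable indoor temperature, yet most installations
still regulate it with on–off fan thermostats. Houses ventilated by a
*combined positive- and negative-pressure* (CPNPV) system add a further
difficulty: exhaust fans pull air out while inlet fans push evaporatively
cooled air in, and the two flows are coupled through a split coefficient
λ ∈ [0, 1]. `coopclim` is for agricultural and building-climate engineers
who want to study this control problem in simulation: it provides the house
as a dynamic plant, a family of controllers of increasing sophistication
(on–off, PID, fuzzy PID, variable-universe fuzzy PID), a synthetic seasonal
weather generator, and the metrics used to compare controllers.

## The model

Indoor temperature follows a lumped heat balance

```
ρ V cp dTi/dt = Qs + Qc − Qv − Qg − Qw
```

with solar gain `Qs = Ps·Sw·I`, CIGR flock sensible heat `Qc` (evaluated
per bird), ventilation loss `Qv`, floor exchange `Qg = hg·Sg·(Ti − tg)` and
envelope loss `Qw = ks·Fs·(tn − tw)`. The exhaust flow `L−` splits into a
positive-pressure stream `λL−` and a guide-plate stream `(1−λ)L−`; each
enters through the evaporative pad at its own face velocity `v`, leaving at

```
tc = ts + (t0 − ts)·exp(−12.28305 · v^−0.30078 · H)
```

between the outdoor wet-bulb `ts` and dry-bulb `t0` (pad thickness `H`).

The controllers share a discrete PID core
`u = (KP+ΔKP)e + (KI+ΔKI)Σe + (KD+ΔKD)Δe` with `e = Tset − Ti`. A 49-rule
Mamdani layer (seven triangular terms per input) schedules the corrections
ΔKP, ΔKI, ΔKD and the split λ from `e` and its rate of change; the
variable-universe variant additionally contracts the fuzzy universes online
with proportional-exponential scaling factors `α = (|x|/E)^P + θ`, so the
rule grid refines itself as the loop closes on the setpoint. Commanded
ventilation is saturated to the seasonal band [1858, 7435] m³/min.

See the methods vignette (`vignettes/coopclim-methods.Rmd`) for the full
model description, parameter defaults and design decisions.

## Worked example

Simulate one noisy synthetic summer day (outdoor 19.3–35.0 °C, cooling pad
open, setpoint 27.5 °C) under the variable-universe fuzzy PID:

```r
library(coopclim)

driver <- synth_driver("summer", days = 1, seed = 7, noise_sd = 0.3)
preset <- season_preset("summer")
trace  <- simulate_house(driver, preset, controller = "vfpid")
str(control_metrics(trace))
#> List of 6
#>  $ mae          : num 1.84
#>  $ rmse         : num 2.89
#>  $ max_error    : num 6.46
#>  $ overshoot_pct: num 23.5
#>  $ response_time: num 492
#>  $ aoi          : num 0.264
```

The trace holds one row per minute with the indoor temperature, the error,
the commanded flow, λ, the effective gains and every heat-budget term. The
MAE of 1.84 °C is dominated by the saturated midday hours, when full solar
gain exceeds the cooling capacity at the maximum flow and every controller
rides the 7435 m³/min limit; the oscillation index (0.264 % mean
step-to-step change) shows how steady the loop is elsewhere. Running all
four controllers on the same driver:

```r
compare_controllers(driver, preset)
#>  controller  mae rmse max_error overshoot_pct response_time   aoi mean_lambda
#>       onoff 2.54 3.22     10.17          22.3            NA 5.509       0.000
#>         pid 1.84 2.57      5.66          20.6           492 1.973       0.000
#>        fpid 1.87 2.89      6.46          23.5           488 0.419       0.284
#>       vfpid 1.84 2.89      6.46          23.5           492 0.264       0.271
```

The thermostat sustains a limit cycle (oscillation index 5.5 %, never
settles); the PID family tracks far more steadily, and the fuzzy layers cut
the residual oscillation by a further factor of 5–8 while scheduling λ up
on this hot driver.

A thin command-line front end over the same functions is installed at
`system.file("scripts", "coopclim", package = "coopclim")` with
`synth`, `simulate`, `compare` and `metrics` subcommands, and seasonal
configuration presets ship as YAML under `inst/extdata/`.

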