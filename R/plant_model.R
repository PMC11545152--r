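#' @title House heat-balance plant model
#' @description Individual heat fluxes of the layer-house energy balance and
#'   the explicit-Euler state update. The balance reads
#'   `rho V cp dTi/dt = Qs + Qc - Qv - Qg - Qw`, where `Qs` is solar gain,
#'   `Qc` the flock's sensible heat, `Qv` the ventilation loss (split into a
#'   positive-pressure-fan stream and a guide-plate stream, each cooled by the
#'   evaporative pad), `Qg` the floor exchange and `Qw` the envelope loss.
#'   Heat from lighting/equipment and infiltration leakage are neglected.
#' @name plant_model
NULL

#' Solar heat gain through the envelope
#'
#' @param Ps Radiation conversion coefficient, in `[0, 1]`.
#' @param Sw Effective irradiated envelope area, m2.
#' @param I Solar irradiance, W/m2 (must be non-negative).
#' @return Heat gain, W: `Ps * Sw * I`.
#' @examples
#' solar_gain(0.64, 1491, 500)
#' @export
solar_gain <- function(Ps, Sw, I) {
  if (any(I < 0)) stop("solar_gain: irradiance must be >= 0", call. = FALSE)
  if (any(Ps < 0 | Ps > 1)) stop("solar_gain: Ps must lie in [0, 1]",
                                 call. = FALSE)
  if (any(Sw <= 0)) stop("solar_gain: Sw must be > 0", call. = FALSE)
  Ps * Sw * I
}

#' Total metabolic heat production of the flock (CIGR)
#'
#' CIGR-style total heat production from the flock's total live weight and
#' egg output, with a cubic indoor-temperature correction that equals 1 at
#' 20 C.
#'
#' @param M Total flock weight, kg.
#' @param Y Total egg production, kg/day.
#' @param Ti Indoor temperature, C.
#' @return Total heat production, W:
#'   `(6.28 M^0.75 + 25 Y) * (4e-5 (20 - Ti)^3 + 1)`.
#' @examples
#' total_heat_production(16, 0, 20) # 6.28 * 16^0.75 = 50.24 W
#' @export
total_heat_production <- function(M, Y, Ti) {
  if (any(M < 0) || any(Y < 0)) {
    stop("total_heat_production: M and Y must be >= 0", call. = FALSE)
  }
  (6.28 * M^0.75 + 25 * Y) * (4e-5 * (20 - Ti)^3 + 1)
}

#' Sensible heat released by the flock to the room air
#'
#' The sensible fraction of [total_heat_production()],
#' `0.67 (1 - 0.02 (20 - Ti)) - 9.8e-11 Ti^6`, clamped to `[0, 1]` since the
#' polynomial leaves the physical range at extreme temperatures.
#'
#' @inheritParams total_heat_production
#' @return Sensible heat, W.
#' @export
sensible_heat <- function(M, Y, Ti) {
  frac <- sensible_fraction(Ti)
  total_heat_production(M, Y, Ti) * frac
}

#' @rdname sensible_heat
#' @export
sensible_fraction <- function(Ti) {
  pmin(pmax(0.67 * (1 - 0.02 * (20 - Ti)) - 9.8e-11 * Ti^6, 0), 1)
}

#' Air temperature at the cooling-pad outlet
#'
#' Evaporative pad model: the outlet temperature approaches the outdoor
#' wet-bulb temperature `ts` as the pad effectiveness rises, with a decay
#' factor `exp(-12.28305 * v^-0.30078 * H)` in the pad-face velocity `v` and
#' pad thickness `H`. When the pad is closed (autumn/winter operation) the
#' outlet equals the outdoor dry-bulb `t0`. As `v -> 0` the factor tends to 0
#' and the outlet to `ts`; below a 1e-6 m/s floor it is set to `ts` exactly
#' (the associated mass flow is then also ~0, so the flux is unaffected).
#'
#' @param t0 Outdoor dry-bulb temperature, C.
#' @param ts Outdoor wet-bulb temperature, C (`ts <= t0`).
#' @param v Air velocity through the pad, m/s (>= 0).
#' @param H Pad thickness, m.
#' @param rho,cp Air density and specific heat; only used when
#'   `include_rho_cp = TRUE`.
#' @param pad_open Logical; closed pad returns `t0`.
#' @param include_rho_cp Multiply the decay exponent by `rho * cp`
#'   (alternative literal model reading; drives the factor to 0).
#' @return Outlet temperature, C, always in `[ts, t0]`.
#' @examples
#' pad_outlet_temperature(30, 22, v = 1.5, H = 0.15)
#' @export
pad_outlet_temperature <- function(t0, ts, v, H, rho = 1.2, cp = 1006,
                                   pad_open = TRUE, include_rho_cp = FALSE) {
  if (any(ts > t0 + 1e-12)) {
    stop("pad_outlet_temperature: wet-bulb ts must not exceed dry-bulb t0",
         call. = FALSE)
  }
  if (any(v < 0)) stop("pad_outlet_temperature: v must be >= 0", call. = FALSE)
  if (any(H <= 0)) stop("pad_outlet_temperature: H must be > 0", call. = FALSE)
  if (!pad_open) return(t0)
  ex <- ifelse(v < 1e-6, -Inf, -12.28305 * v^(-0.30078) * H)
  if (include_rho_cp) ex <- ex * rho * cp
  decay <- exp(ex)
  out <- ts + (t0 - ts) * decay
  pmin(pmax(out, pmin(ts, t0)), t0)
}

#' Face velocities of the two intake streams
#'
#' The negative-pressure exhaust flow `L_neg` is balanced by two intake
#' streams: a fraction `lambda` through the positive-pressure fans and the
#' remainder through the guide plates. Velocities follow from continuity.
#'
#' @param L_neg Total negative-pressure exhaust flow, m3/s.
#' @param lambda Split coefficient in `[0, 1]` (fraction through the
#'   positive-pressure fans).
#' @param A_pos,A_duct Summed areas of positive-pressure fans and guide-plate
#'   openings, m2.
#' @return Named list `v_pos`, `v_duct` (m/s); satisfies
#'   `A_pos*v_pos + A_duct*v_duct = L_neg`.
#' @export
split_velocities <- function(L_neg, lambda, A_pos, A_duct) {
  if (any(L_neg < 0)) stop("split_velocities: L_neg must be >= 0",
                           call. = FALSE)
  if (any(lambda < 0 | lambda > 1)) {
    stop("split_velocities: lambda must lie in [0, 1]", call. = FALSE)
  }
  if (any(A_pos <= 0) || any(A_duct <= 0)) {
    stop("split_velocities: areas must be > 0", call. = FALSE)
  }
  list(v_pos = lambda * L_neg / A_pos, v_duct = (1 - lambda) * L_neg / A_duct)
}

#' Ventilation heat loss of the combined system
#'
#' Each intake stream is cooled by the pad at its own face velocity; the heat
#' removed from the room is `m cp (Ti - tc)` per stream with mass flow
#' `m = rho * flow`.
#'
#' @param Ti Indoor temperature, C.
#' @param cmd List with `L_neg` (m3/s) and `lambda`.
#' @param cfg A [house_config()].
#' @param exo Exogenous record: list with `t0`, `ts`, `pad_open`.
#' @return Named list `Qv_pos`, `Qv_duct` (W).
#' @export
ventilation_heat_loss <- function(Ti, cmd, cfg, exo) {
  vel <- split_velocities(cmd$L_neg, cmd$lambda, cfg$pos_fan_area,
                          cfg$duct_area)
  tc_pos <- pad_outlet_temperature(exo$t0, exo$ts, vel$v_pos,
                                   cfg$pad_thickness, cfg$air_density,
                                   cfg$air_cp, pad_open = exo$pad_open,
                                   include_rho_cp = cfg$pad_exponent_rho_cp)
  tc_duct <- pad_outlet_temperature(exo$t0, exo$ts, vel$v_duct,
                                    cfg$pad_thickness, cfg$air_density,
                                    cfg$air_cp, pad_open = exo$pad_open,
                                    include_rho_cp = cfg$pad_exponent_rho_cp)
  m_pos <- cfg$air_density * cmd$lambda * cmd$L_neg
  m_duct <- cfg$air_density * (1 - cmd$lambda) * cmd$L_neg
  list(Qv_pos = m_pos * cfg$air_cp * (Ti - tc_pos),
       Qv_duct = m_duct * cfg$air_cp * (Ti - tc_duct))
}

#' Floor (manure-pit) convective heat loss
#'
#' @param Ti Indoor temperature, C.
#' @param tg Floor / manure-pit temperature, C.
#' @param hg Floor heat-transfer coefficient, W/(m2 C).
#' @param Sg Floor area, m2.
#' @return `hg * Sg * (Ti - tg)`, W (negative when the floor heats the room).
#' @export
floor_heat_loss <- function(Ti, tg, hg, Sg) {
  if (any(Sg <= 0)) stop("floor_heat_loss: Sg must be > 0", call. = FALSE)
  hg * Sg * (Ti - tg)
}

#' Envelope conductive heat loss
#'
#' @param tn,tw Inner and outer surface temperatures of the enclosure, C.
#' @param ks Envelope heat-transfer coefficient, W/(m2 C).
#' @param Fs Envelope area, m2.
#' @return `ks * Fs * (tn - tw)`, W.
#' @export
envelope_heat_loss <- function(tn, tw, ks, Fs) {
  if (any(Fs <= 0)) stop("envelope_heat_loss: Fs must be > 0", call. = FALSE)
  ks * Fs * (tn - tw)
}

#' Assemble the full heat budget at a given state
#'
#' @param Ti Indoor temperature, C.
#' @param exo Exogenous record: list with `t0`, `ts`, `irradiance`, `tg`,
#'   `tn`, `tw`, `pad_open`. `tn = NA` defaults to `Ti` (quasi-steady inner
#'   surface); `tw = NA` defaults to `t0`.
#' @param cmd Ventilation command: list with `L_neg` (m3/s) and `lambda`.
#' @param cfg A [house_config()].
#' @return Named list of fluxes `Qs`, `Qc`, `Qv_pos`, `Qv_duct`, `Qg`, `Qw`
#'   and their signed sum `net` (W).
#' @export
heat_budget <- function(Ti, exo, cmd, cfg) {
  tn <- if (is.null(exo$tn) || is.na(exo$tn)) Ti else exo$tn
  tw <- if (is.null(exo$tw) || is.na(exo$tw)) exo$t0 else exo$tw
  Qs <- solar_gain(cfg$radiation_coeff, cfg$solar_area, exo$irradiance)
  # flock heat on the per-animal basis of the CIGR guideline
  Qc <- cfg$n_birds * sensible_heat(cfg$flock_mass / cfg$n_birds,
                                    cfg$egg_yield / cfg$n_birds, Ti)
  Qv <- ventilation_heat_loss(Ti, cmd, cfg, exo)
  Qg <- floor_heat_loss(Ti, exo$tg, cfg$floor_htc, cfg$floor_area)
  Qw <- envelope_heat_loss(tn, tw, cfg$envelope_htc, cfg$envelope_area)
  net <- Qs + Qc - (Qv$Qv_pos + Qv$Qv_duct) - Qg - Qw
  list(Qs = Qs, Qc = Qc, Qv_pos = Qv$Qv_pos, Qv_duct = Qv$Qv_duct,
       Qg = Qg, Qw = Qw, net = net)
}

#' Rate of change of indoor temperature
#'
#' @param net Net heat flux into the room air, W.
#' @param cfg A [house_config()].
#' @return `net / (rho * V * cp)`, C/s.
#' @export
temperature_derivative <- function(net, cfg) {
  net / (cfg$air_density * cfg$volume * cfg$air_cp)
}

#' Advance the indoor temperature by one integrator step
#'
#' Explicit Euler by default (`dt = 60` s, the data cadence of the model);
#' a classical 4th-order Runge-Kutta stepper is available for convergence
#' checks. RK4 re-evaluates the budget at intermediate temperatures while
#' holding the exogenous record and command constant over the step.
#'
#' @param Ti Indoor temperature at the start of the step, C.
#' @param exo,cmd,cfg As in [heat_budget()].
#' @param dt Step length, s.
#' @param method `"euler"` (default) or `"rk4"`.
#' @return List with `Ti` (end-of-step temperature) and `budget` (the heat
#'   budget evaluated at the start of the step).
#' @export
plant_step <- function(Ti, exo, cmd, cfg, dt = 60, method = c("euler", "rk4")) {
  method <- match.arg(method)
  if (dt <= 0) stop("plant_step: dt must be > 0", call. = FALSE)
  budget <- heat_budget(Ti, exo, cmd, cfg)
  f <- function(T_) temperature_derivative(heat_budget(T_, exo, cmd, cfg)$net,
                                           cfg)
  if (method == "euler") {
    Ti_next <- Ti + dt * temperature_derivative(budget$net, cfg)
  } else {
    k1 <- temperature_derivative(budget$net, cfg)
    k2 <- f(Ti + dt / 2 * k1)
    k3 <- f(Ti + dt / 2 * k2)
    k4 <- f(Ti + dt * k3)
    Ti_next <- Ti + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  if (!is.finite(Ti_next)) {
    bad <- names(budget)[!vapply(budget, is.finite, logical(1))]
    stop("plant_step: non-finite temperature after step",
         if (length(bad)) paste0(" (non-finite flux: ",
                                 paste(bad, collapse = ", "), ")"),
         call. = FALSE)
  }
  list(Ti = Ti_next, budget = budget)
}

#' Steady-state indoor temperature for constant inputs
#'
#' Root of the net heat budget in `Ti`, found by bisection. Used as an
#' independent check of the Euler trajectory's equilibrium.
#'
#' @inheritParams heat_budget
#' @param interval Search interval for the root, C.
#' @return Equilibrium temperature, C.
#' @export
equilibrium_temperature <- function(exo, cmd, cfg, interval = c(-60, 90)) {
  f <- function(T_) heat_budget(T_, exo, cmd, cfg)$net
  stats::uniroot(f, interval = interval, tol = 1e-10)$root
}
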