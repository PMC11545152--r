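#' Seasonal control presets
#'
#' Setpoints, base PID gains and actuator limits for the three simulated
#' seasons: summer 27.5 C with gains 23/15/3 and the cooling pad open;
#' autumn 27 C with 17/13/8; winter 25.5 C with 13/12/4, pad closed.
#' Ventilation is bounded in every season by the winter physiological
#' minimum of 1858 m3/min and the summer hardware maximum of 7435 m3/min
#' (0.02 and 0.08 m3/min per kg of flock).
#'
#' @param season `"summer"`, `"autumn"` or `"winter"`, or omit all defaults
#'   by passing the individual fields.
#' @param Tset Target indoor temperature, C.
#' @param KP,KI,KD Base PID gains.
#' @param pad_open Whether the evaporative pad runs.
#' @param L_min,L_max Ventilation bounds, m3/min.
#' @param hysteresis Half-width of the on-off dead band, C.
#' @param lambda_fixed Split coefficient used by the on-off and plain PID
#'   loops (the fuzzy loops derive lambda online).
#' @param act_gain Actuator gain converting controller output units to
#'   m3/min of extra exhaust flow above `L_min`. The default (25) is sized
#'   for a well-damped loop: proportional loop gain near 0.5 per step and an
#'   integral ramp to full actuator authority of about 15 min.
#' @return Object of class `season_preset`.
#' @export
season_preset <- function(season = c("summer", "autumn", "winter"),
                          Tset = NULL, KP = NULL, KI = NULL, KD = NULL,
                          pad_open = NULL, L_min = 1858, L_max = 7435,
                          hysteresis = 0.5, lambda_fixed = 0, act_gain = 25) {
  season <- match.arg(season)
  defaults <- switch(season,
    summer = list(Tset = 27.5, KP = 23, KI = 15, KD = 3, pad_open = TRUE),
    autumn = list(Tset = 27,   KP = 17, KI = 13, KD = 8, pad_open = FALSE),
    winter = list(Tset = 25.5, KP = 13, KI = 12, KD = 4, pad_open = FALSE)
  )
  p <- list(season = season,
            Tset = Tset %||% defaults$Tset,
            KP = KP %||% defaults$KP, KI = KI %||% defaults$KI,
            KD = KD %||% defaults$KD,
            pad_open = pad_open %||% defaults$pad_open,
            L_min = L_min, L_max = L_max, hysteresis = hysteresis,
            lambda_fixed = lambda_fixed, act_gain = act_gain)
  if (p$L_min >= p$L_max) {
    stop("season_preset: need L_min < L_max", call. = FALSE)
  }
  if (p$hysteresis <= 0) {
    stop("season_preset: hysteresis must be > 0", call. = FALSE)
  }
  class(p) <- "season_preset"
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map controller output to a commanded exhaust flow
#'
#' Reverse-acting affine map: with `e = Tset - Ti`, the controller output is
#' negative when cooling is needed, so flow above the baseline is driven by
#' `-u`. The result is saturated to the preset's `[L_min, L_max]` band.
#'
#' @param u Controller output.
#' @param preset A [season_preset()].
#' @return Commanded negative-pressure ventilation, m3/min.
#' @export
actuate <- function(u, preset) {
  L <- preset$L_min + pmax(0, -preset$act_gain * u)
  pmin(pmax(L, preset$L_min), preset$L_max)
}

#' One step of the on-off baseline
#'
#' Two-level thermostat with a symmetric hysteresis band: full flow above
#' `Tset + hysteresis`, minimum flow below `Tset - hysteresis`, previous
#' level held inside the band.
#'
#' @param Ti Measured indoor temperature, C.
#' @param preset A [season_preset()].
#' @param level Previously commanded flow, m3/min.
#' @return Commanded flow, m3/min.
#' @export
onoff_step <- function(Ti, preset, level = preset$L_min) {
  if (Ti > preset$Tset + preset$hysteresis) {
    preset$L_max
  } else if (Ti < preset$Tset - preset$hysteresis) {
    preset$L_min
  } else {
    level
  }
}

#' Closed-loop minutely simulation of the house
#'
#' Couples a controller to the heat-balance plant on the driver's 60 s
#' cadence: at each step the controller reads the current indoor
#' temperature, commands an exhaust flow (m3/min, saturated to the preset
#' band) and a split coefficient, and the plant advances one Euler step.
#' When the driver lacks `tn`/`tw` columns, the envelope inner surface
#' defaults to the current indoor temperature and the outer surface to the
#' outdoor dry-bulb.
#'
#' @param driver Minutely exogenous data frame with columns `t0`, `ts`,
#'   `irradiance`, `tg`, optionally `tn`, `tw`, `pad_open` (see
#'   [synth_day()] / [read_driver()]).
#' @param preset A [season_preset()].
#' @param controller `"onoff"`, `"pid"`, `"fpid"` or `"vfpid"`.
#' @param cfg A [house_config()].
#' @param Ti0 Initial indoor temperature, C; defaults to the setpoint.
#' @param dt Step length, s.
#' @param controller_options Named list overriding [house_controller()]
#'   arguments (e.g. `list(theta = 1e-3)`), or the degeneracy switches
#'   `zero_fuzzy` (force all fuzzy corrections off while keeping the fpid
#'   label) and `freeze_scales` (hold the variable-universe factors at 1).
#' @return A `control_trace` data frame, one row per minute, with the state,
#'   command, effective gains and every heat-budget term.
#' @export
simulate_house <- function(driver, preset, controller = c("vfpid", "fpid",
                                                          "pid", "onoff"),
                           cfg = house_config(), Ti0 = NULL, dt = 60,
                           controller_options = list()) {
  controller <- match.arg(controller)
  n <- nrow(driver)
  cols <- c("t0", "ts", "irradiance", "tg")
  missing_cols <- setdiff(cols, names(driver))
  if (length(missing_cols)) {
    stop("simulate_house: driver lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  pad <- if ("pad_open" %in% names(driver)) driver$pad_open else
    rep(preset$pad_open, n)
  tn_col <- if ("tn" %in% names(driver)) driver$tn else rep(NA_real_, n)
  tw_col <- if ("tw" %in% names(driver)) driver$tw else rep(NA_real_, n)

  zero_fuzzy <- isTRUE(controller_options$zero_fuzzy)
  freeze_scales <- isTRUE(controller_options$freeze_scales)
  ctrl_args <- controller_options[setdiff(names(controller_options),
                                          c("zero_fuzzy", "freeze_scales"))]
  use_fuzzy <- controller %in% c("fpid", "vfpid") && !zero_fuzzy
  variable_universe <- controller == "vfpid" && !freeze_scales
  ctrl <- NULL
  if (controller != "onoff") {
    ctrl <- do.call(house_controller, c(
      list(KP = preset$KP, KI = preset$KI, KD = preset$KD,
           use_fuzzy = use_fuzzy, variable_universe = variable_universe,
           lambda_fixed = preset$lambda_fixed),
      ctrl_args))
  }
  u_span <- (preset$L_max - preset$L_min) / preset$act_gain

  Ti <- Ti0 %||% preset$Tset
  state <- controller_state()
  level <- preset$L_min

  out <- matrix(NA_real_, n, 17)
  colnames(out) <- c("Ti", "e", "ec", "u", "L_neg", "lambda",
                     "Kp_eff", "Ki_eff", "Kd_eff",
                     "Qs", "Qc", "Qv_pos", "Qv_duct", "Qg", "Qw", "net",
                     "beta")
  if (n == 0L) {
    tr <- as.data.frame(out)
    tr <- cbind(minute = numeric(0), tr, Tset = numeric(0))
    return(structure(tr, class = c("control_trace", "data.frame"),
                     controller = controller, preset = preset))
  }

  for (k in seq_len(n)) {
    if (controller == "onoff") {
      level <- onoff_step(Ti, preset, level)
      step_u <- NA_real_
      lambda <- preset$lambda_fixed
      gains <- c(NA_real_, NA_real_, NA_real_)
      ecv <- NA_real_; ev <- preset$Tset - Ti; betav <- NA_real_
      L_cmd <- level
    } else {
      cs <- controller_step(ctrl, preset$Tset, Ti, state, u_span)
      state <- cs$state
      L_cmd <- actuate(cs$u, preset)
      step_u <- cs$u
      lambda <- cs$lambda
      gains <- c(cs$Kp, cs$Ki, cs$Kd)
      ev <- cs$e; ecv <- cs$ec; betav <- cs$beta
    }

    exo <- list(t0 = driver$t0[k], ts = driver$ts[k],
                irradiance = driver$irradiance[k], tg = driver$tg[k],
                tn = tn_col[k], tw = tw_col[k], pad_open = pad[k])
    cmd <- list(L_neg = L_cmd / 60, lambda = lambda) # m3/min -> m3/s
    st <- plant_step(Ti, exo, cmd, cfg, dt = dt)
    b <- st$budget
    out[k, ] <- c(Ti, ev, ecv, step_u, L_cmd, lambda, gains,
                  b$Qs, b$Qc, b$Qv_pos, b$Qv_duct, b$Qg, b$Qw, b$net, betav)
    Ti <- st$Ti
  }

  tr <- as.data.frame(out)
  tr <- cbind(minute = seq_len(n) - 1, tr, Tset = preset$Tset)
  structure(tr, class = c("control_trace", "data.frame"),
            controller = controller, preset = preset)
}

#' Run all controllers on one driver and tabulate their metrics
#'
#' @inheritParams simulate_house
#' @param controllers Character vector of controller kinds to run.
#' @return Data frame with one row per controller: MAE, RMSE, max error,
#'   overshoot, response time, mean oscillation index and mean lambda.
#' @export
compare_controllers <- function(driver, preset, cfg = house_config(),
                                controllers = c("onoff", "pid", "fpid",
                                                "vfpid")) {
  rows <- lapply(controllers, function(kind) {
    tr <- simulate_house(driver, preset, kind, cfg)
    m <- control_metrics(tr)
    data.frame(controller = kind, mae = m$mae, rmse = m$rmse,
               max_error = m$max_error, overshoot_pct = m$overshoot_pct,
               response_time = m$response_time, aoi = m$aoi,
               mean_lambda = mean(tr$lambda))
  })
  do.call(rbind, rows)
}
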