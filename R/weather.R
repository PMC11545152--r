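#' Seasonal diurnal profile
#'
#' Summary statistics of one synthetic day. The seasonal defaults reproduce
#' the measured extremes of the monitored farm days: summer 19.3-35.0 C,
#' autumn 13.2-27.4 C, winter -10.5-1.4 C, with seasonal mean relative
#' humidities near 45 %.
#'
#' @param season `"summer"`, `"autumn"` or `"winter"`.
#' @param t_min,t_max Daily outdoor temperature extremes, C.
#' @param rh_mean Daily mean relative humidity, %.
#' @param I_peak Peak solar irradiance, W/m2.
#' @param sunrise,sunset Hours of day bounding the irradiance half-sine.
#' @param tg_offset Offset of the floor / manure-pit temperature above the
#'   daily mean outdoor temperature, C (the pit stays warm in winter).
#' @param pad_open Whether the cooling pad runs on this day.
#' @return Object of class `day_profile`.
#' @export
day_profile <- function(season = c("summer", "autumn", "winter"),
                        t_min = NULL, t_max = NULL, rh_mean = NULL,
                        I_peak = NULL, sunrise = NULL, sunset = NULL,
                        tg_offset = NULL, pad_open = NULL) {
  season <- match.arg(season)
  d <- switch(season,
    summer = list(t_min = 19.3, t_max = 35.0, rh_mean = 45, I_peak = 850,
                  sunrise = 5, sunset = 19.5, tg_offset = 1,
                  pad_open = TRUE),
    autumn = list(t_min = 13.2, t_max = 27.4, rh_mean = 45, I_peak = 600,
                  sunrise = 6.5, sunset = 18, tg_offset = 4,
                  pad_open = FALSE),
    winter = list(t_min = -10.5, t_max = 1.4, rh_mean = 47, I_peak = 420,
                  sunrise = 7.5, sunset = 17.5, tg_offset = 20,
                  pad_open = FALSE)
  )
  p <- list(season = season,
            t_min = t_min %||% d$t_min, t_max = t_max %||% d$t_max,
            rh_mean = rh_mean %||% d$rh_mean, I_peak = I_peak %||% d$I_peak,
            sunrise = sunrise %||% d$sunrise, sunset = sunset %||% d$sunset,
            tg_offset = tg_offset %||% d$tg_offset,
            pad_open = pad_open %||% d$pad_open)
  if (p$t_min >= p$t_max) stop("day_profile: need t_min < t_max",
                               call. = FALSE)
  if (p$rh_mean <= 0 || p$rh_mean >= 100) {
    stop("day_profile: rh_mean must lie in (0, 100)", call. = FALSE)
  }
  if (p$I_peak < 0) stop("day_profile: I_peak must be >= 0", call. = FALSE)
  class(p) <- "day_profile"
  p
}

# piecewise-cosine diurnal curve: minimum exactly at 05:00, maximum at 15:00
diurnal_temperature <- function(hour, t_min, t_max) {
  mid <- (t_min + t_max) / 2
  amp <- (t_max - t_min) / 2
  h <- hour %% 24
  rising <- h >= 5 & h <= 15
  out <- numeric(length(h))
  out[rising] <- mid - amp * cos(pi * (h[rising] - 5) / 10)
  hf <- h[!rising]
  hf <- ifelse(hf < 5, hf + 24, hf) # evening fall continues past midnight
  out[!rising] <- mid + amp * cos(pi * (hf - 15) / 14)
  out
}

#' Synthesize one minutely day of exogenous drivers
#'
#' Outdoor temperature follows a piecewise-cosine diurnal curve hitting
#' `t_min` at 05:00 and `t_max` at 15:00 exactly (when noise is off);
#' irradiance is a half-sine between sunrise and sunset; relative humidity is
#' anti-correlated with temperature about `rh_mean`; the wet-bulb temperature
#' is derived psychrometrically; the floor temperature is the daily mean
#' outdoor temperature plus `tg_offset`. Seeded AR(1) noise (lag-1
#' correlation 0.98) perturbs temperature and humidity.
#'
#' @param profile A [day_profile()].
#' @param seed Integer seed for the noise (ignored when `noise_sd = 0`).
#' @param noise_sd Marginal standard deviation of the AR(1) temperature
#'   noise, C; humidity noise is scaled 5x. Use 0 for the noise-free
#'   profile.
#' @return Data frame with 1440 rows: `minute`, `t0`, `ts`, `rh`,
#'   `irradiance`, `tg`, `tn`, `tw`, `pad_open`.
#' @export
synth_day <- function(profile, seed = NULL, noise_sd = 0.3) {
  minute <- 0:1439
  hour <- minute / 60
  t0 <- diurnal_temperature(hour, profile$t_min, profile$t_max)
  rh <- profile$rh_mean - 1.5 * (t0 - mean(t0))

  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                         .GlobalEnv)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    t0 <- t0 + ar1_noise(1440, noise_sd)
    rh <- rh + ar1_noise(1440, 5 * noise_sd)
  }
  rh <- pmin(pmax(rh, 5), 100)

  daylight <- hour > profile$sunrise & hour < profile$sunset
  irr <- numeric(1440)
  irr[daylight] <- profile$I_peak *
    sin(pi * (hour[daylight] - profile$sunrise) /
          (profile$sunset - profile$sunrise))

  ts <- wet_bulb(t0, rh)
  tg <- mean(t0) + profile$tg_offset

  data.frame(minute = minute, t0 = t0, ts = ts, rh = rh, irradiance = irr,
             tg = tg, tn = NA_real_, tw = NA_real_,
             pad_open = profile$pad_open)
}

ar1_noise <- function(n, sd, phi = 0.98) {
  eps <- stats::rnorm(n, sd = sd * sqrt(1 - phi^2))
  as.numeric(stats::filter(eps, phi, method = "recursive"))
}

#' Synthesize a multi-day minutely driver
#'
#' Concatenates [synth_day()] outputs for the seasonal profile; each day uses
#' an independent seed derived from `seed`.
#'
#' @param season Season name passed to [day_profile()], or a `day_profile`.
#' @param days Number of days.
#' @param seed Base integer seed.
#' @param noise_sd See [synth_day()].
#' @return Data frame with `1440 * days` rows and a continuous `minute`
#'   column.
#' @export
synth_driver <- function(season, days = 2, seed = 1, noise_sd = 0.3) {
  profile <- if (inherits(season, "day_profile")) season else
    day_profile(season)
  parts <- lapply(seq_len(days), function(d) {
    day <- synth_day(profile, seed = seed + 1000L * (d - 1L),
                     noise_sd = noise_sd)
    day$minute <- day$minute + 1440 * (d - 1)
    day
  })
  do.call(rbind, parts)
}

#' Wet-bulb temperature from dry-bulb and relative humidity
#'
#' Single-expression psychrometric approximation (Stull-type fit), clamped so
#' the wet-bulb never exceeds the dry-bulb; at saturation it equals the
#' dry-bulb.
#'
#' @param t0 Dry-bulb temperature, C.
#' @param rh Relative humidity, % in `(0, 100]`.
#' @return Wet-bulb temperature, C.
#' @export
wet_bulb <- function(t0, rh) {
  if (any(rh <= 0 | rh > 100)) {
    stop("wet_bulb: rh must lie in (0, 100]", call. = FALSE)
  }
  tw <- t0 * atan(0.151977 * sqrt(rh + 8.313659)) +
    atan(t0 + rh) - atan(rh - 1.676331) +
    0.00391838 * rh^1.5 * atan(0.023101 * rh) - 4.686035
  pmin(tw, t0)
}

#' Linear interpolation of a coarser series to 1-min cadence
#'
#' @param time Strictly increasing timestamps, seconds (numeric) or POSIXct.
#' @param value Numeric values at `time`.
#' @return Data frame `time`, `value` at 60 s cadence spanning the input
#'   range; input points are reproduced exactly.
#' @export
interpolate_minutely <- function(time, value) {
  tnum <- as.numeric(time)
  if (anyDuplicated(tnum)) {
    stop("interpolate_minutely: duplicate timestamps", call. = FALSE)
  }
  if (is.unsorted(tnum, strictly = TRUE)) {
    stop("interpolate_minutely: timestamps must be strictly increasing",
         call. = FALSE)
  }
  grid <- seq(tnum[1], tnum[length(tnum)], by = 60)
  data.frame(time = grid,
             value = stats::approx(tnum, value, xout = grid)$y)
}

#' Read a minutely driver CSV
#'
#' Expects columns `timestamp` (ISO-8601 or numeric seconds), `t0`, and
#' either `ts` or `rh` (wet-bulb derived when only humidity is given), plus
#' optional `irradiance`, `tg`, `tn`, `tw`, `pad_open`. Gaps in the 1-min
#' cadence are filled by linear interpolation with a warning.
#'
#' @param path CSV path.
#' @return Driver data frame suitable for [simulate_house()].
#' @export
read_driver <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"timestamp" %in% names(raw)) {
    stop("read_driver: need a `timestamp` column", call. = FALSE)
  }
  tnum <- suppressWarnings(as.numeric(raw$timestamp))
  if (anyNA(tnum)) {
    tnum <- as.numeric(as.POSIXct(raw$timestamp, tz = "UTC"))
  }
  if (anyNA(tnum)) stop("read_driver: unparseable timestamps", call. = FALSE)
  o <- order(tnum)
  raw <- raw[o, , drop = FALSE]; tnum <- tnum[o]
  if (!"t0" %in% names(raw)) stop("read_driver: need `t0`", call. = FALSE)
  if (!"ts" %in% names(raw)) {
    if (!"rh" %in% names(raw)) {
      stop("read_driver: need `ts` or `rh`", call. = FALSE)
    }
    raw$ts <- wet_bulb(raw$t0, raw$rh)
  }
  grid <- seq(tnum[1], tnum[length(tnum)], by = 60)
  if (length(grid) != length(tnum) || any(abs(grid - tnum) > 1e-6)) {
    warning("read_driver: gaps in the 1-min cadence filled by linear ",
            "interpolation")
    num_cols <- setdiff(names(raw), c("timestamp", "pad_open"))
    filled <- data.frame(timestamp = grid)
    for (nm in num_cols) {
      filled[[nm]] <- stats::approx(tnum, raw[[nm]], xout = grid)$y
    }
    if ("pad_open" %in% names(raw)) {
      filled$pad_open <- as.logical(stats::approx(tnum, as.numeric(raw$pad_open),
                                                  xout = grid,
                                                  method = "constant")$y)
    }
    raw <- filled
  }
  for (nm in c("irradiance", "tg", "tn", "tw")) {
    if (!nm %in% names(raw)) raw[[nm]] <- if (nm == "irradiance") 0 else
      NA_real_
  }
  if (all(is.na(raw$tg))) raw$tg <- mean(raw$t0)
  raw$minute <- (as.numeric(raw$timestamp) - as.numeric(raw$timestamp)[1]) / 60
  raw
}
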