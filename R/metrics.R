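#' Elementwise error statistics between two series
#'
#' @param sim Simulated (or controlled) series.
#' @param ref Reference series of the same length.
#' @return List with `mae` (mean absolute error), `rmse` (root-mean-square
#'   error), `r2` (coefficient of determination about the reference mean;
#'   `NA` when the reference is constant) and `max_error`.
#' @examples
#' error_stats(c(1, 2, 3), c(1, 2, 4))
#' @export
error_stats <- function(sim, ref) {
  if (length(sim) != length(ref) || length(sim) < 2) {
    stop("error_stats: series must have equal length >= 2", call. = FALSE)
  }
  d <- sim - ref
  ss_tot <- sum((ref - mean(ref))^2)
  list(mae = mean(abs(d)),
       rmse = sqrt(mean(d^2)),
       r2 = if (ss_tot == 0) NA_real_ else 1 - sum(d^2) / ss_tot,
       max_error = max(abs(d)))
}

#' Mean oscillation index of a temperature series
#'
#' Average absolute step-to-step change, normalized by the series mean and
#' expressed in percent:
#' `100 / (K - 1) * sum(|T_t - T_{t-1}|) / mean(T)`. Lower values indicate
#' steadier control; the index is invariant to uniform positive scaling.
#'
#' @param T_series Temperature series (length >= 2, nonzero mean).
#' @return Mean oscillation index, %.
#' @examples
#' oscillation_index(c(20, 21, 20)) # 300/61 ~ 4.918
#' @export
oscillation_index <- function(T_series) {
  K <- length(T_series)
  if (K < 2) stop("oscillation_index: need at least 2 points", call. = FALSE)
  T_av <- mean(T_series)
  if (T_av == 0) stop("oscillation_index: series mean is zero", call. = FALSE)
  sum(abs(diff(T_series))) / (K - 1) / T_av * 100
}

#' Closed-loop control metrics of a trace
#'
#' Overshoot is `(max(Ti) - Tset) / Tset * 100`, clipped at 0. Response time
#' is the number of minutes between the largest absolute error in the trace
#' and the first step from which the temperature stays within
#' `settle_band` of the setpoint for the rest of the trace; `NA` when the
#' trace never settles. Tracking MAE/RMSE/max error are taken against the
#' constant setpoint, and the mean oscillation index against the temperature
#' series itself.
#'
#' @param trace A `control_trace` from [simulate_house()], or any data frame
#'   with `Ti` and `Tset` columns.
#' @param settle_band Settling half-width, C.
#' @return List: `mae`, `rmse`, `max_error`, `overshoot_pct`,
#'   `response_time` (min), `aoi` (%).
#' @export
control_metrics <- function(trace, settle_band = 0.1) {
  if (!nrow(trace)) stop("control_metrics: empty trace", call. = FALSE)
  Ti <- trace$Ti
  Tset <- trace$Tset[1]
  err <- Ti - Tset
  overshoot <- max(0, (max(Ti) - Tset) / Tset * 100)

  k_dist <- which.max(abs(err))
  inside <- abs(err) <= settle_band
  # first index >= k_dist from which the trace stays inside the band
  stays <- rev(cumprod(rev(inside))) == 1
  k_settle <- which(stays & seq_along(stays) >= k_dist)[1]
  response_time <- if (is.na(k_settle)) NA_real_ else
    as.numeric(k_settle - k_dist)

  list(mae = mean(abs(err)),
       rmse = sqrt(mean(err^2)),
       max_error = max(abs(err)),
       overshoot_pct = overshoot,
       response_time = response_time,
       aoi = oscillation_index(Ti))
}

#' Relative improvement of one metric over another
#'
#' `(a - b) / a * 100`: the percent by which `b` improves on (is smaller
#' than) the baseline `a`.
#'
#' @param a Baseline metric (> 0).
#' @param b Comparison metric.
#' @return Improvement, %.
#' @examples
#' improvement_pct(31.40, 28.95) # 7.80
#' @export
improvement_pct <- function(a, b) {
  if (any(a <= 0)) stop("improvement_pct: baseline must be > 0",
                        call. = FALSE)
  (a - b) / a * 100
}
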