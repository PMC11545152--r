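#' Construct a temperature controller
#'
#' One constructor covers the whole controller family used for the house:
#' a fixed-gain discrete PID (`use_fuzzy = FALSE`), the fuzzy PID that
#' schedules the gain corrections `dKp`, `dKi`, `dKd` and the ventilation
#' split `lambda` from the rule base (`use_fuzzy = TRUE`), and the
#' variable-universe fuzzy PID that additionally contracts the fuzzy
#' universes online (`variable_universe = TRUE`). The discrete law is
#'
#' `u_k = (KP + dKp) e_k + (KI + dKi) sum(e) + (KD + dKd) (e_k - e_{k-1})`
#'
#' with `e = Tset - Ti`, per-control-step integral and difference, and
#' anti-windup clamping of the integral so the integral term can never exceed
#' the actuator span.
#'
#' @param KP,KI,KD Base PID gains (> 0), in controller units per C.
#' @param E1,E2,U3 Initial half-widths of the `e` (C), `ec` (C/step) and
#'   output universes.
#' @param theta,v_eps Variable-universe offsets ("sufficiently small positive
#'   numbers"): `theta` floors the scaling factors, `v_eps` guards the
#'   exponent denominators.
#' @param use_fuzzy Enable the fuzzy correction channels; when `FALSE` the
#'   controller is a plain PID and `lambda` is held at `lambda_fixed`.
#' @param variable_universe Enable online universe contraction; ignored
#'   unless `use_fuzzy` is `TRUE`.
#' @param lambda_fixed Split coefficient used when the fuzzy lambda channel
#'   is disabled.
#' @param output_scale Length-3 multiplier applied to the shared output
#'   universe for the `dKp`, `dKi`, `dKd` channels.
#' @param rules A [fuzzy_rules()] table.
#' @return Object of class `house_controller`.
#' @seealso [controller_step()], [simulate_house()]
#' @export
house_controller <- function(KP, KI, KD, E1 = 3, E2 = 1.5, U3 = 5,
                             theta = 1e-4, v_eps = 1e-6,
                             use_fuzzy = TRUE, variable_universe = TRUE,
                             lambda_fixed = 0, output_scale = c(1, 1, 1),
                             rules = fuzzy_rules()) {
  if (any(c(KP, KI, KD) <= 0)) {
    stop("house_controller: base gains must be > 0", call. = FALSE)
  }
  if (any(c(E1, E2, U3) <= 0) || theta <= 0 || v_eps <= 0) {
    stop("house_controller: universe half-widths, theta and v_eps must be > 0",
         call. = FALSE)
  }
  if (lambda_fixed < 0 || lambda_fixed > 1) {
    stop("house_controller: lambda_fixed must lie in [0, 1]", call. = FALSE)
  }
  structure(list(KP = KP, KI = KI, KD = KD, E1 = E1, E2 = E2, U3 = U3,
                 theta = theta, v_eps = v_eps,
                 use_fuzzy = isTRUE(use_fuzzy),
                 variable_universe = isTRUE(variable_universe),
                 lambda_fixed = lambda_fixed,
                 output_scale = rep_len(output_scale, 3),
                 rules = rules,
                 lambda_universe = fuzzy_universe(0, 1)),
            class = "house_controller")
}

#' Initial controller state
#'
#' @return List holding the integral accumulator, the previous error and the
#'   initialization flag (the first step uses `ec = 0`).
#' @export
controller_state <- function() {
  list(integral = 0, e_prev = 0, started = FALSE)
}

#' One discrete control step
#'
#' Computes the error and its per-step change, runs the fuzzy machinery when
#' enabled (optionally on contracted universes), and evaluates the discrete
#' PID law with anti-windup.
#'
#' @param ctrl A [house_controller()].
#' @param Tset Setpoint, C.
#' @param Ti Measured indoor temperature, C.
#' @param state Controller state from [controller_state()] or a previous
#'   step.
#' @param u_span Actuator span expressed in controller output units; bounds
#'   the integral term (anti-windup). `Inf` disables the clamp.
#' @return List with `u` (controller output), `lambda`, effective gains
#'   `Kp`, `Ki`, `Kd`, the inputs `e` and `ec`, the scaling factors
#'   `alpha_e`, `alpha_ec`, `beta`, and the updated `state`.
#' @export
controller_step <- function(ctrl, Tset, Ti, state, u_span = Inf) {
  e <- Tset - Ti
  ec <- if (state$started) e - state$e_prev else 0

  alpha_e <- 1; alpha_ec <- 1; beta <- 1
  if (ctrl$use_fuzzy && ctrl$variable_universe) {
    P <- scaling_exponent(e, ec, ctrl$E1, ctrl$E2, ctrl$v_eps)
    alpha_e <- input_scaling(e, ctrl$E1, P, ctrl$theta)
    alpha_ec <- input_scaling(ec, ctrl$E2, P, ctrl$theta)
    beta <- output_scaling(alpha_e, alpha_ec, ctrl$theta)
  }

  if (ctrl$use_fuzzy) {
    uni <- contract_universes(ctrl$E1, ctrl$E2, ctrl$U3,
                              alpha_e, alpha_ec, beta)
    st <- fuzzy_infer(fuzzify(e, uni$e), fuzzify(ec, uni$ec), ctrl$rules)
    dKp <- defuzzify(st$dKp, uni$u) * ctrl$output_scale[1]
    dKi <- defuzzify(st$dKi, uni$u) * ctrl$output_scale[2]
    dKd <- defuzzify(st$dKd, uni$u) * ctrl$output_scale[3]
    # lambda is read on the base universes: its [0,1] channel has no
    # contraction law, and contracted inputs would turn it into a
    # bang-bang switch near the setpoint
    base <- contract_universes(ctrl$E1, ctrl$E2, ctrl$U3, 1, 1, 1)
    st_l <- fuzzy_infer(fuzzify(e, base$e), fuzzify(ec, base$ec), ctrl$rules)
    lambda <- lambda_from_output(defuzzify(st_l$lambda, ctrl$lambda_universe),
                                 ctrl$lambda_universe)
  } else {
    dKp <- 0; dKi <- 0; dKd <- 0
    lambda <- ctrl$lambda_fixed
  }

  Kp <- max(ctrl$KP + dKp, 0)
  Ki <- max(ctrl$KI + dKi, 0)
  Kd <- max(ctrl$KD + dKd, 0)

  integral <- state$integral + e
  if (is.finite(u_span) && Ki > 0) {
    i_max <- u_span / Ki
    integral <- min(max(integral, -i_max), i_max)
  }

  u <- Kp * e + Ki * integral + Kd * ec

  list(u = u, lambda = lambda, Kp = Kp, Ki = Ki, Kd = Kd, e = e, ec = ec,
       alpha_e = alpha_e, alpha_ec = alpha_ec, beta = beta,
       state = list(integral = integral, e_prev = e, started = TRUE))
}
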