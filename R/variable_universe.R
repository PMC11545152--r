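#' @title Variable-universe scaling factors
#' @description Online contraction/expansion of the fuzzy universes. Input
#'   universes are rescaled by proportional-exponential factors
#'   `alpha = (|x|/E)^P + theta`, the output universe by
#'   `beta = (alpha_e + alpha_ec)/2 + theta`, with a shared adaptive exponent
#'   `P` that grows as the error shrinks (capped at 1), so the rule grid is
#'   refined precisely where the loop is close to the setpoint.
#' @name variable_universe
NULL

#' Adaptive scaling exponent
#'
#' `P = E1 / (|e| (E1 + E2) + v) + E2 / (|ec| (E1 + E2) + v)`, capped at 1.
#' As `e, ec -> 0` the expression exceeds 1 and the cap applies; for large
#' errors `P` falls towards 0 and the universes stay close to their floors
#' only when contracted by small `|x|/E` ratios.
#'
#' @param e Temperature error, C.
#' @param ec Error change per control step, C/step.
#' @param E1,E2 Initial half-widths of the `e` and `ec` universes.
#' @param v_eps Small positive denominator guard.
#' @return Exponent `P` in `(0, 1]`.
#' @export
scaling_exponent <- function(e, ec, E1 = 3, E2 = 1.5, v_eps = 1e-6) {
  P <- E1 / (abs(e) * (E1 + E2) + v_eps) +
    E2 / (abs(ec) * (E1 + E2) + v_eps)
  pmin(P, 1)
}

#' Input-universe scaling factor
#'
#' `alpha = (min(|x|, E)/E)^P + theta`; the ratio is clipped at 1 so
#' `alpha <= 1 + theta` always.
#'
#' @param x Current crisp input.
#' @param E Initial half-width of the input's universe.
#' @param P Scaling exponent from [scaling_exponent()].
#' @param theta Small positive offset keeping the universe from collapsing.
#' @return Scaling factor in `(theta, 1 + theta]`.
#' @export
input_scaling <- function(x, E, P, theta = 1e-4) {
  r <- pmin(abs(x) / E, 1)
  r^P + theta
}

#' Output-universe scaling factor
#'
#' @param alpha_e,alpha_ec Input scaling factors.
#' @param theta Small positive offset.
#' @return `beta = (alpha_e + alpha_ec)/2 + theta`.
#' @export
output_scaling <- function(alpha_e, alpha_ec, theta = 1e-4) {
  (alpha_e + alpha_ec) / 2 + theta
}

#' Rescale the three controller universes
#'
#' @param E1,E2,U3 Initial half-widths of the `e`, `ec` and output universes.
#' @param alpha_e,alpha_ec,beta Scaling factors.
#' @return List of three [fuzzy_universe()] objects: `e`, `ec`, `u`.
#' @export
contract_universes <- function(E1, E2, U3, alpha_e, alpha_ec, beta) {
  fu <- function(half) fuzzy_universe(-half, half)
  list(e = fu(alpha_e * E1), ec = fu(alpha_ec * E2), u = fu(beta * U3))
}
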