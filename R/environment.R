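#' Oscillating-environment specification
#'
#' Combines the averaged rates with zero-mean periodic oscillations of the two
#' reproduction rates and the gene-transfer balance rate, on the fast time
#' `tau = omega * t`. The instantaneous rates are
#' `r_i(tau) = r_i + r~_i(tau)` and `gamma(tau) = gamma + gamma~(tau)`.
#'
#' @param base A [fixed_rates()] object holding the period averages.
#' @param osc_rA,osc_rB,osc_gamma Signal objects ([osc_signal()] or
#'   [osc_tabulated()]); defaults are the zero signal (fixed environment).
#' @param omega Oscillation frequency; must exceed 1 (the averaging construction
#'   assumes the environment is fast relative to the population dynamics).
#' @return Object of class `environment_spec`.
#' @examples
#' base <- fixed_rates(1.8, 1, 0.1, 0.1, 0.1, 0.1)
#' env <- environment_spec(base,
#'   osc_rA = osc_signal(k = 1, cos = -1.6),
#'   osc_rB = osc_signal(k = 1, cos = 1.6),
#'   osc_gamma = osc_signal(k = 1, sin = 0.5),
#'   omega = 5)
#' effective_payoffs(env)
#' @export
environment_spec <- function(base, osc_rA = osc_signal(), osc_rB = osc_signal(),
                             osc_gamma = osc_signal(), omega = 5) {
  stopifnot(inherits(base, "fixed_rates"))
  for (s in list(osc_rA, osc_rB, osc_gamma))
    if (!inherits(s, c("osc_signal", "osc_tabulated")))
      stop("oscillation components must be signal objects", call. = FALSE)
  if (!is.finite(omega) || omega <= 1)
    stop("omega must be > 1 (fast environmental variation)", call. = FALSE)
  structure(list(base = base, osc_rA = osc_rA, osc_rB = osc_rB,
                 osc_gamma = osc_gamma, omega = omega),
            class = "environment_spec")
}

#' @export
print.environment_spec <- function(x, ...) {
  cat("<environment spec>  omega =", x$omega, "\n")
  print(x$base)
  invisible(x)
}

#' Instantaneous rates at given times
#'
#' @param env An [environment_spec()].
#' @param t Numeric vector of (slow) times; the oscillations are evaluated at
#'   `tau = omega * t`.
#' @return List of numeric vectors `r_A`, `r_B`, `gamma` at each time.
#' @export
rates_at <- function(env, t) {
  tau <- env$omega * t
  list(r_A = env$base$r_A + signal_eval(env$osc_rA, tau),
       r_B = env$base$r_B + signal_eval(env$osc_rB, tau),
       gamma = env$base$gamma + signal_eval(env$osc_gamma, tau))
}

#' Emergent game payoffs from environmental oscillation
#'
#' Coarse-graining the fast-oscillating system yields an additional evolutionary
#' game whose payoffs are the period-averaged overlap of each population's
#' competitor's reproduction-rate primitive with the gene-transfer oscillation,
#' scaled by `1/omega`:
#' \deqn{\xi = \frac{1}{\omega} \int_0^{2\pi} \frac{d\tau}{2\pi}\, \hat r_B \tilde\gamma,
#'       \qquad
#'       \kappa = \frac{1}{\omega} \int_0^{2\pi} \frac{d\tau}{2\pi}\, \hat r_A \tilde\gamma,}
#' where hats denote zero-mean primitives. Both vanish when only reproduction or
#' only gene transfer oscillates, when all signals share one common shape, and
#' as `omega -> Inf` (rate `1/omega`).
#'
#' @param env An [environment_spec()].
#' @return Object of class `effective_payoffs`: list with `xi`, `kappa`,
#'   `omega`.
#' @export
effective_payoffs <- function(env) {
  stopifnot(inherits(env, "environment_spec"))
  xi <- signal_product_mean(signal_primitive(env$osc_rB), env$osc_gamma) / env$omega
  kappa <- signal_product_mean(signal_primitive(env$osc_rA), env$osc_gamma) / env$omega
  structure(list(xi = xi, kappa = kappa, omega = env$omega),
            class = "effective_payoffs")
}

#' Build an effective-payoff object directly from (xi, kappa)
#'
#' Convenience for phase-plane scans where the payoffs, not the underlying
#' oscillations, are the coordinates.
#'
#' @param xi,kappa Emergent payoffs.
#' @param omega Frequency annotation (optional).
#' @return Object of class `effective_payoffs`.
#' @export
payoffs_xk <- function(xi, kappa, omega = NA_real_) {
  stopifnot(is.finite(xi), is.finite(kappa))
  structure(list(xi = xi, kappa = kappa, omega = omega),
            class = "effective_payoffs")
}

#' @export
print.effective_payoffs <- function(x, ...) {
  cat(sprintf("<effective payoffs>  xi = %g, kappa = %g\n", x$xi, x$kappa))
  invisible(x)
}

#' Closed-form payoff for single-harmonic oscillations
#'
#' Analytic oracle: for `r~ = c_r cos(tau)` and `gamma~ = c_g sin(tau)` the
#' primitive is `c_r sin(tau)` and the period average of `sin^2` is 1/2, so the
#' payoff is `c_r * c_g / (2 * omega)`.
#'
#' @param c_r Cosine amplitude of the reproduction-rate oscillation.
#' @param c_g Sine amplitude of the gene-transfer oscillation.
#' @param omega Frequency (> 1).
#' @return Scalar payoff.
#' @export
closed_form_payoff <- function(c_r, c_g, omega) {
  stopifnot(is.finite(c_r), is.finite(c_g), is.finite(omega), omega > 0)
  c_r * c_g / (2 * omega)
}

#' Fitness surpluses induced by the emergent game
#'
#' `phi_A = N (1 - p_A) xi` and `phi_B = -N kappa p_A`: the extra per-capita
#' fitness each population gains (or loses) from the oscillations, at the given
#' composition and total abundance.
#'
#' @param eff An `effective_payoffs` object.
#' @param p_A Fraction of A in \[0, 1\].
#' @param N Total abundance (>= 0).
#' @return List with `phi_A`, `phi_B`.
#' @export
fitness_surplus <- function(eff, p_A, N) {
  stopifnot(inherits(eff, "effective_payoffs"))
  list(phi_A = N * (1 - p_A) * eff$xi, phi_B = -N * eff$kappa * p_A)
}

#' Effective competition rates under the emergent game
#'
#' The coarse-grained dynamics are the fixed-environment dynamics with the
#' between-population competition rates shifted by the emergent payoffs:
#' `a_AB -> a_AB - xi`, `a_BA -> a_BA + kappa`. The result may carry negative
#' between-population entries (competition turned into facilitation); it is
#' flagged `effective` and exempt from the raw positivity check.
#'
#' @param base A [fixed_rates()] object.
#' @param eff An `effective_payoffs` object.
#' @return A `fixed_rates` object with `effective = TRUE`.
#' @export
effective_rates <- function(base, eff) {
  stopifnot(inherits(base, "fixed_rates"), inherits(eff, "effective_payoffs"))
  fixed_rates(r_A = base$r_A, r_B = base$r_B,
              a_AA = base$a_AA, a_AB = base$a_AB - eff$xi,
              a_BA = base$a_BA + eff$kappa, a_BB = base$a_BB,
              gamma = base$gamma, effective = TRUE)
}
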