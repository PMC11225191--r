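#' Named scenario presets
#'
#' Self-contained parameterizations of the study conditions: the
#' fixed-environment exclusion baseline (`r_A = 1.8`, `r_B = 1`, all
#' `a_ij = 0.1`, `gamma = 0`) and the three oscillating scenarios built on it,
#' all with `gamma~ = 0.5 sin(tau)`, `r~_A = c_1 cos(tau)`,
#' `r~_B = c_2 cos(tau)` and `omega = 5`:
#'
#' * `"coexistence_no_synergy"` — `(c_1, c_2) = (-1.6, -0.2)`, payoffs
#'   `(xi, kappa) = (-0.01, -0.08)`, region I.
#' * `"competition_with_synergy"` — `(c_1, c_2) = (-1.6, 1.6)`, payoffs
#'   `(0.08, -0.08)`, region II.
#' * `"mutualism"` — `(c_1, c_2) = (-2.2, 2.2)`, payoffs `(0.11, -0.11)`,
#'   region III.
#' * `"fixed_exclusion"` — no oscillation; A excludes B at `N = 18`.
#'
#' @param name Preset name (see above).
#' @return List with `name`, `base` ([fixed_rates()]), `env`
#'   ([environment_spec()]), `c1`, `c2`, and `expected_region`.
#' @examples
#' p <- scenario_preset("mutualism")
#' effective_payoffs(p$env)
#' @export
scenario_preset <- function(name) {
  name <- match.arg(name, preset_names())
  base <- fixed_rates(r_A = 1.8, r_B = 1, a_AA = 0.1, a_AB = 0.1,
                      a_BA = 0.1, a_BB = 0.1, gamma = 0)
  cc <- switch(name,
               fixed_exclusion = NULL,
               coexistence_no_synergy = c(-1.6, -0.2),
               competition_with_synergy = c(-1.6, 1.6),
               mutualism = c(-2.2, 2.2))
  if (is.null(cc)) {
    env <- environment_spec(base, omega = 5)
    region <- "IV"   # boundary of IV in the payoff plane; A wins
  } else {
    env <- environment_spec(
      base,
      osc_rA = osc_signal(k = 1, cos = cc[1]),
      osc_rB = osc_signal(k = 1, cos = cc[2]),
      osc_gamma = osc_signal(k = 1, sin = 0.5),
      omega = 5)
    region <- switch(name, coexistence_no_synergy = "I",
                     competition_with_synergy = "II", mutualism = "III")
  }
  list(name = name, base = base, env = env,
       c1 = if (is.null(cc)) 0 else cc[1], c2 = if (is.null(cc)) 0 else cc[2],
       expected_region = region)
}

#' @rdname scenario_preset
#' @export
preset_names <- function() {
  c("fixed_exclusion", "coexistence_no_synergy", "competition_with_synergy",
    "mutualism")
}
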