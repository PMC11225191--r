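#' Split a gene-flow balance into directional conversion rates
#'
#' The deterministic model only constrains the balance
#' `gamma = gamma_AB - gamma_BA`; the stochastic simulation needs both
#' directions. The decomposition puts the whole imbalance on one channel and
#' adds a symmetric baseline `gamma0` to both, so the drift is independent of
#' `gamma0` while the conversion traffic (and its noise) is not.
#'
#' @param gamma Net balance (any real).
#' @param gamma0 Symmetric baseline transfer rate (>= 0).
#' @return Named numeric `c(gamma_AB, gamma_BA)` (B->A and A->B conversion
#'   rates) with `gamma_AB - gamma_BA == gamma`.
#' @export
decompose_gamma <- function(gamma, gamma0 = 0) {
  stopifnot(is.finite(gamma), is.finite(gamma0), gamma0 >= 0)
  c(gamma_AB = max(gamma, 0) + gamma0, gamma_BA = max(-gamma, 0) + gamma0)
}

#' Elementary-process rate specification
#'
#' Propensities of the eight stochastic channels whose large-system drift is
#' the deterministic count-space model: per-capita births `r_i n_i`, pairwise
#' competition deaths `a_ij n_i n_j / Omega`, and directional gene conversions
#' `gamma_AB n_A n_B / Omega` (one B becomes A) and `gamma_BA n_A n_B / Omega`.
#' Conversions conserve the total count; births and deaths change it by one.
#'
#' Unlike [fixed_rates()], zero rates are allowed here (e.g. conversion-only
#' systems used to check count conservation).
#'
#' @param r_A,r_B Birth rates (>= 0).
#' @param a_AA,a_AB,a_BA,a_BB Competition death rates (>= 0).
#' @param gamma_AB,gamma_BA Directional conversion rates (>= 0).
#' @param Omega System-size constant (> 0); scaled counts `n / Omega` match the
#'   deterministic model's abundance units.
#' @return Object of class `event_rate_spec`.
#' @export
event_rate_spec <- function(r_A = 0, r_B = 0, a_AA = 0, a_AB = 0, a_BA = 0,
                            a_BB = 0, gamma_AB = 0, gamma_BA = 0, Omega = 1) {
  vals <- c(r_A, r_B, a_AA, a_AB, a_BA, a_BB, gamma_AB, gamma_BA, Omega)
  if (!all(is.finite(vals)) || any(vals[1:8] < 0) || Omega <= 0)
    stop("all propensity parameters must be finite and non-negative, Omega > 0",
         call. = FALSE)
  structure(list(r_A = r_A, r_B = r_B, a_AA = a_AA, a_AB = a_AB, a_BA = a_BA,
                 a_BB = a_BB, gamma_AB = gamma_AB, gamma_BA = gamma_BA,
                 Omega = Omega),
            class = "event_rate_spec")
}

#' Build an event-rate spec from deterministic rates
#'
#' @param rates A [fixed_rates()] object.
#' @param Omega System-size constant (> 0).
#' @param gamma0 Symmetric conversion baseline passed to [decompose_gamma()].
#' @return An `event_rate_spec`.
#' @export
event_spec_from_rates <- function(rates, Omega, gamma0 = 0) {
  stopifnot(inherits(rates, "fixed_rates"))
  g <- decompose_gamma(rates$gamma, gamma0)
  event_rate_spec(rates$r_A, rates$r_B, rates$a_AA, rates$a_AB, rates$a_BA,
                  rates$a_BB, g[["gamma_AB"]], g[["gamma_BA"]], Omega)
}

#' Exact stochastic simulation of the birth-competition-conversion process
#'
#' Gillespie's direct method over the eight elementary channels of an
#' [event_rate_spec()]. The state `(0, 0)` is absorbing. Identical seed gives
#' an identical event sequence.
#'
#' @param spec An `event_rate_spec`.
#' @param n_A0,n_B0 Initial integer counts (>= 0).
#' @param t_end End time (> 0).
#' @param seed Optional integer seed (calls `set.seed`); omit to use the
#'   current RNG stream (e.g. inside ensembles).
#' @param record_times Optional sorted vector of sampling times; if given, the
#'   returned data frame holds the piecewise-constant state at those times
#'   instead of the full event log (memory-friendly for ensembles).
#' @param max_events Safety cap on the number of events.
#' @return data.frame with columns `t`, `n_A`, `n_B`; attribute `n_events`.
#' @examples
#' spec <- event_rate_spec(r_A = 1, a_AA = 0.1, Omega = 50)
#' run <- gillespie_run(spec, 5, 0, t_end = 5, seed = 1)
#' @export
gillespie_run <- function(spec, n_A0, n_B0, t_end, seed = NULL,
                          record_times = NULL, max_events = 5e7) {
  stopifnot(inherits(spec, "event_rate_spec"),
            n_A0 >= 0, n_B0 >= 0, n_A0 == round(n_A0), n_B0 == round(n_B0),
            t_end > 0)
  if (!is.null(seed)) set.seed(seed)
  keep_events <- is.null(record_times)
  rt <- if (keep_events) numeric(0) else as.numeric(record_times)
  res <- gillespie_core(spec$r_A, spec$r_B, spec$a_AA, spec$a_AB, spec$a_BA,
                        spec$a_BB, spec$gamma_AB, spec$gamma_BA, spec$Omega,
                        n_A0, n_B0, t_end, rt, keep_events, max_events)
  if (!is.null(res$error))
    stop(sprintf("stochastic run aborted (%s) at t = %g, state (%g, %g)",
                 res$error, res$t, res$n_A, res$n_B), call. = FALSE)
  out <- if (keep_events)
    data.frame(t = res$ev_t, n_A = res$ev_nA, n_B = res$ev_nB)
  else
    data.frame(t = rt, n_A = res$rec_nA, n_B = res$rec_nB)
  attr(out, "n_events") <- res$n_events
  out
}

#' Replicated stochastic ensemble with checkpoint summaries
#'
#' Runs `n_rep` independent realizations from one master seed (the replicate
#' streams are consecutive segments of the seeded RNG stream, so the whole
#' ensemble is reproducible from `seed` alone) and summarizes the scaled
#' counts `n / Omega` at the checkpoint times.
#'
#' @inheritParams gillespie_run
#' @param n_rep Number of replicates.
#' @param checkpoint_times Times at which the ensemble is summarized.
#' @param seed Master seed (integer).
#' @return List with `summary` (data.frame: `t`, means, standard errors of the
#'   scaled counts) and `draws` (arrays `x_A`, `x_B` of scaled counts,
#'   replicate x checkpoint).
#' @export
gillespie_ensemble <- function(spec, n_A0, n_B0, t_end, n_rep,
                               checkpoint_times, seed) {
  stopifnot(n_rep >= 2)
  set.seed(seed)
  nt <- length(checkpoint_times)
  x_A <- matrix(NA_real_, n_rep, nt)
  x_B <- matrix(NA_real_, n_rep, nt)
  for (r in seq_len(n_rep)) {
    run <- gillespie_run(spec, n_A0, n_B0, t_end,
                         record_times = checkpoint_times)
    x_A[r, ] <- run$n_A / spec$Omega
    x_B[r, ] <- run$n_B / spec$Omega
  }
  se <- function(m) apply(m, 2, stats::sd) / sqrt(n_rep)
  list(summary = data.frame(t = checkpoint_times,
                            x_A_mean = colMeans(x_A), x_A_se = se(x_A),
                            x_B_mean = colMeans(x_B), x_B_se = se(x_B)),
       draws = list(x_A = x_A, x_B = x_B))
}
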