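# Shared replicator RHS in (p_A, N) coordinates for arbitrary instantaneous
# rates; gamma shifts the between-population competition column-wise.
rhs_pn <- function(p, N, r_A, r_B, a_AA, a_AB, a_BA, a_BB, gamma) {
  p <- min(max(p, 0), 1)
  f_A <- r_A - a_AA * N * p - (a_AB - gamma) * N * (1 - p)
  f_B <- r_B - (a_BA + gamma) * N * p - a_BB * N * (1 - p)
  fm <- p * f_A + (1 - p) * f_B
  c(p * (f_A - fm), N * fm)
}

new_trajectory <- function(t, p_A, N, meta) {
  bad_p <- max(0, max(-p_A, na.rm = TRUE), max(p_A - 1, na.rm = TRUE))
  bad_N <- max(0, max(-N, na.rm = TRUE))
  if (bad_p > 1e-6 || bad_N > 1e-6)
    stop(sprintf("state left the admissible set beyond solver tolerance (p by %.3g, N by %.3g)",
                 bad_p, bad_N), call. = FALSE)
  p_A <- pmin(pmax(p_A, 0), 1)
  N <- pmax(N, 0)
  structure(list(t = t, p_A = p_A, p_B = 1 - p_A, N = N, meta = meta),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  n <- length(x$t)
  cat(sprintf("<trajectory>  %d samples on [0, %g]%s\n", n, x$t[n],
              if (isTRUE(x$meta$divergent)) "  [divergent]" else ""))
  cat(sprintf("  final: p_A = %.6g, N = %.6g\n", x$p_A[n], x$N[n]))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(t = x$t, p_A = x$p_A, p_B = x$p_B, N = x$N)
}

solve_pn <- function(derivs, init, times, hmax, rtol, atol, ceiling, meta) {
  root <- function(t, y, parms) y[2] - ceiling
  sol <- deSolve::ode(y = c(p = init[1], N = init[2]), times = times,
                      func = derivs, parms = NULL, method = "lsodar",
                      rootfun = root, rtol = rtol, atol = atol, hmax = hmax)
  sol <- as.matrix(sol)
  t_got <- sol[, 1]
  divergent <- t_got[length(t_got)] < times[length(times)] - 1e-9
  meta$divergent <- divergent
  new_trajectory(t_got, sol[, 2], sol[, 3], meta)
}

#' Integrate the exact time-dependent dynamics
#'
#' Solves the non-autonomous replicator system for `(p_A, N)` with the
#' reproduction and gene-transfer rates oscillating at `tau = omega t`. The
#' solver max step is capped at a twentieth of the environmental period and
#' the output is sampled `n_per_period` times per period so the fast
#' oscillations are resolved.
#'
#' @param env An [environment_spec()].
#' @param init Numeric `c(p_A, N)` with `p_A` in \[0, 1\] and `N >= 0`.
#' @param t_end Final time (> 0).
#' @param n_per_period Output samples per environmental period (>= 40
#'   recommended; default 40).
#' @param rtol,atol Solver tolerances.
#' @param ceiling Abundance ceiling; crossing it terminates the integration and
#'   flags the trajectory divergent (the unbounded-growth N/A regime is a
#'   documented model behaviour, not a failure).
#' @return A `trajectory` object (fields `t`, `p_A`, `p_B`, `N`, `meta`).
#' @examples
#' env <- scenario_preset("competition_with_synergy")$env
#' tr <- integrate_full(env, init = c(0.5, 1), t_end = 10)
#' @export
integrate_full <- function(env, init, t_end, n_per_period = 40,
                           rtol = 1e-8, atol = 1e-10, ceiling = 1e6) {
  stopifnot(inherits(env, "environment_spec"), t_end > 0,
            init[1] >= 0, init[1] <= 1, init[2] >= 0)
  period <- 2 * pi / env$omega
  dt <- period / n_per_period
  times <- seq(0, t_end, by = dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  b <- env$base
  derivs <- function(t, y, parms) {
    rt <- rates_at(env, t)
    list(rhs_pn(y[1], y[2], rt$r_A, rt$r_B, b$a_AA, b$a_AB, b$a_BA, b$a_BB,
                rt$gamma))
  }
  solve_pn(derivs, init, times, hmax = period / 20, rtol, atol, ceiling,
           meta = list(kind = "full", omega = env$omega, period = period,
                       rtol = rtol, atol = atol))
}

#' Integrate the coarse-grained (averaged) dynamics
#'
#' Autonomous replicator system in which each population's fitness is the
#' fixed-environment fitness plus the oscillation-induced surplus
#' (`phi_A = N(1-p_A) xi`, `phi_B = -N kappa p_A`). Algebraically this equals
#' the fixed-rate dynamics on the effective rates `a_AB - xi`, `a_BA + kappa`.
#'
#' @param base A [fixed_rates()] object (the period averages).
#' @param eff An `effective_payoffs` object.
#' @inheritParams integrate_full
#' @return A `trajectory` object. When `eff` carries a finite `omega` the
#'   output grid matches [integrate_full()] so period averages can be compared
#'   on identical windows.
#' @export
integrate_coarse <- function(base, eff, init, t_end, n_per_period = 40,
                             rtol = 1e-8, atol = 1e-10, ceiling = 1e6) {
  stopifnot(inherits(base, "fixed_rates"), inherits(eff, "effective_payoffs"),
            t_end > 0, init[1] >= 0, init[1] <= 1, init[2] >= 0)
  period <- if (is.finite(eff$omega)) 2 * pi / eff$omega else t_end / 50
  dt <- period / n_per_period
  times <- seq(0, t_end, by = dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  derivs <- function(t, y, parms) {
    p <- min(max(y[1], 0), 1); N <- y[2]
    f <- fitness(base, p, max(N, 0))
    phi <- fitness_surplus(eff, p, N)
    fA <- f$f_A + phi$phi_A
    fB <- f$f_B + phi$phi_B
    fm <- p * fA + (1 - p) * fB
    list(c(p * (fA - fm), N * fm))
  }
  solve_pn(derivs, init, times, hmax = period / 20, rtol, atol, ceiling,
           meta = list(kind = "coarse", omega = eff$omega, period = period,
                       rtol = rtol, atol = atol))
}

#' Period average of the tail of a trajectory
#'
#' Trapezoid mean of `p_A` and `N` over an integer number of environmental
#' periods taken from the end of the trajectory, past the transient.
#'
#' @param traj A `trajectory` object.
#' @param n_periods Number of periods to average over; default is the larger of
#'   10 and a quarter of the covered periods.
#' @return List with `p_A_bar`, `N_bar`, and `window = c(from, to)`.
#' @export
period_average <- function(traj, n_periods = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  period <- traj$meta$period
  t_max <- traj$t[length(traj$t)]
  covered <- floor(t_max / period + 1e-9)
  if (is.null(n_periods)) n_periods <- max(10, floor(covered / 4))
  if (n_periods < 1 || covered < n_periods)
    stop(sprintf("trajectory covers %d full periods, fewer than the %d requested",
                 covered, n_periods), call. = FALSE)
  from <- t_max - n_periods * period
  idx <- which(traj$t >= from - 1e-9)
  trap_mean <- function(t, v) {
    n <- length(t)
    sum(diff(t) * (v[-1] + v[-n]) / 2) / (t[n] - t[1])
  }
  list(p_A_bar = trap_mean(traj$t[idx], traj$p_A[idx]),
       N_bar = trap_mean(traj$t[idx], traj$N[idx]),
       window = c(from, t_max))
}

#' Full-vs-coarse comparison metrics
#'
#' Integrates both the exact time-dependent system and its coarse-grained
#' counterpart from the same initial state, period-averages both on matched
#' end windows, and reports the Euclidean distance between the time-averaged
#' fraction vectors and the relative error of the time-averaged total
#' abundances.
#'
#' @param env An [environment_spec()].
#' @inheritParams integrate_full
#' @param n_periods Averaging window (periods from the end); default as in
#'   [period_average()].
#' @return Object of class `comparison_metrics`: `frac_distance`,
#'   `abundance_rel_error`, the two averaged states, and the window. If either
#'   integration diverges the metrics are `NA` and the divergence report is
#'   attached.
#' @export
compare_full_vs_coarse <- function(env, init, t_end, n_periods = NULL,
                                   n_per_period = 40, rtol = 1e-8,
                                   atol = 1e-10, ceiling = 1e6) {
  full <- integrate_full(env, init, t_end, n_per_period, rtol, atol, ceiling)
  eff <- effective_payoffs(env)
  coarse <- integrate_coarse(env$base, eff, init, t_end, n_per_period,
                             rtol, atol, ceiling)
  if (isTRUE(full$meta$divergent) || isTRUE(coarse$meta$divergent)) {
    return(structure(list(frac_distance = NA_real_,
                          abundance_rel_error = NA_real_,
                          divergent = c(full = isTRUE(full$meta$divergent),
                                        coarse = isTRUE(coarse$meta$divergent)),
                          full = full, coarse = coarse),
                     class = "comparison_metrics"))
  }
  af <- period_average(full, n_periods)
  ac <- period_average(coarse, n_periods)
  structure(list(
    frac_distance = sqrt(2) * abs(af$p_A_bar - ac$p_A_bar),
    abundance_rel_error = abs(af$N_bar - ac$N_bar) / af$N_bar,
    divergent = c(full = FALSE, coarse = FALSE),
    full_avg = af, coarse_avg = ac, window = af$window),
    class = "comparison_metrics")
}

#' @export
print.comparison_metrics <- function(x, ...) {
  cat("<full vs coarse>\n")
  if (any(x$divergent)) {
    cat("  divergent:", paste(names(x$divergent)[x$divergent], collapse = ", "),
        "- metrics N/A\n")
  } else {
    cat(sprintf("  fraction distance   = %.4g\n", x$frac_distance))
    cat(sprintf("  abundance rel error = %.4g\n", x$abundance_rel_error))
  }
  invisible(x)
}
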