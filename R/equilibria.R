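#' Stability of the single-population equilibria
#'
#' The monoculture rest points are `(p_A*, N*) = (1, r_A / a_AA)` and
#' `(0, r_B / a_BB)`. The first is stable iff
#' `((a_BA + gamma) / a_AA) * (r_A / r_B) > 1`, the second iff
#' `((a_AB - gamma) / a_BB) * (r_B / r_A) > 1`; an invader grows at a stable
#' resident's density only when its cross-competition (shifted by the
#' gene-flow balance) is weak enough.
#'
#' @param rates A [fixed_rates()] object (effective rates allowed).
#' @param tol Relative tolerance for declaring a boundary hit.
#' @return List with logicals `A_only_stable`, `B_only_stable`, logicals
#'   `A_boundary`, `B_boundary`, and the two inequality margins
#'   (`A_margin`, `B_margin`: condition value minus 1).
#' @export
single_population_stability <- function(rates, tol = 1e-9) {
  qA <- (rates$a_BA + rates$gamma) / rates$a_AA * rates$r_A / rates$r_B
  qB <- (rates$a_AB - rates$gamma) / rates$a_BB * rates$r_B / rates$r_A
  list(A_only_stable = qA > 1, B_only_stable = qB > 1,
       A_boundary = abs(qA - 1) <= tol, B_boundary = abs(qB - 1) <= tol,
       A_margin = qA - 1, B_margin = qB - 1)
}

new_equilibrium <- function(p_A_star, N_star, type, stable, diagnostics = list()) {
  structure(list(p_A_star = p_A_star, N_star = N_star, type = type,
                 stable = stable, diagnostics = diagnostics),
            class = "equilibrium")
}

#' @export
print.equilibrium <- function(x, ...) {
  cat(sprintf("<equilibrium %s>  p_A* = %s, N* = %g, %s\n", x$type,
              format(x$p_A_star), x$N_star,
              if (isTRUE(x$stable)) "stable" else "unstable"))
  invisible(x)
}

#' All rest points of the fixed-rate system
#'
#' Returns the trivial extinction point, the two monocultures, and — when it
#' lies in the open interior — the coexistence/bistability point
#' \deqn{p_A^* = \frac{r_A a_{BB} - r_B (a_{AB}-\gamma)}
#'                     {r_A (a_{BB}-a_{BA}-\gamma) + r_B (a_{AA}-a_{AB}+\gamma)},
#'       \quad
#'       N^* = \frac{r_A (a_{BB}-a_{BA}-\gamma) + r_B (a_{AA}-a_{AB}+\gamma)}
#'                  {a_{AA} a_{BB} - (a_{AB}-\gamma)(a_{BA}+\gamma)}.}
#' The trivial point is always unstable for positive reproduction rates. The
#' interior point, when present, is stable iff both monocultures are unstable
#' (coexistence) and is a saddle separating the two basins when both are stable
#' (bistability).
#'
#' @param rates A [fixed_rates()] object (effective rates allowed).
#' @param tol Relative tolerance for the degenerate-geometry test on the
#'   interior denominator and for boundary calls.
#' @return List of `equilibrium` objects, with attribute `degenerate = TRUE`
#'   (and no interior point) when the interior denominator vanishes — e.g. the
#'   neutral case `r_A = r_B`, equal `a_ij`, `gamma = 0`, where every
#'   composition with `N = r/a` is stationary.
#' @export
equilibria <- function(rates, tol = 1e-9) {
  sp <- single_population_stability(rates, tol)
  out <- list(
    new_equilibrium(NA_real_, 0, "trivial", stable = FALSE),
    new_equilibrium(1, rates$r_A / rates$a_AA, "A_only", sp$A_only_stable,
                    diagnostics = list(margin = sp$A_margin)),
    new_equilibrium(0, rates$r_B / rates$a_BB, "B_only", sp$B_only_stable,
                    diagnostics = list(margin = sp$B_margin))
  )
  den <- rates$a_AA * rates$a_BB -
    (rates$a_AB - rates$gamma) * (rates$a_BA + rates$gamma)
  scale <- rates$a_AA * rates$a_BB +
    abs((rates$a_AB - rates$gamma) * (rates$a_BA + rates$gamma))
  if (abs(den) <= tol * scale) {
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  num_p <- rates$r_A * rates$a_BB - rates$r_B * (rates$a_AB - rates$gamma)
  num_N <- rates$r_A * (rates$a_BB - rates$a_BA - rates$gamma) +
    rates$r_B * (rates$a_AA - rates$a_AB + rates$gamma)
  N_star <- num_N / den
  p_star <- num_p / num_N
  if (is.finite(p_star) && is.finite(N_star) &&
      p_star > 0 && p_star < 1 && N_star > 0) {
    interior_stable <- !sp$A_only_stable && !sp$B_only_stable && den > 0
    out[[4]] <- new_equilibrium(p_star, N_star, "interior", interior_stable,
                                diagnostics = list(denominator = den))
  }
  attr(out, "degenerate") <- FALSE
  out
}

#' Gene-flow window for fixed-environment coexistence
#'
#' With equal competition rates `a_ij = a`, unbalanced gene transfer sustains
#' coexistence exactly when
#' `a (1 - r_A/r_B) < gamma < a (r_B/r_A - 1)`. The window is non-empty only
#' when the slower reproducer is the net beneficiary of the gene flow.
#'
#' @param r_A,r_B Reproduction rates (> 0).
#' @param a Common competition rate (> 0).
#' @return List with `lower`, `upper` and logical `empty` (bounds crossed).
#' @export
coexistence_gamma_window <- function(r_A, r_B, a) {
  stopifnot(a > 0, r_A > 0, r_B > 0)
  lower <- a * (1 - r_A / r_B)
  upper <- a * (r_B / r_A - 1)
  list(lower = lower, upper = upper, empty = !(lower < upper))
}

#' Coexistence conditions under the emergent game
#'
#' For balanced average gene transfer (`gamma = 0`) the coexistence equilibrium
#' of the coarse-grained dynamics exists iff
#' `kappa < a (r_B/r_A - 1)` and `xi > a (1 - r_A/r_B)`, and is stable iff
#' `(1 - xi/a)(1 + kappa/a) < 1`. For `gamma != 0` the general pair is
#' `gamma + kappa < a (r_B/r_A - 1)`, `gamma + xi > a (1 - r_A/r_B)` with
#' stability `a (xi - kappa) + (gamma + xi)(gamma + kappa) > 0`. Existence
#' without stability is the unbounded-growth (N/A) regime of the averaged
#' description.
#'
#' @param r_A,r_B Reproduction rates.
#' @param a Common competition rate (> 0).
#' @param gamma Average gene-transfer balance.
#' @param xi,kappa Emergent payoffs.
#' @return List of logicals `existence`, `stability`.
#' @export
oscillating_coexistence_conditions <- function(r_A, r_B, a, gamma = 0,
                                               xi = 0, kappa = 0) {
  stopifnot(a > 0, r_A > 0, r_B > 0)
  existence <- (gamma + kappa) < a * (r_B / r_A - 1) &&
    (gamma + xi) > a * (1 - r_A / r_B)
  stability <- a * (xi - kappa) + (gamma + xi) * (gamma + kappa) > 0
  list(existence = existence, stability = stability)
}

#' Coexistence abundance and composition in the emergent game
#'
#' For `gamma = 0` and equal competition rates the coarse-grained coexistence
#' equilibrium has total abundance
#' \deqn{N_c^* = \frac{r_B \xi - r_A \kappa}{a(\xi - \kappa) + \xi \kappa}}
#' and composition
#' \deqn{p_A^* = \frac{a (r_B - r_A) - r_B \xi}{r_A \kappa - r_B \xi},}
#' the unique joint root of the two effective fitness functions (both closed
#' forms follow from `f_A + phi_A = f_B + phi_B = 0`). At `xi = 0` the total
#' abundance reduces to the fixed-environment value `r_A / a`.
#'
#' @inheritParams oscillating_coexistence_conditions
#' @param check Verify the existence condition first (default `TRUE`).
#' @return List with `N_c_star`, `p_A_star`, `p_B_star`.
#' @section Errors: if `a(xi - kappa) + xi*kappa <= 0` the averaged abundance
#'   diverges or is negative (the N/A regime); a condition of class
#'   `hgtgame_unbounded` is signalled.
#' @export
coexistence_abundance <- function(r_A, r_B, a, xi, kappa, check = TRUE) {
  stopifnot(a > 0, r_A > 0, r_B > 0)
  if (check) {
    cc <- oscillating_coexistence_conditions(r_A, r_B, a, 0, xi, kappa)
    if (!cc$existence)
      stop("coexistence existence conditions do not hold for these payoffs",
           call. = FALSE)
  }
  den <- a * (xi - kappa) + xi * kappa
  if (den <= 0) {
    cnd <- structure(
      class = c("hgtgame_unbounded", "error", "condition"),
      list(message = paste0(
        "averaged abundance ",
        if (den < 0) "is negative" else "diverges",
        ": a(xi - kappa) + xi*kappa <= 0 (N/A regime)"),
        call = NULL))
    stop(cnd)
  }
  N_c <- (r_B * xi - r_A * kappa) / den
  p_den <- r_A * kappa - r_B * xi
  p_A <- (a * (r_B - r_A) - r_B * xi) / p_den
  list(N_c_star = N_c, p_A_star = p_A, p_B_star = 1 - p_A)
}

#' Synergy test: does coexistence beat the fixed-environment winner?
#'
#' Synergy means the coexistence total abundance `N_c*` exceeds the abundance
#' the winning monoculture would reach in the fixed environment,
#' `N_f* = max(r_A, r_B) / a`. Computed from the abundances, never from region
#' membership. `xi = 0` gives `N_c* = N_f*` exactly: no synergy.
#'
#' @inheritParams coexistence_abundance
#' @param tol Relative tolerance on the comparison.
#' @return Logical.
#' @export
synergy <- function(r_A, r_B, a, xi, kappa, tol = 1e-9) {
  ab <- coexistence_abundance(r_A, r_B, a, xi, kappa)
  N_f <- max(r_A, r_B) / a
  ab$N_c_star > N_f * (1 + tol)
}

#' Symbiosis sub-type from the fitness cross-derivatives
#'
#' The effect of each population on the other's total (fixed + surplus)
#' fitness is sign-fixed by the payoffs:
#' `d(f_A + phi_A)/dp_B = -(a - xi) N` and
#' `d(f_B + phi_B)/dp_A = -(a + kappa) N`. Both negative: pure competition;
#' `xi > a` only: A parasitizes B; `kappa < -a` only: B parasitizes A; both
#' reversed: mutualism.
#'
#' @param a Common competition rate (> 0).
#' @param xi,kappa Emergent payoffs.
#' @param tol Relative tolerance: hits on `xi = a` or `kappa = -a` return
#'   `"boundary"`.
#' @return One of `"pure_competition"`, `"A_parasitizes_B"`,
#'   `"B_parasitizes_A"`, `"mutualism"`, `"boundary"`.
#' @export
classify_symbiosis <- function(a, xi, kappa, tol = 1e-9) {
  stopifnot(a > 0)
  if (abs(xi - a) <= tol * a || abs(kappa + a) <= tol * a) return("boundary")
  a_helps_b <- kappa < -a       # d(f_B + phi_B)/dp_A > 0
  b_helps_a <- xi > a           # d(f_A + phi_A)/dp_B > 0
  if (b_helps_a && a_helps_b) "mutualism"
  else if (b_helps_a) "A_parasitizes_B"
  else if (a_helps_b) "B_parasitizes_A"
  else "pure_competition"
}

#' Classify a point of the (xi, kappa) phase plane
#'
#' Partitions the emergent-payoff plane (balanced average gene transfer,
#' equal competition rates, convention `r_A > r_B`) into:
#' regions I-III (coexistence: I without synergy, `xi < 0`; II pure-competition
#' synergy, `0 < xi < a` and `kappa > -a`; III the remaining synergistic zone
#' including the mutualistic corner `xi > a`, `kappa < -a`), IV (A excludes B,
#' as in the fixed environment), V (bistability), VI (B excludes A, the
#' reversed outcome), and the N/A zone where the coexistence composition exists
#' but the averaged abundance diverges or is negative. The verdicts for IV/V/VI
#' come from the monoculture stability conditions applied to the effective
#' rates, not from a literal transcription of the inequality pairs.
#'
#' Inputs with `r_A < r_B` are relabelled (A <-> B maps
#' `(xi, kappa) -> (-kappa, -xi)`) so the region names keep their meaning; the
#' report records the swap.
#'
#' @param r_A,r_B Reproduction rates.
#' @param a Common competition rate (> 0).
#' @param xi,kappa Emergent payoffs.
#' @param tol Relative tolerance; points within it of any region boundary are
#'   labelled `"boundary"`, never silently binned.
#' @return Object of class `regime_report`: list with `region` (one of I, II,
#'   III, IV, V, VI, NA_unbounded, boundary), `symbiosis`, `synergy`,
#'   `N_c_star`, `N_f_star`, `p_A_star`, `swapped`, and `na_subcode`
#'   (`"negative"` or `"divergent"`, N/A region only).
#' @examples
#' classify_region(1.8, 1, 0.1, xi = 0.08, kappa = -0.08)  # region II
#' @export
classify_region <- function(r_A, r_B, a, xi, kappa, tol = 1e-9) {
  stopifnot(a > 0, r_A > 0, r_B > 0)
  swapped <- FALSE
  if (r_A < r_B) {
    tmp <- r_A; r_A <- r_B; r_B <- tmp
    xk <- c(-kappa, -xi); xi <- xk[1]; kappa <- xk[2]
    swapped <- TRUE
  }
  N_f <- r_A / a
  base <- fixed_rates(r_A, r_B, a, a, a, a, gamma = 0)
  eff <- effective_rates(base, payoffs_xk(xi, kappa))
  sp <- single_population_stability(eff, tol)

  kappa_bound <- a * (r_B / r_A - 1)   # A-monoculture threshold
  xi_bound <- a * (1 - r_A / r_B)      # B-monoculture threshold
  stab_margin <- a * (xi - kappa) + xi * kappa
  scale <- a^2

  report <- function(region, symbiosis = NA_character_, syn = NA,
                     N_c = NA_real_, p_A = NA_real_, subcode = NA_character_) {
    structure(list(region = region, symbiosis = symbiosis, synergy = syn,
                   N_c_star = N_c, N_f_star = N_f, p_A_star = p_A,
                   swapped = swapped, na_subcode = subcode),
              class = "regime_report")
  }

  if (sp$A_boundary || sp$B_boundary)
    return(report("boundary"))

  if (!sp$A_only_stable && !sp$B_only_stable) {
    # both monocultures invadable: coexistence composition exists
    if (abs(stab_margin) <= tol * scale)
      return(report("boundary"))
    if (stab_margin < 0) {
      subcode <- if ((r_B * xi - r_A * kappa) / stab_margin < 0)
        "negative" else "divergent"
      p_A <- (a * (r_B - r_A) - r_B * xi) / (r_A * kappa - r_B * xi)
      return(report("NA_unbounded", p_A = p_A, subcode = subcode))
    }
    ab <- coexistence_abundance(r_A, r_B, a, xi, kappa, check = FALSE)
    symb <- classify_symbiosis(a, xi, kappa, tol)
    syn <- ab$N_c_star > N_f * (1 + tol)
    if (abs(xi) <= tol * a)
      return(report("boundary", symb, syn, ab$N_c_star, ab$p_A_star))
    region <- if (xi < 0) "I"
      else if (symb == "boundary") "boundary"
      else if (xi < a && kappa > -a) "II"
      else "III"
    return(report(region, symb, syn, ab$N_c_star, ab$p_A_star))
  }
  if (sp$A_only_stable && sp$B_only_stable)
    return(report("V", symbiosis = classify_symbiosis(a, xi, kappa, tol),
                  syn = FALSE))
  if (sp$A_only_stable)
    return(report("IV", symbiosis = classify_symbiosis(a, xi, kappa, tol),
                  syn = FALSE))
  report("VI", symbiosis = classify_symbiosis(a, xi, kappa, tol), syn = FALSE)
}

#' @export
print.regime_report <- function(x, ...) {
  cat(sprintf("<regime %s>  symbiosis = %s, synergy = %s\n", x$region,
              x$symbiosis, format(x$synergy)))
  if (is.finite(x$N_c_star))
    cat(sprintf("  N_c* = %.6g (N_f* = %.6g), p_A* = %.6g\n",
                x$N_c_star, x$N_f_star, x$p_A_star))
  if (isTRUE(x$swapped)) cat("  (populations relabelled so that r_A > r_B)\n")
  invisible(x)
}

#' Classify an oscillating environment
#'
#' Computes the emergent payoffs of an [environment_spec()] and classifies the
#' resulting point of the phase plane (requires the balanced, equal-competition
#' setting: `gamma = 0` and all `a_ij` equal).
#'
#' @param env An [environment_spec()].
#' @param tol Boundary tolerance, as in [classify_region()].
#' @return A `regime_report` with the payoffs attached as attribute
#'   `"payoffs"`.
#' @export
classify_environment <- function(env, tol = 1e-9) {
  stopifnot(inherits(env, "environment_spec"))
  b <- env$base
  if (b$gamma != 0 || length(unique(c(b$a_AA, b$a_AB, b$a_BA, b$a_BB))) != 1)
    stop("phase-plane classification requires gamma = 0 and equal a_ij",
         call. = FALSE)
  eff <- effective_payoffs(env)
  rep <- classify_region(b$r_A, b$r_B, b$a_AA, eff$xi, eff$kappa, tol)
  attr(rep, "payoffs") <- eff
  rep
}
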