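#' Count-space right-hand side
#'
#' Time derivatives of the raw abundances under Lotka-Volterra competition with
#' a net gene-conversion flow: the HGT term `+gamma * n_A * n_B` enters A and
#' leaves B antisymmetrically, so conversion conserves nothing but redistributes
#' the total growth between the two alleles.
#'
#' @param n_A,n_B Non-negative finite abundances.
#' @param rates A [fixed_rates()] object.
#' @return Named numeric vector `c(dn_A, dn_B)`.
#' @examples
#' r <- fixed_rates(1.8, 1, 0.1, 0.1, 0.1, 0.1)
#' rhs_counts(1, 0, r)   # growth of A alone
#' @export
rhs_counts <- function(n_A, n_B, rates) {
  if (!is.finite(n_A) || !is.finite(n_B) || n_A < 0 || n_B < 0)
    stop("abundances must be finite and non-negative", call. = FALSE)
  hgt <- rates$gamma * n_A * n_B
  c(dn_A = n_A * (rates$r_A - rates$a_AA * n_A - rates$a_AB * n_B) + hgt,
    dn_B = n_B * (rates$r_B - rates$a_BA * n_A - rates$a_BB * n_B) - hgt)
}

#' Density-dependent payoff matrix
#'
#' The model is a replicator system whose payoffs depend on the total abundance
#' N. Rewriting the count-space dynamics in fraction/abundance variables gives a
#' 2x2 symmetric-game payoff table in which the gene-transfer balance shifts the
#' off-diagonal (between-population) competition column-wise:
#' \deqn{f_A = r_A - a_{AA} N p_A - (a_{AB} - \gamma) N p_B}
#' \deqn{f_B = r_B - (a_{BA} + \gamma) N p_A - a_{BB} N p_B}
#'
#' @param rates A [fixed_rates()] object.
#' @param N Total abundance (>= 0).
#' @return 2x2 matrix; entry `[i, j]` is the payoff to strategy i against
#'   opponent j, rows/cols named A, B.
#' @export
payoff_matrix <- function(rates, N) {
  if (!is.finite(N) || N < 0)
    stop("total abundance N must be finite and non-negative", call. = FALSE)
  matrix(c(rates$r_A - rates$a_AA * N,
           rates$r_A - (rates$a_AB - rates$gamma) * N,
           rates$r_B - (rates$a_BA + rates$gamma) * N,
           rates$r_B - rates$a_BB * N),
         nrow = 2, byrow = TRUE, dimnames = list(c("A", "B"), c("A", "B")))
}

#' Fitness vector at a given composition and abundance
#'
#' Row expectation of the density-dependent payoff matrix under the population
#' mix `(p_A, 1 - p_A)`, plus the population-mean fitness.
#'
#' @inheritParams payoff_matrix
#' @param p_A Fraction of population A, in \[0, 1\].
#' @return List with `f_A`, `f_B` and `f_mean = p_A f_A + p_B f_B`.
#' @export
fitness <- function(rates, p_A, N) {
  if (!is.finite(p_A) || p_A < 0 || p_A > 1)
    stop("p_A must lie in [0, 1]", call. = FALSE)
  M <- payoff_matrix(rates, N)
  p <- c(p_A, 1 - p_A)
  f <- as.vector(M %*% p)
  list(f_A = f[1], f_B = f[2], f_mean = sum(p * f))
}

#' Replicator-space right-hand side
#'
#' Derivatives of the fraction of A and the total abundance:
#' `dp_A/dt = p_A (f_A - f_mean)`, `dN/dt = N f_mean`. Algebraically equivalent
#' to [rhs_counts()] under `p_A = n_A / N`, `N = n_A + n_B`.
#'
#' @inheritParams fitness
#' @return Named numeric vector `c(dp_A, dN)`.
#' @export
rhs_replicator <- function(p_A, N, rates) {
  f <- fitness(rates, p_A, N)
  c(dp_A = p_A * (f$f_A - f$f_mean), dN = N * f$f_mean)
}
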