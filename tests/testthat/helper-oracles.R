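# Shared oracles, independent of the implementation paths they check.

# Random raw rate set; gamma optionally free.
random_rates <- function(gamma = 0) {
  fixed_rates(r_A = runif(1, 0.5, 2.5), r_B = runif(1, 0.5, 2.5),
              a_AA = runif(1, 0.02, 0.5), a_AB = runif(1, 0.02, 0.5),
              a_BA = runif(1, 0.02, 0.5), a_BB = runif(1, 0.02, 0.5),
              gamma = gamma)
}

# Change of variables: (dn_A, dn_B) -> (dp_A, dN) at a state with N > 0.
counts_to_replicator <- function(n_A, n_B, dn) {
  N <- n_A + n_B
  c(dp_A = (dn[1] - (n_A / N) * (dn[1] + dn[2])) / N, dN = dn[1] + dn[2])
}

# Central-difference Jacobian of the count-space vector field, written out in
# raw arithmetic (no domain checks) so boundary equilibria can be probed.
numerical_jacobian_counts <- function(rates, n_A, n_B, h = 1e-6) {
  f <- function(x) {
    hgt <- rates$gamma * x[1] * x[2]
    c(x[1] * (rates$r_A - rates$a_AA * x[1] - rates$a_AB * x[2]) + hgt,
      x[2] * (rates$r_B - rates$a_BA * x[1] - rates$a_BB * x[2]) - hgt)
  }
  J <- matrix(0, 2, 2)
  x0 <- c(n_A, n_B)
  for (j in 1:2) {
    e <- c(0, 0); e[j] <- h * max(1, abs(x0[j]))
    J[, j] <- (f(x0 + e) - f(x0 - e)) / (2 * e[j])
  }
  J
}

# Interior rest point by solving the 2x2 linear system for the counts
# (f_A = f_B = 0), independent of the package's closed forms.
interior_by_linear_solve <- function(rates) {
  A <- matrix(c(rates$a_AA, rates$a_AB - rates$gamma,
                rates$a_BA + rates$gamma, rates$a_BB), 2, byrow = TRUE)
  n <- tryCatch(solve(A, c(rates$r_A, rates$r_B)), error = function(e) NULL)
  if (is.null(n)) return(NULL)
  N <- sum(n)
  if (any(n <= 0)) return(NULL)
  list(p_A = n[1] / N, N = N)
}

# Three oscillating study scenarios: (c1, c2) amplitude pairs at omega = 5.
scenario_table <- function() {
  data.frame(
    name = c("coexistence_no_synergy", "competition_with_synergy", "mutualism"),
    c1 = c(-1.6, -1.6, -2.2), c2 = c(-0.2, 1.6, 2.2),
    xi = c(-0.01, 0.08, 0.11), kappa = c(-0.08, -0.08, -0.11),
    region = c("I", "II", "III"),
    stringsAsFactors = FALSE)
}
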