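base_params <- fixed_rates(1.8, 1, 0.1, 0.1, 0.1, 0.1, gamma = 0)

test_that("fixed-environment equilibria reproduce the exclusion geometry", {
  eq <- equilibria(base_params)
  types <- vapply(eq, `[[`, "", "type")
  expect_setequal(types, c("trivial", "A_only", "B_only"))
  A <- eq[[which(types == "A_only")]]
  B <- eq[[which(types == "B_only")]]
  expect_equal(c(A$p_A_star, A$N_star), c(1, 18))
  expect_true(A$stable)
  expect_equal(c(B$p_A_star, B$N_star), c(0, 10))
  expect_false(B$stable)
  expect_false(eq[[which(types == "trivial")]]$stable)
})

test_that("neutral case is flagged as a degenerate line of rest points", {
  r <- fixed_rates(1.2, 1.2, 0.1, 0.1, 0.1, 0.1, gamma = 0)
  eq <- equilibria(r)
  expect_true(attr(eq, "degenerate"))
  expect_false("interior" %in% vapply(eq, `[[`, "", "type"))
})

test_that("interior equilibrium matches an independent linear solve", {
  # effective rates of the synergy scenario
  eff <- effective_rates(base_params, payoffs_xk(0.08, -0.08))
  eq <- equilibria(eff)
  types <- vapply(eq, `[[`, "", "type")
  expect_true("interior" %in% types)
  it <- eq[[which(types == "interior")]]
  oracle <- interior_by_linear_solve(eff)
  expect_equal(it$p_A_star, oracle$p_A, tolerance = 1e-12)
  expect_equal(it$N_star, oracle$N, tolerance = 1e-12)
  expect_equal(it$N_star, 0.224 / 0.0096, tolerance = 1e-12)  # 23.333...
  expect_true(it$stable)
  # and it is a root of the replicator RHS
  expect_equal(unname(rhs_replicator(it$p_A_star, it$N_star, eff)), c(0, 0),
               tolerance = 1e-9)
})

test_that("stability verdicts agree with numerical Jacobian eigenvalues", {
  set.seed(2024)
  n_checked <- 0
  for (i in 1:200) {
    r <- random_rates(gamma = runif(1, -0.2, 0.2))
    eq <- equilibria(r)
    for (e in eq) {
      if (e$type == "trivial" || is.na(e$p_A_star)) next
      expect_equal(unname(rhs_replicator(e$p_A_star, e$N_star, r)), c(0, 0),
                   tolerance = 1e-9)
      ev <- eigen(numerical_jacobian_counts(r, e$p_A_star * e$N_star,
                                            (1 - e$p_A_star) * e$N_star),
                  only.values = TRUE)$values
      dom <- max(Re(ev))
      if (abs(dom) < 1e-4) next  # too close to a bifurcation to call
      expect_identical(e$stable, dom < 0)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 300)
})

test_that("monoculture stability inequalities match their closed form", {
  sp <- single_population_stability(base_params)
  expect_true(sp$A_only_stable)    # 1 * 1.8 > 1
  expect_false(sp$B_only_stable)   # 1 / 1.8 < 1
  # bistable configuration: both hold with product > 1
  rb <- fixed_rates(1, 1, 0.1, 0.25, 0.25, 0.1)
  spb <- single_population_stability(rb)
  expect_true(spb$A_only_stable && spb$B_only_stable)
  eqb <- equilibria(rb)
  it <- Filter(function(e) e$type == "interior", eqb)[[1]]
  expect_false(it$stable)          # saddle separating the two basins
  # strong gene flow toward the slow reproducer gives stable coexistence
  rc <- fixed_rates(1.8, 1, 0.1, 0.1, 0.1, 0.1, gamma = -0.06)
  spc <- single_population_stability(rc)
  expect_false(spc$A_only_stable || spc$B_only_stable)
  itc <- Filter(function(e) e$type == "interior", equilibria(rc))[[1]]
  expect_true(itc$stable)
})

test_that("gene-flow coexistence window matches the closed form", {
  w <- coexistence_gamma_window(1.8, 1, 0.1)
  expect_equal(w$lower, 0.1 * (1 - 1.8))
  expect_equal(w$upper, 0.1 * (1 / 1.8 - 1))
  expect_false(w$empty)
  expect_true(w$upper < 0)  # the slow reproducer must receive the gene flow
  we <- coexistence_gamma_window(1, 1, 0.1)
  expect_true(we$empty)
  # gamma = 0 with unequal r lies outside the window: exclusion
  expect_false(w$lower < 0 && 0 < w$upper)
  # gamma inside the window indeed yields a stable interior point
  g <- mean(c(w$lower, w$upper))
  eq <- equilibria(fixed_rates(1.8, 1, 0.1, 0.1, 0.1, 0.1, gamma = g))
  it <- Filter(function(e) e$type == "interior", eq)
  expect_length(it, 1)
  expect_true(it[[1]]$stable)
})

test_that("oscillating coexistence conditions evaluate both inequality pairs", {
  cc <- oscillating_coexistence_conditions(1.8, 1, 0.1, 0, 0.08, -0.08)
  expect_true(cc$existence && cc$stability)
  # no oscillation, unequal r: exclusion
  cc0 <- oscillating_coexistence_conditions(1.8, 1, 0.1, 0, 0, 0)
  expect_false(cc0$existence)
  # existence without stability: the N/A regime
  ccna <- oscillating_coexistence_conditions(1.8, 1, 0.1, 0, 0.2, -0.3)
  expect_true(ccna$existence)
  expect_false(ccna$stability)
  # unbalanced-transfer variant reduces to the window at xi = kappa = 0
  w <- coexistence_gamma_window(1.8, 1, 0.1)
  gin <- mean(c(w$lower, w$upper))
  expect_true(oscillating_coexistence_conditions(1.8, 1, 0.1, gin)$existence)
  expect_false(oscillating_coexistence_conditions(1.8, 1, 0.1, 0.05)$existence)
})

test_that("coexistence abundance and composition follow the closed forms", {
  # xi = 0 recovers the fixed-environment abundance r_A / a
  ab0 <- coexistence_abundance(1.8, 1, 0.1, 0, -0.08)
  expect_equal(ab0$N_c_star, 18)
  ab3 <- coexistence_abundance(1.8, 1, 0.1, 0.11, -0.11)
  expect_equal(ab3$N_c_star, 0.308 / 0.0099, tolerance = 1e-12)
  ab1 <- coexistence_abundance(1.8, 1, 0.1, -0.01, -0.08)
  expect_lt(ab1$N_c_star, 18)
  # composition solves both fitness equations (independent check)
  for (xk in list(c(0.08, -0.08), c(0.11, -0.11), c(-0.01, -0.08))) {
    ab <- coexistence_abundance(1.8, 1, 0.1, xk[1], xk[2])
    eff <- effective_rates(base_params, payoffs_xk(xk[1], xk[2]))
    f <- fitness(eff, ab$p_A_star, ab$N_c_star)
    expect_equal(f$f_A, 0, tolerance = 1e-12)
    expect_equal(f$f_B, 0, tolerance = 1e-12)
  }
  expect_error(coexistence_abundance(1.8, 1, 0.1, 0.2, -0.3),
               class = "hgtgame_unbounded")
  expect_error(coexistence_abundance(1.8, 1, 0.1, 0.3, 0.1), "existence")
})

test_that("N_c* increases with xi and meets N_f* at xi = 0", {
  kappa <- -0.08
  xis <- seq(-0.05, 0.2, by = 0.01)
  Ns <- vapply(xis, function(x)
    coexistence_abundance(1.8, 1, 0.1, x, kappa, check = FALSE)$N_c_star, 0)
  expect_true(all(diff(Ns) > 0))
  expect_equal(Ns[xis == 0], 18)
})

test_that("phase-plane classification reproduces the study scenarios", {
  tab <- scenario_table()
  for (i in seq_len(nrow(tab))) {
    rep <- classify_region(1.8, 1, 0.1, tab$xi[i], tab$kappa[i])
    expect_identical(rep$region, tab$region[i])
  }
  expect_identical(classify_region(1.8, 1, 0.1, 0.08, -0.08)$symbiosis,
                   "pure_competition")
  expect_identical(classify_region(1.8, 1, 0.1, 0.11, -0.11)$symbiosis,
                   "mutualism")
  # fixed-environment limit: exclusion, A wins (interior of IV)
  expect_identical(classify_region(1.8, 1, 0.1, 0, 0)$region, "IV")
  # exclusion-preserving and outcome-reversing zones
  expect_identical(classify_region(1.8, 1, 0.1, 0.08, 0.02)$region, "IV")
  expect_identical(classify_region(1.8, 1, 0.1, -0.12, -0.08)$region, "VI")
  expect_identical(classify_region(1.8, 1, 0.1, -0.12, 0.02)$region, "V")
  na <- classify_region(1.8, 1, 0.1, 0.2, -0.3)
  expect_identical(na$region, "NA_unbounded")
  expect_identical(na$na_subcode, "negative")
  expect_true(na$p_A_star > 0 && na$p_A_star < 1)
})

test_that("symbiosis labels follow the fitness cross-derivative signs", {
  expect_identical(classify_symbiosis(0.1, 0.08, -0.08), "pure_competition")
  expect_identical(classify_symbiosis(0.1, 0.11, -0.11), "mutualism")
  expect_identical(classify_symbiosis(0.1, 0.15, -0.05), "A_parasitizes_B")
  expect_identical(classify_symbiosis(0.1, -0.01, -0.15), "B_parasitizes_A")
  expect_identical(classify_symbiosis(0.1, 0.1, -0.05), "boundary")
  expect_identical(classify_symbiosis(0.1, 0.05, -0.1), "boundary")
})

test_that("synergy is decided by abundances, not region labels", {
  expect_true(synergy(1.8, 1, 0.1, 0.08, -0.08))
  expect_true(synergy(1.8, 1, 0.1, 0.11, -0.11))
  expect_false(synergy(1.8, 1, 0.1, -0.01, -0.08))
  expect_false(synergy(1.8, 1, 0.1, 0, -0.08))   # N_c* = N_f* exactly
  expect_error(synergy(1.8, 1, 0.1, 0.3, 0.1))   # outside coexistence
})

test_that("relabelling keeps region semantics when r_A < r_B", {
  rep <- classify_region(1, 1.8, 0.1, xi = 0.08, kappa = -0.08)
  # swap maps (xi, kappa) -> (-kappa, -xi) = (0.08, -0.08): same region II
  ref <- classify_region(1.8, 1, 0.1, 0.08, -0.08)
  expect_identical(rep$region, ref$region)
  expect_true(rep$swapped)
  expect_equal(rep$N_c_star, ref$N_c_star)
})

test_that("exclusion principle: balanced transfer never yields stable interior", {
  set.seed(555)
  for (i in 1:1000) {
    r_A <- runif(1, 0.5, 2.5)
    r_B <- runif(1, 0.5, 2.5)
    if (abs(r_A - r_B) < 1e-3) next
    a <- runif(1, 0.02, 0.5)
    sp <- single_population_stability(fixed_rates(r_A, r_B, a, a, a, a))
    # the two conditions cannot fail together
    expect_true(sp$A_only_stable || sp$B_only_stable)
    eq <- equilibria(fixed_rates(r_A, r_B, a, a, a, a))
    stable_interior <- Filter(function(e) e$type == "interior" && e$stable, eq)
    expect_length(stable_interior, 0)
  }
})

test_that("region partition is exhaustive and exclusive off the boundaries", {
  xi_v <- seq(-0.095, 0.2951, by = 0.013)
  ka_v <- seq(-0.2951, 0.095, by = 0.013)
  labs <- c("I", "II", "III", "IV", "V", "VI", "NA_unbounded", "boundary")
  seen <- character()
  for (x in xi_v) for (k in ka_v) {
    r <- classify_region(1.8, 1, 0.1, x, k)
    expect_true(r$region %in% labs)
    seen <- union(seen, r$region)
  }
  expect_true(all(c("I", "II", "III", "IV", "V", "VI", "NA_unbounded") %in% seen))
})

test_that("region labels agree with long-time coarse-grained integration", {
  base <- base_params
  probes <- list(c(0.08, -0.08), c(0.11, -0.11), c(-0.01, -0.08),
                 c(0.08, 0.02), c(-0.12, -0.08))
  for (xk in probes) {
    rep <- classify_region(1.8, 1, 0.1, xk[1], xk[2])
    eff <- payoffs_xk(xk[1], xk[2], omega = 5)
    tr <- integrate_coarse(base, eff, c(0.5, 1), t_end = 300)
    n <- length(tr$t)
    p_end <- tr$p_A[n]; N_end <- tr$N[n]
    if (rep$region %in% c("I", "II", "III")) {
      expect_equal(p_end, rep$p_A_star, tolerance = 1e-4)
      expect_equal(N_end, rep$N_c_star, tolerance = 1e-4)
    } else if (rep$region == "IV") {
      expect_equal(p_end, 1, tolerance = 1e-4)
    } else if (rep$region == "VI") {
      expect_equal(p_end, 0, tolerance = 1e-4)
    }
  }
})
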