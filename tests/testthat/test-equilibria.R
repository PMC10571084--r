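test_that("input validation rejects unphysical systems", {
  expect_error(component("Mg", "metal", -1), "negative total")
  expect_error(reaction("SM", c(S = 1, Mg = 1), kd = 0), "positive")
  expect_error(reaction("SM", c(S = 1, Mg = 1), kd = -2), "positive")
  expect_error(reaction("SM", numeric(0), kd = 1), "non-empty")
  expect_error(
    equilibrium_system(list(component("S", "sensor", 1e-6)),
                       list(reaction("S", c(S = 1), 1e-3))),
    "collides")
  expect_error(
    equilibrium_system(list(component("S", "sensor", 1e-6)),
                       list(reaction("SX", c(S = 1, X = 1), 1e-3))),
    "unknown species")
  expect_error(
    equilibrium_system(list(component("S", "sensor", 1e-6),
                            component("H", "proton"))),
    "requires 'ph'")
})

test_that("sensor with no binding partner stays fully free", {
  sys <- make_1to1_system(10e-6, 0, 0.14e-3)
  sp <- solve_speciation(sys)
  expect_true(sp$converged)
  expect_equal(sp$free[["S"]], 10e-6)
  expect_equal(sp$complexes[["S.Mg"]], 0)
})

test_that("1:1 speciation matches the closed-form quadratic at equimolar kd", {
  sp <- solve_speciation(make_1to1_system(10e-6, 0.14e-3, 0.14e-3))
  cf <- closed_form_1to1(10e-6, 0.14e-3, 0.14e-3)
  expect_true(sp$converged)
  expect_lt(abs(sp$complexes[["S.Mg"]] / cf - 1), 1e-9)
})

test_that("closed-form 1:1 matches the bisection oracle and its limits", {
  # saturation limit and zero-metal limit
  expect_equal(closed_form_1to1(10e-6, 0, 1e-3), 0)
  expect_gte(closed_form_1to1(10e-6, 1, 0.14e-3), 0.999 * 10e-6)
  expect_error(closed_form_1to1(10e-6, 1e-3, 0), "kd must be")
  expect_error(closed_form_1to1(-1e-6, 1e-3, 1e-3), ">= 0")
  # brute-force bisection oracle across regimes incl. strong depletion
  cases <- expand.grid(s = c(1e-9, 1e-6, 1e-4),
                       m = c(1e-8, 1e-5, 1e-3, 1e-1),
                       kd = c(1e-9, 1e-6, 1e-3, 1))
  for (i in seq_len(nrow(cases))) {
    b_cf <- closed_form_1to1(cases$s[i], cases$m[i], cases$kd[i])
    b_or <- oracle_1to1_bound(cases$s[i], cases$m[i], cases$kd[i])
    expect_lt(abs(b_cf - b_or) / max(b_or, 1e-300), 1e-9)
    expect_lte(b_cf, min(cases$s[i], cases$m[i]) * (1 + 1e-12))
  }
})

test_that("solver agrees with the closed form over a wide log grid", {
  kds <- 10^seq(-9, 0, length.out = 7)
  tots <- 10^seq(-9, 0, length.out = 7)
  for (kd in kds) {
    for (m in tots) {
      sp <- solve_speciation(make_1to1_system(1e-6, m, kd))
      expect_true(sp$converged)
      cf <- closed_form_1to1(1e-6, m, kd)
      denom <- max(cf, 1e-300)
      expect_lt(abs(sp$complexes[["S.Mg"]] - cf) / denom, 1e-9)
      expect_lt(max(abs(sp$residuals)), 1e-9)
    }
  }
})

test_that("three-reaction speciation matches the nested-bisection oracle", {
  sp <- solve_speciation(make_ternary_system(20e-6, 10e-3, 10e-3))
  expect_true(sp$converged)
  orc <- oracle_ternary(20e-6, 10e-3, 10e-3, 0.14e-3, 50e-6, 0.1)
  expect_lt(abs(sp$free[["S"]] / orc$S - 1), 1e-6)
  expect_lt(abs(sp$free[["Mg"]] / orc$Mg - 1), 1e-6)
  expect_lt(abs(sp$free[["ATP"]] / orc$ATP - 1), 1e-6)
  expect_lt(abs(sp$complexes[["S.Mg"]] / orc$SM - 1), 1e-6)
  expect_lt(abs(sp$complexes[["Mg.ATP"]] / orc$MgATP - 1), 1e-6)
  expect_lt(abs(sp$complexes[["S.Mg.ATP"]] / orc$SMT - 1), 1e-6)
})

test_that("mass balance holds across random multi-component systems", {
  set.seed(42)
  for (i in 1:25) {
    s_tot <- 10^stats::runif(1, -7, -4)
    mg_tot <- 10^stats::runif(1, -6, -1)
    atp_tot <- 10^stats::runif(1, -6, -1)
    kd1 <- 10^stats::runif(1, -8, -1)
    kd2 <- 10^stats::runif(1, -6, -2)
    kd3 <- 10^stats::runif(1, -3, 1)
    sp <- solve_speciation(make_ternary_system(s_tot, mg_tot, atp_tot,
                                               kd1, kd2, kd3))
    expect_true(sp$converged)
    expect_lt(max(abs(sp$residuals)), 1e-9)
    expect_true(all(c(sp$free, sp$complexes) >= 0))
  }
})

test_that("bound sensor is monotone in total metal", {
  grid <- 10^seq(-6, -1, length.out = 12)
  sm <- vapply(grid, function(m) {
    solve_speciation(make_1to1_system(10e-6, m, 0.14e-3))$complexes[["S.Mg"]]
  }, numeric(1))
  expect_true(all(diff(sm) > 0))
})

test_that("ATP competition sequesters Mg and the weak ternary barely perturbs", {
  base <- solve_speciation(make_1to1_system(10e-6, 1e-3, 0.14e-3))
  sm0 <- base$complexes[["S.Mg"]]
  # adding ATP never increases the binary sensor-Mg complex
  prev <- sm0
  for (atp in c(1e-4, 1e-3, 1e-2)) {
    spc <- solve_speciation(equilibrium_system(
      list(component("S", "sensor", 10e-6),
           component("Mg", "metal", 1e-3),
           component("ATP", "ligand", atp)),
      list(reaction("S.Mg", c(S = 1, Mg = 1), 0.14e-3),
           reaction("Mg.ATP", c(Mg = 1, ATP = 1), 50e-6))))
    expect_lte(spc$complexes[["S.Mg"]], prev * (1 + 1e-12))
    prev <- spc$complexes[["S.Mg"]]
  }
  # at <= 1 mM totals the 100 mM ternary changes Mg-bound sensor by < 1%
  no_t <- solve_speciation(equilibrium_system(
    list(component("S", "sensor", 10e-6),
         component("Mg", "metal", 1e-3),
         component("ATP", "ligand", 1e-3)),
    list(reaction("S.Mg", c(S = 1, Mg = 1), 0.14e-3),
         reaction("Mg.ATP", c(Mg = 1, ATP = 1), 50e-6))))
  with_t <- solve_speciation(make_ternary_system(10e-6, 1e-3, 1e-3))
  bound_no <- no_t$complexes[["S.Mg"]]
  bound_with <- with_t$complexes[["S.Mg"]] + with_t$complexes[["S.Mg.ATP"]]
  expect_lt(abs(bound_with / bound_no - 1), 0.01)
})

test_that("proton clamping reproduces the Henderson-Hasselbalch fraction", {
  pka <- 7.1
  for (ph in c(5, 6.5, 7.1, 8)) {
    sp <- solve_speciation(equilibrium_system(
      list(component("S", "sensor", 10e-6), component("H", "proton")),
      list(reaction("S.H", c(S = 1, H = 1), 10^(-pka))),
      ph = ph))
    expect_true(sp$converged)
    frac_prot <- sp$complexes[["S.H"]] / 10e-6
    expect_equal(frac_prot, 1 / (1 + 10^(ph - pka)), tolerance = 1e-9)
  }
})

test_that("fraction_bound follows the hyperbolic isotherm", {
  expect_equal(fraction_bound(1e-3, 0), 0)
  expect_equal(fraction_bound(0.14e-3, 0.14e-3), 0.5)
  expect_equal(fraction_bound(1.7e-3, 50e-6), 50e-6 / (1.7e-3 + 50e-6))
  expect_lt(abs(fraction_bound(1.7e-3, 50e-6) - 0.0286), 5e-4)
  x <- fraction_bound(1e-3, 10^seq(-6, 0, length.out = 20))
  expect_true(all(diff(x) > 0) && all(x >= 0 & x < 1))
  expect_error(fraction_bound(1e-3, -1), ">= 0")
})

test_that("non-convergence is reported, never silent", {
  sys <- make_1to1_system(10e-6, 0.14e-3, 0.14e-3)
  sp <- solve_speciation(sys, tol = 1e-9, max_iter = 0L)
  expect_false(sp$converged)
  expect_true(all(is.finite(sp$residuals)))
})
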