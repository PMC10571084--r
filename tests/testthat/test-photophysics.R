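test_that("spectrum evaluation is a brightness-scaled Gaussian band sum", {
  s <- species_spectrum("x", data.frame(center = 530, width = 30,
                                        amplitude = 2), brightness = 0.5)
  # peak value at the band center is amplitude x brightness
  expect_equal(evaluate_spectrum(s, 530), 1)
  # zero brightness kills everything
  dark <- species_spectrum("x", data.frame(center = 530, width = 30,
                                           amplitude = 2), brightness = 0)
  expect_equal(evaluate_spectrum(dark, seq(400, 700, 10)),
               rep(0, length(seq(400, 700, 10))))
  # two-band spectrum equals the sum of single-band evaluations
  b1 <- data.frame(center = 500, width = 25, amplitude = 1)
  b2 <- data.frame(center = 600, width = 40, amplitude = 0.3)
  grid <- seq(400, 700, 5)
  both <- evaluate_spectrum(species_spectrum("x", rbind(b1, b2)), grid)
  sep <- evaluate_spectrum(species_spectrum("x", b1), grid) +
    evaluate_spectrum(species_spectrum("x", b2), grid)
  expect_equal(both, sep)
  # linearity in brightness
  s2 <- species_spectrum("x", b1, brightness = 3)
  expect_equal(evaluate_spectrum(s2, grid),
               3 * evaluate_spectrum(species_spectrum("x", b1), grid))
  expect_error(evaluate_spectrum(s, numeric(0)), "empty")
  expect_error(evaluate_spectrum(s, 200), "300-800")
})

test_that("channel composition reproduces the single-species limits", {
  sp_fix <- fixture_spectra()
  ch <- fixture_channels()
  bounds <- ratio_bounds(sp_fix, ch, "S", "S.Mg")
  # all sensor free -> r_min
  free_state <- solve_speciation(make_1to1_system(10e-6, 0, 1e-3))
  m1 <- compose_channel_intensities(free_state, sp_fix, ch)
  expect_equal(m1$ratio, bounds$r_min, tolerance = 1e-12)
  # all sensor bound (huge metal excess) -> r_max
  sat_state <- solve_speciation(make_1to1_system(10e-6, 10, 1e-6))
  m2 <- compose_channel_intensities(sat_state, sp_fix, ch)
  expect_equal(m2$ratio, bounds$r_max, tolerance = 1e-3)
  # 50/50 mixture lies strictly between
  mid_state <- solve_speciation(make_1to1_system(10e-6, 5e-6 + 1e-3, 1e-3))
  m3 <- compose_channel_intensities(mid_state, sp_fix, ch)
  expect_gt(m3$ratio, bounds$r_min)
  expect_lt(m3$ratio, bounds$r_max)
})

test_that("dark denominator flags the measurement instead of erroring", {
  dark <- list(S = species_spectrum("S",
                                    data.frame(center = 500, width = 30,
                                               amplitude = 1),
                                    brightness = 0))
  st <- solve_speciation(make_1to1_system(10e-6, 0, 1e-3))
  m <- suppressWarnings(compose_channel_intensities(st, dark,
                                                    fixture_channels()))
  expect_false(m$valid)
  expect_true(is.na(m$ratio))
})

test_that("ratio isotherm is monotone with saturation and midpoint at kd", {
  sp_fix <- fixture_spectra()
  ch <- fixture_channels()
  bounds <- ratio_bounds(sp_fix, ch, "S", "S.Mg")
  kd <- 0.14e-3
  iso0 <- ratio_isotherm(kd, 10e-6, 0, sp_fix, ch, sensor = "S")
  expect_equal(iso0$ratio, bounds$r_min, tolerance = 1e-12)
  # 50 mM >> kd saturates to within 1% of r_max
  iso_sat <- ratio_isotherm(kd, 10e-6, 50e-3, sp_fix, ch, sensor = "S")
  expect_lt(abs(iso_sat$ratio / bounds$r_max - 1), 0.01)
  # monotone when the bound spectrum is red of the free one
  grid <- 10^seq(-6, -1, length.out = 15)
  iso <- ratio_isotherm(kd, 10e-6, grid, sp_fix, ch, sensor = "S")
  expect_true(all(diff(iso$ratio) > 0))
  # tracer regime: the half-way ratio occurs at free metal = kd
  s_small <- 1e-9
  iso_kd <- ratio_isotherm(kd, s_small, kd, sp_fix, ch, sensor = "S")
  half_ratio <- (bounds$r_min * bounds$beta + bounds$r_max) /
    (bounds$beta + 1)
  expect_equal(iso_kd$ratio, half_ratio, tolerance = 1e-6)
})

test_that("ratiometric inversion is exact and round-trips the isotherm", {
  sp_fix <- fixture_spectra()
  ch <- fixture_channels()
  b <- ratio_bounds(sp_fix, ch, "S", "S.Mg")
  kd <- 0.14e-3
  # algebraic midpoint (half the sensor bound) corresponds to free = kd:
  # R(kd) = (r_min*beta + r_max)/(beta + 1) with beta = free/bound
  # denominator brightness
  mid <- (b$r_min * b$beta + b$r_max) / (b$beta + 1)
  expect_equal(ratio_to_free_metal(mid, b$r_min, b$r_max, kd, b$beta), kd,
               tolerance = 1e-12)
  # round trip across four decades in the tracer regime
  for (mult in 10^seq(-2, 2, length.out = 9)) {
    m <- kd * mult
    iso <- ratio_isotherm(kd, 1e-9, m, sp_fix, ch, sensor = "S")
    m_back <- ratio_to_free_metal(iso$ratio, b$r_min, b$r_max, kd, b$beta)
    expect_lt(abs(m_back / m - 1), 1e-3)
  }
  expect_error(ratio_to_free_metal(b$r_min - 0.01, b$r_min, b$r_max, kd,
                                   b$beta), "metal-free")
  expect_error(ratio_to_free_metal(b$r_max + 0.01, b$r_min, b$r_max, kd,
                                   b$beta), "saturated")
})

test_that("ratio is invariant to sensor concentration at clamped free metal", {
  sp_fix <- fixture_spectra()
  ch <- fixture_channels()
  kd <- 0.14e-3
  # clamp free metal by overwhelming excess so s_total does not deplete it
  ratios <- vapply(c(0.1e-6, 1e-6, 10e-6, 100e-6), function(s_tot) {
    st <- solve_speciation(make_1to1_system(s_tot, 0.5, kd))
    compose_channel_intensities(st, sp_fix, ch)$ratio
  }, numeric(1))
  expect_lt(diff(range(ratios)) / mean(ratios), 1e-3)
})

test_that("protonated form outside the passbands leaves the ratio pH-stable", {
  # spectra where the protonated band has no overlap with either channel
  sp_fix <- fixture_spectra()
  sp_fix$S.H <- species_spectrum("S.H",
                                 data.frame(center = 700, width = 5,
                                            amplitude = 1),
                                 brightness = 0.5)
  ch <- fixture_channels()
  ratios <- vapply(seq(5.5, 8, 0.5), function(ph) {
    sys <- equilibrium_system(
      list(component("S", "sensor", 10e-6),
           component("H", "proton"),
           component("Mg", "metal", 0.5)),
      list(reaction("S.H", c(S = 1, H = 1), 10^(-7.1)),
           reaction("S.Mg", c(S = 1, Mg = 1), 0.14e-3)),
      ph = ph)
    compose_channel_intensities(solve_speciation(sys), sp_fix, ch)$ratio
  }, numeric(1))
  expect_lt(diff(range(ratios)) / mean(ratios), 0.02)
})

test_that("50 uM Ca shifts the ratio less than 10 uM Mg does", {
  spectra <- magzet1_spectra()
  ch <- magzet1_channels()
  cst <- magzet1_constants()
  panel <- selectivity_panel(
    list(blank = c(), ca = c(Ca = 50e-6), mg10 = c(Mg = 10e-6)),
    constants = c(Mg = cst$kd_mg_25, Ca = cst$kd_ca),
    s_total = 1e-6, spectra = spectra, channels = ch)
  blank <- panel$ratio[panel$condition == "blank"]
  d_ca <- abs(panel$ratio[panel$condition == "ca"] - blank)
  d_mg <- abs(panel$ratio[panel$condition == "mg10"] - blank)
  expect_lt(d_ca, d_mg)
})
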