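# Independent oracles used to validate the speciation solver and the
# closed-form 1:1 result. Both are deliberately naive bracketing searches
# on the free-concentration unknowns, sharing no code with the package's
# Newton solver or quadratic formula.

# 1:1 binding: root-find the free-metal mass balance by pure bisection.
oracle_1to1_bound <- function(s_total, m_total, kd, iters = 200) {
  if (m_total == 0 || s_total == 0) return(0)
  g <- function(m) m + s_total * m / (kd + m) - m_total
  lo <- 0
  hi <- m_total
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  m <- (lo + hi) / 2
  s_total * m / (kd + m)
}

# Three-reaction system {S+Mg<->SM (kd1), Mg+ATP<->MgATP (kd2),
# S+MgATP<->SMT (kd3)}: nested bisection on free Mg (outer) and free ATP
# (inner); free S follows in closed form from the sensor mass balance.
oracle_ternary <- function(s_total, mg_total, atp_total,
                           kd1, kd2, kd3, iters = 120) {
  free_s <- function(m, a) {
    mgatp <- m * a / kd2
    s_total / (1 + m / kd1 + mgatp / kd3)
  }
  atp_balance <- function(m, a) {
    s <- free_s(m, a)
    mgatp <- m * a / kd2
    a + mgatp + s * mgatp / kd3 - atp_total
  }
  inner_a <- function(m) {
    lo <- 0
    hi <- atp_total
    for (i in seq_len(iters)) {
      mid <- (lo + hi) / 2
      if (atp_balance(m, mid) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  mg_balance <- function(m) {
    a <- inner_a(m)
    s <- free_s(m, a)
    mgatp <- m * a / kd2
    m + s * m / kd1 + mgatp + s * mgatp / kd3 - mg_total
  }
  lo <- 0
  hi <- mg_total
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (mg_balance(mid) > 0) hi <- mid else lo <- mid
  }
  m <- (lo + hi) / 2
  a <- inner_a(m)
  s <- free_s(m, a)
  mgatp <- m * a / kd2
  list(S = s, Mg = m, ATP = a,
       SM = s * m / kd1, MgATP = mgatp, SMT = s * mgatp / kd3)
}

# small two-species spectra fixture with well separated bands
fixture_spectra <- function() {
  list(
    S = species_spectrum("S", data.frame(center = 500, width = 30,
                                         amplitude = 1), brightness = 0.4),
    S.Mg = species_spectrum("S.Mg", data.frame(center = 530, width = 30,
                                               amplitude = 1),
                            brightness = 0.8))
}

fixture_channels <- function() {
  channel_set(390, data.frame(name = c("F500", "F530"),
                              center = c(500, 530), bandwidth = c(1, 1)))
}

make_1to1_system <- function(s_total, m_total, kd,
                             sensor = "S", metal = "Mg") {
  equilibrium_system(
    list(component(sensor, "sensor", s_total),
         component(metal, "metal", m_total)),
    list(reaction(paste(sensor, metal, sep = "."),
                  stats::setNames(c(1, 1), c(sensor, metal)), kd)))
}

make_ternary_system <- function(s_total, mg_total, atp_total,
                                kd1 = 0.14e-3, kd2 = 50e-6, kd3 = 0.1) {
  equilibrium_system(
    list(component("S", "sensor", s_total),
         component("Mg", "metal", mg_total),
         component("ATP", "ligand", atp_total)),
    list(reaction("S.Mg", c(S = 1, Mg = 1), kd1),
         reaction("Mg.ATP", c(Mg = 1, ATP = 1), kd2),
         reaction("S.Mg.ATP", c(S = 1, Mg.ATP = 1), kd3)))
}
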