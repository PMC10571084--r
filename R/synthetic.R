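# Synthetic-data generators with known ground truth.
#
# Every generator is a pure function of its arguments and seed: identical
# inputs give identical tables. Each table carries a machine-readable
# ground-truth record in its "truth" attribute (written alongside the CSV
# as a JSON sidecar by write_table_with_truth), so recovery tests read the
# generating parameters from the data, never from constants of their own.

# evaluate code under a fixed seed without disturbing the caller's RNG
.with_seed <- function(seed, code) {
  if (is.null(seed)) stop("a seed is required for stochastic generation")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Default log-spaced titration grid
#'
#' Fifteen log-spaced total-metal concentrations spanning a factor of 30
#' either side of the half-saturation point of the 1:1 isotherm. With
#' ligand depletion the half-saturation total is `kd + s_total/2`, which
#' reduces to `kd` in the usual `s_total << kd` regime and keeps
#' nanomolar-affinity titrations (e.g. Zn at micromolar sensor)
#' informative.
#'
#' @param kd Dissociation constant (molar).
#' @param s_total Sensor total (molar), default 0.
#' @param n Number of points (default 15).
#' @param span Half-decade span factor (default 30).
#' @return Numeric vector of metal totals (molar).
#' @export
default_titration_grid <- function(kd, s_total = 0, n = 15, span = 30) {
  mid <- kd + s_total / 2
  exp(seq(log(mid / span), log(mid * span), length.out = n))
}

# add per-channel Gaussian noise (SD = frac of each channel's dynamic
# range over the grid) and recompute the ratio
.noisify <- function(base, channel_names, numerator, denominator,
                     noise_sd, replicates) {
  out <- do.call(rbind, lapply(seq_len(replicates), function(rep) {
    d <- base
    d$replicate <- rep
    d
  }))
  if (noise_sd > 0) {
    for (ch in channel_names) {
      rng <- diff(range(base[[ch]]))
      if (rng == 0) rng <- max(abs(base[[ch]]), 1)
      out[[ch]] <- out[[ch]] + stats::rnorm(nrow(out), 0, noise_sd * rng)
      out[[ch]] <- pmax(out[[ch]], 0)
    }
  }
  out$ratio <- ifelse(out[[denominator]] > 0,
                      out[[numerator]] / out[[denominator]], NA_real_)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic 1:1 metal titration
#'
#' Composes the speciation solver and the emission model over a metal
#' grid, then adds per-replicate Gaussian noise on the channel intensities
#' (SD expressed as a fraction of each channel's dynamic range, emulating
#' triplicate cuvette titrations).
#'
#' @param kd True dissociation constant (molar).
#' @param s_total Sensor total (molar), default 10e-6.
#' @param metal_grid Metal totals (molar); default
#'   [default_titration_grid()] around `kd`.
#' @param noise_sd Noise SD as a fraction of channel dynamic range
#'   (default 0.01).
#' @param replicates Number of replicates (default 3).
#' @param seed RNG seed (required when `noise_sd > 0`).
#' @param spectra,channels Emission model.
#' @param sensor,metal Component names.
#' @param numerator,denominator Ratio channels.
#' @return Data frame with columns `metal_total`, `replicate`, one column
#'   per channel, and `ratio`; the `"truth"` attribute records the
#'   generating parameters (including `r_min`, `r_max`, `beta`).
#' @export
gen_titration_series <- function(kd, s_total = 10e-6, metal_grid = NULL,
                                 noise_sd = 0.01, replicates = 3, seed = 1,
                                 spectra = magzet1_spectra(),
                                 channels = magzet1_channels(),
                                 sensor = "MagZet1", metal = "Mg",
                                 numerator = "F530", denominator = "F500") {
  stopifnot(kd > 0, noise_sd >= 0, replicates >= 1)
  if (is.null(metal_grid)) metal_grid <- default_titration_grid(kd, s_total)
  if (is.unsorted(metal_grid, strictly = TRUE)) {
    stop("metal_grid must be strictly increasing")
  }
  base <- ratio_isotherm(kd, s_total, metal_grid, spectra, channels,
                         sensor, metal, numerator, denominator)
  chn <- channels$channels$name
  out <- .with_seed(seed, .noisify(base, chn, numerator, denominator,
                                   noise_sd, replicates))
  bounds <- ratio_bounds(spectra, channels, sensor,
                         paste(sensor, metal, sep = "."),
                         numerator, denominator)
  attr(out, "truth") <- list(kind = "titration", kd = kd, s_total = s_total,
                             metal = metal, noise_sd = noise_sd,
                             replicates = replicates, seed = seed,
                             r_min = bounds$r_min, r_max = bounds$r_max,
                             beta = bounds$beta)
  out
}

#' Generate a synthetic pH titration
#'
#' Three-species model (protonated, deprotonated-free, Mg-bound sensor):
#' at each pH the proton activity is clamped and the speciation of sensor
#' among SH+, S and S-Mg is solved with strictly competitive protonation.
#' Channel intensities follow the emission model; ratios whose denominator
#' falls below `ratio_floor` times the series maximum are flagged
#' undefined (`NA`), reflecting the loss of signal as the nearly
#' nonemissive protonated form takes over at low pH.
#'
#' @param ph_grid pH values (within 3-10), default `seq(5, 8, by = 0.25)`.
#' @param pka True sensor pKa (default 7.1).
#' @param mg_total Total Mg (molar), default 0.
#' @param kd_mg Sensor-Mg constant (molar).
#' @param s_total Sensor total (molar).
#' @param noise_sd,replicates,seed As in [gen_titration_series()].
#' @param spectra,channels Emission model (needs the protonated species
#'   `<sensor>.H`).
#' @param sensor Sensor name.
#' @param numerator,denominator Ratio channels.
#' @param ratio_floor Fraction of the maximum denominator intensity below
#'   which the ratio is reported `NA` (default 0.01).
#' @return Data frame with columns `ph`, `replicate`, channels, `ratio`;
#'   `"truth"` attribute with the generating parameters.
#' @export
gen_ph_series <- function(ph_grid = seq(5, 8, by = 0.25), pka = 7.1,
                          mg_total = 0, kd_mg = 0.14e-3, s_total = 10e-6,
                          noise_sd = 0.01, replicates = 3, seed = 1,
                          spectra = magzet1_spectra(),
                          channels = magzet1_channels(),
                          sensor = "MagZet1",
                          numerator = "F530", denominator = "F500",
                          ratio_floor = 0.01) {
  stopifnot(all(ph_grid >= 3 & ph_grid <= 10), pka > 0, noise_sd >= 0)
  rows <- lapply(ph_grid, function(ph) {
    comps <- list(component(sensor, "sensor", s_total),
                  component("H", "proton"))
    rxns <- list(reaction(paste0(sensor, ".H"),
                          stats::setNames(c(1, 1), c(sensor, "H")),
                          10^(-pka)))
    if (mg_total > 0) {
      comps <- c(comps, list(component("Mg", "metal", mg_total)))
      rxns <- c(rxns, list(reaction(paste0(sensor, ".Mg"),
                                    stats::setNames(c(1, 1),
                                                    c(sensor, "Mg")),
                                    kd_mg)))
    }
    sp <- solve_speciation(equilibrium_system(comps, rxns, ph = ph))
    meas <- compose_channel_intensities(sp, spectra, channels, numerator,
                                        denominator, x = ph)
    c(ph = ph, meas$intensities)
  })
  base <- as.data.frame(do.call(rbind, rows))
  chn <- channels$channels$name
  out <- .with_seed(seed, .noisify(base, chn, numerator, denominator,
                                   noise_sd, replicates))
  floor_abs <- ratio_floor * max(out[[denominator]])
  out$ratio[out[[denominator]] < floor_abs] <- NA_real_
  attr(out, "truth") <- list(kind = "ph", pka = pka, mg_total = mg_total,
                             kd_mg = kd_mg, s_total = s_total,
                             noise_sd = noise_sd, replicates = replicates,
                             seed = seed)
  out
}

#' Generate a synthetic MgATP competition series
#'
#' Emulates titration with MgATP prepared in situ from an equimolar
#' mixture of Mg and ATP: at each point the full speciation with the
#' binary sensor-Mg and Mg-ATP reactions — and optionally the ternary
#' sensor-Mg-ATP complex — is solved and composed into channel
#' intensities. `kd_ternary = NULL` gives the pure-competition limit
#' (no ternary complex).
#'
#' @param mgatp_grid Equimolar Mg/ATP totals (molar); default 15
#'   log-spaced points from 0.1 to 50 mM.
#' @param s_total Sensor total (molar), default 20e-6.
#' @param kd_sm,kd_mgatp Binary constants (molar).
#' @param kd_ternary Ternary constant (molar) or `NULL` for none.
#' @param ternary_scale Brightness multiplier applied to the ternary
#'   species spectrum (default 1).
#' @param noise_sd,replicates,seed As in [gen_titration_series()].
#' @param spectra,channels Emission model.
#' @param sensor Sensor name.
#' @param numerator,denominator Ratio channels.
#' @return Data frame with columns `mgatp_total`, `replicate`, channels,
#'   `ratio`; `"truth"` attribute with the generating parameters.
#' @export
gen_mgatp_series <- function(mgatp_grid = exp(seq(log(0.1e-3), log(50e-3),
                                                  length.out = 15)),
                             s_total = 20e-6,
                             kd_sm = 0.14e-3, kd_mgatp = 50e-6,
                             kd_ternary = 0.1, ternary_scale = 1,
                             noise_sd = 0.01, replicates = 3, seed = 1,
                             spectra = magzet1_spectra(),
                             channels = magzet1_channels(),
                             sensor = "MagZet1",
                             numerator = "F530", denominator = "F500") {
  stopifnot(s_total > 0, kd_sm > 0, kd_mgatp > 0, noise_sd >= 0)
  spectra <- .as_spectra_list(spectra)
  nm <- vapply(spectra, `[[`, character(1), "name")
  names(spectra) <- nm
  tern <- paste0(sensor, ".Mg.ATP")
  if (!is.null(kd_ternary) && tern %in% nm) {
    spectra[[tern]]$brightness <- spectra[[tern]]$brightness * ternary_scale
  }
  rows <- lapply(mgatp_grid, function(tot) {
    rxns <- list(reaction(paste0(sensor, ".Mg"),
                          stats::setNames(c(1, 1), c(sensor, "Mg")), kd_sm),
                 reaction("Mg.ATP", c(Mg = 1, ATP = 1), kd_mgatp))
    if (!is.null(kd_ternary)) {
      rxns <- c(rxns, list(reaction(tern,
                                    stats::setNames(c(1, 1),
                                                    c(sensor, "Mg.ATP")),
                                    kd_ternary)))
    }
    sys <- equilibrium_system(
      list(component(sensor, "sensor", s_total),
           component("Mg", "metal", tot),
           component("ATP", "ligand", tot)),
      rxns)
    sp <- solve_speciation(sys)
    meas <- compose_channel_intensities(sp, spectra, channels, numerator,
                                        denominator, x = tot)
    c(mgatp_total = tot, meas$intensities)
  })
  base <- as.data.frame(do.call(rbind, rows))
  chn <- channels$channels$name
  out <- .with_seed(seed, .noisify(base, chn, numerator, denominator,
                                   noise_sd, replicates))
  attr(out, "truth") <- list(kind = "mgatp", s_total = s_total,
                             kd_sm = kd_sm, kd_mgatp = kd_mgatp,
                             kd_ternary = kd_ternary,
                             ternary_scale = ternary_scale,
                             noise_sd = noise_sd, replicates = replicates,
                             seed = seed)
  out
}

#' Standard cell-population conditions
#'
#' Free-Mg settings emulating the flow-cytometry study arms: untreated
#' vehicle cells at a typical cytosolic free Mg of 0.5 mM, metal-depleted
#' cells (EDTA co-loading, free Mg near zero), and ionophore-equilibrated
#' cells in 50 mM extracellular Mg (saturating).
#'
#' @return Named list of per-group parameter lists (`free_mg` in molar,
#'   `cv` coefficient of variation of free Mg across cells).
#' @export
cell_population_presets <- function() {
  list(vehicle = list(free_mg = 0.5e-3, cv = 0.1),
       edta = list(free_mg = 1e-6, cv = 0.1),
       ionophore_mg = list(free_mg = 50e-3, cv = 0.1))
}

#' Generate a synthetic per-cell two-channel population
#'
#' Per cell: a log-normal dye loading L (AM-ester loading heterogeneity)
#' and a log-normal free-Mg level M are drawn; channel intensities are
#' `L * ((1 - f) * S_free + f * S_bound) + additive noise`, where
#' `f = M / (kd + M)` is the fractional saturation and `S` are the
#' per-channel band-integrated signals of the free and Mg-bound sensor.
#'
#' @param n_cells Events per group (default 1000).
#' @param groups Named list of per-group parameters with elements
#'   `free_mg` (molar median) and `cv`; default
#'   [cell_population_presets()].
#' @param kd Sensor-Mg constant (molar).
#' @param loading_meanlog,loading_sdlog Log-normal dye-loading parameters
#'   (defaults `log(100)` and 0.5).
#' @param noise_sd Additive per-channel Gaussian noise SD in intensity
#'   units (default 0.5).
#' @param seed RNG seed.
#' @param spectra Emission model (free and Mg-bound sensor species).
#' @param channels Detection channels, default [flow_channels()].
#' @param sensor Sensor name.
#' @return Data frame with columns `event_id`, one column per channel and
#'   `group`; `"truth"` attribute with generating parameters and the
#'   channel-space `r_min`/`r_max`.
#' @export
gen_cell_population <- function(n_cells = 1000,
                                groups = cell_population_presets(),
                                kd = 0.14e-3,
                                loading_meanlog = log(100),
                                loading_sdlog = 0.5,
                                noise_sd = 0.5, seed = 1,
                                spectra = magzet1_spectra(),
                                channels = flow_channels(),
                                sensor = "MagZet1") {
  stopifnot(n_cells >= 1, kd > 0, loading_sdlog >= 0, noise_sd >= 0)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("groups must be a named list")
  }
  for (g in groups) {
    if (is.null(g$free_mg) || g$free_mg < 0 || is.null(g$cv) || g$cv < 0) {
      stop("each group needs free_mg >= 0 and cv >= 0")
    }
  }
  spectra <- .as_spectra_list(spectra)
  nm <- vapply(spectra, `[[`, character(1), "name")
  bound <- paste0(sensor, ".Mg")
  if (!all(c(sensor, bound) %in% nm)) {
    stop("spectra must include the free and Mg-bound sensor species")
  }
  sig <- .signal_matrix(spectra[match(c(sensor, bound), nm)], channels)
  chn <- channels$channels$name
  .with_seed(seed, {
    blocks <- lapply(names(groups), function(gname) {
      g <- groups[[gname]]
      L <- stats::rlnorm(n_cells, loading_meanlog, loading_sdlog)
      M <- if (g$free_mg == 0 || g$cv == 0) {
        rep(g$free_mg, n_cells)
      } else {
        sdlog <- sqrt(log(1 + g$cv^2))
        stats::rlnorm(n_cells, log(g$free_mg), sdlog)
      }
      f <- fraction_bound(kd, M)
      vals <- lapply(seq_along(chn), function(j) {
        I <- L * ((1 - f) * sig[sensor, j] + f * sig[bound, j])
        if (noise_sd > 0) I <- I + stats::rnorm(n_cells, 0, noise_sd)
        pmax(I, 0)
      })
      d <- as.data.frame(stats::setNames(vals, chn))
      d$group <- gname
      d
    })
    out <- do.call(rbind, blocks)
    out <- cbind(event_id = seq_len(nrow(out)), out)
    attr(out, "truth") <- list(kind = "cells", n_cells = n_cells,
                               groups = groups, kd = kd,
                               loading_meanlog = loading_meanlog,
                               loading_sdlog = loading_sdlog,
                               noise_sd = noise_sd, seed = seed,
                               r_min = sig[sensor, 2] / sig[sensor, 1],
                               r_max = sig[bound, 2] / sig[bound, 1])
    out
  })
}
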