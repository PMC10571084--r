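# Species-resolved emission model and two-channel ratio composition.
#
# Each emissive species carries a sum-of-Gaussian-bands emission profile and
# a relative brightness (proportional to epsilon x phi). Channel intensities
# are concentration-weighted sums of per-species band integrals over the
# channel passband; the ratio of two named channels is the ratiometric
# readout.

#' Define a species emission spectrum
#'
#' @param name Species name; must match a free component or complex name in
#'   the speciation result it will be composed with.
#' @param bands Data frame (or matrix) with columns `center`, `width`,
#'   `amplitude`: Gaussian band center (nm), standard deviation (nm), and
#'   peak amplitude (arbitrary units).
#' @param brightness Relative brightness scale, proportional to the product
#'   of the extinction coefficient and the quantum yield. A species with
#'   brightness 0 contributes nothing to any channel.
#' @param absorption_max,emission_max Optional metadata (nm).
#' @return An object of class `species_spectrum`.
#' @examples
#' species_spectrum("MagZet1.Mg", data.frame(center = 530, width = 34,
#'                                           amplitude = 1), brightness = 0.76)
#' @export
species_spectrum <- function(name, bands, brightness = 1,
                             absorption_max = NA_real_,
                             emission_max = NA_real_) {
  bands <- as.data.frame(bands)
  stopifnot(all(c("center", "width", "amplitude") %in% names(bands)),
            nrow(bands) >= 1L)
  if (any(bands$width <= 0)) stop("band widths must be > 0")
  if (any(bands$amplitude < 0)) stop("band amplitudes must be >= 0")
  if (!is.numeric(brightness) || length(brightness) != 1L || brightness < 0) {
    stop("brightness must be a single non-negative number")
  }
  structure(list(name = name, bands = bands, brightness = brightness,
                 absorption_max = absorption_max,
                 emission_max = emission_max),
            class = "species_spectrum")
}

#' Define excitation and detection channels
#'
#' @param excitation Excitation wavelength in nm (metadata only; excitation
#'   efficiency differences are folded into per-species brightness).
#' @param channels Data frame with columns `name`, `center` (nm),
#'   `bandwidth` (nm). At least two channels are required to form a ratio.
#' @return An object of class `channel_set`.
#' @examples
#' channel_set(390, data.frame(name = c("F500", "F530"),
#'                             center = c(500, 530), bandwidth = c(1, 1)))
#' @export
channel_set <- function(excitation, channels) {
  channels <- as.data.frame(channels)
  stopifnot(all(c("name", "center", "bandwidth") %in% names(channels)))
  if (nrow(channels) < 2L) stop("at least two channels are required")
  if (any(channels$bandwidth <= 0)) stop("channel bandwidths must be > 0")
  if (anyDuplicated(channels$name)) stop("channel names must be unique")
  structure(list(excitation = excitation, channels = channels),
            class = "channel_set")
}

#' Evaluate a species emission spectrum on a wavelength grid
#'
#' Sum of Gaussian bands scaled by the species brightness.
#'
#' @param spectrum A [species_spectrum()].
#' @param wavelength_grid Numeric vector of wavelengths (nm), within
#'   300-800 nm.
#' @return Intensity at each grid point (>= 0, linear in brightness).
#' @export
evaluate_spectrum <- function(spectrum, wavelength_grid) {
  stopifnot(inherits(spectrum, "species_spectrum"))
  if (length(wavelength_grid) == 0L) stop("empty wavelength grid")
  if (any(wavelength_grid < 300 | wavelength_grid > 800)) {
    stop("wavelength grid must lie within 300-800 nm")
  }
  out <- numeric(length(wavelength_grid))
  for (i in seq_len(nrow(spectrum$bands))) {
    b <- spectrum$bands[i, ]
    out <- out + b$amplitude *
      exp(-((wavelength_grid - b$center)^2) / (2 * b$width^2))
  }
  spectrum$brightness * out
}

# Per-mole channel signal: trapezoid integral of the spectrum over the
# passband on a 1 nm grid. Channels narrower than 1 nm behave as
# single-wavelength reads scaled by their bandwidth.
.channel_signal <- function(spectrum, center, bandwidth) {
  lo <- center - bandwidth / 2
  hi <- center + bandwidth / 2
  if (bandwidth <= 1) {
    return(evaluate_spectrum(spectrum, center) * bandwidth)
  }
  grid <- seq(lo, hi, length.out = max(2L, ceiling(bandwidth) + 1L))
  y <- evaluate_spectrum(spectrum, grid)
  sum(diff(grid) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# Matrix of per-mole channel signals [species x channels] for the spectra
# present; species without spectra contribute zero.
.signal_matrix <- function(spectra, channels) {
  ch <- channels$channels
  out <- matrix(0, nrow = length(spectra), ncol = nrow(ch),
                dimnames = list(vapply(spectra, `[[`, character(1), "name"),
                                ch$name))
  for (s in seq_along(spectra)) {
    for (j in seq_len(nrow(ch))) {
      out[s, j] <- .channel_signal(spectra[[s]], ch$center[j], ch$bandwidth[j])
    }
  }
  out
}

#' Compose channel intensities and ratio from a speciation state
#'
#' Each channel intensity is the concentration-weighted sum over emissive
#' species of the species' band integral across the channel passband.
#' Sensor-containing species with nonzero concentration but no spectrum are
#' treated as dark (brightness 0) with a warning.
#'
#' @param speciation A `speciation_result` from [solve_speciation()].
#' @param spectra Named list of [species_spectrum()] objects (names are the
#'   species they describe).
#' @param channels A [channel_set()].
#' @param numerator,denominator Channel names forming the reported ratio.
#' @param x Optional value of the independent variable (metal concentration
#'   or pH) stored with the measurement.
#' @return An object of class `ratio_measurement`: list with `x`,
#'   `intensities` (named), `ratio`, `valid` (FALSE when the denominator
#'   intensity is not positive; the ratio is then `NA`, not an error) and
#'   `replicate`.
#' @export
compose_channel_intensities <- function(speciation, spectra, channels,
                                        numerator = "F530",
                                        denominator = "F500",
                                        x = NA_real_) {
  stopifnot(inherits(speciation, "speciation_result"),
            inherits(channels, "channel_set"))
  chn <- channels$channels$name
  if (!all(c(numerator, denominator) %in% chn)) {
    stop("numerator/denominator must name channels in the channel set")
  }
  conc_all <- c(speciation$free, speciation$complexes)
  spectra <- .as_spectra_list(spectra)
  have <- vapply(spectra, `[[`, character(1), "name")
  # warn about emissive-looking species (sensor-containing complexes or free
  # sensor) that carry concentration but have no spectrum
  missing_sp <- setdiff(names(conc_all)[conc_all > 0], have)
  if (length(have)) {
    missing_sp <- missing_sp[grepl(paste(have, collapse = "|"),
                                   missing_sp, fixed = FALSE)]
  }
  if (length(missing_sp)) {
    warning("species without spectra treated as dark: ",
            paste(missing_sp, collapse = ", "))
  }
  sig <- .signal_matrix(spectra, channels)
  conc <- conc_all[have]
  conc[is.na(conc)] <- 0
  intensities <- as.numeric(conc %*% sig)
  names(intensities) <- colnames(sig)
  den <- intensities[[denominator]]
  valid <- is.finite(den) && den > 0
  structure(list(x = x,
                 intensities = intensities,
                 ratio = if (valid) intensities[[numerator]] / den else NA_real_,
                 numerator = numerator, denominator = denominator,
                 valid = valid, replicate = NA_integer_),
            class = "ratio_measurement")
}

.as_spectra_list <- function(spectra) {
  if (inherits(spectra, "species_spectrum")) spectra <- list(spectra)
  lapply(spectra, function(s) {
    if (!inherits(s, "species_spectrum")) stop("spectra must be species_spectrum objects")
    s
  })
}

#' Predicted ratio isotherm for a 1:1 titration
#'
#' Composes [solve_speciation()] and [compose_channel_intensities()] over a
#' grid of total metal concentrations for a single sensor + metal system.
#'
#' @param kd Dissociation constant of the sensor-metal complex (molar).
#' @param s_total Total sensor concentration (molar).
#' @param metal_grid Total metal concentrations (molar), length >= 1.
#' @param spectra Named list of spectra; must contain entries for the free
#'   sensor and the bound complex.
#' @param channels A [channel_set()].
#' @param sensor,metal Component names (defaults `"MagZet1"`, `"Mg"`); the
#'   complex is named `<sensor>.<metal>`.
#' @param numerator,denominator Ratio channel names.
#' @return Data frame with columns `metal_total`, one column per channel,
#'   and `ratio`.
#' @export
ratio_isotherm <- function(kd, s_total, metal_grid, spectra, channels,
                           sensor = "MagZet1", metal = "Mg",
                           numerator = "F530", denominator = "F500") {
  stopifnot(kd > 0, s_total >= 0, length(metal_grid) >= 1)
  cplx <- paste(sensor, metal, sep = ".")
  rows <- lapply(metal_grid, function(m) {
    sys <- equilibrium_system(
      list(component(sensor, "sensor", s_total),
           component(metal, "metal", m)),
      list(reaction(cplx, stats::setNames(c(1, 1), c(sensor, metal)), kd)))
    sp <- solve_speciation(sys)
    meas <- compose_channel_intensities(sp, spectra, channels,
                                        numerator, denominator, x = m)
    c(metal_total = m, meas$intensities, ratio = meas$ratio)
  })
  out <- as.data.frame(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Ratio bounds and calibration constants of a two-species system
#'
#' Computes `r_min` (all sensor free), `r_max` (all sensor bound) and the
#' denominator-brightness ratio `beta` (free over bound) used in the
#' ratiometric inversion.
#'
#' @inheritParams ratio_isotherm
#' @param free_species,bound_species Names of the free and bound sensor
#'   species in `spectra`.
#' @return List with `r_min`, `r_max`, `beta`.
#' @export
ratio_bounds <- function(spectra, channels,
                         free_species = "MagZet1",
                         bound_species = "MagZet1.Mg",
                         numerator = "F530", denominator = "F500") {
  spectra <- .as_spectra_list(spectra)
  nm <- vapply(spectra, `[[`, character(1), "name")
  sig <- .signal_matrix(spectra, channels)
  if (!all(c(free_species, bound_species) %in% nm)) {
    stop("spectra must include the free and bound species")
  }
  list(r_min = sig[free_species, numerator] / sig[free_species, denominator],
       r_max = sig[bound_species, numerator] / sig[bound_species, denominator],
       beta = sig[free_species, denominator] / sig[bound_species, denominator])
}

#' Invert a fluorescence ratio to free metal concentration
#'
#' Standard ratiometric calibration:
#' `[M]_free = kd * beta * (R - r_min) / (r_max - R)`, where `beta` is the
#' ratio of denominator-channel brightness of the free over the bound form.
#'
#' @param ratio Measured ratio, strictly between `r_min` and `r_max`.
#' @param r_min,r_max Ratio limits for fully free / fully bound sensor.
#' @param kd Dissociation constant (molar).
#' @param beta Denominator-brightness ratio (free/bound), > 0.
#' @return Free metal concentration in molar; strictly increasing in
#'   `ratio`.
#' @export
ratio_to_free_metal <- function(ratio, r_min, r_max, kd, beta) {
  stopifnot(kd > 0, beta > 0, r_min < r_max)
  if (any(ratio <= r_min)) {
    stop("ratio at or below r_min: sensor fully in the metal-free form")
  }
  if (any(ratio >= r_max)) {
    stop("ratio at or above r_max: sensor saturated with metal")
  }
  kd * beta * (ratio - r_min) / (r_max - ratio)
}

#' Bundled emission spectra for the MagZet1 sensor forms
#'
#' Gaussian-band fixtures with emission maxima at 500 nm (metal-free),
#' 530 nm (Mg-bound), 520 nm (Ca-bound), 545 nm (Zn-bound) and 630 nm
#' (protonated), and brightness following the measured quantum yields where
#' available (free 40.4%, Mg-bound 76%). Band widths and the Ca-/Zn-bound
#' and protonated brightness values are synthetic modeling choices: those
#' quantum yields were not determined experimentally, and the protonated
#' form is modeled as nearly nonemissive and strongly red-shifted.
#'
#' @param sensor Sensor species prefix (default `"MagZet1"`).
#' @param width Gaussian band standard deviation in nm (default 34,
#'   corresponding to roughly 80 nm full width at half maximum).
#' @return Named list of [species_spectrum()] objects for the free sensor
#'   and its Mg, Ca, Zn, proton and ternary Mg-ATP adducts.
#' @export
magzet1_spectra <- function(sensor = "MagZet1", width = 34) {
  band <- function(center, w = width) {
    data.frame(center = center, width = w, amplitude = 1)
  }
  sp <- list(
    species_spectrum(sensor, band(500), brightness = 0.404,
                     absorption_max = 490, emission_max = 500),
    species_spectrum(paste0(sensor, ".Mg"), band(530), brightness = 0.76,
                     absorption_max = 395, emission_max = 530),
    species_spectrum(paste0(sensor, ".Ca"), band(520), brightness = 0.40,
                     absorption_max = 383, emission_max = 520),
    species_spectrum(paste0(sensor, ".Zn"), band(545), brightness = 0.20,
                     absorption_max = 410, emission_max = 545),
    species_spectrum(paste0(sensor, ".H"), band(630, 40), brightness = 0.02,
                     absorption_max = 480, emission_max = 630),
    species_spectrum(paste0(sensor, ".Mg.ATP"), band(530), brightness = 0.76,
                     emission_max = 530))
  stats::setNames(sp, vapply(sp, `[[`, character(1), "name"))
}

#' Standard channel sets
#'
#' `magzet1_channels()` gives the in vitro two-wavelength readout
#' (excitation 390 nm; F500 and F530 as 1 nm passbands, ratio F530/F500).
#' `flow_channels()` gives the flow-cytometry configuration (405 nm
#' excitation; 450/50 and 530/30 bandpass filters).
#'
#' @return A [channel_set()].
#' @export
magzet1_channels <- function() {
  channel_set(390, data.frame(name = c("F500", "F530"),
                              center = c(500, 530), bandwidth = c(1, 1)))
}

#' @rdname magzet1_channels
#' @export
flow_channels <- function() {
  channel_set(405, data.frame(name = c("BP450", "BP530"),
                              center = c(450, 530), bandwidth = c(50, 30)))
}
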