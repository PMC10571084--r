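# Configuration files, unit handling, preset constants, CSV/JSON I/O and
# run manifests. All physical quantities in config files carry explicit
# unit tags; everything is converted to molar internally.

.unit_factors <- c(M = 1, mM = 1e-3, uM = 1e-6, "µM" = 1e-6, nM = 1e-9)

#' Convert a tagged concentration to molar
#'
#' @param value Numeric value(s).
#' @param unit Unit string: `"M"`, `"mM"`, `"uM"` (or the micro sign
#'   variant), `"nM"`.
#' @return Concentration in molar.
#' @export
to_molar <- function(value, unit) {
  if (!unit %in% names(.unit_factors)) {
    stop("unknown concentration unit '", unit, "'")
  }
  value * .unit_factors[[unit]]
}

#' Literature constants for the MagZet1 / MagDMA sensor pair
#'
#' Apparent dissociation constants and the sensor pKa measured in aqueous
#' buffer (50 mM PIPES, 100 mM KCl, pH 7.0), as molar values: MagZet1
#' Kd,Mg 0.14 mM (25 C) and 0.088 mM (37 C), Kd,Ca 1.7 mM, Kd,Zn 2.6 nM,
#' pKa 7.1, the MgATP constant 50 uM and the ternary
#' sensor-Mg-ATP constant 100 mM; MagDMA Kd,Mg 0.22 mM and Kd,Ca 2.2 mM.
#'
#' @return Named list of constants (molar; `pka` unitless).
#' @export
magzet1_constants <- function() {
  list(kd_mg_25 = 0.14e-3,
       kd_mg_37 = 0.088e-3,
       kd_ca = 1.7e-3,
       kd_zn = 2.6e-9,
       pka = 7.1,
       kd_mgatp = 50e-6,
       kd_ternary = 100e-3,
       magdma_kd_mg = 0.22e-3,
       magdma_kd_ca = 2.2e-3,
       medium = "50 mM PIPES, 100 mM KCl, pH 7.0")
}

#' Load a system configuration file
#'
#' Reads a YAML configuration describing components, reactions (with
#' explicit units), optional pH, species spectra and detection channels,
#' and returns validated package objects. The bundled MagZet1 preset is
#' available via `magzet1_config_path()`.
#'
#' @param path Path to the YAML file.
#' @return List with elements `system` ([equilibrium_system()]), `spectra`
#'   (named list of [species_spectrum()]) and `channels`
#'   ([channel_set()]); `spectra`/`channels` are `NULL` when the file does
#'   not define them.
#' @export
load_system_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$components)) stop("config is missing 'components'")
  comps <- lapply(cfg$components, function(x) {
    if (is.null(x$name)) stop("component entry is missing 'name'")
    if (is.null(x$role)) stop("component '", x$name, "' is missing 'role'")
    total <- 0
    if (!identical(x$role, "proton")) {
      if (is.null(x$total)) stop("component '", x$name, "' is missing 'total'")
      total <- to_molar(x$total, if (is.null(x$unit)) "M" else x$unit)
    }
    component(x$name, x$role, total)
  })
  rxns <- lapply(cfg$reactions, function(x) {
    if (is.null(x$product)) stop("reaction entry is missing 'product'")
    if (is.null(x$kd)) stop("reaction '", x$product, "' is missing 'kd'")
    kd <- to_molar(x$kd, if (is.null(x$unit)) "M" else x$unit)
    st <- unlist(x$stoichiometry)
    reaction(x$product, st, kd,
             temperature = if (is.null(x$temperature)) NA_character_
                           else x$temperature,
             medium = if (is.null(x$medium)) NA_character_ else x$medium)
  })
  system <- equilibrium_system(comps, rxns, ph = cfg$ph)
  spectra <- NULL
  if (!is.null(cfg$spectra)) {
    spectra <- lapply(cfg$spectra, function(x) {
      bands <- do.call(rbind, lapply(x$bands, function(b) {
        data.frame(center = b$center, width = b$width,
                   amplitude = if (is.null(b$amplitude)) 1 else b$amplitude)
      }))
      species_spectrum(x$name, bands, brightness = x$brightness,
                       absorption_max = if (is.null(x$absorption_max))
                         NA_real_ else x$absorption_max,
                       emission_max = if (is.null(x$emission_max))
                         NA_real_ else x$emission_max)
    })
    names(spectra) <- vapply(spectra, `[[`, character(1), "name")
  }
  chans <- NULL
  if (!is.null(cfg$channels)) {
    ch <- do.call(rbind, lapply(cfg$channels$detect, function(x) {
      data.frame(name = x$name, center = x$center, bandwidth = x$bandwidth)
    }))
    chans <- channel_set(cfg$channels$excitation, ch)
  }
  list(system = system, spectra = spectra, channels = chans)
}

#' Write a system configuration file
#'
#' Serializes a system (plus optional spectra and channels) to YAML with
#' all concentrations in molar; [load_system_config()] on the result
#' reproduces the objects.
#'
#' @param config List with elements `system` and optionally `spectra`,
#'   `channels` (as returned by [load_system_config()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_system_config <- function(config, path) {
  sys <- config$system
  stopifnot(inherits(sys, "equilibrium_system"))
  cfg <- list(
    components = lapply(sys$components, function(x) {
      out <- list(name = x$name, role = x$role)
      if (x$role != "proton") {
        out$total <- x$total
        out$unit <- "M"
      }
      out
    }),
    reactions = lapply(sys$reactions, function(x) {
      out <- list(product = x$product,
                  stoichiometry = as.list(x$stoichiometry),
                  kd = x$kd, unit = "M")
      if (!is.na(x$temperature)) out$temperature <- x$temperature
      if (!is.na(x$medium)) out$medium <- x$medium
      out
    }))
  if (!is.null(sys$ph)) cfg$ph <- sys$ph
  if (!is.null(config$spectra)) {
    cfg$spectra <- lapply(unname(config$spectra), function(s) {
      out <- list(name = s$name,
                  bands = lapply(seq_len(nrow(s$bands)), function(i) {
                    as.list(s$bands[i, c("center", "width", "amplitude")])
                  }),
                  brightness = s$brightness)
      if (!is.na(s$absorption_max)) out$absorption_max <- s$absorption_max
      if (!is.na(s$emission_max)) out$emission_max <- s$emission_max
      out
    })
  }
  if (!is.null(config$channels)) {
    ch <- config$channels
    cfg$channels <- list(
      excitation = ch$excitation,
      detect = lapply(seq_len(nrow(ch$channels)), function(i) {
        as.list(ch$channels[i, c("name", "center", "bandwidth")])
      }))
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Path to the bundled MagZet1 system preset
#'
#' YAML configuration encoding the MagZet1 competition system (sensor,
#' Mg, Ca, Zn, ATP, MgATP and the ternary complex) with the literature
#' constants of [magzet1_constants()], plus the emission-band fixtures and
#' the two-wavelength channel set.
#'
#' @return File path within the installed package.
#' @export
magzet1_config_path <- function() {
  system.file("extdata", "magzet1_system.yaml", package = "magsense",
              mustWork = TRUE)
}

#' Write a data table with its ground-truth sidecar
#'
#' Writes `x` as CSV and its `"truth"` attribute (if present) as a JSON
#' sidecar named `<path>.truth.json`, so downstream recovery checks can
#' read the generating parameters from disk.
#'
#' @param x Data frame (typically from a `gen_*` generator).
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_table_with_truth <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  truth <- attr(x, "truth")
  if (!is.null(truth)) {
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a data table and its ground-truth sidecar
#'
#' @param path CSV path previously written by [write_table_with_truth()].
#' @return Data frame with the `"truth"` attribute restored when the
#'   sidecar exists.
#' @export
read_table_with_truth <- function(path) {
  x <- utils::read.csv(path)
  sidecar <- paste0(path, ".truth.json")
  if (file.exists(sidecar)) {
    attr(x, "truth") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  x
}

#' Append a run manifest entry
#'
#' Records one pipeline invocation (command, seed, input/output paths,
#' config file checksum, package version, timestamp) as a JSON line
#' appended to a manifest file, making runs reproducible from the
#' manifest alone.
#'
#' @param manifest_path Manifest file (created if absent; append-only).
#' @param command Command or function name.
#' @param seed Seed(s) used, or `NULL`.
#' @param config_path Optional config file; its MD5 checksum is recorded.
#' @param inputs,outputs Character vectors of file paths.
#' @return The manifest entry, invisibly.
#' @export
write_run_manifest <- function(manifest_path, command, seed = NULL,
                               config_path = NULL, inputs = character(),
                               outputs = character()) {
  entry <- list(command = command,
                seed = seed,
                config = config_path,
                config_md5 = if (!is.null(config_path) &&
                                 file.exists(config_path)) {
                  unname(tools::md5sum(config_path))
                },
                inputs = inputs,
                outputs = outputs,
                package_version =
                  as.character(utils::packageVersion("magsense")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  line <- jsonlite::toJSON(entry, auto_unbox = TRUE, null = "null")
  con <- file(manifest_path, open = "a")
  on.exit(close(con))
  writeLines(line, con)
  invisible(entry)
}
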