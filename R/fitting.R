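# Nonlinear least-squares estimation of binding and protonation constants
# from titration data. All positive parameters (kd, beta, brightness
# scales) are fitted on the log scale so that Levenberg-Marquardt behaves
# across the nine-orders-of-magnitude range of the constants involved
# (low-nM Zn to 100 mM ternary); standard errors come from the Jacobian at
# the optimum with delta-method back-transformation.

.fit_result <- function(estimates, se, cov, rss, converged, n, fixed = list(),
                        flags = character(), message = NULL) {
  structure(list(estimates = estimates, se = se, cov = cov, rss = rss,
                 converged = converged, n = n, fixed = fixed,
                 flags = flags, message = message),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Nonlinear least-squares fit (",
      if (x$converged) "converged" else "NOT converged",
      ", n = ", x$n, ", RSS = ", format(x$rss, digits = 4), ")\n", sep = "")
  tab <- data.frame(estimate = x$estimates,
                    se = x$se[names(x$estimates)])
  print(signif(tab, 5))
  if (length(x$fixed)) {
    cat("Fixed:", paste(names(x$fixed), unlist(x$fixed), sep = " = ",
                        collapse = ", "), "\n")
  }
  if (length(x$flags)) cat("Flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# Run nls.lm and return estimates/SEs on the natural scale. `trans` marks
# which internal parameters are log-transformed.
.lm_fit <- function(start, resid_fn, trans, lower = NULL, upper = NULL) {
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                     ptol = 1e-12)
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn, control = ctrl,
                            lower = lower, upper = upper)
  p <- fit$par
  r <- resid_fn(p)
  n <- length(r)
  k <- length(p)
  # numeric Jacobian at the optimum (internal scale)
  J <- matrix(0, n, k)
  h <- 1e-6
  for (j in seq_len(k)) {
    pj <- p
    pj[j] <- pj[j] + h
    J[, j] <- (resid_fn(pj) - r) / h
  }
  rss <- sum(r^2)
  sigma2 <- if (n > k) rss / (n - k) else 0
  cov_int <- tryCatch(sigma2 * solve(crossprod(J)),
                      error = function(e) matrix(NA_real_, k, k))
  se_int <- sqrt(pmax(diag(cov_int), 0))
  est <- p
  se <- se_int
  for (j in seq_len(k)) {
    if (trans[j]) {            # delta method: se(exp(x)) = exp(x) * se(x)
      est[j] <- exp(p[j])
      se[j] <- est[j] * se_int[j]
    }
  }
  names(se) <- names(est)
  list(estimates = est, se = se, cov = cov_int, rss = rss,
       converged = fit$info %in% 1:4, n = n, info = fit$info,
       par_internal = p)
}

# Two-species ratio model given the bound fraction fb:
# R = (r_min * beta * (1-fb) + r_max * fb) / (beta * (1-fb) + fb)
.ratio_from_fb <- function(fb, r_min, r_max, beta) {
  (r_min * beta * (1 - fb) + r_max * fb) / (beta * (1 - fb) + fb)
}

#' Fit an apparent dissociation constant from a ratiometric titration
#'
#' Estimates `kd`, `r_min`, `r_max` and the denominator-brightness ratio
#' `beta` by least squares on the measured ratios. The model computes the
#' bound sensor fraction per titration point from the exact 1:1 mass
#' balance (ligand depletion included, which matters for nM-affinity
#' metals at micromolar sensor concentrations) and maps it to a ratio via
#' the two-species mixing formula.
#'
#' In the tracer regime (`s_total << kd`, negligible depletion) the ratio
#' curve depends on `kd` and `beta` only through their product, so the two
#' cannot be separated by the fit: supply `beta` from an independent
#' spectral calibration (e.g. [ratio_bounds()]) to estimate `kd` itself.
#' With `beta = NULL` all four parameters are estimated, which is reliable
#' only when depletion is appreciable (sensor comparable to or above the
#' dissociation constant).
#'
#' @param titration Data frame with columns `metal_total` (molar) and
#'   `ratio`; an optional `replicate` column is used for the noise-level
#'   estimate and replicate-SD reporting.
#' @param s_total Total sensor concentration (molar).
#' @param beta Denominator-brightness ratio to hold fixed, or `NULL` to
#'   estimate it (see Details).
#' @param start Optional named list overriding starting values
#'   (`kd`, `r_min`, `r_max`, `beta`).
#' @return A `fit_result` with estimates, standard errors, covariance
#'   (internal scale), residual sum of squares and, when replicates are
#'   present, the per-replicate kd spread under `$replicate_sd`.
#' @export
fit_kd_ratio <- function(titration, s_total, beta = NULL, start = NULL) {
  titration <- as.data.frame(titration)
  stopifnot(all(c("metal_total", "ratio") %in% names(titration)),
            s_total > 0)
  titration <- titration[is.finite(titration$ratio), , drop = FALSE]
  m <- titration$metal_total
  r <- titration$ratio
  if (max(m) <= 0) {
    stop("uninformative data: no titration point contains metal")
  }
  if (length(unique(m)) < 5L) {
    stop("need at least 5 distinct metal concentrations")
  }
  dr <- diff(range(r))
  noise_sd <- 0
  if (!is.null(titration$replicate) &&
      length(unique(titration$replicate)) > 1L) {
    noise_sd <- mean(tapply(r, m, stats::sd), na.rm = TRUE)
    if (!is.finite(noise_sd)) noise_sd <- 0
  }
  if (dr < max(3 * noise_sd, 1e-10 * max(abs(r), 1))) {
    stop("uninformative data: ratio dynamic range below 3x the noise level")
  }

  agg <- tapply(r, m, mean)
  mu <- as.numeric(names(agg))
  r_min0 <- agg[[1]]
  r_max0 <- agg[[length(agg)]]
  half <- (r_min0 + r_max0) / 2
  m_half <- mu[which.min(abs(agg - half))]
  if (m_half <= 0) m_half <- stats::median(mu[mu > 0])
  # with depletion the half-saturation total is kd + s_total/2
  kd0 <- max(m_half - s_total / 2, m_half / 100)
  if (!is.null(start)) {
    if (!is.null(start$kd)) kd0 <- start$kd
    if (!is.null(start$r_min)) r_min0 <- start$r_min
    if (!is.null(start$r_max)) r_max0 <- start$r_max
  }
  beta0 <- if (!is.null(start$beta)) start$beta else 1
  fixed_beta <- !is.null(beta)
  if (fixed_beta) stopifnot(is.numeric(beta), beta > 0)

  resid_fn <- function(p) {
    kd <- exp(p[["log_kd"]])
    bt <- if (fixed_beta) beta else exp(p[["log_beta"]])
    fb <- closed_form_1to1(s_total, m, kd) / s_total
    .ratio_from_fb(fb, p[["r_min"]], p[["r_max"]], bt) - r
  }
  if (fixed_beta) {
    fit <- .lm_fit(c(log_kd = log(kd0), r_min = r_min0, r_max = r_max0),
                   resid_fn, trans = c(TRUE, FALSE, FALSE),
                   lower = c(log(1e-15), -Inf, -Inf),
                   upper = c(log(1e3), Inf, Inf))
    names(fit$estimates) <- c("kd", "r_min", "r_max")
  } else {
    fit <- .lm_fit(c(log_kd = log(kd0), r_min = r_min0, r_max = r_max0,
                     log_beta = log(beta0)),
                   resid_fn, trans = c(TRUE, FALSE, FALSE, TRUE),
                   lower = c(log(1e-15), -Inf, -Inf, log(1e-6)),
                   upper = c(log(1e3), Inf, Inf, log(1e6)))
    names(fit$estimates) <- c("kd", "r_min", "r_max", "beta")
  }
  names(fit$se) <- names(fit$estimates)
  fixed <- list(s_total = s_total)
  if (fixed_beta) fixed$beta <- beta
  out <- .fit_result(fit$estimates, fit$se, fit$cov, fit$rss, fit$converged,
                     fit$n, fixed = fixed)
  # Table-1-style replicate spread: refit each replicate independently
  if (!is.null(titration$replicate) &&
      length(unique(titration$replicate)) > 1L) {
    kds <- vapply(split(titration, titration$replicate), function(d) {
      tryCatch(fit_kd_ratio(d[setdiff(names(d), "replicate")],
                            s_total, beta = beta,
                            start = as.list(fit$estimates))$
                 estimates[["kd"]],
               error = function(e) NA_real_)
    }, numeric(1))
    out$replicate_sd <- stats::sd(kds, na.rm = TRUE)
    out$replicate_kds <- kds
  }
  out
}

#' Fit a pKa from single-wavelength pH titration data
#'
#' Fits the sigmoidal protonation model
#' `I(pH) = (I_acid + I_base * 10^(pH - pKa)) / (1 + 10^(pH - pKa))`.
#'
#' @param ph_series Data frame with columns `ph` and `intensity`.
#' @return A `fit_result` with estimates `pka`, `i_acid`, `i_base`. A
#'   `"inflection_not_bracketed"` flag is attached when the fitted pKa lies
#'   outside the pH range of the data.
#' @export
fit_pka <- function(ph_series) {
  ph_series <- as.data.frame(ph_series)
  stopifnot(all(c("ph", "intensity") %in% names(ph_series)))
  ph <- ph_series$ph
  y <- ph_series$intensity
  if (length(unique(ph)) < 5L) stop("need at least 5 distinct pH points")
  if (diff(range(ph)) < 2) stop("pH range must span at least 2 units")
  if (diff(range(y)) < 1e-9 * max(abs(y), 1)) {
    stop("uninformative data: intensity does not vary across the pH range")
  }
  agg <- tapply(y, ph, mean)
  pu <- as.numeric(names(agg))
  i_acid0 <- agg[[which.min(pu)]]
  i_base0 <- agg[[which.max(pu)]]
  pka0 <- pu[which.min(abs(agg - (i_acid0 + i_base0) / 2))]
  resid_fn <- function(p) {
    t10 <- 10^(ph - p[["pka"]])
    (p[["i_acid"]] + p[["i_base"]] * t10) / (1 + t10) - y
  }
  fit <- .lm_fit(c(pka = pka0, i_acid = i_acid0, i_base = i_base0),
                 resid_fn, trans = c(FALSE, FALSE, FALSE))
  names(fit$estimates) <- c("pka", "i_acid", "i_base")
  names(fit$se) <- names(fit$estimates)
  flags <- character()
  if (fit$estimates[["pka"]] < min(ph) || fit$estimates[["pka"]] > max(ph)) {
    flags <- "inflection_not_bracketed"
  }
  .fit_result(fit$estimates, fit$se, fit$cov, fit$rss, fit$converged,
              fit$n, flags = flags)
}

# Predicted ratio for an equimolar Mg/ATP competition series under the
# binary + ternary speciation model.
.ternary_model_ratio <- function(mgatp_totals, s_total, kd_sm, kd_mgatp,
                                 kd_ternary, ternary_scale, spectra,
                                 channels, sensor = "MagZet1",
                                 numerator = "F530", denominator = "F500") {
  spectra <- .as_spectra_list(spectra)
  nm <- vapply(spectra, `[[`, character(1), "name")
  names(spectra) <- nm
  tern <- paste0(sensor, ".Mg.ATP")
  if (tern %in% nm) {
    spectra[[tern]]$brightness <- spectra[[tern]]$brightness * ternary_scale
  }
  vapply(mgatp_totals, function(tot) {
    sys <- equilibrium_system(
      list(component(sensor, "sensor", s_total),
           component("Mg", "metal", tot),
           component("ATP", "ligand", tot)),
      list(reaction(paste0(sensor, ".Mg"),
                    stats::setNames(c(1, 1), c(sensor, "Mg")), kd_sm),
           reaction("Mg.ATP", c(Mg = 1, ATP = 1), kd_mgatp),
           reaction(tern,
                    stats::setNames(c(1, 1), c(sensor, "Mg.ATP")),
                    kd_ternary)))
    sp <- solve_speciation(sys)
    compose_channel_intensities(sp, spectra, channels, numerator,
                                denominator, x = tot)$ratio
  }, numeric(1))
}

#' Fit the ternary-complex dissociation constant from an MgATP series
#'
#' Analyzes an equimolar Mg/ATP competition titration with a model that
#' includes both the binary sensor-Mg complex (populated through
#' competition with ATP) and the ternary sensor-Mg-ATP complex formed from
#' the sensor and MgATP. The sensor-Mg and Mg-ATP constants are held fixed;
#' the ternary constant and a ternary brightness scale are estimated. The
#' objective evaluates the full three-reaction speciation at every
#' titration point.
#'
#' @param series Data frame with columns `mgatp_total` (equimolar total of
#'   Mg and ATP, molar) and `ratio`.
#' @param s_total Total sensor concentration (molar), default 20e-6.
#' @param kd_sm Fixed sensor-Mg dissociation constant (molar).
#' @param kd_mgatp Fixed MgATP dissociation constant (molar).
#' Because the ternary complex shares the Mg-bound chromophore state, its
#' ratio contribution in the weak-binding limit is governed by the
#' quotient of its brightness scale and its constant, making the two
#' jointly flat under noise. The brightness scale is therefore held at its
#' calibrated value by default; set `fit_scale = TRUE` to co-estimate it
#' (appropriate only for low-noise data).
#'
#' @param spectra,channels Emission model used to compose predicted ratios.
#' @param ternary_scale Brightness multiplier of the ternary species
#'   spectrum, held fixed unless `fit_scale = TRUE` (default 1).
#' @param fit_scale Also estimate the ternary brightness scale?
#' @param kd_upper Upper bound for the ternary constant (molar); fits
#'   driven to this bound are flagged non-identifiable.
#' @return A `fit_result` with estimate `kd_ternary` (and `ternary_scale`
#'   when `fit_scale = TRUE`). When the residual profile over the ternary
#'   constant is flat (RSS change below 1% of the data's total sum of
#'   squares across the two decades above the estimate), the result
#'   carries a `"non_identifiable"` flag and the estimate is a lower
#'   bound.
#' @export
fit_ternary <- function(series, s_total = 20e-6,
                        kd_sm = 0.14e-3, kd_mgatp = 50e-6,
                        spectra = magzet1_spectra(),
                        channels = magzet1_channels(),
                        ternary_scale = 1, fit_scale = FALSE,
                        kd_upper = 100) {
  series <- as.data.frame(series)
  stopifnot(all(c("mgatp_total", "ratio") %in% names(series)))
  series <- series[is.finite(series$ratio), , drop = FALSE]
  tot <- series$mgatp_total
  r <- series$ratio
  if (length(unique(tot)) < 5L) stop("need at least 5 distinct MgATP totals")

  resid_fn <- function(p) {
    sc <- if (fit_scale) exp(p[["log_scale"]]) else ternary_scale
    .ternary_model_ratio(tot, s_total, kd_sm, kd_mgatp,
                         exp(p[["log_kd_t"]]), sc,
                         spectra, channels) - r
  }
  if (fit_scale) {
    fit <- .lm_fit(c(log_kd_t = log(0.05), log_scale = 0), resid_fn,
                   trans = c(TRUE, TRUE),
                   lower = c(log(1e-6), log(1e-3)),
                   upper = c(log(kd_upper), log(1e3)))
    names(fit$estimates) <- c("kd_ternary", "ternary_scale")
  } else {
    fit <- .lm_fit(c(log_kd_t = log(0.05)), resid_fn, trans = TRUE,
                   lower = log(1e-6), upper = log(kd_upper))
    names(fit$estimates) <- "kd_ternary"
  }
  names(fit$se) <- names(fit$estimates)
  kd_hat <- fit$estimates[["kd_ternary"]]
  scale_hat <- if (fit_scale) fit$estimates[["ternary_scale"]] else
    ternary_scale

  # identifiability screen: 1-D RSS profile over the ternary constant on a
  # fixed 40-point log grid; flat over the next two decades => lower bound
  grid <- exp(seq(log(kd_hat), log(kd_hat * 1e2), length.out = 40))
  rss_prof <- vapply(grid, function(k) {
    sum((.ternary_model_ratio(tot, s_total, kd_sm, kd_mgatp, k, scale_hat,
                              spectra, channels) - r)^2)
  }, numeric(1))
  flags <- character()
  # flat relative to the noise floor (the fit's own RSS, with a tiny
  # TSS-scaled floor so exact noiseless fits do not divide by zero)
  noise_floor <- max(fit$rss, 1e-12 * sum((r - mean(r))^2),
                     .Machine$double.eps)
  if ((max(rss_prof) - min(rss_prof)) / noise_floor < 0.01 ||
      kd_hat >= 0.99 * kd_upper ||
      (fit_scale && scale_hat <= 1.01e-3)) {
    flags <- "non_identifiable"
  }
  fixed <- list(s_total = s_total, kd_sm = kd_sm, kd_mgatp = kd_mgatp)
  if (!fit_scale) fixed$ternary_scale <- ternary_scale
  .fit_result(fit$estimates, fit$se, fit$cov, fit$rss, fit$converged,
              fit$n, fixed = fixed, flags = flags)
}

#' Selectivity ratio between two binding constants
#'
#' Ratio of a competitor's dissociation constant to the target's; values
#' above 1 mean the sensor prefers the target.
#'
#' @param kd_competitor,kd_target Dissociation constants (molar, > 0).
#' @return Dimensionless fold-selectivity.
#' @examples
#' selectivity_ratio(1.7e-3, 0.14e-3)  # Ca vs Mg
#' @export
selectivity_ratio <- function(kd_competitor, kd_target) {
  if (any(kd_competitor <= 0) || any(kd_target <= 0)) {
    stop("dissociation constants must be > 0")
  }
  kd_competitor / kd_target
}

#' Predicted-ratio selectivity panel
#'
#' Computes the equilibrium fluorescence ratio for a list of named
#' total-concentration conditions (e.g. blank, +1 mM Mg, +50 uM Ca,
#' +Mg+Ca), solving the full competition speciation for each.
#'
#' @param conditions Named list; each element is a named numeric vector of
#'   metal totals in molar (empty vector = sensor only).
#' @param constants Named vector of sensor-metal dissociation constants,
#'   e.g. `c(Mg = 0.14e-3, Ca = 1.7e-3, Zn = 2.6e-9)`.
#' @param s_total Sensor total (molar), default 1e-6 as in the selectivity
#'   screen.
#' @param spectra,channels Emission model.
#' @param sensor Sensor component name.
#' @param numerator,denominator Ratio channels.
#' @return Data frame with columns `condition` and `ratio`.
#' @export
selectivity_panel <- function(conditions,
                              constants = c(Mg = 0.14e-3, Ca = 1.7e-3,
                                            Zn = 2.6e-9),
                              s_total = 1e-6,
                              spectra = magzet1_spectra(),
                              channels = magzet1_channels(),
                              sensor = "MagZet1",
                              numerator = "F530", denominator = "F500") {
  stopifnot(is.list(conditions), length(names(conditions)) ==
              length(conditions))
  ratios <- vapply(conditions, function(tots) {
    metals <- names(tots)[tots > 0]
    unknown <- setdiff(metals, names(constants))
    if (length(unknown)) {
      stop("no dissociation constant for: ", paste(unknown, collapse = ", "))
    }
    comps <- c(list(component(sensor, "sensor", s_total)),
               lapply(metals, function(mt) component(mt, "metal", tots[[mt]])))
    rxns <- lapply(metals, function(mt) {
      reaction(paste(sensor, mt, sep = "."),
               stats::setNames(c(1, 1), c(sensor, mt)), constants[[mt]])
    })
    sp <- solve_speciation(equilibrium_system(comps, rxns))
    compose_channel_intensities(sp, spectra, channels, numerator,
                                denominator)$ratio
  }, numeric(1))
  data.frame(condition = names(conditions), ratio = unname(ratios),
             stringsAsFactors = FALSE)
}
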