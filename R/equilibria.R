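# Multi-component chemical equilibrium speciation.
#
# A system is a set of components (sensor, metals, ligands, optionally a
# proton with fixed activity set by pH) plus stepwise assembly reactions,
# each with a dissociation constant
#   Kd = prod(free reactant concentrations ^ stoichiometry) / [product].
# Products may themselves appear as reactants in later reactions (stepwise
# assembly, e.g. Mg + ATP <-> MgATP then S + MgATP <-> S.Mg.ATP).

#' Define a chemical component
#'
#' A component is an independent chemical entity carrying a mass balance:
#' the fluorescent sensor, a metal ion, a ligand such as ATP, or the proton.
#' For a proton component the free concentration is clamped by the system pH
#' instead of being governed by a total concentration.
#'
#' @param name Component name (unique within a system).
#' @param role One of `"sensor"`, `"metal"`, `"ligand"`, `"proton"`.
#' @param total Total (analytical) concentration in molar. Ignored for
#'   `role = "proton"`.
#' @return An object of class `component`.
#' @examples
#' component("Mg", "metal", total = 1e-3)
#' @export
component <- function(name, role = c("sensor", "metal", "ligand", "proton"),
                      total = 0) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(total) || length(total) != 1L || is.na(total)) {
    stop("total concentration for '", name, "' must be a single number")
  }
  if (total < 0) {
    stop("negative total concentration for component '", name, "'")
  }
  structure(list(name = name, role = role, total = total),
            class = "component")
}

#' Define an assembly reaction
#'
#' Describes the formation of one product species from free components (or
#' previously defined products), parameterised by a dissociation constant
#' `kd` for the assembly step:
#' `kd = prod([free reactant]^stoichiometry) / [product]`.
#'
#' @param product Name of the product species (must not collide with a
#'   component name).
#' @param stoichiometry Named integer vector mapping reactant name to count,
#'   e.g. `c(MagZet1 = 1, Mg = 1)`.
#' @param kd Dissociation constant in molar (> 0).
#' @param temperature Free-text temperature label, e.g. `"25 C"`.
#' @param medium Free-text buffer/medium label.
#' @return An object of class `reaction`.
#' @examples
#' reaction("MagZet1.Mg", c(MagZet1 = 1, Mg = 1), kd = 0.14e-3)
#' @export
reaction <- function(product, stoichiometry, kd,
                     temperature = NA_character_, medium = NA_character_) {
  stopifnot(is.character(product), length(product) == 1L, nzchar(product))
  if (!is.numeric(kd) || length(kd) != 1L || is.na(kd) || kd <= 0) {
    stop("kd for product '", product, "' must be a single positive number")
  }
  if (length(stoichiometry) == 0L || is.null(names(stoichiometry)) ||
      any(!nzchar(names(stoichiometry)))) {
    stop("stoichiometry for '", product, "' must be a non-empty named vector")
  }
  if (any(stoichiometry != round(stoichiometry)) || any(stoichiometry < 1)) {
    stop("stoichiometry counts for '", product, "' must be positive integers")
  }
  structure(list(product = product,
                 stoichiometry = stoichiometry,
                 kd = kd,
                 temperature = temperature,
                 medium = medium),
            class = "reaction")
}

#' Assemble an equilibrium system
#'
#' Bundles components and reactions into a validated speciation problem.
#' Stoichiometry keys must resolve to a component or to the product of an
#' earlier reaction (stepwise assembly; cycles are therefore impossible).
#' If `ph` is given, the free proton concentration is clamped at `10^-ph`
#' and a `proton` component must be present.
#'
#' @param components List of [component()] objects.
#' @param reactions List of [reaction()] objects (may be empty).
#' @param ph Optional pH clamping the free proton concentration.
#' @return An object of class `equilibrium_system`.
#' @examples
#' sys <- equilibrium_system(
#'   list(component("S", "sensor", 10e-6), component("Mg", "metal", 1e-3)),
#'   list(reaction("S.Mg", c(S = 1, Mg = 1), kd = 0.14e-3)))
#' @export
equilibrium_system <- function(components, reactions = list(), ph = NULL) {
  stopifnot(is.list(components), is.list(reactions))
  if (length(components) == 0L) stop("at least one component is required")
  lapply(components, function(x) {
    if (!inherits(x, "component")) stop("components must be component objects")
  })
  lapply(reactions, function(x) {
    if (!inherits(x, "reaction")) stop("reactions must be reaction objects")
  })
  cnames <- vapply(components, `[[`, character(1), "name")
  if (anyDuplicated(cnames)) stop("component names must be unique")
  roles <- vapply(components, `[[`, character(1), "role")
  if (sum(roles == "sensor") > 1L) {
    warning("system defines more than one sensor component")
  }
  if (sum(roles == "proton") > 1L) stop("at most one proton component allowed")
  if (!is.null(ph)) {
    stopifnot(is.numeric(ph), length(ph) == 1L, is.finite(ph))
    if (!any(roles == "proton")) {
      stop("ph was set but no proton component is present")
    }
  } else if (any(roles == "proton")) {
    stop("a proton component requires 'ph' to clamp its free concentration")
  }
  pnames <- vapply(reactions, `[[`, character(1), "product")
  if (anyDuplicated(pnames)) stop("product names must be unique")
  if (any(pnames %in% cnames)) {
    stop("product name collides with a component name: ",
         paste(intersect(pnames, cnames), collapse = ", "))
  }
  # stepwise-assembly check: each reactant is a component or an earlier product
  for (i in seq_along(reactions)) {
    keys <- names(reactions[[i]]$stoichiometry)
    known <- c(cnames, pnames[seq_len(i - 1L)])
    bad <- setdiff(keys, known)
    if (length(bad)) {
      stop("reaction '", pnames[i], "' references unknown species: ",
           paste(bad, collapse = ", "))
    }
  }
  structure(list(components = components, reactions = reactions, ph = ph),
            class = "equilibrium_system")
}

# Expand each product to its elemental composition in components.
# Returns a matrix [n_reactions x n_components] of counts.
.composition_matrix <- function(system) {
  cnames <- vapply(system$components, `[[`, character(1), "name")
  nr <- length(system$reactions)
  comp <- matrix(0, nrow = nr, ncol = length(cnames),
                 dimnames = list(vapply(system$reactions, `[[`,
                                        character(1), "product"), cnames))
  for (i in seq_len(nr)) {
    st <- system$reactions[[i]]$stoichiometry
    for (k in names(st)) {
      if (k %in% cnames) {
        comp[i, k] <- comp[i, k] + st[[k]]
      } else {
        comp[i, ] <- comp[i, ] + st[[k]] * comp[k, ]
      }
    }
  }
  comp
}

# Complex concentrations given free component concentrations (named vector
# over all components, proton included). Evaluated in definition order so
# stepwise products can feed later reactions.
.complex_concentrations <- function(system, free) {
  nr <- length(system$reactions)
  conc <- c(free, stats::setNames(numeric(nr),
                                  vapply(system$reactions, `[[`,
                                         character(1), "product")))
  for (i in seq_len(nr)) {
    rx <- system$reactions[[i]]
    st <- rx$stoichiometry
    conc[rx$product] <- prod(conc[names(st)]^st) / rx$kd
  }
  conc[setdiff(names(conc), names(free))]
}

# Relative mass-balance residuals for the solved (non-proton, total>0)
# components: (free + bound - total) / total.
.mass_residuals <- function(system, free, comp_mat, solve_names, totals) {
  cx <- .complex_concentrations(system, free)
  bound <- if (length(cx)) {
    as.numeric(crossprod(comp_mat[, solve_names, drop = FALSE], cx))
  } else numeric(length(solve_names))
  (free[solve_names] + bound - totals[solve_names]) / totals[solve_names]
}

#' Solve coupled mass-balance equilibria
#'
#' Computes free and complexed concentrations for an
#' [equilibrium_system()] by damped Newton iteration on the logarithms of
#' the free concentrations (guaranteeing positivity), with a per-component
#' bisection (Gauss-Seidel) fallback when Newton fails to reduce the
#' residual. Components with zero total are fixed at zero; a proton
#' component is clamped at `10^-ph`.
#'
#' @param system An [equilibrium_system()].
#' @param tol Convergence tolerance on the maximum relative mass-balance
#'   residual (default `1e-9`).
#' @param max_iter Iteration cap (default 200).
#' @return An object of class `speciation_result`: a list with elements
#'   `free` (named molar concentrations, proton included when pH is set),
#'   `complexes`, `residuals` (relative mass-balance errors), `converged`
#'   and `iterations`. Non-convergence is reported via `converged = FALSE`
#'   carrying the last residuals, never silently.
#' @examples
#' sys <- equilibrium_system(
#'   list(component("S", "sensor", 10e-6), component("Mg", "metal", 0.14e-3)),
#'   list(reaction("S.Mg", c(S = 1, Mg = 1), kd = 0.14e-3)))
#' solve_speciation(sys)
#' @export
solve_speciation <- function(system, tol = 1e-9, max_iter = 200L) {
  stopifnot(inherits(system, "equilibrium_system"))
  cnames <- vapply(system$components, `[[`, character(1), "name")
  roles <- vapply(system$components, `[[`, character(1), "role")
  totals <- stats::setNames(vapply(system$components, `[[`, numeric(1),
                                   "total"), cnames)
  comp_mat <- .composition_matrix(system)

  free <- stats::setNames(numeric(length(cnames)), cnames)
  if (!is.null(system$ph)) free[roles == "proton"] <- 10^(-system$ph)
  solve_names <- cnames[roles != "proton" & totals > 0]
  free[solve_names] <- totals[solve_names] * 0.5

  result <- function(converged, iterations) {
    res <- if (length(solve_names)) {
      .mass_residuals(system, free, comp_mat, solve_names, totals)
    } else stats::setNames(numeric(0), character(0))
    structure(list(free = free,
                   complexes = .complex_concentrations(system, free),
                   residuals = res,
                   converged = converged,
                   iterations = iterations),
              class = "speciation_result")
  }
  if (length(solve_names) == 0L) return(result(TRUE, 0L))

  n <- length(solve_names)
  fvec <- function(x) {
    free[solve_names] <- exp(x)
    .mass_residuals(system, free, comp_mat, solve_names, totals)
  }
  x <- log(free[solve_names])
  f <- fvec(x)
  iter <- 0L
  while (max(abs(f)) > tol && iter < max_iter) {
    iter <- iter + 1L
    # forward-difference Jacobian in log space
    J <- matrix(0, n, n)
    h <- 1e-7
    for (j in seq_len(n)) {
      xj <- x
      xj[j] <- xj[j] + h
      J[, j] <- (fvec(xj) - f) / h
    }
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    improved <- FALSE
    if (!is.null(step) && all(is.finite(step))) {
      lambda <- 1
      for (k in 1:40) {
        xn <- x + lambda * step
        fn <- fvec(xn)
        if (all(is.finite(fn)) && max(abs(fn)) < max(abs(f))) {
          x <- xn; f <- fn; improved <- TRUE
          break
        }
        lambda <- lambda / 2
      }
    }
    if (!improved) {
      # Gauss-Seidel bisection sweep: each residual is monotone increasing
      # in its own free concentration with the others held fixed.
      for (j in seq_len(n)) {
        g <- function(xj) { xi <- x; xi[j] <- xj; fvec(xi)[j] }
        lo <- log(totals[solve_names[j]]) - 60
        hi <- log(totals[solve_names[j]])
        if (g(lo) < 0 && g(hi) >= 0) {
          x[j] <- stats::uniroot(g, c(lo, hi), tol = 1e-13)$root
        }
      }
      f <- fvec(x)
    }
  }
  free[solve_names] <- exp(x)
  result(max(abs(f)) <= tol, iter)
}

#' @export
print.speciation_result <- function(x, ...) {
  cat("Speciation result (", if (x$converged) "converged" else "NOT converged",
      ", ", x$iterations, " iterations)\n", sep = "")
  cat("Free (M):\n")
  print(signif(x$free, 6))
  if (length(x$complexes)) {
    cat("Complexes (M):\n")
    print(signif(x$complexes, 6))
  }
  if (length(x$residuals)) {
    cat("Max |relative residual|:", format(max(abs(x$residuals))), "\n")
  }
  invisible(x)
}

#' Closed-form 1:1 bound-complex concentration
#'
#' Analytic solution of the quadratic mass balance for a single 1:1 binding
#' equilibrium S + M <-> SM with dissociation constant `kd`, including
#' ligand depletion. Uses the numerically stable root form.
#'
#' @param s_total Total sensor concentration (molar).
#' @param m_total Total metal concentration (molar).
#' @param kd Dissociation constant (molar, > 0).
#' @return Bound complex concentration in molar, within
#'   `[0, min(s_total, m_total)]`.
#' @examples
#' closed_form_1to1(10e-6, 0.14e-3, 0.14e-3)
#' @export
closed_form_1to1 <- function(s_total, m_total, kd) {
  if (any(s_total < 0) || any(m_total < 0)) stop("totals must be >= 0")
  if (!is.numeric(kd) || any(kd <= 0)) stop("kd must be > 0")
  b <- s_total + m_total + kd
  # stable: 2ac / (b + sqrt(b^2 - 4ac)) avoids cancellation for small roots
  disc <- b^2 - 4 * s_total * m_total
  disc[disc < 0] <- 0
  2 * s_total * m_total / (b + sqrt(disc))
}

#' Fractional saturation of a 1:1 binder
#'
#' Fraction of sensor bound at a given free metal concentration,
#' `f = [M] / (kd + [M])`. Quantifies, e.g., how little of the sensor a
#' competing cation occupies at its typical intracellular level.
#'
#' @param kd Dissociation constant (molar, > 0).
#' @param free_metal Free metal concentration (molar, >= 0).
#' @return Fraction in `[0, 1)`, monotone in `free_metal`.
#' @examples
#' fraction_bound(1.7e-3, 50e-6)  # Ca occupancy at 50 uM free Ca
#' @export
fraction_bound <- function(kd, free_metal) {
  if (!is.numeric(kd) || any(kd <= 0)) stop("kd must be > 0")
  if (any(free_metal < 0)) stop("free_metal must be >= 0")
  free_metal / (kd + free_metal)
}
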