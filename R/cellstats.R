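# Per-cell ratio computation and population comparison statistics for
# imaging and flow-cytometry style two-channel data.

#' Background-corrected per-cell fluorescence ratios
#'
#' Computes `(I_num - bg_num) / (I_den - bg_den)` for each event. Events
#' whose corrected denominator is not positive cannot yield a ratio; they
#' are excluded and counted in the attached QC report rather than silently
#' dropped.
#'
#' @param events Data frame with one row per cell, containing the two
#'   intensity columns and optionally `event_id` and `group`.
#' @param numerator,denominator Names of the intensity columns.
#' @param background Named (or length-2) numeric vector of per-channel
#'   background levels, in the same order/names as the channels; default 0.
#' @return Data frame with columns `event_id`, `ratio` and (if present)
#'   `group`; attribute `"qc"` holds `n_input`, `n_excluded`, and the
#'   excluded event ids.
#' @export
per_cell_ratio <- function(events, numerator, denominator,
                           background = c(0, 0)) {
  events <- as.data.frame(events)
  if (!all(c(numerator, denominator) %in% names(events))) {
    stop("events must contain columns '", numerator, "' and '",
         denominator, "'")
  }
  if (is.null(names(background))) {
    names(background) <- c(numerator, denominator)
  }
  if (any(background < 0)) stop("background must be >= 0")
  if (is.null(events$event_id)) events$event_id <- seq_len(nrow(events))
  num <- events[[numerator]] - background[[numerator]]
  den <- events[[denominator]] - background[[denominator]]
  keep <- is.finite(den) & den > 0 & is.finite(num)
  if (!any(keep)) stop("empty population: all events excluded by QC")
  out <- data.frame(event_id = events$event_id[keep],
                    ratio = num[keep] / den[keep])
  if (!is.null(events$group)) out$group <- events$group[keep]
  attr(out, "qc") <- list(n_input = nrow(events),
                          n_excluded = sum(!keep),
                          excluded_ids = events$event_id[!keep])
  out
}

#' Chi-square homogeneity comparison of two ratio populations
#'
#' Bins both samples on shared edges computed from the pooled data
#' (equal-width bins across the central quantile range), merges adjacent
#' bins until every expected count is at least `min_expected`, and applies
#' the chi-square homogeneity test to the resulting 2 x k table.
#'
#' @param a,b Numeric vectors of per-cell ratios (each n >= 50).
#' @param bins Initial number of equal-width bins (default 64).
#' @param central Central quantile mass used for the bin range (default
#'   0.99); values outside are pooled into the edge bins.
#' @param min_expected Minimum expected count per bin after merging.
#' @return An object of class `population_comparison`: group sizes and
#'   medians, shared bin edges and counts, the chi-square statistic,
#'   degrees of freedom and p-value. Identical samples give statistic 0 and
#'   p = 1.
#' @export
compare_populations_chi2 <- function(a, b, bins = 64, central = 0.99,
                                     min_expected = 5) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 50 || length(b) < 50) {
    stop("each population must contain at least 50 events")
  }
  pooled <- c(a, b)
  qs <- stats::quantile(pooled, c((1 - central) / 2, 1 - (1 - central) / 2),
                        names = FALSE)
  if (qs[2] <= qs[1]) qs <- range(pooled) + c(-1, 1) * 1e-12
  edges <- seq(qs[1], qs[2], length.out = bins + 1L)
  edges[1] <- -Inf
  edges[length(edges)] <- Inf
  ca <- as.numeric(table(cut(a, edges)))
  cb <- as.numeric(table(cut(b, edges)))

  # merge adjacent bins until all expected counts reach min_expected
  tot <- ca + cb
  repeat {
    n <- sum(tot)
    exp_a <- tot * length(a) / n
    exp_b <- tot * length(b) / n
    low <- which(pmin(exp_a, exp_b) < min_expected)
    if (!length(low) || length(tot) <= 2L) break
    i <- low[1]
    j <- if (i == length(tot)) i - 1L else i
    ca <- c(ca[seq_len(j - 1)], ca[j] + ca[j + 1],
            if (j + 2 <= length(ca)) ca[(j + 2):length(ca)])
    cb <- c(cb[seq_len(j - 1)], cb[j] + cb[j + 1],
            if (j + 2 <= length(cb)) cb[(j + 2):length(cb)])
    tot <- ca + cb
  }
  if (length(tot) < 2L ||
      any(pmin(tot * length(a), tot * length(b)) / sum(tot) < 1)) {
    stop("comparison impossible: fewer than 2 valid bins after merging")
  }
  tab <- rbind(a = ca, b = cb)
  keep <- colSums(tab) > 0
  tab <- tab[, keep, drop = FALSE]
  if (ncol(tab) < 2L) stop("comparison impossible: fewer than 2 valid bins")
  if (identical(ca, cb)) {
    stat <- 0
    df <- ncol(tab) - 1L
    p <- 1
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    stat <- unname(ct$statistic)
    df <- unname(ct$parameter)
    p <- unname(ct$p.value)
  }
  structure(list(n = c(a = length(a), b = length(b)),
                 median = c(a = stats::median(a), b = stats::median(b)),
                 edges = edges, counts = tab,
                 statistic = stat, df = df, p_value = p),
            class = "population_comparison")
}

#' @export
print.population_comparison <- function(x, ...) {
  cat("Chi-square population comparison\n")
  cat(sprintf("  n: %d vs %d; medians: %.4g vs %.4g\n",
              x$n[1], x$n[2], x$median[1], x$median[2]))
  cat(sprintf("  X-squared = %.4g, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Welch two-sample t test on per-cell ratios
#'
#' Thin wrapper over the two-sided Welch test with a defined outcome for
#' the degenerate zero-variance case: two constant, equal samples give
#' `t = 0, p = 1`.
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @return List with `statistic`, `p_value`, `df` and group means.
#' @export
two_group_ttest <- function(a, b) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(statistic = 0, p_value = 1, df = NA_real_,
                  means = c(a = mean(a), b = mean(b))))
    }
    stop("zero variance in both groups with unequal means: t undefined")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), means = c(a = mean(a), b = mean(b)))
}
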