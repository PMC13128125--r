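#' Locate the G'/G'' crossover of an amplitude sweep
#'
#' The storage modulus G' dominates at low strain (solid-like response)
#' and decays faster than the loss modulus G'' as strain grows; where the
#' two cross, the material transitions to liquid-like behaviour. The
#' crossover is located at the first sign change of `G' - G''` by
#' log-log linear interpolation between the bracketing grid points; exact
#' equality at a grid point returns that point.
#'
#' @param sweep Data frame with columns `strain_pct`, `gprime_pa`,
#'   `gdoubleprime_pa` (e.g. from [gen_rheology_dataset()]).
#' @return List `(strain_pct, modulus_pa)`, or `NULL` when the curves
#'   never cross (no-crossover signal, not an error).
#' @export
find_crossover <- function(sweep) {
  g <- sweep$strain_pct
  d <- sweep$gprime_pa - sweep$gdoubleprime_pa
  eq <- which(d == 0)
  if (length(eq))
    return(list(strain_pct = g[eq[1]], modulus_pa = sweep$gprime_pa[eq[1]]))
  flips <- which(d[-length(d)] > 0 & d[-1] < 0)
  if (!length(flips)) return(NULL)
  i <- flips[1]
  # interpolate log(G') and log(G'') linearly in log(strain)
  lx <- log(g[i + 0:1])
  f <- (0 - d[i] / (d[i + 1] - d[i]))  # not used directly; solve in log space
  lgp <- log(sweep$gprime_pa[i + 0:1])
  lgpp <- log(sweep$gdoubleprime_pa[i + 0:1])
  s1 <- (lgp[2] - lgp[1]) / (lx[2] - lx[1])
  s2 <- (lgpp[2] - lgpp[1]) / (lx[2] - lx[1])
  lxc <- lx[1] + (lgpp[1] - lgp[1]) / (s1 - s2)
  list(strain_pct = exp(lxc), modulus_pa = exp(lgp[1] + s1 * (lxc - lx[1])))
}

#' Yield stress from the intersection of two power-law fits
#'
#' Fits straight lines to `log(stress)` versus `log(strain)` in a
#' below-yield region and an above-yield region of an amplitude sweep and
#' intersects them: for fits `stress = a gamma^b`, the intersection is at
#' `gamma* = (a2/a1)^(1/(b1-b2))` and the yield stress is
#' `a1 gamma*^b1`. The default region rule takes the below region as
#' strains under half the G'/G'' crossover strain and the above region as
#' the top decade of strain; both are configurable and recorded in the
#' result.
#'
#' @param sweep Data frame with `strain_pct` and `stress_pa`.
#' @param below_max Upper strain limit (%) of the below-yield fit region;
#'   default: half the crossover strain.
#' @param above_min Lower strain limit (%) of the above-yield fit region;
#'   default: one tenth of the maximum strain.
#' @return An object of class `"yield_estimate"`: `tau_yield_pa`,
#'   `gamma_yield_pct`, `method = "intersection"`, and the two fits
#'   (prefactor `a`, exponent `b`, strain range).
#' @export
yield_from_intersection <- function(sweep, below_max = NULL,
                                    above_min = NULL) {
  g <- sweep$strain_pct; s <- sweep$stress_pa
  if (is.null(below_max)) {
    cr <- find_crossover(sweep)
    if (is.null(cr)) stop("no G'/G'' crossover; supply 'below_max' explicitly")
    below_max <- cr$strain_pct / 2
  }
  if (is.null(above_min)) above_min <- max(g) / 10
  if (below_max >= above_min) stop("fit regions overlap")
  lo <- g < below_max
  hi <- g >= above_min
  if (sum(lo) < 4L || sum(hi) < 4L)
    stop("need at least 4 points in each fit region")
  fit <- function(sel) {
    co <- stats::coef(stats::lm(log(s[sel]) ~ log(g[sel])))
    c(a = exp(unname(co[1])), b = unname(co[2]))
  }
  f1 <- fit(lo); f2 <- fit(hi)
  if (f1["b"] <= f2["b"] + 1e-8)
    stop("no flattening above yield (below-exponent <= above-exponent)")
  gstar <- (f2["a"] / f1["a"])^(1 / (f1["b"] - f2["b"]))
  tau <- f1["a"] * gstar^f1["b"]
  structure(list(tau_yield_pa = unname(tau),
                 gamma_yield_pct = unname(gstar),
                 method = "intersection",
                 fit_below = list(a = unname(f1["a"]), b = unname(f1["b"]),
                                  strain_max = below_max),
                 fit_above = list(a = unname(f2["a"]), b = unname(f2["b"]),
                                  strain_min = above_min)),
            class = "yield_estimate")
}

#' Yield stress from creep fluidization
#'
#' Under an applied stress below yield, creep compliance saturates; at or
#' above yield the material fluidizes and compliance grows linearly at
#' late times. For each applied stress a line is fitted to the final
#' `tail_fraction` of the record; a curve is classified as fluidized when
#' the fitted slope exceeds `slope_threshold` and the tail is genuinely
#' linear (R^2 at least 0.98). The yield stress is the lowest fluidized
#' applied stress. The default threshold is 10x the median absolute tail
#' slope among curves failing the linearity screen (0 if every curve
#' passes it), separating flow from saturation without an absolute scale.
#'
#' @param creep A `creep_set` (see [gen_rheology_dataset()]) or named list
#'   of data frames `time_s`, `compliance_per_pa`, named by applied
#'   stress in Pa.
#' @param tail_fraction Fraction of the record used for the tail fit.
#' @param slope_threshold Minimum fluidized slope, (1/Pa)/s, or `NULL`
#'   for the default rule.
#' @return A `yield_estimate` with `method = "creep"`, the per-stress
#'   classification table, and `tau_yield_pa = NA` (with
#'   `fluidized = FALSE`) when no curve fluidizes.
#' @export
yield_from_creep <- function(creep, tail_fraction = 0.5,
                             slope_threshold = NULL) {
  stresses <- as.numeric(names(creep))
  if (length(creep) < 2L) stop("need at least 2 applied stresses")
  fits <- lapply(creep, function(cu) {
    t <- cu$time_s; J <- cu$compliance_per_pa
    if (is.unsorted(t, strictly = TRUE)) stop("time vector must be increasing")
    sel <- t >= t[1] + (1 - tail_fraction) * (t[length(t)] - t[1])
    fit <- stats::lm(J[sel] ~ t[sel])
    ss_tot <- sum((J[sel] - mean(J[sel]))^2)
    r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 0
    c(slope = unname(stats::coef(fit)[2]), r2 = r2)
  })
  slope <- vapply(fits, `[[`, numeric(1), "slope")
  r2 <- vapply(fits, `[[`, numeric(1), "r2")
  linear <- r2 >= 0.98
  if (is.null(slope_threshold))
    slope_threshold <- if (all(linear)) 0 else 10 * stats::median(abs(slope[!linear]))
  fluid <- linear & slope > slope_threshold
  tab <- data.frame(stress_pa = stresses, tail_slope = slope, tail_r2 = r2,
                    fluidized = fluid, row.names = NULL)
  tau <- if (any(fluid)) min(stresses[fluid]) else NA_real_
  structure(list(tau_yield_pa = tau, method = "creep",
                 fluidized = any(fluid), curves = tab,
                 slope_threshold = slope_threshold,
                 tail_fraction = tail_fraction),
            class = "yield_estimate")
}

#' @export
print.yield_estimate <- function(x, ...) {
  if (is.na(x$tau_yield_pa)) {
    cat(sprintf("yield estimate (%s): undefined (no fluidized curve)\n", x$method))
  } else {
    cat(sprintf("yield estimate (%s): tau_yield = %.4g Pa", x$method,
                x$tau_yield_pa))
    if (!is.null(x$gamma_yield_pct))
      cat(sprintf(" at gamma = %.4g %%", x$gamma_yield_pct))
    cat("\n")
  }
  invisible(x)
}

#' Summarize replicate yield-stress estimates
#'
#' Mean and sample standard deviation (n - 1 denominator) of per-sample
#' yield stresses; the standard reporting convention is mean +/- SD.
#'
#' @param estimates Numeric vector of at least 2 yield stresses, Pa.
#' @return List `(mean_pa, sd_pa, n)`.
#' @examples
#' summarize_yield(c(47.79, 50.13, 39.66, 36.25, 58.21))  # 46.4 +/- 8.7
#' @export
summarize_yield <- function(estimates) {
  if (length(estimates) < 2L)
    stop("need at least 2 estimates (SD undefined otherwise)")
  list(mean_pa = mean(estimates), sd_pa = stats::sd(estimates),
       n = length(estimates))
}
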