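#' Parameters of the oscillating-wall (Stokes second problem) model
#'
#' Describes gut-wall contractions as an in-plane oscillating rigid plane
#' under a semi-infinite Newtonian approximation of the digesta. Defaults
#' for viscosity, density and yield stress are the measured gut-content
#' values (2237 Pa s, 1250 kg/m^3, 45 Pa). All quantities are SI.
#'
#' @param amplitude Oscillation amplitude A, m.
#' @param omega Angular frequency omega, rad/s.
#' @param mu Dynamic viscosity of the digesta, Pa s.
#' @param rho Density of the digesta, kg/m^3.
#' @param tau_yield Yield stress of the digesta, Pa.
#' @return A `stokes_parameters` list with the derived kinematic
#'   viscosity `nu = mu / rho` (m^2/s).
#' @export
stokes_parameters <- function(amplitude, omega, mu = 2237, rho = 1250,
                              tau_yield = 45) {
  for (nm in c("amplitude", "omega", "mu", "rho", "tau_yield"))
    stop_if_not_scalar_pos(get(nm), nm)
  structure(list(amplitude = amplitude, omega = omega, mu = mu, rho = rho,
                 tau_yield = tau_yield, nu = mu / rho),
            class = "stokes_parameters")
}

#' @export
print.stokes_parameters <- function(x, ...) {
  cat(sprintf("Stokes second problem: A = %g m, omega = %g rad/s, mu = %g Pa s, rho = %g kg/m^3, tau_yield = %g Pa\n",
              x$amplitude, x$omega, x$mu, x$rho, x$tau_yield))
  cat(sprintf("  nu = %g m^2/s, decay length sqrt(2 nu / omega) = %.4g m\n",
              x$nu, sqrt(2 * x$nu / x$omega)))
  invisible(x)
}

#' Velocity and shear-stress field above an oscillating wall
#'
#' The wall at `y = 0` oscillates in its own plane with velocity
#' `A omega cos(omega t)`; the fluid response decays exponentially away
#' from the wall with wavenumber `k = sqrt(omega / (2 nu))`:
#' \deqn{u(y,t) = A\omega \, e^{-ky} \cos(\omega t - ky)}
#' \deqn{\tau(y,t) = A\omega \sqrt{\rho\omega\mu} \, e^{-ky}
#'   \sin(\omega t - ky - \pi/4)}
#'
#' @param y Distance(s) from the wall, m (>= 0).
#' @param t Time(s), s. `y` and `t` are recycled against each other; give
#'   one of them length 1 for a profile.
#' @param params A [stokes_parameters()].
#' @return List with numeric `u` (velocity, m/s) and `tau` (shear stress,
#'   Pa).
#' @export
flow_field <- function(y, t, params) {
  stopifnot(inherits(params, "stokes_parameters"))
  if (any(y < 0)) stop("'y' must be >= 0")
  k <- sqrt(params$omega / (2 * params$nu))
  phase <- params$omega * t - k * y
  decay <- exp(-k * y)
  amp_u <- params$amplitude * params$omega
  amp_tau <- amp_u * sqrt(params$rho * params$omega * params$mu)
  list(u = amp_u * decay * cos(phase),
       tau = amp_tau * decay * sin(phase - pi / 4))
}

#' Shear-stress amplitude exerted by the wall on the digesta
#'
#' The stress at the wall is `A omega sqrt(rho omega mu) sin(omega t -
#' pi/4)`; its amplitude, returned here, scales linearly with the
#' contraction amplitude and as omega^(3/2) with frequency.
#'
#' @param params A [stokes_parameters()].
#' @return Wall stress amplitude, Pa.
#' @export
wall_stress_amplitude <- function(params) {
  stopifnot(inherits(params, "stokes_parameters"))
  params$amplitude * params$omega *
    sqrt(params$rho * params$omega * params$mu)
}

#' Mixing depth: where the stress amplitude falls to the yield stress
#'
#' Matching the exponentially decaying shear-stress amplitude to the
#' digesta's yield stress gives the depth to which a contraction can
#' fluidize (and hence mix) the content:
#' \deqn{D = -\sqrt{2\nu/\omega} \,
#'   \ln\!\left[\tau_{yield} / (A\omega\sqrt{\rho\omega\mu})\right].}
#' If even the wall stress amplitude does not reach the yield stress the
#' formula would give a negative (unphysical) depth; the model then
#' returns `D = 0` with `attained = FALSE`.
#'
#' @param params A [stokes_parameters()].
#' @return An object of class `"depth_result"`: `D` (m, >= 0), `attained`
#'   (logical), `wall_amplitude_pa`.
#' @export
mixing_depth <- function(params) {
  stopifnot(inherits(params, "stokes_parameters"))
  wall <- wall_stress_amplitude(params)
  if (wall <= params$tau_yield) {
    d <- 0; attained <- FALSE
  } else {
    d <- -sqrt(2 * params$nu / params$omega) * log(params$tau_yield / wall)
    attained <- TRUE
  }
  structure(list(D = d, attained = attained, wall_amplitude_pa = wall),
            class = "depth_result")
}

#' @export
print.depth_result <- function(x, ...) {
  if (x$attained)
    cat(sprintf("mixing depth D = %.4g m (wall stress amplitude %.4g Pa)\n",
                x$D, x$wall_amplitude_pa))
  else
    cat(sprintf("wall stress amplitude %.4g Pa below yield: no mixing (D = 0)\n",
                x$wall_amplitude_pa))
  invisible(x)
}

#' Mixing-depth map over contraction amplitudes and frequencies
#'
#' Evaluates [mixing_depth()] elementwise over grids of contraction
#' amplitude and frequency, for plotting how deep contractions of a given
#' strength can mix the digesta.
#'
#' @param amplitudes Amplitudes A, m.
#' @param omegas Angular frequencies, rad/s.
#' @param mu,rho,tau_yield Material parameters (see
#'   [stokes_parameters()]).
#' @return Matrix of depths D (m), rows indexed by amplitude, columns by
#'   frequency, with dimnames giving the grid values.
#' @export
depth_grid <- function(amplitudes, omegas, mu = 2237, rho = 1250,
                       tau_yield = 45) {
  if (!length(amplitudes) || !length(omegas)) stop("grids must be nonempty")
  out <- matrix(NA_real_, length(amplitudes), length(omegas),
                dimnames = list(A = signif(amplitudes, 6),
                                omega = signif(omegas, 6)))
  for (i in seq_along(amplitudes)) for (j in seq_along(omegas))
    out[i, j] <- mixing_depth(stokes_parameters(amplitudes[i], omegas[j],
                                                mu, rho, tau_yield))$D
  out
}

#' Digesta density from replicate measurements
#'
#' Converts replicate density measurements in g/ml to kg/m^3 and reports
#' their mean rounded to three significant figures (the precision at
#' which the model parameter is quoted).
#'
#' @param replicates_g_per_ml Numeric vector of densities, g/ml.
#' @return List `(mean_kg_m3, replicates_kg_m3)`.
#' @examples
#' digesta_density(c(1.16, 1.29, 1.31))$mean_kg_m3  # 1250
#' @export
digesta_density <- function(replicates_g_per_ml) {
  kg <- replicates_g_per_ml * 1000
  list(mean_kg_m3 = signif(mean(kg), 3), replicates_kg_m3 = kg)
}

#' Unit helpers
#'
#' Small conversion helpers used when feeding micrometre-scale imaging
#' quantities and percent strains into the SI flow model.
#'
#' @param x Numeric vector.
#' @return Converted numeric vector.
#' @export
um_to_m <- function(x) x * 1e-6

#' @rdname um_to_m
#' @export
m_to_um <- function(x) x * 1e6

#' @rdname um_to_m
#' @export
pct_to_fraction <- function(x) x / 100

#' @rdname um_to_m
#' @export
fraction_to_pct <- function(x) x * 100
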