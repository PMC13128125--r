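#' Ground truth for a synthetic rheology dataset
#'
#' Describes a yield-stress material in terms of its amplitude-sweep
#' behaviour: stress follows one power law in strain below the yield
#' strain and a flatter one above it (the two branches meet at
#' `(yield_strain, yield_stress)`), the storage/loss moduli are power laws
#' crossing at `crossover_strain`, and creep curves fluidize (gain a
#' late-time linear compliance term) only for applied stresses at or above
#' the yield stress.
#'
#' @param yield_stress Yield stress tau_y, Pa (> 0).
#' @param yield_strain Yield strain gamma_y, % strain (> 0).
#' @param below_exponent,above_exponent Power-law exponents of stress vs
#'   strain below/above yield; must satisfy
#'   `below_exponent > above_exponent >= 0` (the curve flattens at yield).
#' @param crossover_strain Strain (%) at which G' and G'' cross; the
#'   default `NULL` places it at twice the yield strain, where the
#'   solid-to-liquid transition sits in yield-stress materials.
#' @param creep_stresses Applied stresses for the creep protocol, Pa.
#' @param modulus Elastic modulus G of the pre-yield creep response, Pa.
#' @param retardation_time Creep retardation time t_r, s.
#' @param flow_viscosity Post-yield flow viscosity eta, Pa s.
#' @return A `rheology_truth` list.
#' @export
rheology_truth <- function(yield_stress = 45, yield_strain = 10,
                           below_exponent = 0.9, above_exponent = 0.2,
                           crossover_strain = NULL,
                           creep_stresses = seq(10, 50, by = 10),
                           modulus = 500, retardation_time = 10,
                           flow_viscosity = 5000) {
  stop_if_not_scalar_pos(yield_stress, "yield_stress")
  stop_if_not_scalar_pos(yield_strain, "yield_strain")
  if (!(below_exponent > above_exponent && above_exponent >= 0))
    stop("exponents must satisfy below_exponent > above_exponent >= 0")
  if (is.null(crossover_strain)) crossover_strain <- 2 * yield_strain
  structure(list(yield_stress = yield_stress, yield_strain = yield_strain,
                 below_exponent = below_exponent,
                 above_exponent = above_exponent,
                 crossover_strain = crossover_strain,
                 creep_stresses = creep_stresses, modulus = modulus,
                 retardation_time = retardation_time,
                 flow_viscosity = flow_viscosity),
            class = "rheology_truth")
}

#' Generate a synthetic amplitude sweep and creep set with known yield
#'
#' The amplitude sweep is evaluated on a log-spaced strain grid from 0.1%
#' to 1000% (the standard protocol for gut-content measurements at
#' omega = 1 rad/s). Stress follows
#' `tau_y * (gamma / gamma_y)^b1` below the yield strain and
#' `tau_y * (gamma / gamma_y)^b2` above it, times multiplicative Gaussian
#' noise. G' and G'' are decaying power laws constructed to cross at
#' `crossover_strain`. Creep compliance is
#' `J(t) = (1/G) (1 - exp(-t / t_r))`, plus `t / eta` for applied stresses
#' at or above yield (fluidization).
#'
#' @param truth A [rheology_truth()].
#' @param n_points_per_decade Strain grid resolution (default 10).
#' @param noise_rel Relative (multiplicative) noise level, e.g. 0.02.
#' @param seed Integer seed.
#' @param creep_times Time grid for creep curves, s.
#' @return A list with elements `sweep` (class `amplitude_sweep`: data
#'   frame with `strain_pct`, `stress_pa`, `gprime_pa`, `gdoubleprime_pa`
#'   and attribute `omega = 1` rad/s) and `creep` (class `creep_set`: a
#'   list, per applied stress, of data frames `time_s`, `compliance_per_pa`).
#' @export
gen_rheology_dataset <- function(truth, n_points_per_decade = 10,
                                 noise_rel = 0, seed = NULL,
                                 creep_times = seq(1, 300, by = 1)) {
  stopifnot(inherits(truth, "rheology_truth"))
  with_seed(seed, {
    gamma <- 10^seq(log10(0.1), log10(1000),
                    length.out = 4L * n_points_per_decade + 1L)
    below <- gamma < truth$yield_strain
    stress <- ifelse(below,
      truth$yield_stress * (gamma / truth$yield_strain)^truth$below_exponent,
      truth$yield_stress * (gamma / truth$yield_strain)^truth$above_exponent)
    # G'/G'' as power laws pinned to cross at crossover_strain; the modulus
    # scale at the crossover is tied to the stress there
    gcross <- truth$yield_stress * (truth$crossover_strain /
      truth$yield_strain)^truth$above_exponent / (truth$crossover_strain / 100)
    gp <- gcross * (gamma / truth$crossover_strain)^(-0.6)
    gpp <- gcross * (gamma / truth$crossover_strain)^(-0.25)
    if (noise_rel > 0) {
      stress <- stress * (1 + noise_rel * stats::rnorm(length(gamma)))
      gp <- gp * (1 + noise_rel * stats::rnorm(length(gamma)))
      gpp <- gpp * (1 + noise_rel * stats::rnorm(length(gamma)))
    }
    sweep <- structure(
      data.frame(strain_pct = gamma, stress_pa = stress, gprime_pa = gp,
                 gdoubleprime_pa = gpp),
      omega = 1, class = c("amplitude_sweep", "data.frame"))
    creep <- lapply(truth$creep_stresses, function(s) {
      J <- (1 / truth$modulus) * (1 - exp(-creep_times / truth$retardation_time))
      if (s >= truth$yield_stress) J <- J + creep_times / truth$flow_viscosity
      if (noise_rel > 0)
        J <- J * (1 + noise_rel * stats::rnorm(length(creep_times)))
      data.frame(time_s = creep_times, compliance_per_pa = J)
    })
    names(creep) <- as.character(truth$creep_stresses)
    creep <- structure(creep, stresses_pa = truth$creep_stresses,
                       class = "creep_set")
    list(sweep = sweep, creep = creep)
  })
}

#' Generate Dirichlet-distributed relative-abundance tables
#'
#' Draws per-sample taxon compositions around per-site mean profiles: each
#' sample is Dirichlet with concentration vector
#' `concentration * mean profile`, the simplest compositional noise model
#' with a single precision knob. Rows sum to one.
#'
#' @param site_profiles Named list of mean compositions (named numeric
#'   vectors over a common taxon set, each summing to 1 within 1e-9); names
#'   are the site labels (e.g. `base`, `tip`).
#' @param concentration Dirichlet precision (> 0); large values concentrate
#'   samples near the mean profile.
#' @param n_per_site Samples per site.
#' @param seed Integer seed.
#' @return A data frame with columns `sample_id`, `site`, then one column
#'   per taxon; abundance rows sum to 1.
#' @export
gen_abundance_table <- function(site_profiles, concentration, n_per_site,
                                seed = NULL) {
  stop_if_not_scalar_pos(concentration, "concentration")
  taxa <- names(site_profiles[[1]])
  for (p in site_profiles) {
    if (is.null(names(p)) || !identical(names(p), taxa))
      stop("all site profiles must share one named taxon set")
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("each mean composition must be non-negative and sum to 1 within 1e-9")
  }
  with_seed(seed, {
    ids <- character(0); sites <- character(0)
    comp <- matrix(numeric(0), ncol = length(taxa),
                   dimnames = list(NULL, taxa))
    for (site in names(site_profiles)) {
      alpha <- concentration * site_profiles[[site]]
      for (k in seq_len(n_per_site)) {
        g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
        # gamma draws with shape ~ 0 are numerically 0; guard the total
        if (sum(g) <= 0) g[which.max(alpha)] <- 1
        comp <- rbind(comp, g / sum(g))
        ids <- c(ids, sprintf("%s_%02d", site, k))
        sites <- c(sites, site)
      }
    }
    cbind(data.frame(sample_id = ids, site = sites,
                     stringsAsFactors = FALSE),
          as.data.frame(comp))
  })
}
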