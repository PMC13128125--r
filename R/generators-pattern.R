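#' Simulate a (possibly inhomogeneous) Poisson point pattern
#'
#' The null model of complete spatial randomness (CSR) against which
#' clustering and regularity are judged. A constant `intensity` gives a
#' homogeneous Poisson process; a function `intensity(x, y)` gives an
#' inhomogeneous process simulated by thinning a homogeneous proposal at
#' the intensity maximum.
#'
#' @param intensity Points per square micrometre: a single non-negative
#'   number, or a vectorized non-negative function of `(x, y)`.
#' @param window A [spat_window()].
#' @param seed Integer seed for reproducibility, or `NULL` to use the
#'   current RNG stream.
#' @param intensity_max Upper bound for a function-valued `intensity`; if
#'   missing it is taken as the maximum over a 101 x 101 evaluation grid.
#' @return A [point_pattern()].
#' @examples
#' pp <- gen_poisson_pattern(0.05, spat_window(0, 100, 0, 100), seed = 1)
#' @export
gen_poisson_pattern <- function(intensity, window, seed = NULL,
                                intensity_max = NULL) {
  if (!inherits(window, "spat_window")) stop("'window' must be a spat_window")
  with_seed(seed, {
    if (is.function(intensity)) {
      if (is.null(intensity_max)) {
        gx <- seq(window$xmin, window$xmax, length.out = 101L)
        gy <- seq(window$ymin, window$ymax, length.out = 101L)
        vals <- outer(gx, gy, intensity)
        if (any(vals < 0)) stop("intensity function must be non-negative")
        intensity_max <- max(vals)
      }
      lmax <- intensity_max
      n <- stats::rpois(1L, lmax * window_area(window))
      x <- stats::runif(n, window$xmin, window$xmax)
      y <- stats::runif(n, window$ymin, window$ymax)
      lam <- intensity(x, y)
      if (any(lam < 0)) stop("intensity function must be non-negative")
      keep <- stats::runif(n) < lam / lmax
      point_pattern(x[keep], y[keep], window)
    } else {
      stop_if_not_scalar_pos(intensity, "intensity", allow_zero = TRUE)
      n <- stats::rpois(1L, intensity * window_area(window))
      point_pattern(stats::runif(n, window$xmin, window$xmax),
                    stats::runif(n, window$ymin, window$ymax), window)
    }
  })
}

#' Simulate a Thomas cluster process
#'
#' Poisson parents with Gaussian-dispersed offspring; the standard clustered
#' stand-in for bacterial microcolonies. It has the closed-form Ripley
#' function K(r) = pi r^2 + (1 - exp(-r^2 / (4 sigma^2))) / kappa, which the
#' test-suite uses as an analytic oracle. Parents are simulated in a window
#' expanded by `4 * offspring_sigma` so that clusters straddling the border
#' contribute without edge deficit.
#'
#' @param parent_intensity Parent (cluster-centre) intensity kappa, per um^2.
#' @param mean_offspring Mean number of offspring per parent (Poisson).
#' @param offspring_sigma Isotropic Gaussian dispersion of offspring, um.
#' @inheritParams gen_poisson_pattern
#' @return A [point_pattern()] of the offspring falling inside `window`.
#' @export
gen_thomas_pattern <- function(parent_intensity, mean_offspring,
                               offspring_sigma, window, seed = NULL) {
  stop_if_not_scalar_pos(parent_intensity, "parent_intensity")
  stop_if_not_scalar_pos(mean_offspring, "mean_offspring", allow_zero = TRUE)
  stop_if_not_scalar_pos(offspring_sigma, "offspring_sigma", allow_zero = TRUE)
  with_seed(seed, {
    g <- 4 * offspring_sigma
    wexp <- spat_window(window$xmin - g, window$xmax + g,
                        window$ymin - g, window$ymax + g)
    npar <- stats::rpois(1L, parent_intensity * window_area(wexp))
    px <- stats::runif(npar, wexp$xmin, wexp$xmax)
    py <- stats::runif(npar, wexp$ymin, wexp$ymax)
    noff <- stats::rpois(npar, mean_offspring)
    cx <- rep(px, noff); cy <- rep(py, noff)
    ntot <- sum(noff)
    x <- cx + stats::rnorm(ntot, 0, offspring_sigma)
    y <- cy + stats::rnorm(ntot, 0, offspring_sigma)
    keep <- points_inside(x, y, window)
    point_pattern(x[keep], y[keep], window)
  })
}

#' Simulate a Matern type-II hard-core pattern
#'
#' Regular stand-in pattern: a Poisson proposal is thinned so that no two
#' retained points are closer than `hardcore_radius`. Each proposal point
#' receives an i.i.d. uniform "age" mark and is deleted if any neighbour
#' within the hard-core radius has a smaller mark.
#'
#' @param proposal_intensity Intensity of the Poisson proposal, per um^2.
#' @param hardcore_radius Minimum allowed pairwise distance, um.
#' @inheritParams gen_poisson_pattern
#' @return A [point_pattern()] with minimum pairwise distance
#'   `>= hardcore_radius`.
#' @export
gen_hardcore_pattern <- function(proposal_intensity, hardcore_radius, window,
                                 seed = NULL) {
  stop_if_not_scalar_pos(hardcore_radius, "hardcore_radius", allow_zero = TRUE)
  with_seed(seed, {
    prop <- gen_poisson_pattern(proposal_intensity, window)
    n <- npoints(prop)
    if (n == 0L || hardcore_radius == 0) return(prop)
    age <- stats::runif(n)
    d <- as.matrix(stats::dist(cbind(prop$x, prop$y)))
    diag(d) <- Inf
    keep <- vapply(seq_len(n), function(i) {
      nb <- which(d[i, ] < hardcore_radius)
      !any(age[nb] < age[i])
    }, logical(1))
    point_pattern(prop$x[keep], prop$y[keep], window)
  })
}

#' Configuration for the growth--dispersal cluster simulator
#'
#' Parameters of a minimal mechanistic simulator for microcolony formation:
#' cells divide in place (daughters displaced by a small Gaussian jitter,
#' mimicking growth in a gel-like matrix that holds offspring in place) and
#' periodic shear events scatter whole clusters, mimicking gut contractions
#' that fluidize the content and disperse microcolonies.
#'
#' @param n_founders Number of founder cells (>= 1).
#' @param generations Number of synchronous doubling generations.
#' @param division_jitter_sigma Gaussian displacement of a daughter cell at
#'   division, um.
#' @param event_period Generations between shear events (an event occurs
#'   after every `event_period`-th generation); `Inf` disables events.
#' @param dispersal_fraction Probability that a given cluster (founder
#'   lineage) is scattered at an event, in `[0, 1]`.
#' @param seed Integer seed.
#' @param max_cells Population cap; exceeding it raises an error.
#' @return A `growth_dispersal_config` list.
#' @export
growth_dispersal_config <- function(n_founders, generations,
                                    division_jitter_sigma = 0.5,
                                    event_period = Inf,
                                    dispersal_fraction = 0,
                                    seed = NULL, max_cells = 1e6) {
  if (n_founders < 1) stop("'n_founders' must be >= 1")
  if (generations < 0) stop("'generations' must be >= 0")
  if (division_jitter_sigma < 0) stop("'division_jitter_sigma' must be >= 0")
  if (dispersal_fraction < 0 || dispersal_fraction > 1)
    stop("'dispersal_fraction' must be in [0, 1]")
  structure(list(n_founders = as.integer(n_founders),
                 generations = as.integer(generations),
                 division_jitter_sigma = division_jitter_sigma,
                 event_period = event_period,
                 dispersal_fraction = dispersal_fraction,
                 seed = seed, max_cells = max_cells),
            class = "growth_dispersal_config")
}

#' Simulate clustered patterns by growth with intermittent dispersal
#'
#' Founders are placed uniformly; every generation each cell duplicates and
#' the daughter is displaced by an isotropic Gaussian jitter. After every
#' `event_period` generations each cluster (founder lineage) is
#' independently scattered with probability `dispersal_fraction`: its cells
#' are re-placed uniformly in the window and become new singleton lineages.
#' Cells falling outside the window are clipped. The mechanism is a
#' deliberately minimal model of microcolony growth between gut
#' contractions; its rules are configurable, not canonical.
#'
#' @param config A [growth_dispersal_config()].
#' @param window A [spat_window()].
#' @return A [point_pattern()].
#' @export
gen_growth_dispersal_pattern <- function(config, window) {
  stopifnot(inherits(config, "growth_dispersal_config"))
  with_seed(config$seed, {
    x <- stats::runif(config$n_founders, window$xmin, window$xmax)
    y <- stats::runif(config$n_founders, window$ymin, window$ymax)
    lineage <- seq_len(config$n_founders)
    next_lineage <- config$n_founders + 1L
    gen <- 0L
    while (gen < config$generations) {
      gen <- gen + 1L
      if (2 * length(x) > config$max_cells)
        stop("population cap exceeded (", config$max_cells, " cells)")
      n <- length(x)
      x <- c(x, x + stats::rnorm(n, 0, config$division_jitter_sigma))
      y <- c(y, y + stats::rnorm(n, 0, config$division_jitter_sigma))
      lineage <- c(lineage, lineage)
      if (is.finite(config$event_period) &&
          gen %% config$event_period == 0 && config$dispersal_fraction > 0) {
        for (ln in unique(lineage)) {
          if (stats::runif(1) < config$dispersal_fraction) {
            idx <- which(lineage == ln)
            x[idx] <- stats::runif(length(idx), window$xmin, window$xmax)
            y[idx] <- stats::runif(length(idx), window$ymin, window$ymax)
            lineage[idx] <- seq(next_lineage, length.out = length(idx))
            next_lineage <- next_lineage + length(idx)
          }
        }
      }
    }
    keep <- points_inside(x, y, window)
    point_pattern(x[keep], y[keep], window)
  })
}
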