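#' Studentized permutation test between groups of H curves
#'
#' Compares two or more groups of per-image H curves with the Studentized
#' permutation test for groups of functional summaries. The observed
#' statistic is
#' \deqn{T = \sum_{i<j} \int_0^{r_{max}}
#'   \frac{(\bar H_i(r) - \bar H_j(r))^2}
#'        {s_i^2(r)/m_i + s_j^2(r)/m_j} \, dr,}
#' with group means, within-group sample variances and group sizes, the
#' integral taken by the trapezoid rule; radii where the pooled variance is
#' zero (or any group value undefined) contribute nothing. The null
#' distribution is obtained by uniformly reassigning whole patterns to
#' groups, preserving group sizes, and the p-value uses the add-one
#' convention `p = (1 + #\{T^* \ge T\}) / (1 + n_perm)` so it can never be
#' exactly zero.
#'
#' @param groups List of 2 or more groups; each group is a list of
#'   [kinhom_border()] summary functions (>= 2 per group) on a common
#'   radius grid.
#' @param r_max Upper limit of the analysis radius range, um (default 20).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the permutations.
#' @return An object of class `"group_test"`: fields `statistic`,
#'   `p_value`, `n_permutations`, `r_range`, `group_sizes`.
#' @export
studentized_permutation_test <- function(groups, r_max = 20, n_perm = 1000,
                                         seed = NULL) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2L))
    stop("each group needs at least 2 patterns (within-group variance)")
  all_sf <- do.call(c, groups)
  r <- check_common_grid(all_sf)
  if (r_max > max(r) + 1e-9) stop("'r_max' exceeds the radius grid")
  keep <- r <= r_max + 1e-12
  rr <- r[keep]
  hmat <- sapply(all_sf, function(s) s$Hhat[keep])  # radii x patterns
  grp <- rep(seq_along(groups), sizes)

  stat <- function(assign) {
    tot <- 0
    means <- vars <- vector("list", length(sizes))
    for (g in seq_along(sizes)) {
      hg <- hmat[, assign == g, drop = FALSE]
      means[[g]] <- rowMeans(hg)
      vars[[g]] <- apply(hg, 1L, stats::var)
    }
    for (i in seq_len(length(sizes) - 1L)) for (j in seq((i + 1L), length(sizes))) {
      den <- vars[[i]] / sizes[i] + vars[[j]] / sizes[j]
      num <- (means[[i]] - means[[j]])^2
      integrand <- ifelse(is.finite(den) & den > 0 & is.finite(num),
                          num / den, 0)
      tot <- tot + trapz(rr, integrand)
    }
    tot
  }

  t_obs <- stat(grp)
  with_seed(seed, {
    t_perm <- replicate(n_perm, stat(sample(grp)))
  })
  structure(list(statistic = t_obs,
                 p_value = (1 + sum(t_perm >= t_obs)) / (1 + n_perm),
                 n_permutations = n_perm,
                 r_range = c(0, r_max), group_sizes = as.integer(sizes)),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("Studentized permutation test: T = %.4g, p = %.4g (%d permutations, r in [0, %g] um, groups %s)\n",
              x$statistic, x$p_value, x$n_permutations, x$r_range[2],
              paste(x$group_sizes, collapse = "/")))
  invisible(x)
}

#' Bonferroni correction
#'
#' @param p_values Numeric vector of p-values.
#' @param m Number of comparisons (>= 1); defaults to `length(p_values)`.
#' @return `pmin(1, m * p_values)`.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (m < 1) stop("'m' must be >= 1")
  pmin(1, m * p_values)
}

#' Test a group of patterns against complete spatial randomness
#'
#' The permutation test needs two groups, but a common question is whether
#' one set of images deviates from CSR. This helper reconstructs a matched
#' null group: for each observed pattern it simulates a homogeneous Poisson
#' pattern with the same window and expected point count, computes its
#' summary function with estimated intensity under the same settings, and
#' runs the two-group test against the observed summaries.
#'
#' @param patterns List of >= 2 [point_pattern()] objects.
#' @param radii Radius grid (see [default_radii()]).
#' @param bandwidth Intensity bandwidth passed to [estimate_intensity()].
#' @param r_max,n_perm,seed Passed to [studentized_permutation_test()].
#' @return A `group_test` (observed group vs matched CSR group).
#' @export
test_against_csr <- function(patterns, radii = default_radii(),
                             bandwidth = "auto", r_max = 20,
                             n_perm = 1000, seed = NULL) {
  if (length(patterns) < 2L) stop("need at least 2 patterns")
  with_seed(seed, {
    obs <- lapply(patterns, function(p)
      kinhom_border(p, estimate_intensity(p, bandwidth), radii))
    null <- lapply(patterns, function(p) {
      lam <- npoints(p) / window_area(p$window)
      q <- gen_poisson_pattern(lam, p$window)
      while (npoints(q) < 2L) q <- gen_poisson_pattern(lam, p$window)
      kinhom_border(q, estimate_intensity(q, bandwidth), radii)
    })
    studentized_permutation_test(list(obs, null), r_max = r_max,
                                 n_perm = n_perm)
  })
}
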