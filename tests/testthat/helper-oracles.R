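# Independent oracles and fixture builders shared across tests.

# Brute-force double-loop border-corrected inhomogeneous K estimator.
brute_kinhom <- function(pp, lam, radii) {
  n <- npoints(pp)
  w <- pp$window
  b <- pmin(pp$x - w$xmin, w$xmax - pp$x, pp$y - w$ymin, w$ymax - pp$y)
  sapply(radii, function(r) {
    num <- 0; den <- 0; nf <- 0
    for (i in seq_len(n)) {
      if (b[i] >= r) {
        nf <- nf + 1
        den <- den + 1 / lam[i]
        for (j in seq_len(n)) {
          if (j != i) {
            d <- sqrt((pp$x[i] - pp$x[j])^2 + (pp$y[i] - pp$y[j])^2)
            if (d <= r) num <- num + (1 / lam[i]) * (1 / lam[j])
          }
        }
      }
    }
    if (nf == 0) NA_real_ else num / den
  })
}

# Exact one-sided Mann-Whitney p-value by enumerating all group
# assignments of the pooled sample (no ties assumed).
exact_mwu_less <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pooled), n1)
  obs <- sum(rank(pooled)[seq_len(n1)])
  stats <- apply(idx, 2, function(k) sum(rank(pooled)[k]))
  mean(stats <= obs)
}

# Closed-form K of a Thomas process.
thomas_K <- function(r, kappa, sigma) {
  pi * r^2 + (1 - exp(-r^2 / (4 * sigma^2))) / kappa
}

# Well-separated pattern for detection round trips: hard-core spacing of
# at least `sep` between cell centres.
separated_pattern <- function(window, sep, intensity = 0.01, seed = NULL) {
  gen_hardcore_pattern(intensity, sep, window, seed = seed)
}
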