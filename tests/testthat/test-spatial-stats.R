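test_that("intensity estimates are positive, floored, and roughly unbiased", {
  w <- spat_window(0, 10, 0, 10)
  # two far points, small bandwidth: leave-one-out sums vanish to the floor
  far <- point_pattern(c(1, 9), c(1, 9), w)
  est <- estimate_intensity(far, bandwidth = 0.1)
  expect_true(all(est$values > 0))
  expect_lt(max(est$values), 1e-9)
  expect_error(estimate_intensity(point_pattern(1, 1, w)), "at least 2")
  # consistency on homogeneous patterns
  w200 <- spat_window(0, 200, 0, 200)
  means <- vapply(1:20, function(s) {
    p <- gen_poisson_pattern(0.05, w200, seed = 900 + s)
    mean(estimate_intensity(p)$values)
  }, numeric(1))
  expect_lt(abs(mean(means) - 0.05) / 0.05, 0.2)
})

test_that("the border-corrected estimator reproduces the hand-worked pair", {
  pp <- point_pattern(c(5, 5), c(5, 6), spat_window(0, 10, 0, 10))
  sf <- kinhom_border(pp, lambda = 0.02, radii = c(0, 1, 2))
  expect_equal(sf$Khat[3], 50)
  expect_equal(sf$Lhat[3], sqrt(50 / pi), tolerance = 1e-12)
  expect_equal(sf$Hhat[3], sqrt(50 / pi) - 2, tolerance = 1e-12)
  expect_equal(sf$Hhat[3], 1.989, tolerance = 1e-3)
})

test_that("estimator agrees with the brute-force double loop to 1e-10", {
  radii <- default_radii(10, 0.5)
  for (s in 1:3) {
    w <- spat_window(0, 50, 0, 50)
    pp <- gen_poisson_pattern(0.015, w, seed = 30 + s)  # ~ 40 points
    lam <- stats::runif(npoints(pp), 0.01, 0.05)
    expect_lt(max(abs(kinhom_border(pp, lam, radii)$Khat -
                        brute_kinhom(pp, lam, radii)), na.rm = TRUE), 1e-10)
  }
})

test_that("patterns without close pairs give K = 0 and H = -r", {
  pp <- point_pattern(c(20, 80), c(20, 80), spat_window(0, 100, 0, 100))
  sf <- kinhom_border(pp, 0.001, default_radii(10, 1))
  expect_true(all(sf$Khat == 0))
  expect_equal(sf$Hhat, -sf$r)
})

test_that("empty and undefined cases are signalled", {
  w <- spat_window(0, 100, 0, 100)
  expect_warning(sf <- kinhom_border(point_pattern(numeric(0), numeric(0), w),
                                     0.01), "empty")
  expect_true(all(is.na(sf$Khat)))
  expect_error(cluster_radius(sf), "undefined")
  expect_error(kinhom_border(point_pattern(1, 1, w), 0.01,
                             radii = seq(0, 80, 1)), "half the shorter")
})

test_that("K is unbiased under CSR when the true intensity is supplied", {
  w <- spat_window(0, 100, 0, 100)
  radii <- default_radii(10, 0.5)
  km <- sapply(1:100, function(s)
    kinhom_border(gen_poisson_pattern(0.05, w, seed = 1200 + s), 0.05,
                  radii)$Khat)
  mk <- rowMeans(km)
  se <- apply(km, 1, stats::sd) / sqrt(100)
  inside <- abs(mk - pi * radii^2) <= 1.96 * se
  expect_gte(mean(inside[-1]), 0.9)
})

test_that("ratio pooling sums numerators and denominators, not ratios", {
  w <- spat_window(0, 100, 0, 100)
  radii <- default_radii(10, 1)
  s1 <- kinhom_border(gen_poisson_pattern(0.05, w, seed = 41), 0.05, radii)
  s2 <- kinhom_border(gen_thomas_pattern(0.002, 20, 2, w, seed = 42), 0.04,
                      radii)
  po <- pool_and_ci(list(s1, s2))
  expect_equal(po$Khat, (s1$numerator + s2$numerator) /
                 (s1$denominator + s2$denominator))
  # identical inputs: pooled H equals each input and the band has width 0
  pid <- pool_and_ci(list(s1, s1, s1))
  expect_equal(pid$Hhat, s1$Hhat)
  expect_equal(pid$upper, pid$lower)
  expect_error(pool_and_ci(list(s1)), "at least 2")
  expect_error(pool_and_ci(list(s1, kinhom_border(
    gen_poisson_pattern(0.05, w, seed = 43), 0.05, default_radii(5, 1)))),
    "common radius grid")
})

test_that("cluster radius is half the argmax of H, undefined when H <= 0", {
  fake <- list(r = 0:10, Hhat = c(0, 1, 2, 3, 3.5, 3, 2, 3.5, 1, 0, -1))
  expect_equal(cluster_radius(fake), 2)  # first tie at r = 4 wins
  fake$Hhat <- -abs(fake$Hhat)
  expect_true(is.na(cluster_radius(fake)))
})

test_that("Thomas cluster-radius readout lands within a factor of two", {
  w <- spat_window(0, 200, 0, 200)
  sig <- 2
  hits <- vapply(1:20, function(s) {
    sfs <- lapply(1:4, function(i)
      kinhom_border(gen_thomas_pattern(0.002, 20, sig, w,
                                       seed = 3000 + 10 * s + i), 0.04))
    est <- cluster_radius(pool_and_ci(sfs))
    !is.na(est) && est >= sig && est <= 8 * sig   # factor 2 around 2 sigma
  }, logical(1))
  expect_gte(sum(hits), 18)
})
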