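w100 <- spat_window(0, 100, 0, 100)

test_that("Poisson generator hits the zero case and stays in the window", {
  expect_equal(npoints(gen_poisson_pattern(0, w100, seed = 1)), 0L)
  pp <- gen_poisson_pattern(0.05, w100, seed = 2)
  expect_true(all(pp$x >= 0 & pp$x <= 100 & pp$y >= 0 & pp$y <= 100))
  expect_error(gen_poisson_pattern(-1, w100), "non-negative")
  # reproducibility
  expect_equal(gen_poisson_pattern(0.05, w100, seed = 7)$x,
               gen_poisson_pattern(0.05, w100, seed = 7)$x)
})

test_that("Poisson mean count matches its intensity over replicate seeds", {
  counts <- vapply(1:100, function(s)
    npoints(gen_poisson_pattern(0.1, w100, seed = s)), numeric(1))
  # Poisson(1000): mean over 100 replicates within +/- 3.16 SE of 1000
  expect_gte(mean(counts), 990)
  expect_lte(mean(counts), 1010)
})

test_that("inhomogeneous Poisson thinning follows the intensity surface", {
  lam <- function(x, y) 0.2 * (x / 100)
  pp <- gen_poisson_pattern(lam, w100, seed = 3)
  # twice as many points in the right half as expected under uniformity
  expect_gt(mean(pp$x > 50), 0.6)
  expect_error(gen_poisson_pattern(function(x, y) -x, w100, seed = 1),
               "non-negative")
})

test_that("Poisson output passes a quadrat chi-square uniformity screen", {
  # true pass rate at alpha = 0.01 is 99%; 1000 seeds keep the binomial
  # fluctuation of the observed rate well clear of the 98% requirement
  pass <- vapply(1:1000, function(s) {
    p <- gen_poisson_pattern(0.1, w100, seed = 4000 + s)
    counts <- as.vector(table(cut(p$x, seq(0, 100, 20)),
                              cut(p$y, seq(0, 100, 20))))
    x2 <- sum((counts - mean(counts))^2 / mean(counts))
    stats::pchisq(x2, df = 24, lower.tail = FALSE) > 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.98)
})

test_that("Thomas generator handles degenerate parameters", {
  expect_equal(npoints(gen_thomas_pattern(0.005, 0, 2, w100, seed = 1)), 0L)
  # sigma = 0: offspring coincide with parent locations
  pp <- gen_thomas_pattern(0.002, 10, 0, w100, seed = 2)
  expect_lte(length(unique(paste(pp$x, pp$y))), npoints(pp))
  expect_lte(length(unique(round(pp$x, 9))), 0.5 * npoints(pp))
})

test_that("Thomas mean count matches kappa |W| mu over replicate seeds", {
  w200 <- spat_window(0, 200, 0, 200)
  counts <- vapply(1:100, function(s)
    npoints(gen_thomas_pattern(0.005, 10, 2, w200, seed = 500 + s)),
    numeric(1))
  expected <- 0.005 * 200^2 * 10
  # compound-Poisson count: Var = kappa |W| mu (1 + mu); 3 SE band
  se <- sqrt(0.005 * 200^2 * 10 * 11 / 100)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("hard-core thinning enforces the minimum distance", {
  pp <- gen_hardcore_pattern(0.005, 5, w100, seed = 3)
  d <- stats::dist(cbind(pp$x, pp$y))
  expect_gte(min(d), 5)
  # radius 0: no thinning, identical to the Poisson proposal
  p0 <- gen_hardcore_pattern(0.005, 0, w100, seed = 3)
  prop <- gen_poisson_pattern(0.005, w100, seed = 3)
  expect_equal(p0$x, prop$x)
  # thinning monotonicity
  expect_lte(npoints(pp), npoints(p0))
})

test_that("growth-dispersal simulator follows its counting rules", {
  w <- spat_window(0, 200, 0, 200)
  cfg0 <- growth_dispersal_config(50, 0, seed = 1)
  expect_equal(npoints(gen_growth_dispersal_pattern(cfg0, w)), 50L)
  # jitter 0, no dispersal: exact doubling, nothing clipped
  cfg <- growth_dispersal_config(10, 4, division_jitter_sigma = 0, seed = 2)
  expect_equal(npoints(gen_growth_dispersal_pattern(cfg, w)), 10L * 2^4)
  expect_error(gen_growth_dispersal_pattern(
    growth_dispersal_config(10, 25, division_jitter_sigma = 0, seed = 1,
                            max_cells = 1e4), w), "cap")
  expect_error(growth_dispersal_config(0, 1), "n_founders")
  expect_error(growth_dispersal_config(2, 1, dispersal_fraction = 1.5),
               "dispersal_fraction")
})

test_that("growth without dispersal produces clustered H curves", {
  w <- spat_window(0, 200, 0, 200)
  radii <- default_radii()
  sel <- radii >= 1 & radii <= 10
  pos <- vapply(1:25, function(s) {
    cfg <- growth_dispersal_config(50, 5, division_jitter_sigma = 1, seed = s)
    pp <- gen_growth_dispersal_pattern(cfg, w)
    sf <- kinhom_border(pp, estimate_intensity(pp), radii)
    all(sf$Hhat[sel] > 0)
  }, logical(1))
  expect_gte(sum(pos), 24)
})
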