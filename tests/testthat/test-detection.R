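test_that("top-hat preprocessing flattens backgrounds and keeps blobs", {
  # constant image maps to zero
  flat <- matrix(0.7, 64, 64)
  expect_true(all(preprocess(flat, 0.18) == 0))
  # linear ramp + one blob: ramp suppressed, blob preserved
  n <- 120
  ramp_amp <- 0.5
  ramp <- matrix(rep(seq(0, ramp_amp, length.out = n), n), n, n)
  blob <- matrix(0, n, n)
  cx <- 60.5
  for (i in 55:66) for (j in 55:66)
    blob[i, j] <- 2 * exp(-((i - cx)^2 + (j - cx)^2) / (2 * 2^2))
  out <- preprocess(ramp + blob, 0.18, detection_params(tophat_radius = 1.2))
  expect_true(all(out >= 0))
  peak <- max(out[50:70, 50:70])
  residual <- max(out[, 1:40])   # blob-free strip
  # residual ramp relative to the blob peak: >= 90% suppression of a ramp
  # whose raw amplitude is a quarter of the blob's
  expect_lt(residual / peak, 0.1 * ramp_amp / (0.8 * 2))
  expect_error(preprocess(flat, 0.18, detection_params(tophat_radius = 0.05)),
               "smaller than one pixel")
})

test_that("segmentation counts disjoint blobs and reacts to the threshold", {
  blank <- matrix(0, 64, 64)
  seg0 <- segment(blank, 0.18)
  expect_equal(nrow(seg0$regions), 0L)
  w <- spat_window(0, 11.52, 0, 11.52)
  pp <- point_pattern(c(2.5, 6, 9.2), c(2.5, 8.5, 4), w)
  img <- render_image(pp, cell_radius = 0.5, pixel_size = 0.18)
  f <- preprocess(img$pixels, 0.18)
  seg <- segment(f, 0.18)
  expect_equal(nrow(seg$regions), 3L)
  # raising the threshold never increases foreground size
  hi <- segment(f, 0.18, detection_params(threshold_factor = 4))
  expect_lte(sum(hi$mask), sum(seg$mask))
})

test_that("region classification applies the morphological rules as a partition", {
  regions <- data.frame(
    x_um = 0, y_um = 0,
    area_um2 = c(0.8, 60, 5, 0.05, 1.5),
    eccentricity = c(0.5, 0.99, 0.5, 0.1, 0.99),
    solidity = c(0.95, 0.9, 0.9, 1, 0.95),
    major_um = 1, minor_um = 1,
    aspect = c(1.2, 5, 1.5, 1, 1.1))
  cls <- classify_regions(regions)
  expect_equal(as.character(cls),
               c("cell", "particle", "cluster", "noise", "cluster"))
  expect_true(all(table(seq_along(cls), cls) %in% c(0, 1)))  # one class each
})

test_that("touching cell pairs split into two accurate centroids", {
  w <- spat_window(0, 9.216, 0, 9.216)
  r <- 0.5
  pp <- point_pattern(c(4.2, 4.2 + 1.5 * r), c(4.5, 4.5), w)
  img <- render_image(pp, cell_radius = r, pixel_size = 0.09)
  f <- preprocess(img$pixels, 0.09)
  seg <- segment(f, 0.09)
  expect_equal(nrow(seg$regions), 1L)  # fused into one region
  sp <- split_clusters(seg, 1, f, 0.09)
  expect_equal(nrow(sp), 2L)
  m <- match_to_truth(sp, pp, max_dist = 0.5)
  expect_equal(m$n_matched, 2L)
  expect_lt(m$rmse_um, 0.09)  # within 1 px
  # a single round blob routed to the splitter stays one centroid
  pp1 <- point_pattern(4.5, 4.5, w)
  img1 <- render_image(pp1, cell_radius = r, pixel_size = 0.09)
  f1 <- preprocess(img1$pixels, 0.09)
  seg1 <- segment(f1, 0.09)
  sp1 <- split_clusters(seg1, 1, f1, 0.09)
  expect_equal(nrow(sp1), 1L)
  expect_lt(abs(sp1$x_um - 4.5), 0.09)
})

test_that("the full pipeline round-trips separated cells and removes particles", {
  blank <- matrix(0, 64, 64)
  expect_equal(detect_cells(blank, 0.18)$total_count, 0L)
  w <- spat_window(0, 64.8, 0, 64.8)
  pp <- separated_pattern(w, sep = 3, seed = 21)
  img <- render_image(pp, cell_radius = 0.5, pixel_size = 0.18)
  res <- detect_cells(img)
  m <- match_to_truth(res, pp, max_dist = 1)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_lt(m$rmse_um, 0.18)
  # adding non-overlapping food particles leaves cell recall intact
  imgp <- render_image(pp, cell_radius = 0.5, pixel_size = 0.18,
                       n_food_particles = 2, seed = 22)
  resp <- detect_cells(imgp)
  mp <- match_to_truth(resp, pp, max_dist = 1)
  expect_equal(resp$removed_particles, 2L)
  expect_equal(mp$recall, 1)
  expect_equal(mp$precision, 1)
})

test_that("detection is invariant to affine intensity rescaling", {
  w <- spat_window(0, 46.08, 0, 46.08)
  pp <- separated_pattern(w, sep = 3, seed = 23)
  img <- render_image(pp, cell_radius = 0.5, pixel_size = 0.18)
  a <- detect_cells(img$pixels, 0.18)
  b <- detect_cells(5.3 * img$pixels + 0.71, 0.18)
  expect_equal(a$total_count, b$total_count)
  expect_equal(a$cells$x_um, b$cells$x_um, tolerance = 1e-9)
  expect_equal(a$cells$y_um, b$cells$y_um, tolerance = 1e-9)
})

test_that("truth matching counts hits, misses and spurious detections", {
  w <- spat_window(0, 20, 0, 20)
  empty_truth <- point_pattern(numeric(0), numeric(0), w)
  empty_det <- data.frame(x_um = numeric(0), y_um = numeric(0))
  m0 <- match_to_truth(empty_det, empty_truth, max_dist = 1)
  expect_equal(m0$precision, 1)
  expect_equal(m0$recall, 1)
  truth <- point_pattern(c(0, 10), c(0, 10), w)
  m1 <- match_to_truth(data.frame(x_um = 0.5, y_um = 0), truth, max_dist = 1)
  expect_equal(m1$precision, 1)
  expect_equal(m1$recall, 0.5)
  expect_equal(m1$rmse_um, 0.5)
  # identical sets
  m2 <- match_to_truth(data.frame(x_um = c(0, 10), y_um = c(0, 10)), truth,
                       max_dist = 1)
  expect_equal(m2$precision, 1)
  expect_equal(m2$recall, 1)
  expect_equal(m2$rmse_um, 0)
  # one spurious detection costs precision, not recall
  m3 <- match_to_truth(data.frame(x_um = c(0, 10, 15), y_um = c(0, 10, 15)),
                       truth, max_dist = 1)
  expect_equal(m3$recall, 1)
  expect_equal(m3$precision, 2 / 3)
})
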