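#' Render a synthetic fluorescence microscopy image of a point pattern
#'
#' Produces a single-channel image emulating a maximum-intensity projection
#' of FISH-stained bacteria: each cell is an isotropic Gaussian blob of
#' scale `cell_radius / 2` (about 95% of its mass falls within
#' `cell_radius` of the centre), optional autofluorescent "food particles"
#' are drawn as bright elongated rectangles (area at least 10 cell
#' footprints, aspect ratio at least 3, matching the detector's removal
#' rule), and additive Gaussian noise is applied. The input pattern is
#' stored unchanged as the ground truth.
#'
#' Pixel `(i, j)` (1-based) has its centre at
#' `(xmin + (i - 0.5) * pixel_size, ymin + (j - 0.5) * pixel_size)`; the
#' first matrix index runs along x.
#'
#' @param pattern A [point_pattern()] of cell centres.
#' @param cell_radius Cell radius in um (> 0).
#' @param peak_intensity Peak intensity of a cell blob (arbitrary units).
#' @param background Constant background level (a.u.).
#' @param noise_sigma Standard deviation of additive Gaussian noise (a.u.).
#' @param pixel_size Micrometres per pixel (> 0).
#' @param n_food_particles Number of food particles to draw.
#' @param particle_intensity Intensity of particle interiors (a.u.);
#'   defaults to `peak_intensity`.
#' @param particle_area_min Minimum particle area in um^2; rendered
#'   particles exceed both this and 10 cell footprints, so the truth is
#'   consistent with the detector's default removal rule.
#' @param seed Integer seed.
#' @return An object of class `"synthetic_image"` with fields `pixels`
#'   (matrix, x by y), `pixel_size`, `truth` (the input pattern) and
#'   `particle_truth` (a data frame of particle footprints).
#' @export
render_image <- function(pattern, cell_radius = 0.5, peak_intensity = 1,
                         background = 0, noise_sigma = 0,
                         pixel_size = 184.5 / 2048, n_food_particles = 0,
                         particle_intensity = peak_intensity,
                         particle_area_min = 20, seed = NULL) {
  stopifnot(inherits(pattern, "point_pattern"))
  stop_if_not_scalar_pos(cell_radius, "cell_radius")
  stop_if_not_scalar_pos(pixel_size, "pixel_size")
  w <- pattern$window
  nx <- max(1L, as.integer(round((w$xmax - w$xmin) / pixel_size)))
  ny <- max(1L, as.integer(round((w$ymax - w$ymin) / pixel_size)))
  with_seed(seed, {
    img <- matrix(background, nx, ny)
    sigma <- cell_radius / 2
    sig_px <- sigma / pixel_size
    half <- max(2L, ceiling(4 * sig_px))
    for (k in seq_len(npoints(pattern))) {
      # continuous pixel coordinates of the centre (1-based pixel centres)
      cx <- (pattern$x[k] - w$xmin) / pixel_size + 0.5
      cy <- (pattern$y[k] - w$ymin) / pixel_size + 0.5
      i0 <- max(1L, floor(cx) - half); i1 <- min(nx, floor(cx) + half)
      j0 <- max(1L, floor(cy) - half); j1 <- min(ny, floor(cy) + half)
      if (i0 > i1 || j0 > j1) next
      ii <- i0:i1; jj <- j0:j1
      gx <- exp(-((ii - cx)^2) / (2 * sig_px^2))
      gy <- exp(-((jj - cy)^2) / (2 * sig_px^2))
      img[ii, jj] <- img[ii, jj] + peak_intensity * outer(gx, gy)
    }
    particle_truth <- NULL
    if (n_food_particles > 0) {
      cell_area <- pi * cell_radius^2
      pwidth <- 2 * cell_radius
      plength <- max(3.5 * pwidth,
                     1.25 * max(10 * cell_area, particle_area_min) / pwidth)
      rows <- vector("list", n_food_particles)
      px_x <- ((seq_len(nx)) - 0.5) * pixel_size + w$xmin
      px_y <- ((seq_len(ny)) - 0.5) * pixel_size + w$ymin
      margin <- 2 * cell_radius
      for (k in seq_len(n_food_particles)) {
        # rejection sampling keeps particles clear of cells and of each
        # other, so particle truth and cell truth stay independent
        placed <- FALSE
        for (try in seq_len(200L)) {
          cxu <- stats::runif(1, w$xmin + plength / 2, w$xmax - plength / 2)
          cyu <- stats::runif(1, w$ymin + plength / 2, w$ymax - plength / 2)
          th <- stats::runif(1, 0, pi)
          if (npoints(pattern)) {
            uu <- (pattern$x - cxu) * cos(th) + (pattern$y - cyu) * sin(th)
            vv <- -(pattern$x - cxu) * sin(th) + (pattern$y - cyu) * cos(th)
            if (any(abs(uu) <= plength / 2 + margin &
                    abs(vv) <= pwidth / 2 + margin)) next
          }
          clash <- FALSE
          for (prev in rows) if (!is.null(prev)) {
            if (sqrt((prev$x_um - cxu)^2 + (prev$y_um - cyu)^2) <
                plength + margin) { clash <- TRUE; break }
          }
          if (clash) next
          placed <- TRUE
          break
        }
        if (!placed)
          warning("could not place a food particle clear of cells; placing anyway")
        dx <- outer(px_x - cxu, rep(1, ny))
        dy <- outer(rep(1, nx), px_y - cyu)
        u <- dx * cos(th) + dy * sin(th)
        v <- -dx * sin(th) + dy * cos(th)
        inside <- abs(u) <= plength / 2 & abs(v) <= pwidth / 2
        img[inside] <- pmax(img[inside], background + particle_intensity)
        rows[[k]] <- data.frame(x_um = cxu, y_um = cyu, length_um = plength,
                                width_um = pwidth, angle_rad = th)
      }
      particle_truth <- do.call(rbind, rows)
    }
    if (noise_sigma > 0)
      img <- img + matrix(stats::rnorm(nx * ny, 0, noise_sigma), nx, ny)
    structure(list(pixels = img, pixel_size = pixel_size, truth = pattern,
                   particle_truth = particle_truth),
              class = "synthetic_image")
  })
}

#' @export
print.synthetic_image <- function(x, ...) {
  cat(sprintf("synthetic image: %d x %d px at %.4f um/px, %d true cells, %d particles\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              npoints(x$truth),
              if (is.null(x$particle_truth)) 0L else nrow(x$particle_truth)))
  invisible(x)
}

#' Write / read a synthetic image as TIFF
#'
#' Intensities are rescaled to `[0, 1]` for storage (32-bit float TIFF keeps
#' them exact up to the linear rescaling). Requires the `tiff` package.
#'
#' @param img A `synthetic_image` (write) or file path (read).
#' @param path Output file path.
#' @return `write_image_tiff` returns `path` invisibly; `read_image_tiff`
#'   returns a plain intensity matrix oriented as in [render_image()].
#' @export
write_image_tiff <- function(img, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF files")
  px <- img$pixels
  rng <- range(px)
  if (diff(rng) > 0) px <- (px - rng[1]) / diff(rng)
  # tiff expects [row = y from top]; transpose so x runs along columns
  tiff::writeTIFF(t(px)[rev(seq_len(ncol(px))), , drop = FALSE], path,
                  bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read TIFF files")
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  t(m[rev(seq_len(nrow(m))), , drop = FALSE])
}
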