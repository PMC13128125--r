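#' Parameters of the cell-detection pipeline
#'
#' Tunable knobs of the image-analysis pipeline. The morphological
#' defaults (cell area 0.2--3 um^2, eccentricity at most 0.95, solidity at
#' least 0.8, particle area at least 20 um^2 with aspect ratio at least 3,
#' threshold at 2x the mean filtered intensity) are tuned on synthetic
#' fixtures and are not canonical; every analysis should record the values
#' used.
#'
#' @param tophat_radius Disk radius of the white top-hat structuring
#'   element, um; must exceed one pixel after unit conversion.
#' @param threshold_factor Binarization threshold as a multiple of the
#'   mean filtered pixel intensity.
#' @param cell_area_range Length-2 vector, plausible single-cell area
#'   range in um^2.
#' @param eccentricity_max Maximum eccentricity of a single cell, in [0, 1].
#' @param solidity_min Minimum solidity (area / convex area) of a single
#'   cell, in (0, 1].
#' @param particle_area_min Minimum area of a food particle, um^2.
#' @param particle_aspect_min Minimum major/minor axis ratio of a food
#'   particle.
#' @param split_dilation_radius Disk radius (pixels) used to close the
#'   edge map when splitting clusters (default 1).
#' @return A `detection_params` list.
#' @export
detection_params <- function(tophat_radius = 2,
                             threshold_factor = 2,
                             cell_area_range = c(0.2, 3),
                             eccentricity_max = 0.95,
                             solidity_min = 0.8,
                             particle_area_min = 20,
                             particle_aspect_min = 3,
                             split_dilation_radius = 1) {
  stop_if_not_scalar_pos(tophat_radius, "tophat_radius")
  stop_if_not_scalar_pos(threshold_factor, "threshold_factor")
  if (length(cell_area_range) != 2L || diff(cell_area_range) <= 0 ||
      any(cell_area_range <= 0))
    stop("'cell_area_range' must be an increasing positive (min, max) pair")
  if (eccentricity_max < 0 || eccentricity_max > 1)
    stop("'eccentricity_max' must be in [0, 1]")
  if (solidity_min <= 0 || solidity_min > 1)
    stop("'solidity_min' must be in (0, 1]")
  structure(list(tophat_radius = tophat_radius,
                 threshold_factor = threshold_factor,
                 cell_area_range = cell_area_range,
                 eccentricity_max = eccentricity_max,
                 solidity_min = solidity_min,
                 particle_area_min = particle_area_min,
                 particle_aspect_min = particle_aspect_min,
                 split_dilation_radius = split_dilation_radius),
            class = "detection_params")
}

#' Background removal and contrast stretch
#'
#' White top-hat filtering with a disk structuring element removes
#' background structures larger than a cell (the image minus its
#' morphological opening), then intensities are stretched so that the
#' 99.9th percentile maps to full scale. Because the later binarization
#' threshold is mean-relative, the whole pipeline is invariant to affine
#' rescaling of the input intensities.
#'
#' @param image Non-negative 2-D intensity matrix (x along the first
#'   dimension).
#' @param pixel_size Micrometres per pixel.
#' @param params A [detection_params()].
#' @return Filtered non-negative matrix of the same size.
#' @export
preprocess <- function(image, pixel_size, params = detection_params()) {
  if (!is.matrix(image) || any(image < 0, na.rm = TRUE))
    stop("'image' must be a non-negative 2-D matrix")
  rpx <- round(params$tophat_radius / pixel_size)
  if (rpx < 1) stop("'tophat_radius' is smaller than one pixel")
  brush <- EBImage::makeBrush(2L * rpx + 1L, shape = "disc")
  filtered <- EBImage::imageData(EBImage::whiteTopHat(EBImage::Image(image), brush))
  filtered[filtered < 0] <- 0
  q <- stats::quantile(filtered, 0.999, names = FALSE)
  if (q > 0) filtered <- filtered / q
  filtered
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally with a small union-find over label ids.
label_components_8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  nlab <- max(lab)
  if (nlab < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  if (nrow(pairs)) {
    parent <- seq_len(nlab)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(nlab), find, integer(1))
    relab <- match(root, sort(unique(root)))
    lab[lab > 0] <- relab[lab[lab > 0]]
  }
  lab
}

# Shoelace area of the convex hull of pixel centres, with a half-perimeter
# + 1 correction approximating the pixelated convex area.
hull_pixel_area <- function(ix, iy) {
  if (length(ix) <= 2L) return(length(ix))
  h <- grDevices::chull(ix, iy)
  hx <- ix[h]; hy <- iy[h]
  n <- length(hx)
  j <- c(2:n, 1L)
  area <- abs(sum(hx * hy[j] - hx[j] * hy)) / 2
  perim <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
  area + perim / 2 + 1
}

# Shape and intensity properties of one labeled region.
region_props_one <- function(idx, dims, intensity, pixel_size) {
  ix <- ((idx - 1L) %% dims[1]) + 1L
  iy <- ((idx - 1L) %/% dims[1]) + 1L
  wt <- intensity[idx]
  if (sum(wt) <= 0) wt <- rep(1, length(idx))
  cx <- sum(ix * wt) / sum(wt)
  cy <- sum(iy * wt) / sum(wt)
  npx <- length(idx)
  # binary second central moments + 1/12 pixel-extent term
  mx <- mean(ix); my <- mean(iy)
  cxx <- mean((ix - mx)^2) + 1 / 12
  cyy <- mean((iy - my)^2) + 1 / 12
  cxy <- mean((ix - mx) * (iy - my))
  tr <- cxx + cyy
  det <- cxx * cyy - cxy^2
  disc <- sqrt(max(0, tr^2 / 4 - det))
  l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 1e-12)
  data.frame(
    x_um = (cx - 0.5) * pixel_size,
    y_um = (cy - 0.5) * pixel_size,
    area_um2 = npx * pixel_size^2,
    eccentricity = sqrt(max(0, 1 - l2 / l1)),
    solidity = min(1, npx / hull_pixel_area(ix, iy)),
    major_um = 4 * sqrt(l1) * pixel_size,
    minor_um = 4 * sqrt(l2) * pixel_size,
    aspect = sqrt(l1 / l2))
}

#' Threshold a filtered image and label connected regions
#'
#' The binarization threshold is `threshold_factor` times the mean pixel
#' intensity of the filtered image. Foreground pixels are labeled as
#' 8-connected components and region properties (area, intensity-weighted
#' centroid, eccentricity, solidity, axis lengths) are computed in
#' micrometres. Pixel centres sit at `(i - 0.5) * pixel_size` so reported
#' coordinates are continuous positions with origin at the image corner.
#'
#' @inheritParams preprocess
#' @param filtered Output of [preprocess()].
#' @return A list: `mask` (logical matrix), `labels` (integer matrix),
#'   `regions` (data frame of properties, one row per region), `pixels`
#'   (list of pixel index vectors per region), `threshold`.
#' @export
segment <- function(filtered, pixel_size, params = detection_params()) {
  thr <- params$threshold_factor * mean(filtered)
  mask <- filtered > thr
  lab <- label_components_8(mask)
  nlab <- max(lab)
  pix <- if (nlab > 0) split(which(lab > 0), lab[lab > 0]) else list()
  regions <- if (nlab > 0)
    do.call(rbind, lapply(pix, region_props_one, dims = dim(filtered),
                          intensity = filtered, pixel_size = pixel_size))
  else region_props_one(integer(0), dim(filtered), filtered, pixel_size)[0, ]
  rownames(regions) <- NULL
  list(mask = mask, labels = lab, regions = regions, pixels = unname(pix),
       threshold = thr)
}

#' Classify labeled regions into cells, clusters, particles and noise
#'
#' A region is a food particle if its area is at least `particle_area_min`
#' and its major/minor axis ratio at least `particle_aspect_min`; a single
#' cell if its area lies in `cell_area_range`, eccentricity is at most
#' `eccentricity_max` and solidity at least `solidity_min`; any other
#' region larger than the minimum cell area is a cluster candidate; the
#' rest is noise. Every region lands in exactly one class.
#'
#' @param regions Region-property data frame from [segment()].
#' @param params A [detection_params()].
#' @return Factor with levels `cell`, `cluster`, `particle`, `noise`.
#' @export
classify_regions <- function(regions, params = detection_params()) {
  n <- nrow(regions)
  cls <- rep("noise", n)
  is_particle <- regions$area_um2 >= params$particle_area_min &
    regions$aspect >= params$particle_aspect_min
  is_cell <- !is_particle &
    regions$area_um2 >= params$cell_area_range[1] &
    regions$area_um2 <= params$cell_area_range[2] &
    regions$eccentricity <= params$eccentricity_max &
    regions$solidity >= params$solidity_min
  is_cluster <- !is_particle & !is_cell &
    regions$area_um2 > params$cell_area_range[1]
  cls[is_cluster] <- "cluster"
  cls[is_cell] <- "cell"
  cls[is_particle] <- "particle"
  factor(cls, levels = c("cell", "cluster", "particle", "noise"))
}

# Sobel gradients with replicated borders.
sobel_gradients <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  px <- img[c(1, 1:(nr - 1)), , drop = FALSE]
  nx <- img[c(2:nr, nr), , drop = FALSE]
  py <- img[, c(1, 1:(nc - 1)), drop = FALSE]
  ny <- img[, c(2:nc, nc), drop = FALSE]
  pxy <- px[, c(1, 1:(nc - 1)), drop = FALSE]; pxn <- px[, c(2:nc, nc), drop = FALSE]
  nxy <- nx[, c(1, 1:(nc - 1)), drop = FALSE]; nxn <- nx[, c(2:nc, nc), drop = FALSE]
  gx <- (nxy + 2 * nx + nxn) - (pxy + 2 * px + pxn)
  gy <- (pxn + 2 * ny + nxn) - (pxy + 2 * py + nxy)
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

sobel_magnitude <- function(img) sobel_gradients(img)$mag

# Thin (1-px) edge curves: Sobel magnitude above a threshold, kept only at
# local maxima along the quantized gradient direction (non-maximum
# suppression, as in classical edge detectors).
thin_edges <- function(patch, threshold) {
  g <- sobel_gradients(patch)
  nr <- nrow(patch); nc <- ncol(patch)
  shift <- function(m, di, dj) {
    m[pmin(pmax(seq_len(nr) + di, 1L), nr),
      pmin(pmax(seq_len(nc) + dj, 1L), nc), drop = FALSE]
  }
  ang <- atan2(g$gy, g$gx)            # direction of steepest ascent
  sector <- (round(ang / (pi / 4)) %% 4)  # 0:x, 1:diag, 2:y, 3:anti-diag
  off <- list(c(1L, 0L), c(1L, 1L), c(0L, 1L), c(-1L, 1L))
  keep <- matrix(FALSE, nr, nc)
  for (s in 0:3) {
    d <- off[[s + 1L]]
    ok <- g$mag >= shift(g$mag, d[1], d[2]) &
          g$mag >= shift(g$mag, -d[1], -d[2])
    keep <- keep | (sector == s & ok)
  }
  keep & g$mag > threshold
}

# Local maxima of a patch (8-neighbourhood, ties allowed).
local_maxima <- function(patch) {
  nr <- nrow(patch); nc <- ncol(patch)
  best <- matrix(-Inf, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    src_i <- pmin(pmax(seq_len(nr) + di, 1L), nr)
    src_j <- pmin(pmax(seq_len(nc) + dj, 1L), nc)
    best <- pmax(best, patch[src_i, src_j, drop = FALSE])
  }
  patch >= best
}

# Split one cluster region into cells. Two passes of: Sobel edge map ->
# closing (dilate then erode) of the edge band -> core components of the
# mask minus the edge band; cores that contain a local intensity maximum
# act as cell markers (this rejects the low-gradient outer rim and saddle
# pockets between cells), and every mask pixel joins its nearest marker.
# Sub-regions passing the single-cell rule become cells; an unsplittable
# blob contributes its intensity-weighted centroid.
split_one_cluster <- function(idx, dims, filtered, pixel_size, params,
                              depth = 1L) {
  fallback <- function() {
    p <- region_props_one(idx, dims, filtered, pixel_size)
    data.frame(x_um = p$x_um, y_um = p$y_um, area_um2 = p$area_um2)
  }
  if (length(idx) > 5e4 || depth > 2L) return(fallback())
  ix <- ((idx - 1L) %% dims[1]) + 1L
  iy <- ((idx - 1L) %/% dims[1]) + 1L
  pad <- params$split_dilation_radius + 2L
  x0 <- max(1L, min(ix) - pad); x1 <- min(dims[1], max(ix) + pad)
  y0 <- max(1L, min(iy) - pad); y1 <- min(dims[2], max(iy) + pad)
  patch <- filtered[x0:x1, y0:y1, drop = FALSE]
  msk <- matrix(FALSE, nrow(patch), ncol(patch))
  msk[cbind(ix - x0 + 1L, iy - y0 + 1L)] <- TRUE
  grad <- sobel_magnitude(patch)
  gvals <- grad[msk]
  if (max(gvals) <= 0) return(fallback())
  edge <- thin_edges(patch, mean(gvals))
  br <- EBImage::makeBrush(2L * params$split_dilation_radius + 1L, "disc")
  closed <- EBImage::imageData(EBImage::erode(
    EBImage::dilate(EBImage::Image(edge * 1), br), br)) > 0
  cores <- label_components_8(msk & !closed)
  if (max(cores) >= 2L) {
    peaks <- local_maxima(patch) & msk
    marker_ids <- sort(unique(cores[cores > 0 & peaks]))
    keep <- cores %in% marker_ids & cores > 0
    cores[!keep] <- 0L
    cores[keep] <- match(cores[keep], marker_ids)
  }
  ncore <- max(cores)
  if (ncore < 2L) return(fallback())
  # assign every mask pixel to the nearest marker pixel
  core_idx <- which(cores > 0)
  cxi <- ((core_idx - 1L) %% nrow(cores)) + 1L
  cyi <- ((core_idx - 1L) %/% nrow(cores)) + 1L
  clab <- cores[core_idx]
  mxi <- ix - x0 + 1L; myi <- iy - y0 + 1L
  assign_lab <- integer(length(idx))
  for (k in seq_along(idx)) {
    d2 <- (cxi - mxi[k])^2 + (cyi - myi[k])^2
    assign_lab[k] <- clab[which.min(d2)]
  }
  out <- list()
  for (g in seq_len(ncore)) {
    sub <- idx[assign_lab == g]
    if (!length(sub)) next
    p <- region_props_one(sub, dims, filtered, pixel_size)
    ok <- p$area_um2 >= params$cell_area_range[1] &
      p$area_um2 <= params$cell_area_range[2] &
      p$eccentricity <= params$eccentricity_max &
      p$solidity >= params$solidity_min
    if (ok || length(sub) <= 2L) {
      out[[length(out) + 1L]] <- data.frame(x_um = p$x_um, y_um = p$y_um,
                                            area_um2 = p$area_um2)
    } else {
      out[[length(out) + 1L]] <-
        split_one_cluster(sub, dims, filtered, pixel_size, params,
                          depth = depth + 1L)
    }
  }
  if (!length(out)) return(fallback())
  do.call(rbind, out)
}

#' Split cluster regions into individual cells
#'
#' @param seg Result of [segment()].
#' @param cluster_rows Integer indices of the regions to split (rows of
#'   `seg$regions`).
#' @param filtered The preprocessed image.
#' @inheritParams preprocess
#' @return Data frame with `x_um`, `y_um`, `area_um2`, one row per
#'   recovered cell; at least one row per non-empty cluster region.
#' @export
split_clusters <- function(seg, cluster_rows, filtered, pixel_size,
                           params = detection_params()) {
  if (!length(cluster_rows))
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0)))
  do.call(rbind, lapply(seg$pixels[cluster_rows], split_one_cluster,
                        dims = dim(filtered), filtered = filtered,
                        pixel_size = pixel_size, params = params))
}

#' Detect bacterial cells in a grayscale image
#'
#' Full pipeline: [preprocess()] (top-hat + contrast stretch),
#' [segment()] (mean-relative threshold, 8-connected labeling, region
#' properties), [classify_regions()] (single cells, clusters, food
#' particles, noise) and [split_clusters()] (per-cell centroids inside
#' cluster regions). Coordinates are reported in micrometres with the
#' origin at the image corner.
#'
#' @param image Non-negative 2-D intensity matrix, or a
#'   [render_image()] result (its pixel size is then used).
#' @param pixel_size Micrometres per pixel (ignored for a
#'   `synthetic_image` input).
#' @param params A [detection_params()].
#' @return An object of class `"detection_result"`: data frame `cells`
#'   (`x_um`, `y_um`, `area_um2`, `label` in single/from_cluster), counts
#'   `total_count` and `removed_particles`, plus the `params` used.
#' @export
detect_cells <- function(image, pixel_size = NULL,
                         params = detection_params()) {
  if (inherits(image, "synthetic_image")) {
    pixel_size <- image$pixel_size
    image <- image$pixels
  }
  if (is.null(pixel_size)) stop("'pixel_size' is required for a plain matrix")
  filtered <- preprocess(image, pixel_size, params)
  seg <- segment(filtered, pixel_size, params)
  cls <- classify_regions(seg$regions, params)
  singles <- seg$regions[cls == "cell", c("x_um", "y_um", "area_um2")]
  from_cl <- split_clusters(seg, which(cls == "cluster"), filtered,
                            pixel_size, params)
  cells <- rbind(
    if (nrow(singles)) cbind(singles, label = "single"),
    if (nrow(from_cl)) cbind(from_cl, label = "from_cluster"))
  if (is.null(cells))
    cells <- data.frame(x_um = numeric(0), y_um = numeric(0),
                        area_um2 = numeric(0), label = character(0))
  rownames(cells) <- NULL
  structure(list(cells = cells, total_count = nrow(cells),
                 removed_particles = sum(cls == "particle"),
                 params = params),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("detected %d cells (%d single, %d from clusters); %d food particles removed\n",
              x$total_count, sum(x$cells$label == "single"),
              sum(x$cells$label == "from_cluster"), x$removed_particles))
  invisible(x)
}

#' Convert a detection result to a point pattern
#'
#' @param result A [detect_cells()] result.
#' @param window The observation window ([spat_window()]); coordinates are
#'   shifted by its lower-left corner.
#' @return A [point_pattern()]; detections falling outside the window
#'   (possible at the very edge) are clipped.
#' @export
detection_to_pattern <- function(result, window) {
  x <- result$cells$x_um + window$xmin
  y <- result$cells$y_um + window$ymin
  keep <- points_inside(x, y, window)
  point_pattern(x[keep], y[keep], window)
}

#' Match detections against ground truth
#'
#' Greedy one-to-one nearest-neighbour matching: the globally closest
#' detection/truth pair within `max_dist` is matched first, both points
#' are removed, and the process repeats. Precision is matched/detected,
#' recall is matched/true, and the RMSE is over matched pairs. Truth
#' coordinates are taken relative to the truth window's lower-left corner
#' so they live in the same frame as the detections.
#'
#' @param result A [detect_cells()] result (or data frame with `x_um`,
#'   `y_um`).
#' @param truth A [point_pattern()] of true cell centres.
#' @param max_dist Maximum matching distance, um (> 0).
#' @return List with `precision`, `recall`, `rmse_um`, `n_matched`. Empty
#'   truth with empty detections gives precision = recall = 1.
#' @export
match_to_truth <- function(result, truth, max_dist) {
  stop_if_not_scalar_pos(max_dist, "max_dist")
  cells <- if (inherits(result, "detection_result")) result$cells else result
  dx <- cells$x_um; dy <- cells$y_um
  tx <- truth$x - truth$window$xmin; ty <- truth$y - truth$window$ymin
  nd <- length(dx); nt <- length(tx)
  if (nd == 0L && nt == 0L)
    return(list(precision = 1, recall = 1, rmse_um = 0, n_matched = 0L))
  if (nd == 0L || nt == 0L)
    return(list(precision = as.numeric(nd == 0L), recall = as.numeric(nt == 0L),
                rmse_um = NA_real_, n_matched = 0L))
  d <- sqrt(outer(dx, tx, "-")^2 + outer(dy, ty, "-")^2)
  d[d > max_dist] <- Inf
  matched <- 0L
  sq <- 0
  while (any(is.finite(d))) {
    k <- arrayInd(which.min(d), dim(d))
    sq <- sq + d[k]^2
    matched <- matched + 1L
    d[k[1], ] <- Inf
    d[, k[2]] <- Inf
  }
  list(precision = matched / nd, recall = matched / nt,
       rmse_um = if (matched) sqrt(sq / matched) else NA_real_,
       n_matched = matched)
}
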