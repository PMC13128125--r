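#' Planar point pattern
#'
#' Container for a planar point pattern in a rectangular window: point
#' coordinates in micrometres, an optional species mark per point, and
#' optional site metadata (`site` from tip/base x center/epithelium, and an
#' image identifier). This is the object all spatial statistics consume.
#'
#' @param x,y Numeric coordinate vectors (micrometres), equal length.
#' @param window A [spat_window()]; every point must lie inside it.
#' @param marks Optional character/factor vector of species labels, one per
#'   point.
#' @param site,image_id Optional single-string metadata labels.
#' @return An object of class `"point_pattern"`.
#' @examples
#' pp <- point_pattern(c(5, 5), c(5, 6), spat_window(0, 10, 0, 10))
#' npoints(pp)
#' @export
point_pattern <- function(x, y, window, marks = NULL, site = NULL,
                          image_id = NULL) {
  if (!inherits(window, "spat_window")) stop("'window' must be a spat_window")
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) && !all(points_inside(x, y, window, tol = 1e-9)))
    stop("all points must lie inside the window")
  if (!is.null(marks) && length(marks) != length(x))
    stop("'marks' length must equal the number of points")
  structure(list(x = x, y = y, window = window, marks = marks,
                 site = site, image_id = image_id),
            class = "point_pattern")
}

#' @rdname point_pattern
#' @param pp A `point_pattern`.
#' @export
npoints <- function(pp) length(pp$x)

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point pattern: %d points", npoints(x)))
  if (!is.null(x$site)) cat(sprintf(" [site %s]", x$site))
  if (!is.null(x$image_id)) cat(sprintf(" [image %s]", x$image_id))
  cat("\n")
  print(x$window)
  invisible(x)
}

#' @export
as.data.frame.point_pattern <- function(x, ...) {
  data.frame(x_um = x$x, y_um = x$y,
             species = if (is.null(x$marks)) NA_character_ else as.character(x$marks),
             image_id = if (is.null(x$image_id)) NA_character_ else x$image_id,
             site = if (is.null(x$site)) NA_character_ else x$site,
             stringsAsFactors = FALSE)
}

#' Read and write point patterns as delimited text
#'
#' Patterns are stored as comma-separated tables with columns `x_um`, `y_um`,
#' `species`, `image_id`, `site`; the window is kept in `#`-prefixed header
#' comment lines so a file round-trips to an identical pattern.
#'
#' @param pp A [point_pattern()].
#' @param path File path.
#' @return `read_pattern()` returns a `point_pattern`; `write_pattern()`
#'   returns `path` invisibly.
#' @export
write_pattern <- function(pp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- pp$window
  writeLines(sprintf("# window: %g %g %g %g", w$xmin, w$xmax, w$ymin, w$ymax),
             con)
  utils::write.csv(as.data.frame(pp), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pattern
#' @export
read_pattern <- function(path) {
  hdr <- readLines(path, n = 20L)
  wline <- grep("^#\\s*window:", hdr, value = TRUE)
  if (!length(wline)) stop("no '# window:' header line in ", path)
  wv <- as.numeric(strsplit(sub("^#\\s*window:\\s*", "", wline[1]), "\\s+")[[1]])
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  site <- if (all(is.na(df$site))) NULL else df$site[1]
  img <- if (all(is.na(df$image_id))) NULL else df$image_id[1]
  marks <- if (all(is.na(df$species))) NULL else df$species
  point_pattern(df$x_um, df$y_um, spat_window(wv[1], wv[2], wv[3], wv[4]),
                marks = marks, site = site, image_id = img)
}
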