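#' Rectangular observation window
#'
#' Defines the rectangular region (in micrometres) inside which a point
#' pattern is observed. All spatial statistics in the package are computed
#' relative to such a window; the border correction uses each point's
#' distance to its boundary.
#'
#' @param xmin,xmax,ymin,ymax Window limits in micrometres; `xmax > xmin`
#'   and `ymax > ymin`.
#' @return An object of class `"spat_window"` with fields `xmin`, `xmax`,
#'   `ymin`, `ymax`.
#' @examples
#' w <- spat_window(0, 184.5, 0, 184.5)
#' window_area(w)
#' @export
spat_window <- function(xmin, xmax, ymin, ymax) {
  vals <- c(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax)
  if (!all(is.finite(vals))) stop("window limits must be finite numbers")
  if (xmax <= xmin || ymax <= ymin)
    stop("window must have positive extent: xmax > xmin and ymax > ymin")
  structure(list(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax),
            class = "spat_window")
}

#' @rdname spat_window
#' @param w A `spat_window`.
#' @export
window_area <- function(w) (w$xmax - w$xmin) * (w$ymax - w$ymin)

# Shorter window side, used for bandwidth defaults and radius limits.
window_short_side <- function(w) min(w$xmax - w$xmin, w$ymax - w$ymin)

# Distance from each point to the nearest window edge (the border distance
# b_i of the border correction).
boundary_distance <- function(x, y, w) {
  pmin(x - w$xmin, w$xmax - x, y - w$ymin, w$ymax - y)
}

points_inside <- function(x, y, w, tol = 0) {
  x >= w$xmin - tol & x <= w$xmax + tol & y >= w$ymin - tol & y <= w$ymax + tol
}

#' @export
print.spat_window <- function(x, ...) {
  cat(sprintf("window: [%g, %g] x [%g, %g] um (area %g um^2)\n",
              x$xmin, x$xmax, x$ymin, x$ymax, window_area(x)))
  invisible(x)
}
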