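#' Default radius grid for summary functions
#'
#' 201 radii from 0 to 20 um in 0.1 um steps: the analysis range used for
#' bacterial patterns at image scale.
#' @param r_max Maximum radius, um.
#' @param step Grid step, um.
#' @return Numeric vector of radii starting at 0.
#' @export
default_radii <- function(r_max = 20, step = 0.1) seq(0, r_max, by = step)

# Resolve an intensity argument to a per-point numeric vector.
resolve_lambda <- function(lambda, pattern) {
  n <- npoints(pattern)
  if (inherits(lambda, "intensity_at_points")) lambda <- lambda$values
  if (is.function(lambda)) lambda <- lambda(pattern$x, pattern$y)
  if (length(lambda) == 1L) lambda <- rep(lambda, n)
  if (length(lambda) != n) stop("intensity must have one value per point")
  if (any(!is.finite(lambda)) || any(lambda <= 0))
    stop("all intensity values must be finite and > 0")
  lambda
}

#' Border-corrected inhomogeneous Ripley K function
#'
#' Estimates the inhomogeneous K function of a point pattern, weighting
#' each point by the reciprocal of its local intensity and correcting for
#' window edges with the border method (only points at distance at least r
#' from the boundary act as focal points):
#' \deqn{\hat K(r) = \frac{\sum_{i: b_i \ge r} \lambda_i^{-1}
#'   \sum_{j \ne i, d_{ij} \le r} \lambda_j^{-1}}
#'   {\sum_{i: b_i \ge r} \lambda_i^{-1}},}
#' with `b_i` the distance from point i to the window boundary. No further
#' renormalization is applied. The per-radius numerator and denominator are
#' retained so that summaries from several images can be ratio-pooled.
#'
#' @param pattern A [point_pattern()].
#' @param lambda Local intensity: an [estimate_intensity()] result, a
#'   per-point numeric vector, a single known constant (per um^2), or a
#'   function of `(x, y)`.
#' @param radii Increasing radius grid starting at 0 (um); must not exceed
#'   half the shorter window side.
#' @return An object of class `"summary_function"`: data-frame-like list
#'   with `r`, `Khat`, `Lhat`, `Hhat`, `numerator`, `denominator`,
#'   `n_focal`, and a `correction = "border"` tag. Radii with no eligible
#'   focal point have `NA` values.
#' @examples
#' pp <- point_pattern(c(5, 5), c(5, 6), spat_window(0, 10, 0, 10))
#' sf <- kinhom_border(pp, lambda = 0.02, radii = c(0, 1, 2))
#' sf$Khat[3]  # 50
#' @export
kinhom_border <- function(pattern, lambda, radii = default_radii()) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (is.unsorted(radii, strictly = TRUE) || radii[1] != 0)
    stop("'radii' must be strictly increasing and start at 0")
  w <- pattern$window
  if (max(radii) > window_short_side(w) / 2 + 1e-9)
    stop("max radius exceeds half the shorter window side")
  n <- npoints(pattern)
  nr <- length(radii)
  out <- list(r = radii, Khat = rep(NA_real_, nr), Lhat = rep(NA_real_, nr),
              Hhat = rep(NA_real_, nr), numerator = rep(NA_real_, nr),
              denominator = rep(NA_real_, nr), n_focal = integer(nr),
              correction = "border")
  if (n == 0L) {
    warning("empty pattern: summary function is undefined at all radii")
    class(out) <- "summary_function"
    return(out)
  }
  lam <- resolve_lambda(lambda, pattern)
  wgt <- 1 / lam
  b <- boundary_distance(pattern$x, pattern$y, w)
  rmax <- max(radii)
  # Each point i is an eligible focal point at radii r <= b_i; each ordered
  # pair (i, j) enters the numerator once r >= d_ij and leaves it once
  # r > b_i. Both are contiguous radius-index intervals, so per-radius sums
  # are cumulative sums of difference arrays: O(pairs + radii).
  i_end <- findInterval(b, radii)     # last radius index with radii[k] <= b_i
  den_diff <- numeric(nr + 1L); den_diff[1L] <- sum(wgt)
  nf_diff <- numeric(nr + 1L); nf_diff[1L] <- n
  drop_at <- pmin(i_end + 1L, nr + 1L)  # index at which point i stops being focal
  agg <- rowsum(cbind(wgt, rep(1, n)), drop_at)
  at <- as.integer(rownames(agg))
  den_diff[at] <- den_diff[at] - agg[, 1L]
  nf_diff[at] <- nf_diff[at] - agg[, 2L]
  denominator <- cumsum(den_diff)[seq_len(nr)]
  n_focal <- as.integer(round(cumsum(nf_diff)[seq_len(nr)]))
  num <- numeric(nr)
  if (n > 1L) {
    d2 <- pairwise_d2(pattern$x, pattern$y)
    diag(d2) <- Inf
    pr <- which(d2 <= rmax^2, arr.ind = TRUE)  # ordered pairs (focal i, nb j)
    if (nrow(pr)) {
      pd <- sqrt(d2[pr])
      pw <- wgt[pr[, 1L]] * wgt[pr[, 2L]]
      pb <- b[pr[, 1L]]
      # pair active for radius indices start..stop (inclusive)
      start <- findInterval(pd, radii, left.open = TRUE) + 1L  # first radii >= d
      stop_ <- findInterval(pb, radii)                          # last radii <= b
      ok <- start <= stop_ & start <= nr
      if (any(ok)) {
        ndiff <- numeric(nr + 1L)
        add <- rowsum(pw[ok], start[ok])
        ndiff[as.integer(rownames(add))] <- add
        sub <- rowsum(pw[ok], pmin(stop_[ok] + 1L, nr + 1L))
        iat <- as.integer(rownames(sub))
        ndiff[iat] <- ndiff[iat] - sub
        num <- cumsum(ndiff)[seq_len(nr)]
      }
    }
  }
  defined <- n_focal > 0L
  out$n_focal <- n_focal
  out$numerator[defined] <- num[defined]
  out$denominator[defined] <- denominator[defined]
  out$Khat[defined] <- num[defined] / denominator[defined]
  out <- to_LH(out)
  class(out) <- "summary_function"
  out
}

#' Fill the L and H transforms of a summary function
#'
#' `L(r) = sqrt(K(r) / pi)` is the variance-stabilizing transform of K
#' (equal to r under complete spatial randomness) and `H(r) = L(r) - r`
#' centres it at zero: positive H indicates clustering, negative H
#' regularity. Undefined entries propagate.
#'
#' @param sf A summary function (or list) containing `r` and `Khat`.
#' @return The input with `Lhat` and `Hhat` (re)computed.
#' @export
to_LH <- function(sf) {
  k <- sf$Khat
  if (any(k < 0, na.rm = TRUE))
    stop("negative Khat: internal consistency error")
  sf$Lhat <- sqrt(k / pi)
  sf$Hhat <- sf$Lhat - sf$r
  sf
}

#' @export
print.summary_function <- function(x, ...) {
  def <- sum(!is.na(x$Khat))
  cat(sprintf("summary function (%s correction): %d radii in [0, %g] um, %d defined\n",
              x$correction, length(x$r), max(x$r), def))
  if (def) cat(sprintf("  max Hhat = %.3f um at r = %.2f um\n",
                       max(x$Hhat, na.rm = TRUE),
                       x$r[which.max(x$Hhat)]))
  invisible(x)
}

#' @export
as.data.frame.summary_function <- function(x, ...) {
  data.frame(r = x$r, Khat = x$Khat, Lhat = x$Lhat, Hhat = x$Hhat,
             numerator = x$numerator, denominator = x$denominator,
             n_focal = x$n_focal)
}

check_common_grid <- function(summaries) {
  r <- summaries[[1]]$r
  for (s in summaries[-1])
    if (!isTRUE(all.equal(s$r, r)))
      stop("summary functions must share a common radius grid")
  r
}

#' Pool summary functions across images with a pointwise confidence band
#'
#' Ratio pooling: the pooled K at each radius is the sum of per-image
#' numerators divided by the sum of per-image denominators (not the mean of
#' the per-image ratios), then transformed to L and H. The confidence band
#' is the pointwise mean of the per-image H curves plus/minus a
#' t-quantile times the standard error across images.
#'
#' @param summaries List of at least 2 [kinhom_border()] results on a
#'   common radius grid.
#' @param level Confidence level for the band (default 0.95).
#' @return An object of class `"pooled_summary"`: fields `r`, `Khat`,
#'   `Lhat`, `Hhat` (pooled), `Hmean`, `lower`, `upper` (band), `n`.
#' @export
pool_and_ci <- function(summaries, level = 0.95) {
  if (length(summaries) < 2L) stop("pooling needs at least 2 summaries")
  r <- check_common_grid(summaries)
  num <- rowSums(sapply(summaries, `[[`, "numerator"))
  den <- rowSums(sapply(summaries, `[[`, "denominator"))
  pooled <- list(r = r, Khat = num / den, numerator = num, denominator = den,
                 correction = summaries[[1]]$correction)
  pooled <- to_LH(pooled)
  hmat <- sapply(summaries, `[[`, "Hhat")   # radii x images
  m <- length(summaries)
  hbar <- rowMeans(hmat)
  se <- apply(hmat, 1L, stats::sd) / sqrt(m)
  tq <- stats::qt(1 - (1 - level) / 2, df = m - 1L)
  structure(list(r = r, Khat = pooled$Khat, Lhat = pooled$Lhat,
                 Hhat = pooled$Hhat, Hmean = hbar,
                 lower = hbar - tq * se, upper = hbar + tq * se,
                 level = level, n = m),
            class = "pooled_summary")
}

#' @export
print.pooled_summary <- function(x, ...) {
  cat(sprintf("pooled summary over %d patterns, %d radii in [0, %g] um (%.0f%% band)\n",
              x$n, length(x$r), max(x$r), 100 * x$level))
  invisible(x)
}

#' Typical cluster radius from a pooled H curve
#'
#' The radius at which H(r) peaks approximates the diameter of a typical
#' cluster (within about a factor of two), so the returned estimate is
#' `argmax_r H(r) / 2`. Ties are broken toward the smallest radius. If the
#' curve never rises above zero there is no evidence of clustering and the
#' estimate is `NA`.
#'
#' @param pooled A `pooled_summary` or `summary_function` (anything with
#'   `r` and `Hhat`).
#' @return Cluster radius estimate in um, or `NA_real_`.
#' @export
cluster_radius <- function(pooled) {
  h <- pooled$Hhat
  if (all(is.na(h))) stop("H function undefined at every radius")
  mx <- max(h, na.rm = TRUE)
  if (mx <= 0) return(NA_real_)
  pooled$r[which.max(h)] / 2
}
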