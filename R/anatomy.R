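#' Prostate anatomy container
#'
#' Bundles the contoured prostate slice stack and the urethra path used by
#' all geometric partitions.  Each slice carries its axial position (mm,
#' increasing toward the superior/base end), a closed prostate contour
#' polygon, and the urethral center point in that slice.  The urethra is
#' modelled as a circle of fixed radius around the per-slice center; the
#' urethra-near annulus extends from that radius out to
#' `nearzone_outer_radius`.
#'
#' @param slices list of slices, each a list with elements `z` (numeric,
#'   mm), `prostate` (n x 2 numeric matrix of polygon vertices, mm; the
#'   polygon is implicitly closed) and `urethra_center` (length-2 numeric,
#'   mm).
#' @param urethra_radius radius (mm) of the circular urethra model.
#' @param nearzone_outer_radius outer radius (mm) of the urethra-near
#'   annulus.
#' @return an object of class `prostate_anatomy`.
#' @export
prostate_anatomy <- function(slices, urethra_radius = 7,
                             nearzone_outer_radius = 10) {
  if (length(slices) == 0L)
    stop("anatomy must contain at least one contoured slice")
  if (!(urethra_radius > 0 && urethra_radius < nearzone_outer_radius))
    stop("need 0 < urethra_radius < nearzone_outer_radius")
  z <- vapply(slices, function(s) as.numeric(s$z), numeric(1))
  if (any(diff(z) <= 0))
    stop("slice z positions must be strictly increasing")
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    if (is.null(s$urethra_center) || length(s$urethra_center) != 2L ||
        any(!is.finite(s$urethra_center)))
      stop(sprintf("slice %d (z = %g mm) has no valid urethra center", i, z[i]))
    p <- s$prostate
    if (is.null(p) || !is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L)
      stop(sprintf("slice %d: prostate contour must be an n x 2 matrix, n >= 3", i))
    if (!polygon_is_simple(p))
      stop(sprintf("slice %d: prostate contour is self-intersecting", i))
  }
  structure(list(slices = slices,
                 z = z,
                 urethra_radius = urethra_radius,
                 nearzone_outer_radius = nearzone_outer_radius),
            class = "prostate_anatomy")
}

#' @export
print.prostate_anatomy <- function(x, ...) {
  cat(sprintf("Prostate anatomy: %d slices, z in [%.1f, %.1f] mm\n",
              length(x$slices), min(x$z), max(x$z)))
  cat(sprintf("  urethra radius %.1f mm, near-zone outer radius %.1f mm\n",
              x$urethra_radius, x$nearzone_outer_radius))
  invisible(x)
}

# Simple-polygon check: no two non-adjacent edges properly intersect.
# Vectorized over all edge pairs (contours have a few dozen vertices).
polygon_is_simple <- function(p) {
  n <- nrow(p)
  nxt <- c(2:n, 1L)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- pr[, 1]; j <- pr[, 2]
  keep <- (j - i) >= 2L & !(i == 1L & j == n)   # skip adjacent edges
  i <- i[keep]; j <- j[keep]
  if (!length(i)) return(TRUE)
  cross <- function(ox, oy, ax, ay, px, py)
    (ax - ox) * (py - oy) - (ay - oy) * (px - ox)
  a1x <- p[i, 1]; a1y <- p[i, 2]; b1x <- p[nxt[i], 1]; b1y <- p[nxt[i], 2]
  a2x <- p[j, 1]; a2y <- p[j, 2]; b2x <- p[nxt[j], 1]; b2y <- p[nxt[j], 2]
  d1 <- cross(a2x, a2y, b2x, b2y, a1x, a1y)
  d2 <- cross(a2x, a2y, b2x, b2y, b1x, b1y)
  d3 <- cross(a1x, a1y, b1x, b1y, a2x, a2y)
  d4 <- cross(a1x, a1y, b1x, b1y, b2x, b2y)
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}

# Urethra center at arbitrary z, linear interpolation between contoured
# slices, constant beyond the ends.
urethra_center_at <- function(anatomy, z) {
  cx <- vapply(anatomy$slices, function(s) s$urethra_center[1], numeric(1))
  cy <- vapply(anatomy$slices, function(s) s$urethra_center[2], numeric(1))
  if (length(anatomy$z) == 1L)
    return(cbind(rep(cx, length(z)), rep(cy, length(z))))
  cbind(stats::approx(anatomy$z, cx, xout = z, rule = 2)$y,
        stats::approx(anatomy$z, cy, xout = z, rule = 2)$y)
}

# Index of the contoured slice nearest to each z (ties toward the inferior
# slice), used to look up the polygon governing a voxel layer.
nearest_slice_index <- function(anatomy, z) {
  zi <- anatomy$z
  vapply(z, function(zz) which.min(abs(zi - zz) + 1e-9 * (zi > zz)), integer(1))
}

#' Polygon area by the shoelace formula (mm^2)
#' @keywords internal
#' @noRd
polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}
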