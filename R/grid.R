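#' Voxel grid covering an anatomy
#'
#' Builds an axis-aligned voxel grid whose bounding box contains every
#' contour with a lateral margin of at least the urethra-near outer radius
#' and an axial margin of one slice thickness, so that no labelled or dosed
#' structure is clipped.
#'
#' @param anatomy a [prostate_anatomy()] object.
#' @param spacing voxel edge lengths (mm); a scalar is recycled to
#'   `(dx, dy, dz)`.
#' @return an object of class `voxel_grid` with `origin`, `spacing`, `dims`.
#' @export
build_grid <- function(anatomy, spacing = 1) {
  stopifnot(inherits(anatomy, "prostate_anatomy"))
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  xy <- do.call(rbind, lapply(anatomy$slices, function(s) s$prostate))
  uc <- do.call(rbind, lapply(anatomy$slices, function(s) rbind(s$urethra_center)))
  m <- anatomy$nearzone_outer_radius
  xr <- range(c(xy[, 1], uc[, 1] - anatomy$urethra_radius,
                uc[, 1] + anatomy$urethra_radius))
  yr <- range(c(xy[, 2], uc[, 2] - anatomy$urethra_radius,
                uc[, 2] + anatomy$urethra_radius))
  zr <- range(anatomy$z)
  dz_slice <- if (length(anatomy$z) > 1L) stats::median(diff(anatomy$z)) else spacing[3]
  zmarg <- max(dz_slice, spacing[3])
  origin <- c(xr[1] - m, yr[1] - m, zr[1] - zmarg)
  extent <- c(diff(xr) + 2 * m, diff(yr) + 2 * m, diff(zr) + 2 * zmarg)
  dims <- pmax(1L, as.integer(ceiling(extent / spacing)))
  structure(list(origin = origin, spacing = spacing, dims = dims),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("Voxel grid %d x %d x %d, spacing (%.2g, %.2g, %.2g) mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Voxel center coordinates
#'
#' @param grid a `voxel_grid`.
#' @return n x 3 matrix of voxel center coordinates (mm), in column-major
#'   voxel order (x fastest).
#' @export
voxel_centers <- function(grid) {
  ax <- lapply(1:3, function(k)
    grid$origin[k] + (seq_len(grid$dims[k]) - 0.5) * grid$spacing[k])
  cbind(rep(ax[[1]], times = grid$dims[2] * grid$dims[3]),
        rep(rep(ax[[2]], each = grid$dims[1]), times = grid$dims[3]),
        rep(ax[[3]], each = grid$dims[1] * grid$dims[2]))
}

voxel_volume <- function(grid) prod(grid$spacing)
n_voxels <- function(grid) prod(grid$dims)
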