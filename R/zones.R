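#' Names of the 48 prostate/urethra subzones
#'
#' The catalogue combines three partition families of the prostate-plus-
#' urethra volume: axial (Base / MidGland / Apex, a 1:2:1 split along the
#' superior-inferior axis), coronal (Anterior / Posterior of the urethral
#' center line), and radial (Urethra, the 7-10 mm urethra-near annulus
#' `Urethra10mm`, and the Peripheral remainder).  Nine individual zones
#' (the whole prostate plus the eight family members) and 39 composite
#' intersections give 48 zones in total.
#'
#' @return character vector of 48 zone names, in catalogue order.
#' @export
zone_names <- function() {
  radial3 <- c("Peripheral", "Urethra", "Urethra10mm")
  per_axial <- function(ax) {
    c(paste0(ax, "_Anterior"),
      paste0(ax, "_Anterior_", radial3),
      paste0(ax, "_Posterior"),
      paste0(ax, "_Posterior_", radial3),
      paste0(ax, "_", radial3))
  }
  c("Prostate", "Anterior", "Posterior", "Urethra", "Urethra10mm",
    "Peripheral", "Base", "MidGland", "Apex",
    per_axial("Base"), per_axial("MidGland"), per_axial("Apex"),
    paste0("Anterior_", radial3),
    paste0("Posterior_", radial3))
}

#' Axial 1:2:1 partition of the prostate extent
#'
#' Splits the contoured superior-inferior extent into apex (inferior
#' quarter), mid-gland (central half) and base (superior quarter).
#' Internal boundaries are half-open: the apex/mid boundary belongs to the
#' mid-gland and the mid/base boundary to the base.
#'
#' @param anatomy a [prostate_anatomy()] object.
#' @return list with numeric `apex`, `mid`, `base` z-intervals (mm) and the
#'   two internal `boundaries`.
#' @export
axial_partition <- function(anatomy) {
  stopifnot(inherits(anatomy, "prostate_anatomy"))
  z0 <- min(anatomy$z); z1 <- max(anatomy$z)
  L <- z1 - z0
  if (L <= 0) stop("prostate superior-inferior extent must be positive")
  a <- z0 + L / 4
  b <- z0 + 3 * L / 4
  list(apex = c(z0, a), mid = c(a, b), base = c(b, z1), boundaries = c(a, b))
}

#' Label grid voxels with the 48-zone catalogue
#'
#' Every voxel whose center lies inside the prostate contour of its
#' (nearest) slice, or inside the urethra disc around the interpolated
#' urethral center, is a member of the labelled volume and receives exactly
#' one label from each of the three partition families.  Composite zones
#' are the intersections of their parents.  The urethra disc is included
#' whether or not it lies inside the prostate contour; the `Prostate`
#' individual zone is the polygon interior (plus any overlapping urethra
#' voxels).
#'
#' Radial boundaries are closed inward: a voxel exactly at the urethra
#' radius is `Urethra`, exactly at the outer annulus radius `Urethra10mm`.
#' A voxel on the coronal center line is `Posterior`.
#'
#' @param anatomy a [prostate_anatomy()] object.
#' @param grid a `voxel_grid` from [build_grid()].
#' @return an object of class `zone_catalogue`: list with `masks` (named
#'   list of integer voxel indices, one per zone), `grid`,
#'   `axial_boundaries`, and per-voxel family labels for the member set.
#' @export
label_voxels <- function(anatomy, grid) {
  stopifnot(inherits(anatomy, "prostate_anatomy"), inherits(grid, "voxel_grid"))
  ctr <- voxel_centers(grid)
  nxy <- grid$dims[1] * grid$dims[2]
  zlev <- grid$origin[3] + (seq_len(grid$dims[3]) - 0.5) * grid$spacing[3]
  z0 <- min(anatomy$z); z1 <- max(anatomy$z)
  ax <- axial_partition(anatomy)

  in_prost <- logical(nrow(ctr))
  in_ureth <- logical(nrow(ctr))
  r2u <- numeric(nrow(ctr))
  dy_ant <- numeric(nrow(ctr))
  layer_xy <- ctr[seq_len(nxy), 1:2, drop = FALSE]
  active <- which(zlev >= z0 & zlev <= z1)
  if (length(active) == 0L) stop("grid does not intersect the contoured extent")
  sl_idx <- nearest_slice_index(anatomy, zlev[active])
  uc <- urethra_center_at(anatomy, zlev[active])
  for (k in seq_along(active)) {
    rows <- (active[k] - 1L) * nxy + seq_len(nxy)
    poly <- anatomy$slices[[sl_idx[k]]]$prostate
    in_prost[rows] <- mgcv::in.out(rbind(poly, poly[1L, ]), layer_xy)
    dx <- layer_xy[, 1] - uc[k, 1]
    dy <- layer_xy[, 2] - uc[k, 2]
    r2 <- dx * dx + dy * dy
    r2u[rows] <- r2
    in_ureth[rows] <- r2 <= anatomy$urethra_radius^2
    dy_ant[rows] <- dy
  }
  member <- which(in_prost | in_ureth)
  if (length(member) == 0L) stop("no voxel falls inside the anatomy")

  zmem <- ctr[member, 3]
  axial <- ifelse(zmem < ax$boundaries[1], "Apex",
                  ifelse(zmem < ax$boundaries[2], "MidGland", "Base"))
  coronal <- ifelse(dy_ant[member] > 0, "Anterior", "Posterior")
  r <- sqrt(r2u[member])
  radial <- ifelse(r <= anatomy$urethra_radius, "Urethra",
                   ifelse(r <= anatomy$nearzone_outer_radius,
                          "Urethra10mm", "Peripheral"))

  masks <- vector("list", 48L)
  names(masks) <- zone_names()
  fam <- function(sel) member[sel]
  masks[["Prostate"]] <- member[in_prost[member]]
  for (nm in c("Base", "MidGland", "Apex")) masks[[nm]] <- fam(axial == nm)
  for (nm in c("Anterior", "Posterior")) masks[[nm]] <- fam(coronal == nm)
  for (nm in c("Urethra", "Urethra10mm", "Peripheral")) masks[[nm]] <- fam(radial == nm)
  for (nm in zone_names()) {
    if (!is.null(masks[[nm]])) next
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    sel <- rep(TRUE, length(member))
    for (p in parts) {
      sel <- sel & switch(p,
        Base = , MidGland = , Apex = axial == p,
        Anterior = , Posterior = coronal == p,
        Urethra = , Urethra10mm = , Peripheral = radial == p)
    }
    masks[[nm]] <- fam(sel)
  }

  structure(list(masks = masks,
                 grid = grid,
                 axial_boundaries = ax$boundaries,
                 member = member,
                 labels = data.frame(voxel = member, axial = axial,
                                     coronal = coronal, radial = radial,
                                     stringsAsFactors = FALSE)),
            class = "zone_catalogue")
}

#' @export
print.zone_catalogue <- function(x, ...) {
  cat(sprintf("Zone catalogue: %d zones over %d labelled voxels\n",
              length(x$masks), length(x$member)))
  invisible(x)
}

#' Zone volume in cc
#'
#' @param catalogue a `zone_catalogue`.
#' @param zone zone name.
#' @return volume (cc) of the zone's voxel mask.
#' @export
zone_volume_cc <- function(catalogue, zone) {
  length(catalogue$masks[[zone]]) * voxel_volume(catalogue$grid) / 1000
}
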