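#' TG-43 source model for an I-125 seed
#'
#' Point-source (1-D) TG-43 parameters: dose-rate constant Lambda
#' (cGy h^-1 U^-1), radionuclide half-life (days), radial dose function
#' g(r) and anisotropy factor phi_an(r) tabulated against radius (cm).
#' `"best2301"` carries the published consensus parameters for the
#' Best Medical model 2301 seed; `"generic"` is a plain I-125 parameter
#' set for sensitivity checks.
#'
#' @param model `"best2301"` (default) or `"generic"`.
#' @return an object of class `source_model`.
#' @export
source_model <- function(model = c("best2301", "generic")) {
  model <- match.arg(model)
  if (model == "best2301") {
    sm <- list(
      name = "Best 2301 (I-125)",
      lambda = 1.018,           # cGy / (h U)
      half_life_days = 59.4,
      g = list(r = c(0.10, 0.15, 0.25, 0.50, 0.75, 1.00, 1.50, 2.00,
                     3.00, 4.00, 5.00, 6.00, 7.00),
               value = c(1.033, 1.029, 1.027, 1.028, 1.030, 1.000, 0.938,
                         0.866, 0.707, 0.555, 0.427, 0.320, 0.236)),
      phi = list(r = c(0.5, 1, 2, 3, 4, 5, 6, 7),
                 value = c(0.973, 0.972, 0.968, 0.965, 0.962, 0.960,
                           0.958, 0.956)),
      r0 = 1.0)
  } else {
    sm <- list(
      name = "generic I-125",
      lambda = 0.965,
      half_life_days = 59.4,
      g = list(r = c(0.10, 0.25, 0.50, 1.00, 1.50, 2.00, 3.00, 4.00,
                     5.00, 6.00, 7.00),
               value = c(1.055, 1.042, 1.033, 1.000, 0.926, 0.842, 0.668,
                         0.509, 0.380, 0.280, 0.204)),
      phi = list(r = c(0.5, 1, 2, 3, 4, 5, 6, 7),
                 value = c(0.950, 0.944, 0.941, 0.940, 0.940, 0.940,
                           0.940, 0.940)),
      r0 = 1.0)
  }
  stopifnot(all(diff(sm$g$r) > 0), all(diff(sm$phi$r) > 0),
            abs(sm$g$value[sm$g$r == 1] - 1) < 1e-12)
  class(sm) <- "source_model"
  sm
}

# Log-linear interpolation of a radial table: value linear in log(r),
# held constant beyond either end (the geometry factor supplies the
# inverse-square tail).
radial_interp <- function(tab, r) {
  stats::approx(log(tab$r), tab$value, xout = log(pmax(r, min(tab$r))),
                rule = 2)$y
}

#' Initial dose rate at a point from one seed
#'
#' TG-43 1-D point-source form: rate = Sk * Lambda * (r0/r)^2 * g(r) *
#' phi_an(r), with the radius clamped below at `r_min` so the seed's own
#' voxel sees a finite dose.
#'
#' @param r distance seed-to-point, cm (vectorized).
#' @param sk air-kerma strength, U.
#' @param sm a [source_model()].
#' @param r_min minimum radius clamp, cm (default 0.1 = 1 mm).
#' @return initial dose rate, cGy/h.
#' @export
initial_dose_rate <- function(r, sk, sm = source_model(), r_min = 0.1) {
  r <- pmax(r, r_min)
  sk * sm$lambda * (sm$r0 / r)^2 * radial_interp(sm$g, r) *
    radial_interp(sm$phi, r)
}

#' Mean life of the source in hours
#'
#' A permanent implant delivers initial rate times tau = T_half / ln 2.
#' @param sm a [source_model()].
#' @return mean life, hours.
#' @export
mean_life_hours <- function(sm = source_model()) sm$half_life_days * 24 / log(2)

#' Seed implant description
#'
#' @param seeds n x 3 matrix of seed coordinates (mm).
#' @param air_kerma_strength per-seed strength Sk (U).
#' @param sm a [source_model()].
#' @return object of class `seed_implant`.
#' @export
seed_implant <- function(seeds, air_kerma_strength, sm = source_model()) {
  seeds <- as.matrix(seeds)
  if (nrow(seeds) < 1L || ncol(seeds) != 3L)
    stop("seeds must be an n x 3 coordinate matrix with n >= 1")
  if (!(air_kerma_strength > 0)) stop("air-kerma strength must be positive")
  structure(list(seeds = seeds, sk = air_kerma_strength, source = sm),
            class = "seed_implant")
}

#' Total permanent-implant dose on a voxel grid
#'
#' Superposes the TG-43 point-source dose of every seed over all voxel
#' centers and integrates the exponential decay to total dose
#' (initial rate times mean life).  Doses are returned both in Gy and in
#' percent of the prescription.
#'
#' @param implant a [seed_implant()].
#' @param grid a `voxel_grid`.
#' @param prescription prescription dose, Gy (default 110).
#' @param r_min minimum-radius clamp, cm.
#' @return object of class `dose_grid`: `grid`, `dose_gy`, `dose_pct`,
#'   `prescription`.
#' @export
compute_dose_grid <- function(implant, grid, prescription = 110, r_min = 0.1) {
  stopifnot(inherits(implant, "seed_implant"), inherits(grid, "voxel_grid"))
  lo <- grid$origin
  hi <- grid$origin + grid$dims * grid$spacing
  out <- implant$seeds[, 1] < lo[1] | implant$seeds[, 1] > hi[1] |
         implant$seeds[, 2] < lo[2] | implant$seeds[, 2] > hi[2] |
         implant$seeds[, 3] < lo[3] | implant$seeds[, 3] > hi[3]
  if (any(out))
    warning(sprintf("%d seed(s) outside the grid bounding box; still summed",
                    sum(out)))
  sm <- implant$source
  rate <- tg43_superpose(voxel_centers(grid) / 10, implant$seeds / 10,
                         log(sm$g$r), sm$g$value,
                         log(sm$phi$r), sm$phi$value, r_min)
  rate <- rate * implant$sk * sm$lambda  # cGy/h (r0 = 1 cm)
  dose_gy <- rate * mean_life_hours(sm) / 100
  structure(list(grid = grid,
                 dose_gy = dose_gy,
                 dose_pct = 100 * dose_gy / prescription,
                 prescription = prescription),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("Dose grid: %d voxels, prescription %.0f Gy, max %.1f%% of Rx\n",
              length(x$dose_gy), x$prescription, max(x$dose_pct)))
  invisible(x)
}
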