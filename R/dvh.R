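#' Cumulative DVH of a zone
#'
#' For each node of a fixed dose axis (percent of prescription), the
#' fraction of the zone's voxels receiving at least that dose.  The fixed
#' axis makes every zone DVH a commensurate vector, which the PCA
#' featurization requires.
#'
#' @param dose a `dose_grid` from [compute_dose_grid()].
#' @param mask integer voxel indices of the zone.
#' @param axis dose axis in percent of prescription (default 0-400% in 1%
#'   steps).
#' @return object of class `dvh_curve`: `dose_pct` (axis),
#'   `volume_fraction`, `empty` flag.
#' @export
compute_dvh <- function(dose, mask, axis = seq(0, 400, by = 1)) {
  stopifnot(inherits(dose, "dose_grid"))
  if (length(mask) == 0L) {
    return(structure(list(dose_pct = axis,
                          volume_fraction = rep(0, length(axis)),
                          empty = TRUE),
                     class = "dvh_curve"))
  }
  x <- dose$dose_pct[mask]
  # count(x >= d) = count(-x <= -d), exact under ties
  s <- sort(-x)
  vf <- findInterval(-axis, s) / length(x)
  structure(list(dose_pct = axis, volume_fraction = vf, empty = FALSE),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  if (x$empty) cat("DVH curve: empty zone\n")
  else cat(sprintf("DVH curve: %d nodes, D50 ~ %.0f%% of Rx\n",
                   length(x$dose_pct), dvh_metric(x, "D", 50)))
  invisible(x)
}

#' Named DVH metrics
#'
#' `D_x%`: the maximal axis dose received by at least x% of the zone
#' volume (percent of prescription).  `V_y%`: the volume fraction
#' receiving at least y% of the prescription.
#'
#' @param curve a `dvh_curve`.
#' @param kind `"D"` or `"V"`.
#' @param q the x (volume percent) for D-metrics, or the y (dose percent)
#'   for V-metrics.
#' @return scalar metric value.
#' @export
dvh_metric <- function(curve, kind = c("D", "V"), q) {
  kind <- match.arg(kind)
  stopifnot(inherits(curve, "dvh_curve"))
  ax <- curve$dose_pct
  vf <- curve$volume_fraction
  if (kind == "D") {
    if (q <= 0 || q > 100) stop("volume percent must be in (0, 100]")
    if (curve$empty) return(0)
    ok <- vf >= q / 100
    if (!any(ok)) return(0)
    max(ax[ok])
  } else {
    if (q < 0 || q > max(ax)) stop("dose percent outside the DVH axis")
    stats::approx(ax, vf, xout = q, rule = 2)$y
  }
}

#' All DVHs of a catalogue
#'
#' @param dose a `dose_grid`.
#' @param catalogue a `zone_catalogue`.
#' @param axis dose axis (percent of prescription).
#' @return 48 x length(axis) matrix of volume fractions, rows named by
#'   zone; empty zones are all-zero rows with attribute `empty`.
#' @export
zone_dvh_matrix <- function(dose, catalogue, axis = seq(0, 400, by = 1)) {
  zn <- names(catalogue$masks)
  out <- matrix(0, length(zn), length(axis), dimnames = list(zn, NULL))
  empty <- logical(length(zn)); names(empty) <- zn
  for (i in seq_along(zn)) {
    cv <- compute_dvh(dose, catalogue$masks[[zn[i]]], axis)
    out[i, ] <- cv$volume_fraction
    empty[i] <- cv$empty
  }
  attr(out, "empty") <- empty
  attr(out, "axis") <- axis
  out
}
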