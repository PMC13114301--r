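#' Per-zone PCA of cohort DVHs
#'
#' Fits a two-component PCA to the mean-centered DVH vectors of one zone
#' across the cohort.  DVH bins share units, so the matrix is centered but
#' not bin-standardized.  Component signs are fixed so each loading sums
#' to a non-negative value, making scores comparable across runs.
#'
#' @param curves n x m matrix: one DVH (volume fractions on the fixed dose
#'   axis) per patient.
#' @param empty optional logical vector flagging patients whose zone was
#'   empty; they are excluded from the fit and later projected to (0, 0).
#' @return object of class `zone_pca`: `center`, `loadings` (m x 2),
#'   `explained` (variance fractions).
#' @export
fit_zone_pca <- function(curves, empty = NULL) {
  curves <- as.matrix(curves)
  keep <- if (is.null(empty)) rep(TRUE, nrow(curves)) else !empty
  if (sum(keep) < 3L)
    stop("zone PCA needs at least 3 patients with non-empty curves")
  M <- curves[keep, , drop = FALSE]
  ctr <- colMeans(M)
  Mc <- sweep(M, 2L, ctr)
  sv <- svd(Mc, nu = 0, nv = 2)
  load <- sv$v
  if (ncol(load) < 2L) load <- cbind(load, 0)
  for (k in 1:2) if (sum(load[, k]) < 0) load[, k] <- -load[, k]
  tot <- sum(Mc^2)
  expl <- if (tot > 0) (sv$d[1:2]^2) / tot else c(0, 0)
  expl[!is.finite(expl)] <- 0
  structure(list(center = ctr, loadings = load, explained = expl),
            class = "zone_pca")
}

#' Project a DVH onto a fitted zone PCA
#'
#' @param curve a patient's DVH vector for the zone (or a matrix, one row
#'   per patient).
#' @param model a `zone_pca` fit.
#' @param empty logical; empty-zone patients are imputed at the cohort
#'   mean, i.e. scores (0, 0).
#' @return length-2 score vector (or n x 2 matrix).
#' @export
project_zone_pca <- function(curve, model, empty = FALSE) {
  stopifnot(inherits(model, "zone_pca"))
  if (is.matrix(curve)) {
    sc <- sweep(curve, 2L, model$center) %*% model$loadings
    sc[empty, ] <- 0
    return(sc)
  }
  if (isTRUE(empty)) return(c(0, 0))
  as.numeric(crossprod(model$loadings, curve - model$center))
}

#' The ten additional dosimetric, implant and clinical indicators
#'
#' Whole-organ DVH metrics (prostate D90%, V100%, V150%; urethra D5%,
#' D30%, V150%), implant counts (needles, seeds), prostate volume (cc)
#' and baseline IPSS.
#'
#' @param dose a `dose_grid`.
#' @param catalogue a `zone_catalogue`.
#' @param clinical list or one-row data.frame with `needles`, `seeds`,
#'   `baseline_ipss`.
#' @param patient_id optional id used in error messages.
#' @return named numeric vector of the 10 indicators.
#' @export
assemble_indicators <- function(dose, catalogue, clinical,
                                patient_id = "<unknown>") {
  for (f in c("needles", "seeds", "baseline_ipss")) {
    v <- clinical[[f]]
    if (is.null(v) || !is.finite(as.numeric(v)))
      stop(sprintf("patient %s: missing clinical field '%s'", patient_id, f))
  }
  pr <- compute_dvh(dose, catalogue$masks[["Prostate"]])
  ur <- compute_dvh(dose, catalogue$masks[["Urethra"]])
  c(Prostate_D90  = dvh_metric(pr, "D", 90),
    Prostate_V100 = dvh_metric(pr, "V", 100),
    Prostate_V150 = dvh_metric(pr, "V", 150),
    Urethra_D5    = dvh_metric(ur, "D", 5),
    Urethra_D30   = dvh_metric(ur, "D", 30),
    Urethra_V150  = dvh_metric(ur, "V", 150),
    Needles       = as.numeric(clinical$needles),
    Seeds         = as.numeric(clinical$seeds),
    ProstateVolume = zone_volume_cc(catalogue, "Prostate"),
    BaselineIPSS  = as.numeric(clinical$baseline_ipss))
}

#' Assemble the cohort feature table
#'
#' Fits a two-component PCA per zone on the cohort DVHs and projects every
#' patient, yielding `<zone>_PCA1` / `<zone>_PCA2` spatial features (96
#' with the full 48-zone catalogue), then appends the 10 indicators.
#' Zones empty for every patient are dropped with a warning.
#'
#' @param dvhs list (length n patients) of zone DVH matrices from
#'   [zone_dvh_matrix()], or a 3-d array n x zones x axis.
#' @param indicators n x 10 matrix or data.frame of
#'   [assemble_indicators()] rows.
#' @param patient_ids optional character ids.
#' @return object of class `feature_table`: `values` (n x p matrix),
#'   `category` per column, `pca_models` (per zone), `dropped_zones`.
#' @export
build_feature_table <- function(dvhs, indicators, patient_ids = NULL) {
  if (is.list(dvhs)) {
    zn <- rownames(dvhs[[1]])
    arr <- array(0, c(length(dvhs), length(zn), ncol(dvhs[[1]])))
    emp <- matrix(FALSE, length(dvhs), length(zn))
    for (i in seq_along(dvhs)) {
      arr[i, , ] <- dvhs[[i]]
      emp[i, ] <- attr(dvhs[[i]], "empty")
    }
  } else {
    arr <- dvhs
    zn <- dimnames(dvhs)[[2]]
    emp <- attr(dvhs, "empty")
    if (is.null(emp)) emp <- matrix(FALSE, dim(arr)[1], dim(arr)[2])
  }
  n <- dim(arr)[1]
  if (is.null(patient_ids)) patient_ids <- sprintf("P%03d", seq_len(n))
  models <- list(); dropped <- character(0)
  cols <- list()
  for (j in seq_along(zn)) {
    if (sum(!emp[, j]) < 3L) {
      warning(sprintf("zone %s empty for nearly all patients; dropped", zn[j]))
      dropped <- c(dropped, zn[j])
      next
    }
    fit <- fit_zone_pca(arr[, j, ], empty = emp[, j])
    models[[zn[j]]] <- fit
    sc <- project_zone_pca(arr[, j, ], fit, empty = emp[, j])
    cols[[paste0(zn[j], "_PCA1")]] <- sc[, 1]
    cols[[paste0(zn[j], "_PCA2")]] <- sc[, 2]
  }
  spat <- do.call(cbind, cols)
  ind <- as.matrix(indicators)
  stopifnot(ncol(ind) == 10L, nrow(ind) == n)
  values <- cbind(spat, ind)
  rownames(values) <- patient_ids
  category <- c(rep("spatial_pca", ncol(spat)),
                rep(c("dvh_metric", "implant", "clinical"), c(6, 3, 1)))
  names(category) <- colnames(values)
  structure(list(values = values, category = category,
                 pca_models = models, dropped_zones = dropped),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d patients x %d features (%d spatial PCA, %d indicators)\n",
              nrow(x$values), ncol(x$values),
              sum(x$category == "spatial_pca"),
              sum(x$category != "spatial_pca")))
  if (!is.null(x$pruned)) cat(sprintf("  pruned %d collinear columns (|r| > %.2g)\n",
                                      length(x$pruned), x$r_threshold))
  invisible(x)
}

#' Min-max scale and prune collinear features
#'
#' Scales every column to [0, 1] (constant columns become all-zero and are
#' flagged), then removes collinear columns: walking the columns in table
#' order, any later column whose absolute Pearson correlation with a
#' surviving earlier column exceeds `r_threshold` is dropped.  The walk
#' order makes pruning deterministic and keeps the earlier (individual-
#' zone) member of a correlated pair.
#'
#' @param table a `feature_table`.
#' @param r_threshold Pearson cutoff (default 0.9).
#' @return the `feature_table` with scaled, pruned `values`, plus
#'   `scaling` (per-column min/max), `pruned` (dropped names),
#'   `constant` (flagged names).
#' @export
scale_and_prune <- function(table, r_threshold = 0.9) {
  stopifnot(inherits(table, "feature_table"))
  X <- table$values
  if (nrow(X) < 2L) stop("scaling needs at least 2 patients")
  mins <- apply(X, 2L, min); maxs <- apply(X, 2L, max)
  rng <- maxs - mins
  const <- rng == 0
  Xs <- sweep(X, 2L, mins)
  Xs[, !const] <- sweep(Xs[, !const, drop = FALSE], 2L, rng[!const], "/")
  Xs[, const] <- 0
  p <- ncol(Xs)
  keep <- rep(TRUE, p)
  cm <- suppressWarnings(stats::cor(Xs))
  cm[!is.finite(cm)] <- 0
  for (i in seq_len(p - 1L)) {
    if (!keep[i]) next
    hit <- which(keep & seq_len(p) > i & abs(cm[i, ]) > r_threshold)
    keep[hit] <- FALSE
  }
  out <- table
  out$values <- Xs[, keep, drop = FALSE]
  out$category <- table$category[keep]
  out$scaling <- data.frame(feature = colnames(X), min = mins, max = maxs,
                            row.names = NULL)
  out$pruned <- colnames(X)[!keep]
  out$constant <- colnames(X)[const]
  out$r_threshold <- r_threshold
  out
}
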