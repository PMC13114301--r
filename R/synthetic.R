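#' Synthetic cohort generator configuration
#'
#' Defaults emulate the study conditions the pipeline is designed for: an
#' 85-patient cohort with ~48% long-term-toxicity prevalence, lognormal
#' prostate volumes (median ~35 cc), a 110 Gy prescription with planning
#' goals prostate D90% >= 100%, V150% < 50% and urethral maximum < 150%,
#' and a planted dose-toxicity effect concentrated in the apex
#' urethra-near zone plus a protective baseline-IPSS effect (odds ratio
#' ~2 per SD in magnitude, negative sign, matching the direction reported
#' for baseline symptoms).
#'
#' @param n_patients cohort size.
#' @param prevalence target toxicity prevalence.
#' @param volume_meanlog,volume_sdlog lognormal prostate-volume (cc)
#'   parameters; defaults give median 35 cc.
#' @param prescription prescription dose, Gy.
#' @param planted_effects named numeric vector: log-odds of toxicity per
#'   SD of the zone's mean dose, names from the 48-zone catalogue.
#' @param ipss_effect log-odds per SD of baseline IPSS (negative =
#'   protective).
#' @param spacing analysis voxel spacing (mm) used when a cohort is
#'   simulated end-to-end.
#' @param slice_thickness contour slice spacing, mm.
#' @param seed master seed; all per-patient randomness derives from it.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 85, prevalence = 0.48,
                          volume_meanlog = log(35), volume_sdlog = 0.3,
                          prescription = 110,
                          planted_effects = c(Apex_Urethra10mm = log(2)),
                          ipss_effect = -log(2),
                          spacing = 1, slice_thickness = 2.5,
                          seed = 1) {
  stopifnot(prevalence > 0, prevalence < 1, n_patients >= 4)
  bad <- setdiff(names(planted_effects), zone_names())
  if (length(bad)) stop("unknown planted zone(s): ", paste(bad, collapse = ", "))
  structure(list(n_patients = n_patients, prevalence = prevalence,
                 volume_meanlog = volume_meanlog, volume_sdlog = volume_sdlog,
                 prescription = prescription,
                 planted_effects = planted_effects,
                 ipss_effect = ipss_effect,
                 spacing = spacing, slice_thickness = slice_thickness,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Per-patient sub-seed derived from the master seed (kept below 2^31).
derive_seed <- function(master, i, salt = 0L) {
  as.integer((as.double(master) * 2654435.0 + i * 97.0 + salt * 131071.0) %%
               2147483647)
}

#' Generate one synthetic prostate anatomy
#'
#' An ellipsoidal gland with mild per-patient axis-ratio variation, sliced
#' at the contouring thickness, with a gently curved urethra running near
#' the posterior-central axis.  In-plane radii are rescaled so the
#' polygon-integrated volume matches the drawn target volume.
#'
#' @param volume_cc target gland volume (cc).
#' @param seed RNG seed.
#' @param slice_thickness slice spacing (mm).
#' @param n_vertices contour polygon vertices.
#' @return a [prostate_anatomy()] object with attribute `volume_cc`.
#' @export
generate_anatomy <- function(volume_cc, seed = 1, slice_thickness = 2.5,
                             n_vertices = 36) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # semi-axes: lateral a, anterior-posterior b, superior-inferior c
  ratio_b <- stats::runif(1, 0.75, 0.9)
  ratio_c <- stats::runif(1, 0.85, 1.05)
  a <- (3 * volume_cc * 1000 / (4 * pi * ratio_b * ratio_c))^(1 / 3)
  b <- a * ratio_b; c_ax <- a * ratio_c
  zs <- seq(-c_ax + slice_thickness / 2, c_ax - slice_thickness / 2,
            by = slice_thickness)
  zs <- zs[abs(zs) < c_ax * 0.995]
  frac <- sqrt(pmax(0, 1 - (zs / c_ax)^2))
  keep <- frac * a > 3          # drop sub-3 mm end caps, as contouring would
  zs <- zs[keep]; frac <- frac[keep]
  # rescale in-plane so the slab-integrated volume hits the target
  vol0 <- sum(pi * (a * frac) * (b * frac)) * slice_thickness
  sc <- sqrt(volume_cc * 1000 / vol0)
  a <- a * sc; b <- b * sc
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  bow <- stats::runif(1, -1.5, 1.5)       # urethra curvature amplitude, mm
  y_off <- stats::runif(1, -3, -1)        # posterior-central offset, mm
  slices <- lapply(seq_along(zs), function(i) {
    az <- a * frac[i]; bz <- b * frac[i]
    list(z = zs[i] - zs[1],               # z = 0 at the apex end
         prostate = cbind(az * cos(th), bz * sin(th)),
         urethra_center = c(0, y_off + bow * sin(pi * (zs[i] + c_ax) /
                                                   (2 * c_ax))))
  })
  an <- prostate_anatomy(slices)
  attr(an, "volume_cc") <- volume_cc
  an
}

#' Generate a planning-goal-compliant seed implant
#'
#' Places needles on a 5 mm template grid inside the largest prostate
#' cross-section (modified peripheral loading: the outermost ring of
#' template positions plus every other interior slot, always keeping
#' needles >= 7 mm from the urethral center line), spaces seeds ~8 mm
#' apart along each needle within the gland, and jitters all coordinates
#' by ~0.75 mm to emulate delivery uncertainty.  Dose is linear in the
#' air-kerma strength, so the compliant strength window — prostate
#' D90% >= 100% from below, V150% < 50% and the urethral maximum < 150%
#' from above — is solved analytically from the unit-strength dose
#' distribution; the urethral constraint is evaluated on a catheter-sized
#' 3 mm planning core around the urethral center line (the 7 mm circle is
#' the feature-zoning urethra).  If the window is empty the jitter is
#' redrawn (up to `max_attempts`).
#'
#' @param anatomy a [prostate_anatomy()].
#' @param grid a `voxel_grid`.
#' @param catalogue the zone catalogue for `anatomy` on `grid`.
#' @param config a [cohort_config()].
#' @param seed RNG seed.
#' @param max_attempts jitter redraws before giving up.
#' @return list: `implant` (a [seed_implant()]), `dose` (a `dose_grid`),
#'   `needles`, `n_seeds`, `metrics` (achieved D90/V150/urethra max).
#' @export
generate_implant <- function(anatomy, grid, catalogue, config, seed = 1,
                             max_attempts = 10) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mid_i <- which.max(vapply(anatomy$slices,
                            function(s) polygon_area(s$prostate), numeric(1)))
  poly <- anatomy$slices[[mid_i]]$prostate
  zr <- range(anatomy$z)
  tmpl <- expand.grid(x = seq(-30, 30, by = 5), y = seq(-30, 30, by = 5))
  inside <- mgcv::in.out(rbind(poly, poly[1, ]), as.matrix(tmpl))
  # margin: stay >= 2 mm inside the contour (shrink the polygon radially)
  cen <- colMeans(poly)
  shr <- sweep(sweep(poly, 2, cen) * 0.92, 2, cen, "+")
  inside2 <- mgcv::in.out(rbind(shr, shr[1, ]), as.matrix(tmpl))
  cand <- tmpl[inside & inside2, , drop = FALSE]
  uc_mid <- anatomy$slices[[mid_i]]$urethra_center
  du_all <- sqrt((tmpl$x - uc_mid[1])^2 + (tmpl$y - uc_mid[2])^2)
  # planning urethra: catheter-sized 3 mm core around the urethral center
  # line, on which the urethral maximum-dose constraint is evaluated (the
  # 7 mm circle is the feature-zoning urethra, not the planning organ)
  ctr <- voxel_centers(grid)
  ucl <- urethra_center_at(anatomy, ctr[catalogue$member, 3])
  rcl <- sqrt((ctr[catalogue$member, 1] - ucl[, 1])^2 +
              (ctr[catalogue$member, 2] - ucl[, 2])^2)
  core <- catalogue$member[rcl <= 3]

  for (attempt in seq_len(max_attempts)) {
    # modified peripheral loading: full outer ring plus a fraction of the
    # interior slots; later attempts widen interior coverage and edge the
    # urethral corridor inward, which small glands sometimes need
    excl <- if (attempt <= 3L) 7 else 6.5
    intfrac <- min(1, 0.5 + 0.1 * (attempt - 1L))
    cand <- tmpl[inside & inside2 & du_all > excl, , drop = FALSE]
    if (nrow(cand) < 4L) stop("anatomy too small to place a needle template")
    dc <- sqrt((cand$x - mean(cand$x))^2 + (cand$y - mean(cand$y))^2)
    ring <- dc >= stats::quantile(dc, 0.4)
    interior <- which(!ring)
    use <- c(which(ring),
             interior[sample.int(length(interior),
                                 size = ceiling(length(interior) * intfrac))])
    needles <- cand[sort(unique(use)), , drop = FALSE]
    seeds <- NULL
    for (i in seq_len(nrow(needles))) {
      L <- zr[2] - zr[1] - 5
      # densify axial loading on successive attempts: homogeneity is the
      # usual reason a draw misses the strength window
      zstep <- max(5.5, 8 - 0.4 * (attempt - 1L))
      nz <- max(2L, ceiling(L / zstep) + 1L)
      zz <- seq(zr[1] + 2.5, zr[2] - 2.5, length.out = nz)
      seeds <- rbind(seeds,
                     cbind(needles$x[i] + stats::rnorm(nz, 0, 0.75),
                           needles$y[i] + stats::rnorm(nz, 0, 0.75),
                           zz + stats::rnorm(nz, 0, 0.75)))
    }
    imp1 <- seed_implant(seeds, air_kerma_strength = 1)
    d1 <- compute_dose_grid(imp1, grid, prescription = config$prescription)
    pd <- d1$dose_pct[catalogue$masks[["Prostate"]]]
    # exact dose quantiles of the unit-strength distribution (the binned
    # DVH axis would clip them): D90 = 10th percentile, D50 = median
    d90_1 <- unname(stats::quantile(pd, 0.10, type = 1))
    d50_1 <- unname(stats::quantile(pd, 0.50, type = 1))
    umax_1 <- max(d1$dose_pct[core])
    # dose is linear in Sk, so the compliant strength window is analytic:
    # D90 >= 100% sets the floor, V150 < 50% and the urethral cap the
    # ceiling; take the geometric mid of the window, capped at D90 = 110%
    k_lo <- 1.005 * 100 / d90_1
    k_hi <- min(149 / d50_1, 149.5 / umax_1)
    if (k_hi > 1.01 * k_lo / 1.005) {
      k <- min(sqrt(k_lo * k_hi), 1.10 * 100 / d90_1)
      imp <- seed_implant(seeds, air_kerma_strength = k)
      dose <- d1
      dose$dose_gy <- d1$dose_gy * k
      dose$dose_pct <- d1$dose_pct * k
      prk <- compute_dvh(dose, catalogue$masks[["Prostate"]])
      return(list(implant = imp, dose = dose,
                  needles = nrow(needles), n_seeds = nrow(seeds),
                  metrics = c(D90 = dvh_metric(prk, "D", 90),
                              V150 = dvh_metric(prk, "V", 150),
                              urethra_max = k * umax_1)))
    }
  }
  stop(sprintf(paste0("no planning-goal-compliant strength after %d draws ",
                      "(D90x1 = %.1f, D50x1 = %.1f, urethra max x1 = %.1f)"),
               max_attempts, d90_1, d50_1, umax_1))
}

#' Generate IPSS trajectories consistent with latent toxicity labels
#'
#' Toxicity probability is logistic in the standardized planted zone dose
#' summaries and baseline IPSS, with the intercept calibrated so the mean
#' probability hits the prevalence target.  Each patient then receives a
#' transient post-implant IPSS rise (peak +5 to +15 near 3 months)
#' decaying toward baseline, with the resolution time placed inside the
#' 12-month horizon exactly when the latent label is 0 — so
#' [label_toxicity()] recovers the latent label for every patient.
#'
#' @param zone_summary numeric matrix (patients x planted zones) of the
#'   true zone mean doses (percent of prescription).
#' @param baseline_ipss integer baseline scores.
#' @param config a [cohort_config()].
#' @param seed RNG seed.
#' @return list: `records` (list of per-patient `baseline`, `times`,
#'   `scores`), `labels`, `latent_prob`.
#' @export
generate_outcomes <- function(zone_summary, baseline_ipss, config, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- length(baseline_ipss)
  zs <- scale(as.matrix(zone_summary))
  zs[!is.finite(zs)] <- 0
  lp0 <- as.numeric(zs %*% config$planted_effects) +
    config$ipss_effect * as.numeric(scale(baseline_ipss))
  lp0[!is.finite(lp0)] <- 0
  f <- function(a) mean(stats::plogis(a + lp0)) - config$prevalence
  a <- stats::uniroot(f, c(-20, 20))$root
  prob <- stats::plogis(a + lp0)
  labels <- stats::rbinom(n, 1L, prob)
  visits <- c(1.5, 3, 6, 9, 12, 18)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    B <- baseline_ipss[i]
    P <- stats::runif(1, 5, 15)
    Tres <- if (labels[i] == 1L) stats::runif(1, 15, 30) else stats::runif(1, 4, 10)
    tau <- (Tres - 3) / log(P / 2)
    sc <- vapply(visits, function(t) {
      v <- if (t < 3) B + P * t / 3 else B + P * exp(-(t - 3) / tau)
      v
    }, numeric(1))
    sc <- round(pmin(pmax(sc, 0), 35))
    # keep the trajectory consistent with the latent label after rounding
    if (labels[i] == 1L) {
      w <- visits <= 12
      sc[w] <- pmax(sc[w], min(B + 3, 35))
    } else {
      w <- visits <= 12 & visits >= Tres
      if (!any(w)) w <- visits == 12
      sc[w] <- pmin(sc[w], B + 2)
    }
    records[[i]] <- list(baseline = B, times = visits, scores = sc)
  }
  list(records = records, labels = labels, latent_prob = prob)
}

#' Simulate a complete synthetic cohort
#'
#' Draws anatomy, a planning-compliant implant and serial IPSS for every
#' patient, computes the zone DVHs and the ten indicators, and returns
#' everything the downstream featurization/modelling stages need.  The
#' per-patient dose grids are reduced to DVHs on the fly to keep memory
#' flat.
#'
#' @param config a [cohort_config()].
#' @param progress print a dot every 25 patients.
#' @return object of class `synthetic_cohort`: `dvhs` (n x 48 x 401
#'   array with `empty` attribute), `indicators`, `records`, `labels`,
#'   `zone_summary` (planted-zone mean doses), `meta` (per-patient volume,
#'   needles, seeds, achieved metrics), `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), progress = FALSE) {
  n <- config$n_patients
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  volumes <- stats::rlnorm(n, config$volume_meanlog, config$volume_sdlog)
  baseline <- pmin(30L, pmax(0L, as.integer(round(
    stats::rgamma(n, shape = 2.2, scale = 3.6)))))
  axis <- seq(0, 400, by = 1)
  zn <- zone_names()
  dvhs <- array(0, c(n, length(zn), length(axis)),
                dimnames = list(NULL, zn, NULL))
  empty <- matrix(FALSE, n, length(zn), dimnames = list(NULL, zn))
  ind <- matrix(0, n, 10)
  meta <- data.frame(volume_cc = volumes, needles = NA_real_,
                     seeds = NA_real_, D90 = NA_real_, V150 = NA_real_,
                     urethra_max = NA_real_)
  pz <- names(config$planted_effects)
  zsum <- matrix(NA_real_, n, length(pz), dimnames = list(NULL, pz))
  for (i in seq_len(n)) {
    an <- generate_anatomy(volumes[i], seed = derive_seed(config$seed, i, 1L),
                           slice_thickness = config$slice_thickness)
    gr <- build_grid(an, spacing = config$spacing)
    cat_i <- label_voxels(an, gr)
    impl <- generate_implant(an, gr, cat_i, config,
                             seed = derive_seed(config$seed, i, 2L))
    dm <- zone_dvh_matrix(impl$dose, cat_i, axis)
    dvhs[i, , ] <- dm
    empty[i, ] <- attr(dm, "empty")
    for (k in seq_along(pz)) {
      m <- cat_i$masks[[pz[k]]]
      zsum[i, k] <- if (length(m)) mean(impl$dose$dose_pct[m]) else NA_real_
    }
    ind[i, ] <- assemble_indicators(impl$dose, cat_i,
                                    list(needles = impl$needles,
                                         seeds = impl$n_seeds,
                                         baseline_ipss = baseline[i]),
                                    patient_id = i)
    meta$needles[i] <- impl$needles
    meta$seeds[i] <- impl$n_seeds
    meta$D90[i] <- impl$metrics[["D90"]]
    meta$V150[i] <- impl$metrics[["V150"]]
    meta$urethra_max[i] <- impl$metrics[["urethra_max"]]
    if (progress && i %% 25 == 0) cat(".")
  }
  colnames(ind) <- c("Prostate_D90", "Prostate_V100", "Prostate_V150",
                     "Urethra_D5", "Urethra_D30", "Urethra_V150",
                     "Needles", "Seeds", "ProstateVolume", "BaselineIPSS")
  zfill <- zsum
  for (k in seq_len(ncol(zfill)))
    zfill[!is.finite(zfill[, k]), k] <- mean(zfill[, k], na.rm = TRUE)
  outc <- generate_outcomes(zfill, baseline, config,
                            seed = derive_seed(config$seed, 0L, 3L))
  attr(dvhs, "empty") <- empty
  structure(list(dvhs = dvhs, indicators = ind, records = outc$records,
                 labels = outc$labels, latent_prob = outc$latent_prob,
                 zone_summary = zsum, meta = meta, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, prevalence %.2f (target %.2f)\n",
              length(x$labels), mean(x$labels), x$config$prevalence))
  cat(sprintf("  volumes %.0f-%.0f cc, D90 %.0f-%.0f%%, V150 max %.2f\n",
              min(x$meta$volume_cc), max(x$meta$volume_cc),
              min(x$meta$D90), max(x$meta$D90), max(x$meta$V150)))
  invisible(x)
}
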