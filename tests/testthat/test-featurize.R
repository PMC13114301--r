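test_that("zone PCA handles degenerate and rank-1 cohorts", {
  ax <- seq(0, 400)
  base <- 1 / (1 + exp((ax - 140) / 20))
  same <- matrix(rep(base, 5), 5, byrow = TRUE)
  m <- fit_zone_pca(same)
  expect_equal(m$explained, c(0, 0))
  expect_equal(project_zone_pca(same, m), matrix(0, 5, 2), tolerance = 1e-9)

  # rank-1 variation: PCA1 recovers the known direction, PCA2 is empty
  set.seed(1)
  dir <- dnorm(ax, 150, 25); dir <- dir / sqrt(sum(dir^2))
  coef <- rnorm(12)
  M <- matrix(rep(base, 12), 12, byrow = TRUE) + outer(coef, dir)
  m2 <- fit_zone_pca(M)
  expect_gt(abs(sum(m2$loadings[, 1] * dir)), 1 - 1e-8)
  expect_equal(m2$explained[1], 1, tolerance = 1e-9)
  expect_lt(m2$explained[2], 1e-9)
  # explained-variance ordering and loadings orthonormality
  expect_gte(m2$explained[1], m2$explained[2])
  expect_equal(crossprod(m2$loadings), diag(2), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("projection is the centered dot product, with mean-imputed empties", {
  set.seed(2)
  M <- synthetic_dvh_array(8, zones = "Prostate", seed = 3)[, 1, ]
  m <- fit_zone_pca(M)
  for (i in c(1, 5)) {
    oracle <- as.numeric(t(m$loadings) %*% (M[i, ] - m$center))
    expect_equal(project_zone_pca(M[i, ], m), oracle, tolerance = 1e-12)
  }
  expect_equal(project_zone_pca(colMeans(M), m), c(0, 0), tolerance = 1e-9)
  expect_equal(project_zone_pca(M[1, ], m, empty = TRUE), c(0, 0))
})

test_that("the assembled table has 96 spatial + 10 indicator columns", {
  n <- 8
  arr <- synthetic_dvh_array(n, seed = 4)
  ft <- build_feature_table(arr, random_indicators(n))
  expect_equal(sum(ft$category == "spatial_pca"), 96L)
  expect_equal(ncol(ft$values), 106L)
  expect_equal(sum(ft$category == "dvh_metric"), 6L)
  expect_equal(sum(ft$category == "implant"), 3L)
  expect_equal(sum(ft$category == "clinical"), 1L)
  expect_true(all(paste0(zone_names(), "_PCA1") %in% colnames(ft$values)))
})

test_that("feature values are invariant to patient ordering", {
  n <- 10
  arr <- synthetic_dvh_array(n, seed = 5)
  ind <- random_indicators(n, seed = 6)
  ft <- build_feature_table(arr, ind)
  perm <- sample(n)
  arr2 <- arr[perm, , , drop = FALSE]
  attr(arr2, "empty") <- attr(arr, "empty")[perm, , drop = FALSE]
  dimnames(arr2) <- dimnames(arr)
  ft2 <- build_feature_table(arr2, ind[perm, , drop = FALSE])
  expect_equal(unname(ft2$values), unname(ft$values[perm, ]),
               tolerance = 1e-9)
})

test_that("min-max scaling and Pearson pruning behave deterministically", {
  X <- cbind(a = c(2, 4, 6, 8), b = c(1, 0, 2, 5), const = rep(3, 4))
  ft <- structure(list(values = X,
                       category = setNames(rep("clinical", 3), colnames(X)),
                       pca_models = list(), dropped_zones = character(0)),
                  class = "feature_table")
  out <- scale_and_prune(ft)
  expect_equal(unname(out$values[, "a"]), c(0, 1/3, 2/3, 1))
  expect_equal(out$constant, "const")
  expect_equal(range(out$values[, "b"]), c(0, 1))

  # a duplicated column: exactly the later copy is dropped
  X2 <- cbind(X[, 1:2], a_copy = X[, 1] * 3 + 1)
  ft2 <- structure(list(values = X2,
                        category = setNames(rep("clinical", 3), colnames(X2)),
                        pca_models = list(), dropped_zones = character(0)),
                   class = "feature_table")
  out2 <- scale_and_prune(ft2)
  expect_equal(out2$pruned, "a_copy")
  expect_true("a" %in% colnames(out2$values))

  # independent noise: nothing pruned; pruning is idempotent
  set.seed(7)
  Xn <- matrix(rnorm(40 * 8), 40, 8,
               dimnames = list(NULL, paste0("f", 1:8)))
  ftn <- structure(list(values = Xn,
                        category = setNames(rep("clinical", 8), colnames(Xn)),
                        pca_models = list(), dropped_zones = character(0)),
                   class = "feature_table")
  o1 <- scale_and_prune(ftn)
  expect_length(o1$pruned, 0L)
  o2 <- scale_and_prune(o1)
  expect_equal(o2$values, o1$values)
})

test_that("indicator assembly reports the ten named quantities", {
  co <- test_cohort()
  expect_equal(colnames(co$indicators),
               c("Prostate_D90", "Prostate_V100", "Prostate_V150",
                 "Urethra_D5", "Urethra_D30", "Urethra_V150",
                 "Needles", "Seeds", "ProstateVolume", "BaselineIPSS"))
  expect_equal(ncol(co$indicators), 10L)
  # D5 >= D30 and V100 >= V150 hold for every patient
  expect_true(all(co$indicators[, "Urethra_D5"] >= co$indicators[, "Urethra_D30"]))
  expect_true(all(co$indicators[, "Prostate_V100"] >= co$indicators[, "Prostate_V150"]))
  an <- generate_anatomy(30, seed = 1)
  g <- build_grid(an, spacing = 2.5)
  ct <- label_voxels(an, g)
  d <- compute_dose_grid(seed_implant(rbind(c(0, 0, 15)), 1), g)
  expect_error(assemble_indicators(d, ct, list(needles = 20, seeds = 60),
                                   patient_id = "P9"),
               "P9.*baseline_ipss")
})
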