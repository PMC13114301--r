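test_that("zone catalogue enumerates the 48 named subzones", {
  zn <- zone_names()
  expect_length(zn, 48L)
  expect_false(anyDuplicated(zn) > 0)
  expect_setequal(zn[1:9],
                  c("Prostate", "Anterior", "Posterior", "Urethra",
                    "Urethra10mm", "Peripheral", "Base", "MidGland", "Apex"))
  expect_true(all(c("Apex_Anterior_Urethra", "Apex_Anterior_Urethra10mm",
                    "MidGland_Posterior_Urethra", "Base_Urethra10mm",
                    "Anterior_Peripheral", "Posterior_Urethra10mm") %in% zn))
  # 9 individual + 11 per axial region x 3 + 3 per coronal region x 2
  expect_length(grep("^Base_", zn), 11L)
  expect_length(grep("^MidGland_", zn), 11L)
  expect_length(grep("^Apex_", zn), 11L)
})

test_that("grid construction covers the anatomy with the required margins", {
  an <- disc_anatomy(radius = 20, z = 0)
  g <- build_grid(an, spacing = 1)
  expect_gte(g$dims[1] * g$spacing[1], 60)   # 2 x (20 + 10) mm
  expect_gte(g$dims[2] * g$spacing[2], 60)

  an2 <- disc_anatomy(radius = 20, z = seq(0, 40, by = 2.5))
  g2 <- build_grid(an2, spacing = 1)
  expect_gte(g2$dims[1], 60)
  expect_gte(g2$dims[3], 42)                 # 40 mm + one slice thickness/side

  expect_error(prostate_anatomy(list()), "at least one")
})

test_that("axial partition splits the extent 1:2:1 with half-open boundaries", {
  an <- disc_anatomy(z = seq(0, 40, by = 2.5))
  ax <- axial_partition(an)
  expect_equal(ax$apex, c(0, 10))
  expect_equal(ax$mid, c(10, 30))
  expect_equal(ax$base, c(30, 40))

  an2 <- disc_anatomy(z = seq(0, 8, by = 2))
  ax2 <- axial_partition(an2)
  expect_equal(ax2$boundaries, c(2, 6))

  # z exactly at the apex/mid boundary belongs to the mid-gland
  g <- build_grid(an, spacing = c(5, 5, 2.5))
  ct <- label_voxels(an, g)
  zc <- voxel_centers(g)[, 3]
  at10 <- ct$member[abs(zc[ct$member] - 10) < 1e-9]
  if (length(at10)) {
    expect_true(all(at10 %in% ct$masks[["MidGland"]]))
    expect_false(any(at10 %in% ct$masks[["Apex"]]))
  }
})

test_that("radial and coronal labels follow the urethral geometry", {
  an <- disc_anatomy(radius = 20, z = seq(0, 40, by = 2.5))
  g <- build_grid(an, spacing = 1)
  ct <- label_voxels(an, g)
  zmid <- g$origin[3] + (round(g$dims[3] / 2) - 0.5) * g$spacing[3]

  v_ur <- voxel_at(g, 3, 0, zmid)        # 3 mm lateral: urethra
  expect_true(v_ur %in% ct$masks[["Urethra"]])
  v_near <- voxel_at(g, 8.5, 0, zmid)    # 7-10 mm annulus
  expect_true(v_near %in% ct$masks[["Urethra10mm"]])
  v_per <- voxel_at(g, 14.5, 0, zmid)    # beyond 10 mm
  expect_true(v_per %in% ct$masks[["Peripheral"]])
  v_ant <- voxel_at(g, 12.5, 2.5, zmid)  # anterior of the center line
  expect_true(v_ant %in% ct$masks[["Anterior"]])
  v_post <- voxel_at(g, 12.5, -2.5, zmid)
  expect_true(v_post %in% ct$masks[["Posterior"]])
  expect_length(ct$masks, 48L)
})

test_that("the three families partition the labelled set and composites intersect", {
  set.seed(42)
  for (s in 1:3) {
    an <- generate_anatomy(rlnorm(1, log(35), 0.3), seed = 100 + s)
    g <- build_grid(an, spacing = 2.5)
    ct <- label_voxels(an, g)
    member <- sort(ct$member)
    fams <- list(c("Base", "MidGland", "Apex"),
                 c("Anterior", "Posterior"),
                 c("Urethra", "Urethra10mm", "Peripheral"))
    for (f in fams) {
      parts <- lapply(f, function(nm) ct$masks[[nm]])
      expect_equal(sort(unlist(parts)), member)
      expect_equal(sum(lengths(parts)), length(member))  # disjoint
    }
    for (nm in sample(zone_names()[10:48], 8)) {
      parts <- strsplit(nm, "_")[[1]]
      expected <- Reduce(intersect, lapply(parts, function(p) ct$masks[[p]]))
      expect_setequal(ct$masks[[nm]], expected)
    }
    # axial zones jointly exhaust the labelled volume
    v3 <- zone_volume_cc(ct, "Base") + zone_volume_cc(ct, "MidGland") +
      zone_volume_cc(ct, "Apex")
    expect_equal(v3, length(member) * prod(g$spacing) / 1000)
  }
})

test_that("prostate volume tracks the contoured volume and scales isotropically", {
  an <- disc_anatomy(radius = 15, z = seq(0, 30, by = 2.5), urethra_xy = c(0, -2))
  g <- build_grid(an, spacing = 1)
  ct <- label_voxels(an, g)
  slab <- sum(vapply(an$slices,
                     function(s) brachytox:::polygon_area(s$prostate),
                     numeric(1))) * 2.5 / 1000
  expect_lt(abs(zone_volume_cc(ct, "Prostate") - slab) / slab, 0.12)

  # scaling the whole geometry (including the urethral radii) by k scales
  # zone volumes by ~k^3, up to discretization at the boundaries
  k <- 1.5
  an2 <- prostate_anatomy(lapply(an$slices, function(s)
    list(z = s$z * k, prostate = s$prostate * k,
         urethra_center = s$urethra_center * k)),
    urethra_radius = 7 * k, nearzone_outer_radius = 10 * k)
  ct2 <- label_voxels(an2, build_grid(an2, spacing = 1))
  r <- zone_volume_cc(ct2, "Peripheral") / zone_volume_cc(ct, "Peripheral")
  expect_lt(abs(r - k^3) / k^3, 0.1)
})
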