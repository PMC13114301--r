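# Shared fixtures, built once per test run and cached across files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A small cohort exercised by several files.
test_cohort <- function(n = 20, seed = 11, spacing = 3) {
  key <- sprintf("cohort_%d_%d_%g", n, seed, spacing)
  cached(key, simulate_cohort(
    cohort_config(n_patients = n, spacing = spacing, seed = seed)))
}

# A single circular-slice-stack anatomy: stack of identical discs of the
# given radius, urethra on the axis (offset optionally).
disc_anatomy <- function(radius = 20, z = seq(0, 40, by = 2.5),
                         urethra_xy = c(0, 0), n_vertices = 48) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  slices <- lapply(z, function(zz)
    list(z = zz,
         prostate = cbind(radius * cos(th), radius * sin(th)),
         urethra_center = urethra_xy))
  prostate_anatomy(slices)
}

# Voxel index of the grid voxel whose center is nearest a point.
voxel_at <- function(grid, x, y, z) {
  ijk <- pmin(pmax(floor(((c(x, y, z) - grid$origin) / grid$spacing)), 0),
              grid$dims - 1L)
  as.integer(ijk[1] + grid$dims[1] * (ijk[2] + grid$dims[2] * ijk[3]) + 1L)
}

# Smooth synthetic DVH-like cohort (sigmoid curves with random midpoints),
# for featurization tests that need no dosimetry.
synthetic_dvh_array <- function(n, zones = zone_names(), seed = 1,
                                axis = seq(0, 400, by = 1)) {
  set.seed(seed)
  arr <- array(0, c(n, length(zones), length(axis)),
               dimnames = list(NULL, zones, NULL))
  for (j in seq_along(zones)) {
    mid <- runif(1, 100, 180)
    for (i in seq_len(n)) {
      m <- mid + rnorm(1, 0, 15)
      s <- runif(1, 10, 30)
      arr[i, j, ] <- 1 / (1 + exp((axis - m) / s))
    }
  }
  attr(arr, "empty") <- matrix(FALSE, n, length(zones))
  arr
}

random_indicators <- function(n, seed = 2) {
  set.seed(seed)
  m <- cbind(runif(n, 100, 120), runif(n, 0.9, 1), runif(n, 0.2, 0.5),
             runif(n, 110, 140), runif(n, 100, 130), runif(n, 0, 0.3),
             sample(15:30, n, TRUE), sample(50:90, n, TRUE),
             runif(n, 20, 60), sample(0:20, n, TRUE))
  colnames(m) <- c("Prostate_D90", "Prostate_V100", "Prostate_V150",
                   "Urethra_D5", "Urethra_D30", "Urethra_V150",
                   "Needles", "Seeds", "ProstateVolume", "BaselineIPSS")
  m
}
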