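# Shared fixtures, all built in code at load time.

# axis-aligned solid box given 1-based voxel index ranges
box_mask <- function(shape, xr, yr, zr, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  a <- array(FALSE, dim = shape)
  a[xr, yr, zr] <- TRUE
  mask_volume(a, spacing, origin)
}

# sphere by voxel-centre distance, physical units
sphere_mask <- function(shape, centre_mm, radius_mm, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0)) {
  xs <- origin[1] + (seq_len(shape[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(shape[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(shape[3]) - 1) * spacing[3]
  d2 <- outer(outer((xs - centre_mm[1])^2, (ys - centre_mm[2])^2, "+"),
              (zs - centre_mm[3])^2, "+")
  mask_volume(d2 <= radius_mm^2, spacing, origin)
}

random_mask <- function(shape, p = 0.3, seed = 1, spacing = c(1, 1, 1)) {
  set.seed(seed)
  mask_volume(array(runif(prod(shape)) < p, dim = shape), spacing)
}

shift_mask <- function(m, off) {
  mask_volume(potdassess:::shift3(m$data, as.integer(off), FALSE),
              m$spacing_mm, m$origin_mm)
}

# compact phantom configuration used throughout the suite
test_phantom_params <- function(seed = 1L, filling = 0.5) {
  phantom_params(shape = c(64, 64, 64), spacing_mm = c(3, 3, 3),
                 bladder_filling = filling, seed = seed)
}

# one shared mid-filling phantom, generated once per test run
fixture_env <- new.env()
test_phantom <- function() {
  if (is.null(fixture_env$phantom)) {
    fixture_env$phantom <- generate_phantom(test_phantom_params())
  }
  fixture_env$phantom
}
test_library <- function() {
  if (is.null(fixture_env$library)) {
    series <- generate_filling_series(test_phantom_params(), c(0.15, 0.5, 0.85))
    fixture_env$series <- series
    fixture_env$library <- build_plan_library(series)
  }
  fixture_env$library
}
test_series <- function() {
  test_library()
  fixture_env$series
}
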