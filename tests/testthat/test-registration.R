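# registration unit tests run on 64^3 grids at 2 mm; the phantom-scale
# propagation checks live in the acceptance suite

grid64 <- c(64, 64, 64)
sp2 <- c(2, 2, 2)

test_that("affine alignment recovers identity, translation and scale", {
  a <- sphere_mask(grid64, c(64, 64, 64), 20, spacing = sp2)
  id <- affine_align(a, a)
  expect_equal(id$matrix, diag(3), tolerance = 1e-6)
  expect_equal(id$translation_mm, c(0, 0, 0), tolerance = 1e-6)
  # fixed = moving translated by (10, 0, 0) mm: pull-back maps back
  b <- shift_mask(a, c(5, 0, 0))
  tr <- affine_align(a, b)
  expect_equal(tr$translation_mm, c(-10, 0, 0), tolerance = 1)  # half a voxel
  expect_equal(tr$matrix, diag(3), tolerance = 0.02)
  # fixed = moving scaled x1.2 about its centroid
  big <- sphere_mask(grid64, c(64, 64, 64), 24, spacing = sp2)
  sc <- affine_align(a, big)
  expect_equal(diag(sc$matrix), rep(1 / 1.2, 3), tolerance = 0.05 / 1.2)
  expect_error(affine_align(a, mask_volume(array(FALSE, grid64), sp2)),
               class = "potd_data_error")
  expect_warning(affine_align(a, box_mask(grid64, 10:20, 10:20, 10,
                                          spacing = sp2)),
                 "degenerate")
})

test_that("demons has a zero-field fixed point and improves a translated sphere", {
  a <- sphere_mask(grid64, c(64, 64, 64), 20, spacing = sp2)
  fid <- demons_register(a, a)
  mag <- sqrt(fid$vectors_mm[, , , 1]^2 + fid$vectors_mm[, , , 2]^2 +
                fid$vectors_mm[, , , 3]^2)
  expect_lt(max(mag), 0.1 * 2)                      # 0.1 voxel
  b <- shift_mask(a, c(0, 3, 0))                    # 6 mm translation
  before <- dice(a, b)
  field <- demons_register(a, b)
  after <- dice(warp_mask(a, field), b)
  expect_gte(after, before + 0.1)
  # the recovered field is near-diffeomorphic inside the target
  expect_gte(jacobian_positive_fraction(field, b$data), 0.99)
})

test_that("composition reduces to its closed forms", {
  d <- c(8, 8, 8)
  zero <- displacement_field(array(0, c(d, 3)), sp2, c(0, 0, 0))
  ident <- affine_transform()
  expect_equal(compose_transforms(ident, zero)$vectors_mm, zero$vectors_mm)
  set.seed(1)
  dv <- displacement_field(array(rnorm(prod(d) * 3), c(d, 3)), sp2, c(0, 0, 0))
  expect_equal(compose_transforms(ident, dv)$vectors_mm, dv$vectors_mm)
  tr <- affine_transform(diag(3), c(4, -2, 6))
  comp <- compose_transforms(tr, zero)
  expect_equal(range(comp$vectors_mm[, , , 1]), c(4, 4))
  expect_equal(range(comp$vectors_mm[, , , 2]), c(-2, -2))
  expect_equal(range(comp$vectors_mm[, , , 3]), c(6, 6))
})

test_that("warping: identity, whole-voxel shift, and inverse consistency", {
  m <- sphere_mask(grid64, c(64, 64, 64), 16, spacing = sp2)
  d <- dim(m$data)
  zero <- displacement_field(array(0, c(d, 3)), sp2, c(0, 0, 0))
  expect_identical(warp_mask(m, zero)$data, m$data)
  # constant field of exactly two voxels along +x: pull-back shifts -x
  const <- displacement_field(
    array(rep(c(4, 0, 0), each = prod(d)), c(d, 3)), sp2, c(0, 0, 0))
  expect_identical(warp_mask(m, const)$data, shift_mask(m, c(-2, 0, 0))$data)
  # smooth small field, then its numerical inverse
  ia <- potdassess:::index_arrays(d)
  wob <- sin(2 * pi * ia$x / d[1]) * cos(2 * pi * ia$y / d[2])
  vec <- array(0, c(d, 3))
  vec[, , , 1] <- 3 * wob
  vec[, , , 3] <- 2 * sin(2 * pi * ia$z / d[3])
  fwd <- displacement_field(vec, sp2, c(0, 0, 0))
  inv_vec <- -vec
  for (k in 1:8) {                                  # fixed-point inversion
    xi <- ia$x + inv_vec[, , , 1] / 2
    yi <- ia$y + inv_vec[, , , 2] / 2
    zi <- ia$z + inv_vec[, , , 3] / 2
    for (c in 1:3) {
      inv_vec[, , , c] <- -array(potdassess:::interp3(vec[, , , c], xi, yi, zi),
                                 dim = d)
    }
  }
  inv <- displacement_field(inv_vec, sp2, c(0, 0, 0))
  round_trip <- warp_mask(warp_mask(m, fwd), inv)
  expect_gte(dice(round_trip, m), 0.95)
  # grid mismatch
  expect_error(warp_mask(box_mask(c(9, 9, 9), 1, 1, 1), zero),
               class = "potd_geometry_error")
})

test_that("displacement fields round-trip through 4-D NIfTI", {
  set.seed(2)
  f <- displacement_field(array(rnorm(6 * 6 * 6 * 3), c(6, 6, 6, 3)),
                          c(2, 2, 2), c(1, 0, -3))
  path <- tempfile(fileext = ".nii.gz")
  write_displacement_field(f, path)
  r <- read_displacement_field(path)
  expect_equal(r$vectors_mm, f$vectors_mm, tolerance = 1e-6)
  expect_equal(r$spacing_mm, f$spacing_mm, tolerance = 1e-4)
  expect_equal(r$origin_mm, f$origin_mm, tolerance = 1e-4)
  unlink(path)
})

test_that("HR-CTV propagation is contained, deterministic and accurate", {
  ss <- test_phantom()
  hr <- ss$masks$hr_ctv
  lr <- ss$masks$lr_ctv
  res <- propagate_hrctv(hr, lr, lr)
  expect_gte(dice(res, hr), 0.98)                   # identity daily anatomy
  daily <- shift_mask(lr, c(0, 2, 1))
  res2 <- propagate_hrctv(hr, lr, daily)
  expect_false(any(res2$data & !daily$data))        # controlling-ROI containment
  res2b <- propagate_hrctv(hr, lr, daily)
  expect_identical(res2$data, res2b$data)           # determinism
  # registration improves alignment of the LR-CTV itself
  aff <- affine_align(lr, daily)
  expect_gte(dice(res2, shift_mask(hr, c(0, 2, 1))),
             dice(hr, shift_mask(hr, c(0, 2, 1))) - 0.01)
  expect_warning(
    propagate_hrctv(shift_mask(hr, c(30, 0, 0)), lr, daily),
    "not contained")
  expect_error(propagate_hrctv(hr, lr, mask_volume(array(FALSE, dim(lr$data)),
                                                   lr$spacing_mm)),
               class = "potd_data_error")
})
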