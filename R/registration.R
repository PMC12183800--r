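#' Affine transforms and displacement fields
#'
#' An `affine_transform` maps fixed-space physical points to moving-space
#' physical points (the pull-back/resampling convention: to warp a moving
#' image onto the fixed grid, each fixed-grid point is mapped into the
#' moving image and sampled there). A `displacement_field` stores a
#' per-voxel displacement in mm on the fixed grid, with the same
#' convention: the moving image is sampled at `x + d(x)`.
#'
#' @param matrix invertible 3x3 matrix.
#' @param translation_mm numeric triple in mm.
#' @return an `affine_transform`.
#' @export
affine_transform <- function(matrix = diag(3), translation_mm = c(0, 0, 0)) {
  matrix <- as.matrix(matrix)
  if (!all(dim(matrix) == c(3, 3)) || any(!is.finite(matrix))) {
    potd_stop("matrix must be a finite 3x3 matrix", "potd_argument_error")
  }
  if (abs(det(matrix)) < 1e-12) {
    potd_stop("affine matrix must be invertible", "potd_argument_error")
  }
  translation_mm <- as.numeric(translation_mm)
  if (length(translation_mm) != 3L || any(!is.finite(translation_mm))) {
    potd_stop("translation_mm must be three finite values", "potd_argument_error")
  }
  structure(list(matrix = matrix, translation_mm = translation_mm),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform> (fixed -> moving, mm)\n")
  print(cbind(x$matrix, t = x$translation_mm))
  invisible(x)
}

#' Apply an affine transform to physical points
#'
#' @param affine an `affine_transform`.
#' @param points numeric n x 3 matrix of physical points (mm).
#' @return n x 3 matrix of mapped points.
#' @export
apply_affine <- function(affine, points) {
  points <- matrix(points, ncol = 3)
  sweep(points %*% t(affine$matrix), 2, affine$translation_mm, "+")
}

#' Per-voxel displacement field on a fixed grid
#'
#' @param vectors_mm 4-D numeric array `(nx, ny, nz, 3)` of displacement
#'   components in mm.
#' @param spacing_mm,origin_mm grid geometry of the fixed image.
#' @return a `displacement_field`.
#' @export
displacement_field <- function(vectors_mm, spacing_mm = c(1, 1, 1),
                               origin_mm = c(0, 0, 0)) {
  d <- dim(vectors_mm)
  if (length(d) != 4L || d[4] != 3L) {
    potd_stop("vectors_mm must be an (nx, ny, nz, 3) array", "potd_shape_error")
  }
  if (any(!is.finite(vectors_mm))) {
    potd_stop("displacement field contains non-finite values",
              "potd_numeric_error")
  }
  structure(list(vectors_mm = vectors_mm, spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  d <- dim(x$vectors_mm)
  mag <- sqrt(x$vectors_mm[, , , 1]^2 + x$vectors_mm[, , , 2]^2 +
                x$vectors_mm[, , , 3]^2)
  cat(sprintf("<displacement_field> %d x %d x %d, |d| max %.2f mm, mean %.2f mm\n",
              d[1], d[2], d[3], max(mag), mean(mag)))
  invisible(x)
}

#' Serialise a displacement field as a 4-D NIfTI volume (mm units)
#'
#' @param field a `displacement_field`.
#' @param path output `.nii`/`.nii.gz` path.
#' @export
write_displacement_field <- function(field, path) {
  img <- RNifti::asNifti(field$vectors_mm)
  RNifti::pixdim(img) <- c(field$spacing_mm, 1)
  m <- diag(c(field$spacing_mm, 1))
  m[1:3, 4] <- field$origin_mm
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_displacement_field
#' @return `read_displacement_field()`: a `displacement_field`.
#' @export
read_displacement_field <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L || dim(img)[4] != 3L) {
    potd_stop(sprintf("'%s' is not a 3-vector 4-D volume", path),
              "potd_shape_error")
  }
  arr <- array(as.numeric(img), dim = dim(img))
  xf <- RNifti::xform(img)
  displacement_field(arr, spacing_mm = abs(RNifti::pixdim(img))[1:3],
                     origin_mm = as.numeric(xf[1:3, 4]))
}

#' Demons registration settings
#'
#' Defaults follow the single-stage configuration used for mask-to-mask
#' HR-CTV propagation: one stage, resolution down-sampled by a factor of
#' 8, 20 iterations, with Gaussian regularisation of the accumulated
#' field. Results are deterministic regardless of any parallel execution
#' of the caller.
#'
#' @param iterations number of demons iterations (>= 1).
#' @param shrink_factor integer down-sampling factor (>= 1).
#' @param smoothing_sigma_mm Gaussian sigma (mm) used both to convert 0/1
#'   masks to smooth scalar images and to regularise the update field.
#' @param stages number of resolution stages; only 1 is supported.
#' @return a `demons_settings` object.
#' @export
demons_settings <- function(iterations = 20L, shrink_factor = 8L,
                            smoothing_sigma_mm = 2, stages = 1L) {
  if (iterations < 1 || shrink_factor < 1) {
    potd_stop("iterations and shrink_factor must be >= 1", "potd_argument_error")
  }
  if (stages != 1L) {
    potd_stop("only single-stage registration is supported", "potd_argument_error")
  }
  if (!is.finite(smoothing_sigma_mm) || smoothing_sigma_mm <= 0) {
    potd_stop("smoothing_sigma_mm must be positive", "potd_argument_error")
  }
  structure(list(iterations = as.integer(iterations),
                 shrink_factor = as.integer(shrink_factor),
                 smoothing_sigma_mm = smoothing_sigma_mm,
                 stages = 1L),
            class = "demons_settings")
}

# 0/1 mask -> smooth scalar image for demons forces
mask_to_image <- function(mask, sigma_mm) {
  gauss_smooth3(array(as.numeric(mask$data), dim = dim(mask$data)),
                sigma_vox = sigma_mm / mask$spacing_mm)
}

index_arrays <- function(d) {
  list(x = array(seq_len(d[1]), dim = d),
       y = array(rep(seq_len(d[2]), each = d[1]), dim = d),
       z = array(rep(seq_len(d[3]), each = d[1] * d[2]), dim = d))
}

#' Closed-form affine initialisation from mask geometry
#'
#' Matches the first and second spatial moments of the two masks: the
#' transform translates the fixed-mask centroid onto the moving-mask
#' centroid and scales each world axis by the ratio of the masks' standard
#' deviations along it. No iterative optimiser is involved. Degenerate
#' (planar or narrower) masks fall back to centroid-only translation with
#' a warning.
#'
#' @param moving,fixed nonempty `mask_volume`s in one physical space.
#' @return an `affine_transform` mapping fixed-space points to
#'   moving-space points.
#' @export
affine_align <- function(moving, fixed) {
  if (sum(moving$data) == 0L || sum(fixed$data) == 0L) {
    potd_stop("affine_align requires nonempty masks", "potd_data_error")
  }
  stats_of <- function(m) {
    idx <- which(m$data, arr.ind = TRUE)
    phys <- sweep(sweep(idx - 1, 2, m$spacing_mm, "*"), 2, m$origin_mm, "+")
    list(centroid = colMeans(phys), sd = apply(phys, 2, stats::sd))
  }
  sm <- stats_of(moving)
  sf <- stats_of(fixed)
  if (any(!is.finite(sm$sd)) || any(!is.finite(sf$sd)) ||
      any(sm$sd < 1e-6) || any(sf$sd < 1e-6)) {
    warning("degenerate mask geometry: falling back to centroid-only translation",
            call. = FALSE)
    A <- diag(3)
  } else {
    A <- diag(sm$sd / sf$sd)
  }
  affine_transform(A, sm$centroid - as.numeric(A %*% sf$centroid))
}

# Core symmetric-forces demons on smooth scalar images defined on one grid.
# Returns the displacement field (mm) on the full-resolution fixed grid.
demons_core <- function(m_img, f_img, spacing, origin, settings) {
  s <- settings$shrink_factor
  mc <- downsample_mean(m_img, s)
  fc <- downsample_mean(f_img, s)
  csp <- spacing * s
  nc <- dim(fc)
  alpha <- 1 / mean(csp)
  gf <- gradient3(fc, csp)
  ia <- index_arrays(nc)
  dx <- array(0, nc); dy <- array(0, nc); dz <- array(0, nc)
  sig_vox <- pmax(settings$smoothing_sigma_mm / csp, 0.5)
  for (it in seq_len(settings$iterations)) {
    xi <- ia$x + dx / csp[1]
    yi <- ia$y + dy / csp[2]
    zi <- ia$z + dz / csp[3]
    mw <- array(interp3(mc, xi, yi, zi), dim = nc)
    gm <- gradient3(mw, csp)
    r <- mw - fc
    gx <- gf$x + gm$x; gy <- gf$y + gm$y; gz <- gf$z + gm$z
    den <- gx^2 + gy^2 + gz^2 + alpha^2 * r^2
    ok <- den > 1e-12
    ux <- array(0, nc); uy <- array(0, nc); uz <- array(0, nc)
    ux[ok] <- -2 * r[ok] * gx[ok] / den[ok]
    uy[ok] <- -2 * r[ok] * gy[ok] / den[ok]
    uz[ok] <- -2 * r[ok] * gz[ok] / den[ok]
    dx <- gauss_smooth3(dx + ux, sig_vox, normalize = TRUE)
    dy <- gauss_smooth3(dy + uy, sig_vox, normalize = TRUE)
    dz <- gauss_smooth3(dz + uz, sig_vox, normalize = TRUE)
    if (any(!is.finite(dx)) || any(!is.finite(dy)) || any(!is.finite(dz))) {
      potd_stop("demons iteration produced non-finite displacements",
                "potd_numeric_error")
    }
  }
  # up-sample the coarse field to the native grid (linear, border-clamped)
  d <- dim(f_img)
  iaf <- index_arrays(d)
  up <- function(comp) {
    ci <- function(i, ax) pmin(pmax(((i - 1) - (s - 1) / 2) / s + 1, 1), nc[ax])
    array(interp3(comp, ci(iaf$x, 1), ci(iaf$y, 2), ci(iaf$z, 3)), dim = d)
  }
  vec <- array(0, dim = c(d, 3L))
  vec[, , , 1] <- up(dx)
  vec[, , , 2] <- up(dy)
  vec[, , , 3] <- up(dz)
  displacement_field(vec, spacing_mm = spacing, origin_mm = origin)
}

#' Fast symmetric-forces demons registration of two masks
#'
#' The 0/1 masks are converted to smooth scalar images by Gaussian
#' smoothing, down-sampled by `shrink_factor`, and iterated with symmetric
#' demons forces
#' `u = -2 (m - f) (grad f + grad m) / (|grad f + grad m|^2 + a^2 (m - f)^2)`
#' (the normalisation constant `a` is the reciprocal of the coarse voxel
#' size, capping each per-iteration step at about one coarse voxel); the
#' accumulated field is Gaussian-smoothed every iteration and finally
#' up-sampled to the native grid.
#'
#' @param moving,fixed nonempty `mask_volume`s on one grid.
#' @param settings a `demons_settings` object.
#' @return a `displacement_field` on the fixed grid: warping `moving` by
#'   it approximates `fixed`.
#' @export
demons_register <- function(moving, fixed, settings = demons_settings()) {
  check_same_grid(moving, fixed)
  if (sum(moving$data) == 0L || sum(fixed$data) == 0L) {
    potd_stop("demons_register requires nonempty masks", "potd_data_error")
  }
  demons_core(mask_to_image(moving, settings$smoothing_sigma_mm),
              mask_to_image(fixed, settings$smoothing_sigma_mm),
              fixed$spacing_mm, fixed$origin_mm, settings)
}

#' Compose an affine transform with a displacement field
#'
#' Produces the single composite field equivalent to applying the demons
#' field first and the affine second under the resampling convention:
#' `T(x) = A (x + d(x)) + t - x`, so warping once with the composite
#' equals warping sequentially.
#'
#' @param affine an `affine_transform`.
#' @param dvf a `displacement_field` on the fixed grid.
#' @return a `displacement_field` on the same grid.
#' @export
compose_transforms <- function(affine, dvf) {
  d <- dim(dvf$vectors_mm)[1:3]
  ia <- index_arrays(d)
  px <- dvf$origin_mm[1] + (ia$x - 1) * dvf$spacing_mm[1]
  py <- dvf$origin_mm[2] + (ia$y - 1) * dvf$spacing_mm[2]
  pz <- dvf$origin_mm[3] + (ia$z - 1) * dvf$spacing_mm[3]
  qx <- px + dvf$vectors_mm[, , , 1]
  qy <- py + dvf$vectors_mm[, , , 2]
  qz <- pz + dvf$vectors_mm[, , , 3]
  A <- affine$matrix; t <- affine$translation_mm
  vec <- array(0, dim = c(d, 3L))
  vec[, , , 1] <- A[1, 1] * qx + A[1, 2] * qy + A[1, 3] * qz + t[1] - px
  vec[, , , 2] <- A[2, 1] * qx + A[2, 2] * qy + A[2, 3] * qz + t[2] - py
  vec[, , , 3] <- A[3, 1] * qx + A[3, 2] * qy + A[3, 3] * qz + t[3] - pz
  displacement_field(vec, dvf$spacing_mm, dvf$origin_mm)
}

#' Warp a binary mask through a displacement field
#'
#' The 0/1 mask is sampled with trilinear interpolation at each displaced
#' grid point and thresholded at 0.5; samples falling outside the moving
#' volume are background.
#'
#' @param mask a `mask_volume` sharing the field's grid.
#' @param dvf a `displacement_field`.
#' @return the warped `mask_volume` on the fixed grid.
#' @export
warp_mask <- function(mask, dvf) {
  d <- dim(dvf$vectors_mm)[1:3]
  if (!all(dim(mask$data) == d) ||
      any(abs(mask$spacing_mm - dvf$spacing_mm) > 1e-3) ||
      any(abs(mask$origin_mm - dvf$origin_mm) > 1e-3)) {
    potd_stop("mask and displacement field are not on the same grid",
              "potd_geometry_error")
  }
  ia <- index_arrays(d)
  xi <- ia$x + dvf$vectors_mm[, , , 1] / mask$spacing_mm[1]
  yi <- ia$y + dvf$vectors_mm[, , , 2] / mask$spacing_mm[2]
  zi <- ia$z + dvf$vectors_mm[, , , 3] / mask$spacing_mm[3]
  vals <- interp3(array(as.numeric(mask$data), dim = d), xi, yi, zi)
  mask_volume(array(vals >= 0.5, dim = d), mask$spacing_mm, mask$origin_mm)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    cls <- setdiff(class(e), c("error", "condition"))
    stop(errorCondition(sprintf("[stage %s] %s", stage, conditionMessage(e)),
                        class = c(cls, "potd_error")))
  })
}

#' Propagate the HR-CTV onto daily anatomy via mask-to-mask registration
#'
#' Re-implements the structure-guided propagation pipeline: (i) the
#' reference LR-CTV is the moving mask and the daily LR-CTV the fixed
#' mask; (ii) closed-form affine initialisation; (iii) fast
#' symmetric-forces demons between the affinely initialised smooth mask
#' images; (iv) the affine and deformable transforms are composed into a
#' single displacement field used to warp the reference HR-CTV once; (v)
#' the warped HR-CTV is intersected with the daily LR-CTV, which acts as
#' the controlling structure, so the result is always contained in it.
#'
#' @param hrctv_ref reference HR-CTV mask (expected within `lrctv_ref`; a
#'   violation only warns).
#' @param lrctv_ref reference LR-CTV mask.
#' @param lrctv_daily daily LR-CTV mask (same grid).
#' @param settings a `demons_settings` object.
#' @return the propagated HR-CTV `mask_volume`, a subset of `lrctv_daily`.
#' @export
propagate_hrctv <- function(hrctv_ref, lrctv_ref, lrctv_daily,
                            settings = demons_settings()) {
  for (m in list(hrctv_ref, lrctv_ref, lrctv_daily)) {
    if (sum(m$data) == 0L) {
      potd_stop("propagate_hrctv requires nonempty masks", "potd_data_error")
    }
  }
  check_same_grid(lrctv_ref, lrctv_daily, "reference and daily LR-CTV")
  check_same_grid(hrctv_ref, lrctv_ref, "HR-CTV and reference LR-CTV")
  if (any(hrctv_ref$data & !lrctv_ref$data)) {
    warning("reference HR-CTV is not contained in the reference LR-CTV",
            call. = FALSE)
  }
  aff <- run_stage("affine", affine_align(lrctv_ref, lrctv_daily))
  sig <- settings$smoothing_sigma_mm
  f_img <- mask_to_image(lrctv_daily, sig)
  m_img <- mask_to_image(lrctv_ref, sig)
  # affine initialisation: resample the moving image into fixed space
  d <- dim(f_img)
  ia <- index_arrays(d)
  px <- lrctv_daily$origin_mm[1] + (ia$x - 1) * lrctv_daily$spacing_mm[1]
  py <- lrctv_daily$origin_mm[2] + (ia$y - 1) * lrctv_daily$spacing_mm[2]
  pz <- lrctv_daily$origin_mm[3] + (ia$z - 1) * lrctv_daily$spacing_mm[3]
  A <- aff$matrix; tr <- aff$translation_mm
  qx <- A[1, 1] * px + A[1, 2] * py + A[1, 3] * pz + tr[1]
  qy <- A[2, 1] * px + A[2, 2] * py + A[2, 3] * pz + tr[2]
  qz <- A[3, 1] * px + A[3, 2] * py + A[3, 3] * pz + tr[3]
  xi <- (qx - lrctv_ref$origin_mm[1]) / lrctv_ref$spacing_mm[1] + 1
  yi <- (qy - lrctv_ref$origin_mm[2]) / lrctv_ref$spacing_mm[2] + 1
  zi <- (qz - lrctv_ref$origin_mm[3]) / lrctv_ref$spacing_mm[3] + 1
  m_init <- array(interp3(m_img, xi, yi, zi), dim = d)
  dvf <- run_stage("demons", demons_core(m_init, f_img,
                                         lrctv_daily$spacing_mm,
                                         lrctv_daily$origin_mm, settings))
  comp <- run_stage("compose", compose_transforms(aff, dvf))
  warped <- run_stage("warp", warp_mask(hrctv_ref, comp))
  run_stage("postprocess", intersect_masks(warped, lrctv_daily))
}
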