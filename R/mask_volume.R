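#' Binary mask volumes on a physical voxel grid
#'
#' `mask_volume()` is the universal currency of the package: a 3-D boolean
#' occupancy grid together with its physical voxel spacing and origin, in
#' millimetres. Array order is `(x, y, z)` with the first index fastest
#' (the native NIfTI layout); the anatomical convention used throughout is
#' +x = patient-left, +y = anterior, +z = superior.
#'
#' @param data a 3-D array; non-logical values are thresholded at > 0.5.
#' @param spacing_mm positive numeric triple, voxel size per axis in mm.
#' @param origin_mm numeric triple, physical position of the centre of voxel
#'   `(1, 1, 1)` in mm.
#' @return an object of class `mask_volume` with fields `data`, `spacing_mm`
#'   and `origin_mm`.
#' @examples
#' m <- mask_volume(array(FALSE, c(8, 8, 8)), spacing_mm = c(2, 2, 2))
#' volume_cc(m)
#' @export
mask_volume <- function(data, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) {
    potd_stop("mask data must be a 3-D array", "potd_shape_error")
  }
  if (!is.logical(data)) {
    data <- array(as.numeric(data) > 0.5, dim = dim(data))
  }
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    potd_stop("spacing_mm must be three positive finite values",
              "potd_argument_error")
  }
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm))) {
    potd_stop("origin_mm must be three finite values", "potd_argument_error")
  }
  structure(list(data = data, spacing_mm = spacing_mm, origin_mm = origin_mm),
            class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mask_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  cat(sprintf("  occupied: %d voxels (%.3f cc), origin (%.1f, %.1f, %.1f) mm\n",
              sum(x$data), volume_cc(x),
              x$origin_mm[1], x$origin_mm[2], x$origin_mm[3]))
  invisible(x)
}

is_mask_volume <- function(x) inherits(x, "mask_volume")

mask_grid <- function(mask) {
  list(shape = dim(mask$data), spacing_mm = mask$spacing_mm,
       origin_mm = mask$origin_mm)
}

#' Test whether two masks share a voxel grid
#'
#' Shapes must match exactly; spacing and origin are compared with a 1e-3 mm
#' tolerance to absorb NIfTI header float round-off.
#'
#' @param a,b `mask_volume` objects.
#' @param tol tolerance in mm for spacing/origin comparison.
#' @return logical scalar.
#' @export
same_grid <- function(a, b, tol = 1e-3) {
  all(dim(a$data) == dim(b$data)) &&
    all(abs(a$spacing_mm - b$spacing_mm) < tol) &&
    all(abs(a$origin_mm - b$origin_mm) < tol)
}

check_same_grid <- function(a, b, what = "masks") {
  if (!same_grid(a, b)) {
    potd_stop(paste(what, "are not on the same voxel grid"),
              "potd_geometry_error")
  }
  invisible(TRUE)
}

#' Occupied volume of a mask in cubic centimetres
#'
#' @param mask a `mask_volume`.
#' @return occupied-voxel count times voxel volume, converted mm^3 to cc.
#' @export
volume_cc <- function(mask) {
  sum(mask$data) * prod(mask$spacing_mm) / 1000
}

#' Centroid of a mask in physical coordinates
#'
#' @param mask a nonempty `mask_volume`.
#' @return numeric triple (x, y, z) in mm.
#' @export
mask_centroid <- function(mask) {
  idx <- which(mask$data, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    potd_stop("centroid of an empty mask is undefined", "potd_data_error")
  }
  mask$origin_mm + (colMeans(idx) - 1) * mask$spacing_mm
}

#' Voxelwise union and intersection of masks
#'
#' All masks must share one voxel grid (within header tolerance); a mismatch
#' raises a geometry error.
#'
#' @param masks a list of `mask_volume` objects on one grid.
#' @return a `mask_volume` on the shared grid.
#' @export
union_masks <- function(masks) {
  if (!is.list(masks) || length(masks) == 0L) {
    potd_stop("union_masks needs a nonempty list of masks", "potd_argument_error")
  }
  out <- masks[[1]]$data
  for (m in masks[-1]) {
    check_same_grid(masks[[1]], m)
    out <- out | m$data
  }
  mask_volume(out, masks[[1]]$spacing_mm, masks[[1]]$origin_mm)
}

#' @rdname union_masks
#' @param a,b `mask_volume` objects on one grid.
#' @export
intersect_masks <- function(a, b) {
  check_same_grid(a, b)
  mask_volume(a$data & b$data, a$spacing_mm, a$origin_mm)
}

#' Read and write binary masks as NIfTI-1 volumes
#'
#' `read_mask()` loads a 3-D NIfTI volume and thresholds intensities at
#' > 0.5 (tolerant of lossy writers); spacing is taken from `pixdim` and the
#' origin from the translation column of the stored xform. No orientation
#' reslicing is performed: all volumes of one case are assumed to live on a
#' single shared grid, which the rest of the package enforces.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return `read_mask()`: a `mask_volume`.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) {
    potd_stop(sprintf("cannot read mask: no such file '%s'", path),
              "potd_io_error")
  }
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) potd_stop(
                    sprintf("failed to read NIfTI '%s': %s", path, conditionMessage(e)),
                    "potd_io_error"))
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 4L && d[4] == 1L) {
    dim(arr) <- d[1:3]
    d <- d[1:3]
  }
  if (length(d) != 3L) {
    potd_stop(sprintf("'%s' is not a 3-D volume (dims: %s)", path,
                      paste(d, collapse = "x")), "potd_shape_error")
  }
  sp <- abs(RNifti::pixdim(img))[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  org <- if (inherits(xf, "try-error")) c(0, 0, 0) else as.numeric(xf[1:3, 4])
  mask_volume(arr, spacing_mm = sp, origin_mm = org)
}

#' @rdname read_mask
#' @param mask a `mask_volume` to serialise (written with 0/1 voxel values).
#' @return `write_mask()`: the path, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (!dir.exists(dirname(path))) {
    potd_stop(sprintf("cannot write mask: no such directory '%s'", dirname(path)),
              "potd_io_error")
  }
  arr <- array(as.integer(mask$data), dim = dim(mask$data))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- mask$spacing_mm
  m <- diag(c(mask$spacing_mm, 1))
  m[1:3, 4] <- mask$origin_mm
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::qform(img) <- structure(m, code = 2L)
  tryCatch(RNifti::writeNifti(img, path),
           error = function(e) potd_stop(
             sprintf("failed to write NIfTI '%s': %s", path, conditionMessage(e)),
             "potd_io_error"))
  invisible(path)
}
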