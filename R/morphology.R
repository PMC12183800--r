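# Physical-unit binary morphology: the CTV-to-PTV margin machinery.

ball_offsets <- function(margin_mm, spacing_mm) {
  r <- floor(margin_mm / spacing_mm + 1e-9)
  g <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  d2 <- (g$dx * spacing_mm[1])^2 + (g$dy * spacing_mm[2])^2 +
    (g$dz * spacing_mm[3])^2
  as.matrix(g[d2 <= margin_mm^2 + 1e-9, , drop = FALSE])
}

dilate_by_offsets <- function(mask, offsets) {
  out <- array(FALSE, dim = dim(mask$data))
  for (i in seq_len(nrow(offsets))) {
    out <- out | shift3(mask$data, as.integer(offsets[i, ]), fill = FALSE)
  }
  mask_volume(out, mask$spacing_mm, mask$origin_mm)
}

#' Uniform margin expansion of a mask
#'
#' Minkowski sum of the occupied set with a closed Euclidean ball of radius
#' `margin_mm` in physical units: a voxel is occupied in the result iff its
#' centre lies within `margin_mm` of some occupied voxel centre of the
#' input. Anisotropic spacing is honoured. This is the CTV/ITV-to-PTV
#' expansion used to build library plans (5 mm for sub-range PTVs, 7 mm for
#' the robust PTV).
#'
#' @param mask a `mask_volume`.
#' @param margin_mm nonnegative margin in mm; 0 returns the input unchanged.
#' @return a `mask_volume` containing the input (dilation is extensive).
#' @export
expand_margin <- function(mask, margin_mm) {
  if (!is.numeric(margin_mm) || length(margin_mm) != 1L ||
      !is.finite(margin_mm) || margin_mm < 0) {
    potd_stop("margin_mm must be a single nonnegative number",
              "potd_argument_error")
  }
  if (margin_mm == 0) return(mask)
  dilate_by_offsets(mask, ball_offsets(margin_mm, mask$spacing_mm))
}

#' Directional (line-segment) margin expansion
#'
#' Dilation with a line segment of length `margin_mm` along one grid axis,
#' in the positive direction, the negative direction, or both. Used for the
#' superior/inferior 10 mm expansion of the HR-CTV; the caller intersects
#' with a bounding structure (the LR-CTV) to keep the expansion inside it.
#'
#' @param mask a `mask_volume`.
#' @param margin_mm nonnegative length in mm.
#' @param axis one of `"x"`, `"y"`, `"z"` (+z is superior).
#' @param directions `"plus"`, `"minus"` or `"both"`.
#' @return a `mask_volume`.
#' @export
expand_directional <- function(mask, margin_mm, axis = c("z", "y", "x"),
                               directions = c("both", "plus", "minus")) {
  if (!is.numeric(margin_mm) || length(margin_mm) != 1L ||
      !is.finite(margin_mm) || margin_mm < 0) {
    potd_stop("margin_mm must be a single nonnegative number",
              "potd_argument_error")
  }
  if (!is.character(axis) || !(axis[1] %in% c("x", "y", "z"))) {
    potd_stop("axis must be one of 'x', 'y', 'z'", "potd_argument_error")
  }
  axis <- match.arg(axis)
  directions <- match.arg(directions)
  if (margin_mm == 0) return(mask)
  ai <- match(axis, c("x", "y", "z"))
  kmax <- floor(margin_mm / mask$spacing_mm[ai] + 1e-9)
  ks <- switch(directions,
               plus = 0:kmax,
               minus = -(0:kmax),
               both = -kmax:kmax)
  offsets <- matrix(0L, nrow = length(ks), ncol = 3L)
  offsets[, ai] <- as.integer(ks)
  dilate_by_offsets(mask, offsets)
}
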