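#' Parameters of the synthetic female-pelvis phantom
#'
#' The phantom emulates the anatomy that drives plan-of-the-day selection
#' in cervical cancer: a bladder whose volume tracks a filling fraction, a
#' uterocervix canal whose tilt (ante-/retro-version) varies continuously
#' with bladder filling, parametrial lateral extension forming the LR-CTV,
#' an HR-CTV confined to the cervix and lower canal, a posterior rectal
#' tube and a superior/anterior bowel-bag compartment. It produces masks
#' only -- no CT/CBCT intensities.
#'
#' Tilt-filling coupling is linear:
#' `tilt = uterus_tilt_deg + tilt_filling_coef_deg * bladder_filling`
#' (degrees from vertical, positive = anteverted), the simplest monotone
#' motion model that orders the library plans by filling. The `seed` draws
#' small per-patient jitters of position, tilt and organ shape, so distinct
#' seeds are distinct virtual patients; generation is fully deterministic
#' for a fixed seed.
#'
#' @param shape integer triple of grid dimensions (x, y, z).
#' @param spacing_mm voxel size in mm.
#' @param origin_mm grid origin in mm.
#' @param bladder_filling filling fraction in `[0, 1]`.
#' @param bladder_volume_range_cc bladder volume (cc) at filling 0 and 1.
#' @param uterus_tilt_deg canal tilt from vertical at empty bladder
#'   (degrees; positive tips the fundus anteriorly).
#' @param tilt_filling_coef_deg linear tilt change over the full filling
#'   range (degrees; negative = a filling bladder pushes the uterus
#'   upright).
#' @param uterus_length_mm,uterus_radius_mm canal length and mid-canal
#'   radius in mm (the canal tapers from 0.6 to 1.3 times the radius,
#'   cervix to fundus).
#' @param parametrium_margin_mm lateral extension of the uterocervix that
#'   forms the LR-CTV, in mm.
#' @param rectum_radius_mm rectal tube radius in mm.
#' @param hrctv_supinf_margin_mm superior/inferior expansion of the cervix
#'   segment forming the HR-CTV (kept inside the LR-CTV), in mm.
#' @param hrctv_canal_frac fraction of the canal (from the cervix) seeding
#'   the HR-CTV.
#' @param seed integer; per-patient jitter and determinism.
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(shape = c(96, 96, 96),
                           spacing_mm = c(2, 2, 2),
                           origin_mm = c(0, 0, 0),
                           bladder_filling = 0.5,
                           bladder_volume_range_cc = c(80, 400),
                           uterus_tilt_deg = 60,
                           tilt_filling_coef_deg = -45,
                           uterus_length_mm = 80,
                           uterus_radius_mm = 15,
                           parametrium_margin_mm = 12,
                           rectum_radius_mm = 12,
                           hrctv_supinf_margin_mm = 10,
                           hrctv_canal_frac = 0.35,
                           seed = 1L) {
  if (!is.numeric(bladder_filling) || length(bladder_filling) != 1L ||
      is.na(bladder_filling) || bladder_filling < 0 || bladder_filling > 1) {
    potd_stop("bladder_filling must lie in [0, 1]", "potd_argument_error")
  }
  dims <- c(uterus_length_mm, uterus_radius_mm, parametrium_margin_mm,
            rectum_radius_mm, bladder_volume_range_cc)
  if (any(!is.finite(dims)) || any(dims <= 0)) {
    potd_stop("all phantom dimensions must be positive", "potd_argument_error")
  }
  if (bladder_volume_range_cc[2] < bladder_volume_range_cc[1]) {
    potd_stop("bladder_volume_range_cc must be (min, max)", "potd_argument_error")
  }
  structure(list(shape = as.integer(shape), spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm),
                 bladder_filling = bladder_filling,
                 bladder_volume_range_cc = as.numeric(bladder_volume_range_cc),
                 uterus_tilt_deg = uterus_tilt_deg,
                 tilt_filling_coef_deg = tilt_filling_coef_deg,
                 uterus_length_mm = uterus_length_mm,
                 uterus_radius_mm = uterus_radius_mm,
                 parametrium_margin_mm = parametrium_margin_mm,
                 rectum_radius_mm = rectum_radius_mm,
                 hrctv_supinf_margin_mm = hrctv_supinf_margin_mm,
                 hrctv_canal_frac = hrctv_canal_frac,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

#' CTV-to-PTV margin specification for plan-library construction
#'
#' @param subrange_margin_mm uniform margin on each sub-range ITV (mm).
#' @param robust_margin_mm uniform margin on the union of all ITVs (mm).
#' @param hrctv_supinf_margin_mm superior/inferior HR-CTV expansion (mm).
#' @return an object of class `margin_spec`.
#' @export
margin_spec <- function(subrange_margin_mm = 5, robust_margin_mm = 7,
                        hrctv_supinf_margin_mm = 10) {
  m <- c(subrange_margin_mm, robust_margin_mm, hrctv_supinf_margin_mm)
  if (any(!is.finite(m)) || any(m < 0)) {
    potd_stop("all margins must be nonnegative", "potd_argument_error")
  }
  structure(list(subrange_margin_mm = subrange_margin_mm,
                 robust_margin_mm = robust_margin_mm,
                 hrctv_supinf_margin_mm = hrctv_supinf_margin_mm),
            class = "margin_spec")
}

# quadratic-in-arc-length bent canal: direction rotates linearly from
# vertical at the cervix to the tilt angle at the fundus (y-z plane)
canal_points <- function(p0, length_mm, tilt_rad, n = 40) {
  t <- seq(0, 1, length.out = n)
  dt <- length_mm / (n - 1)
  ang <- tilt_rad * t
  dy <- sin(ang) * dt
  dz <- cos(ang) * dt
  cbind(x = rep(p0[1], n),
        y = p0[2] + cumsum(dy) - dy[1],
        z = p0[3] + cumsum(dz) - dz[1])
}

# occupancy of a union of spheres, via separable squared-distance sums
spheres_mask <- function(shape, spacing, origin, centres, radii) {
  xs <- origin[1] + (seq_len(shape[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(shape[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(shape[3]) - 1) * spacing[3]
  out <- array(FALSE, dim = shape)
  for (i in seq_len(nrow(centres))) {
    r2 <- radii[i]^2
    ex <- (xs - centres[i, 1])^2
    ey <- (ys - centres[i, 2])^2
    ez <- (zs - centres[i, 3])^2
    # prune to the sphere's bounding box to keep the update local
    ix <- which(ex <= r2); iy <- which(ey <= r2); iz <- which(ez <= r2)
    if (!length(ix) || !length(iy) || !length(iz)) next
    d2 <- outer(outer(ex[ix], ey[iy], "+"), ez[iz], "+")
    out[ix, iy, iz] <- out[ix, iy, iz] | (d2 <= r2)
  }
  out
}

ellipsoid_mask <- function(shape, spacing, origin, centre, semi) {
  xs <- ((origin[1] + (seq_len(shape[1]) - 1) * spacing[1]) - centre[1]) / semi[1]
  ys <- ((origin[2] + (seq_len(shape[2]) - 1) * spacing[2]) - centre[2]) / semi[2]
  zs <- ((origin[3] + (seq_len(shape[3]) - 1) * spacing[3]) - centre[3]) / semi[3]
  outer(outer(xs^2, ys^2, "+"), zs^2, "+") <= 1
}

touches_boundary <- function(data) {
  d <- dim(data)
  any(data[1, , ]) || any(data[d[1], , ]) ||
    any(data[, 1, ]) || any(data[, d[2], ]) ||
    any(data[, , 1]) || any(data[, , d[3]])
}

#' Generate a synthetic pelvis structure set
#'
#' Deterministic for a fixed seed. Construction guarantees
#' `hr_ctv` within `lr_ctv` and pairwise disjointness of the LR-CTV,
#' bladder, rectum and bowel bag.
#'
#' @param params a `phantom_params` object.
#' @return a `structure_set` with all five roles present.
#' @export
generate_phantom <- function(params = phantom_params()) {
  if (!inherits(params, "phantom_params")) {
    potd_stop("params must be a phantom_params object", "potd_argument_error")
  }
  shp <- params$shape; sp <- params$spacing_mm; org <- params$origin_mm
  extent <- (shp - 1) * sp
  jit <- with_seed(params$seed, list(
    tilt = stats::runif(1, -5, 5),
    cx = stats::runif(1, -4, 4),
    cy = stats::runif(1, -4, 4),
    cz = stats::runif(1, -3, 3),
    bl_aspect = stats::runif(1, 0.95, 1.05),
    rect_y = stats::runif(1, -4, 4),
    len = stats::runif(1, 0.92, 1.08)
  ))
  centre_x <- org[1] + extent[1] / 2 + jit$cx
  p0 <- c(centre_x,
          org[2] + 0.46 * extent[2] + jit$cy,
          org[3] + 0.32 * extent[3] + jit$cz)
  tilt_deg <- params$uterus_tilt_deg + jit$tilt +
    params$tilt_filling_coef_deg * params$bladder_filling
  canal_len <- params$uterus_length_mm * jit$len
  pts <- canal_points(p0, canal_len, tilt_deg * pi / 180)
  t <- seq(0, 1, length.out = nrow(pts))
  radii <- params$uterus_radius_mm * (0.6 + 0.7 * t)

  uterocervix <- mask_volume(
    spheres_mask(shp, sp, org, pts, radii), sp, org)
  lr <- expand_directional(uterocervix, params$parametrium_margin_mm,
                           axis = "x", directions = "both")

  cervix_seg <- mask_volume(
    spheres_mask(shp, sp, org, pts[t <= params$hrctv_canal_frac, , drop = FALSE],
                 radii[t <= params$hrctv_canal_frac]), sp, org)
  hr <- intersect_masks(
    expand_directional(cervix_seg, params$hrctv_supinf_margin_mm,
                       axis = "z", directions = "both"), lr)

  vol_cc <- params$bladder_volume_range_cc[1] + params$bladder_filling *
    diff(params$bladder_volume_range_cc)
  aspect <- c(1.1 * jit$bl_aspect, 1.0, 0.9 / jit$bl_aspect)
  s <- (vol_cc * 1000 / (4 / 3 * pi * prod(aspect)))^(1 / 3)
  bladder_raw <- ellipsoid_mask(shp, sp, org,
                                centre = c(centre_x, p0[2] + 30, p0[3] - 6),
                                semi = aspect * s)
  bladder <- mask_volume(bladder_raw & !lr$data, sp, org)

  xs <- org[1] + (seq_len(shp[1]) - 1) * sp[1]
  ys <- org[2] + (seq_len(shp[2]) - 1) * sp[2]
  zs <- org[3] + (seq_len(shp[3]) - 1) * sp[3]
  yr <- p0[2] - 26 + jit$rect_y
  rect_xy <- outer((xs - centre_x)^2, (ys - yr)^2, "+") <=
    params$rectum_radius_mm^2
  rect_z <- zs >= p0[3] - 35 & zs <= p0[3] + 45
  rectum_raw <- outer(rect_xy, rect_z, "&")
  rectum <- mask_volume(rectum_raw & !lr$data & !bladder$data, sp, org)

  comp_xy <- outer(((xs - centre_x) / (0.38 * extent[1]))^2,
                   ((ys - (p0[2] + 10)) / (0.42 * extent[2]))^2, "+") <= 1
  comp_z <- zs >= p0[3] + 30 & zs <= org[3] + 0.92 * extent[3]
  compartment <- outer(comp_xy, comp_z, "&")
  occupied <- expand_margin(
    mask_volume(lr$data | bladder$data | rectum$data, sp, org), 2)
  bowel <- mask_volume(compartment & !occupied$data, sp, org)

  for (nm in c("lr_ctv", "hr_ctv", "bladder")) {
    m <- switch(nm, lr_ctv = lr, hr_ctv = hr, bladder = bladder)
    if (touches_boundary(m$data)) {
      potd_stop(sprintf("generated %s exceeds the phantom grid", nm),
                "potd_geometry_error")
    }
  }
  if (sum(hr$data) == 0L) {
    potd_stop("generated HR-CTV is empty", "potd_geometry_error")
  }
  structure_set(list(lr_ctv = lr, hr_ctv = hr, bladder = bladder,
                     rectum = rectum, bowel = bowel))
}

#' Generate structure sets over a series of bladder fillings
#'
#' All parameters except the filling fraction (including the per-patient
#' jitter seed) are held fixed, emulating the planning-image series from
#' which sub-range ITVs are built.
#'
#' @param params a `phantom_params` object.
#' @param fillings numeric vector of filling fractions in `[0, 1]`.
#' @return a list of `structure_set`s, one per filling.
#' @export
generate_filling_series <- function(params, fillings) {
  if (length(fillings) == 0L) {
    potd_stop("fillings must be a nonempty vector", "potd_argument_error")
  }
  lapply(fillings, function(f) {
    p <- params
    p$bladder_filling <- f
    generate_phantom(p)
  })
}

#' Build a PTV plan library from a filling series
#'
#' Each sub-range ITV is the union of the LR-CTV masks of its group of
#' series members; sub-range ITVs are uniformly expanded by
#' `subrange_margin_mm` to form PTV1..PTVn, and the union of all ITVs by
#' `robust_margin_mm` to form the robust PTV, appended last in library
#' order.
#'
#' @param series list of `structure_set`s (e.g. from
#'   [generate_filling_series()]).
#' @param subranges list of integer vectors partitioning
#'   `seq_along(series)`; default splits the series into three (or fewer)
#'   consecutive groups.
#' @param margins a `margin_spec`.
#' @return a `plan_library` with the robust plan flagged.
#' @export
build_plan_library <- function(series, subranges = NULL,
                               margins = margin_spec()) {
  if (!is.list(series) || length(series) == 0L) {
    potd_stop("series must be a nonempty list of structure sets",
              "potd_argument_error")
  }
  n <- length(series)
  if (is.null(subranges)) {
    k <- min(3L, n)
    subranges <- split(seq_len(n), cut(seq_len(n), k, labels = FALSE))
  }
  idx <- sort(unlist(subranges))
  if (!identical(as.integer(idx), seq_len(n))) {
    potd_stop("subranges must partition the series indices", "potd_argument_error")
  }
  itvs <- lapply(subranges, function(ix) {
    union_masks(lapply(series[ix], function(s) s$masks$lr_ctv))
  })
  ptvs <- lapply(itvs, expand_margin, margin_mm = margins$subrange_margin_mm)
  robust <- expand_margin(union_masks(itvs), margins$robust_margin_mm)
  plans <- c(ptvs, list(robust))
  names(plans) <- c(paste0("PTV", seq_along(itvs)), "PTV_Robust")
  lib <- plan_library(plans, robust_id = "PTV_Robust")
  attr(lib, "itvs") <- itvs
  lib
}
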