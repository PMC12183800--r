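# Contour-error simulation: smooth random displacement fields calibrated
# to a target Dice agreement with the unperturbed mask. Stands in for the
# segmentation error of an automatic contouring model.

# Smooth unit-RMS random displacement field on the mask's grid,
# deterministic per seed: low-pass-filtered Gaussian noise generated on a
# coarse lattice and linearly up-sampled. Near-incompressible in practice,
# so perturbed masks approximately keep their volume.
random_smooth_field <- function(mask, seed, coarse_factor = 8L,
                                noise_sigma_vox = 1.2) {
  d <- dim(mask$data)
  nc <- pmax(as.integer(ceiling(d / coarse_factor)) + 1L, 4L)
  comps <- with_seed(seed, lapply(1:3, function(k) {
    gauss_smooth3(array(stats::rnorm(prod(nc)), dim = nc), noise_sigma_vox)
  }))
  ia <- index_arrays(d)
  ci <- function(i, ax) pmin(pmax((i - 1) / coarse_factor + 1, 1), nc[ax])
  xi <- ci(ia$x, 1); yi <- ci(ia$y, 2); zi <- ci(ia$z, 3)
  vec <- array(0, dim = c(d, 3L))
  for (k in 1:3) vec[, , , k] <- array(interp3(comps[[k]], xi, yi, zi), dim = d)
  rms <- sqrt(mean(vec[, , , 1]^2 + vec[, , , 2]^2 + vec[, , , 3]^2))
  displacement_field(vec / rms, mask$spacing_mm, mask$origin_mm)
}

scale_field <- function(field, a) {
  displacement_field(field$vectors_mm * a, field$spacing_mm, field$origin_mm)
}

# Bisection on the field amplitude until dice(mask, warped) hits the
# target. Returns list(amplitude, mask, dsc).
calibrate_perturbation <- function(mask, target_dsc, field,
                                   tol = 0.015, max_iter = 30L) {
  bb <- which(mask$data, arr.ind = TRUE)
  ext <- (apply(bb, 2, max) - apply(bb, 2, min) + 1) * mask$spacing_mm
  lo <- 0
  hi <- 0.5 * sqrt(sum(ext^2))
  best <- list(amplitude = 0, mask = mask, dsc = 1)
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    w <- warp_mask(mask, scale_field(field, mid))
    dsc <- if (sum(w$data) + sum(mask$data) == 0L) 0 else dice(mask, w)
    if (abs(dsc - target_dsc) < abs(best$dsc - target_dsc)) {
      best <- list(amplitude = mid, mask = w, dsc = dsc)
    }
    if (abs(dsc - target_dsc) <= tol) break
    if (dsc > target_dsc) lo <- mid else hi <- mid
  }
  if (abs(best$dsc - target_dsc) > 0.03) {
    potd_stop(sprintf(
      "could not reach target DSC %.2f within +/-0.03 (best %.3f after %d bisections)",
      target_dsc, best$dsc, max_iter), "potd_convergence_error")
  }
  best
}

#' Perturb a mask to a target Dice agreement with itself
#'
#' Applies a smooth random displacement field whose amplitude is tuned by
#' bisection until `dice(original, perturbed)` is within 0.03 of
#' `target_dsc`. Deterministic per seed; `target_dsc = 1` returns the
#' input unchanged (the zero-amplitude limit).
#'
#' @param mask a nonempty `mask_volume`.
#' @param target_dsc target Dice coefficient in `(0, 1]`.
#' @param seed integer seed for the random field.
#' @return the perturbed `mask_volume`, with the achieved DSC and the
#'   field amplitude (mm RMS) attached as attributes `achieved_dsc` and
#'   `amplitude_mm`.
#' @export
perturb_mask <- function(mask, target_dsc, seed = 1L) {
  if (!is.numeric(target_dsc) || length(target_dsc) != 1L ||
      is.na(target_dsc) || target_dsc <= 0 || target_dsc > 1) {
    potd_stop("target_dsc must lie in (0, 1]", "potd_argument_error")
  }
  if (sum(mask$data) == 0L) {
    potd_stop("cannot perturb an empty mask", "potd_data_error")
  }
  if (target_dsc == 1) {
    attr(mask, "achieved_dsc") <- 1
    attr(mask, "amplitude_mm") <- 0
    return(mask)
  }
  field <- random_smooth_field(mask, seed)
  res <- calibrate_perturbation(mask, target_dsc, field)
  out <- res$mask
  attr(out, "achieved_dsc") <- res$dsc
  attr(out, "amplitude_mm") <- res$amplitude
  out
}

# Perturb all structures of a set with one shared field whose amplitude is
# calibrated on the LR-CTV (correlated contour error, as produced by a
# single segmentation model). Structures that would come out empty keep
# their original mask.
perturb_structures <- function(structures, target_dsc, seed = 1L) {
  if (target_dsc >= 1) return(structures)
  lr <- structures$masks$lr_ctv
  field <- random_smooth_field(lr, seed)
  res <- calibrate_perturbation(lr, target_dsc, field)
  sf <- scale_field(field, res$amplitude)
  masks <- lapply(structures$masks, function(m) {
    w <- warp_mask(m, sf)
    if (sum(w$data) == 0L) m else w
  })
  masks$lr_ctv <- res$mask
  structure_set(masks)
}
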