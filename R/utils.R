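# Internal numerical helpers shared across modules.

# Classed conditions so callers (and the CLI) can distinguish failure modes.
potd_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "potd_error")))
}

# Run code with a private RNG stream, restoring the caller's .Random.seed.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Trilinear interpolation of a 3-D array at continuous 1-based index
# coordinates. Samples outside the array evaluate to `outside`.
interp3 <- function(arr, xi, yi, zi, outside = 0) {
  d <- dim(arr)
  x0 <- floor(xi); y0 <- floor(yi); z0 <- floor(zi)
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  gather <- function(ix, iy, iz) {
    ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3]
    out <- rep.int(outside, length(ix))
    if (any(ok)) {
      idx <- ((iz[ok] - 1) * d[2] + (iy[ok] - 1)) * d[1] + ix[ok]
      out[ok] <- arr[idx]
    }
    out
  }
  v000 <- gather(x0,     y0,     z0)
  v100 <- gather(x0 + 1, y0,     z0)
  v010 <- gather(x0,     y0 + 1, z0)
  v110 <- gather(x0 + 1, y0 + 1, z0)
  v001 <- gather(x0,     y0,     z0 + 1)
  v101 <- gather(x0 + 1, y0,     z0 + 1)
  v011 <- gather(x0,     y0 + 1, z0 + 1)
  v111 <- gather(x0 + 1, y0 + 1, z0 + 1)
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

# Shift a 3-D numeric/logical array by an integer offset, filling with `fill`.
shift3 <- function(a, off, fill = 0) {
  d <- dim(a)
  out <- array(fill, dim = d)
  sx <- max(1L, 1L - off[1]):min(d[1], d[1] - off[1])
  sy <- max(1L, 1L - off[2]):min(d[2], d[2] - off[2])
  sz <- max(1L, 1L - off[3]):min(d[3], d[3] - off[3])
  if (length(sx) < 1 || length(sy) < 1 || length(sz) < 1 ||
      sx[1] > sx[length(sx)] || sy[1] > sy[length(sy)] || sz[1] > sz[length(sz)]) {
    return(out)
  }
  out[sx + off[1], sy + off[2], sz + off[3]] <- a[sx, sy, sz]
  out
}

# Separable Gaussian smoothing with per-axis sigma in voxel units.
# normalize = TRUE renormalises by the smoothed indicator so that border
# voxels are not attenuated (used when smoothing displacement fields).
gauss_smooth3 <- function(arr, sigma_vox, normalize = FALSE) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  d <- dim(arr)
  out <- arr
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (!is.finite(s) || s <= 0.05) next
    r <- max(1L, as.integer(ceiling(3 * s)))
    w <- stats::dnorm(-r:r, sd = s)
    w <- w / sum(w)
    acc <- array(0, dim = d)
    for (k in seq_along(w)) {
      off <- integer(3)
      off[ax] <- k - r - 1L
      acc <- acc + w[k] * shift3(out, off)
    }
    if (normalize) {
      n <- length(w)
      ones <- rep(1, d[ax])
      corr <- vapply(seq_len(d[ax]), function(i) {
        j <- (i - r):(i + r)
        sum(w[j >= 1 & j <= d[ax]])
      }, numeric(1))
      # broadcast the 1-D correction along the current axis
      if (ax == 1) acc <- acc / array(corr, dim = d)
      if (ax == 2) acc <- acc / array(rep(corr, each = d[1]), dim = d)
      if (ax == 3) acc <- acc / array(rep(corr, each = d[1] * d[2]), dim = d)
    }
    out <- acc
  }
  out
}

# Block-mean down-sampling by an integer factor (zero-padded to a multiple).
downsample_mean <- function(a, s) {
  s <- as.integer(s)
  if (s == 1L) return(a)
  d <- dim(a)
  nd <- as.integer(ceiling(d / s))
  if (!all(nd * s == d)) {
    p <- array(0, dim = nd * s)
    p[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- a
    a <- p
  }
  dim(a) <- c(s, nd[1], s, nd[2], s, nd[3])
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  dim(a) <- c(s^3, prod(nd))
  m <- colMeans(a)
  dim(m) <- nd
  m
}

# Central-difference gradient of a 3-D array, in intensity per mm.
gradient3 <- function(a, spacing) {
  gx <- (shift3(a, c(-1L, 0L, 0L)) - shift3(a, c(1L, 0L, 0L))) / (2 * spacing[1])
  gy <- (shift3(a, c(0L, -1L, 0L)) - shift3(a, c(0L, 1L, 0L))) / (2 * spacing[2])
  gz <- (shift3(a, c(0L, 0L, -1L)) - shift3(a, c(0L, 0L, 1L))) / (2 * spacing[3])
  list(x = gx, y = gy, z = gz)
}
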