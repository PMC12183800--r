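# Independent brute-force oracles. These deliberately share no code with
# the package internals they check.

# dilation by direct distance scan: voxel occupied iff its centre is
# within margin of some occupied input voxel centre
brute_dilate <- function(mask, margin_mm) {
  occ <- which(mask$data, arr.ind = TRUE)
  d <- dim(mask$data)
  sp <- mask$spacing_mm
  out <- array(FALSE, dim = d)
  for (ix in seq_len(d[1])) for (iy in seq_len(d[2])) for (iz in seq_len(d[3])) {
    dx <- (occ[, 1] - ix) * sp[1]
    dy <- (occ[, 2] - iy) * sp[2]
    dz <- (occ[, 3] - iz) * sp[3]
    if (any(dx^2 + dy^2 + dz^2 <= margin_mm^2 + 1e-9)) out[ix, iy, iz] <- TRUE
  }
  out
}

# per-voxel loop counting, no vectorised set operations
naive_coverage_pct <- function(structure, ptv) {
  d <- dim(structure$data)
  n_in <- 0L; n_tot <- 0L
  for (ix in seq_len(d[1])) for (iy in seq_len(d[2])) for (iz in seq_len(d[3])) {
    if (structure$data[ix, iy, iz]) {
      n_tot <- n_tot + 1L
      if (ptv$data[ix, iy, iz]) n_in <- n_in + 1L
    }
  }
  100 * n_in / n_tot
}

naive_dice <- function(a, b) {
  d <- dim(a$data)
  na <- 0L; nb <- 0L; nab <- 0L
  for (ix in seq_len(d[1])) for (iy in seq_len(d[2])) for (iz in seq_len(d[3])) {
    va <- a$data[ix, iy, iz]; vb <- b$data[ix, iy, iz]
    if (va) na <- na + 1L
    if (vb) nb <- nb + 1L
    if (va && vb) nab <- nab + 1L
  }
  2 * nab / (na + nb)
}

# independent rule-by-rule evaluator of the qSOP decision procedure
qsop_oracle <- function(table, cfg = qsop_config()) {
  n <- nrow(table)
  status <- rep("unacceptable", n)
  hr_ok <- table$hr_ctv_pct >= cfg$hr_required_pct
  opt_set <- which(table$lr_ctv_pct >= cfg$lr_optimal_pct & hr_ok)
  man_set <- which(table$lr_ctv_pct >= cfg$lr_mandatory_pct & hr_ok)
  cand <- if (length(opt_set) > 0) opt_set else man_set
  if (length(cand) == 0) {
    return(list(selected = NA_character_, status = status))
  }
  if (length(cand) == 1) {
    sel <- cand[1]
  } else {
    # reference: least bowel, earliest row on ties
    ref <- cand[1]
    for (j in cand) if (table$bowel_pct[j] < table$bowel_pct[ref]) ref <- j
    sel <- ref
    best_sp <- -Inf
    for (j in cand) {
      if (j == ref) next
      if (cfg$oar_diff_mode == "relative") {
        binc <- if (table$bowel_pct[ref] == 0) {
          table$bowel_pct[j]
        } else 100 * (table$bowel_pct[j] - table$bowel_pct[ref]) / table$bowel_pct[ref]
        sp <- if (table$bladder_pct[ref] == 0) {
          -table$bladder_pct[j]
        } else 100 * (table$bladder_pct[ref] - table$bladder_pct[j]) / table$bladder_pct[ref]
      } else {
        binc <- table$bowel_pct[j] - table$bowel_pct[ref]
        sp <- table$bladder_pct[ref] - table$bladder_pct[j]
      }
      if (binc > cfg$bowel_increase_cap_pct) next
      grants <- FALSE
      for (r in cfg$exception_ladder) {
        if (binc < r$max_bowel_increase_pct && sp >= r$min_bladder_sparing_pct) {
          grants <- TRUE
        }
      }
      if (grants && sp > best_sp) {
        sel <- j
        best_sp <- sp
      }
    }
  }
  status[cand] <- "acceptable"
  status[sel] <- "optimal"
  list(selected = table$plan_id[sel], status = status)
}

# deterministic sampler over the synthetic coverage-table grid
sample_coverage_tables <- function(n_tables, seed = 42) {
  lr_grid <- c(90, 94, 95, 96, 98, 99, 99.5, 100)
  hr_grid <- c(99, 99.7, 99.8, 100)
  diff_grid <- c(-50, -25, -10, 0, 8, 15, 25)
  set.seed(seed)
  lapply(seq_len(n_tables), function(i) {
    k <- sample(2:4, 1)
    as_coverage_table(data.frame(
      plan_id = paste0("P", seq_len(k)),
      lr_ctv_pct = sample(lr_grid, k, replace = TRUE),
      hr_ctv_pct = sample(hr_grid, k, replace = TRUE),
      bladder_pct = 40 * (1 + sample(diff_grid, k, replace = TRUE) / 100),
      bowel_pct = 10 * (1 + sample(diff_grid, k, replace = TRUE) / 100)))
  })
}

# fraction of voxels (inside a mask) whose finite-difference Jacobian
# determinant of x + d(x) is positive
jacobian_positive_fraction <- function(field, inside) {
  v <- field$vectors_mm
  sp <- field$spacing_mm
  d <- dim(v)[1:3]
  ctr <- function(a, ax) {
    up <- potdassess:::shift3(a, as.integer((1:3 == ax) * -1))
    dn <- potdassess:::shift3(a, as.integer((1:3 == ax) * 1))
    (up - dn) / (2 * sp[ax])
  }
  J11 <- 1 + ctr(v[, , , 1], 1); J12 <- ctr(v[, , , 1], 2); J13 <- ctr(v[, , , 1], 3)
  J21 <- ctr(v[, , , 2], 1); J22 <- 1 + ctr(v[, , , 2], 2); J23 <- ctr(v[, , , 2], 3)
  J31 <- ctr(v[, , , 3], 1); J32 <- ctr(v[, , , 3], 2); J33 <- 1 + ctr(v[, , , 3], 3)
  det <- J11 * (J22 * J33 - J23 * J32) - J12 * (J21 * J33 - J23 * J31) +
    J13 * (J21 * J32 - J22 * J31)
  # exclude the one-voxel border where central differences are one-sided
  core <- array(FALSE, dim = d)
  core[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- TRUE
  sel <- inside & core
  mean(det[sel] > 0)
}
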