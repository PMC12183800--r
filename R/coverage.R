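#' Percent coverage of a structure by a PTV
#'
#' The fraction of the structure's voxels lying inside the PTV, times 100.
#' Voxel-centre containment on binary masks; no partial-volume weighting
#' and no dose model (the PTV is used as the surrogate for the high-dose
#' region).
#'
#' @param structure a nonempty `mask_volume`.
#' @param ptv a `mask_volume` on the same grid.
#' @return percent in `[0, 100]`.
#' @export
percent_coverage <- function(structure, ptv) {
  check_same_grid(structure, ptv, "structure and PTV")
  n <- sum(structure$data)
  if (n == 0L) {
    potd_stop("coverage of an empty structure is undefined", "potd_data_error")
  }
  100 * sum(structure$data & ptv$data) / n
}

#' Dice similarity coefficient between two masks
#'
#' `2|A n B| / (|A| + |B|)` by voxel count; symmetric, 1 iff the voxel sets
#' are equal, 0 for disjoint masks.
#'
#' @param a,b `mask_volume` objects on one grid, not both empty.
#' @return DSC in `[0, 1]`.
#' @export
dice <- function(a, b) {
  check_same_grid(a, b)
  na <- sum(a$data); nb <- sum(b$data)
  if (na + nb == 0L) {
    potd_stop("DSC of two empty masks is undefined", "potd_data_error")
  }
  2 * sum(a$data & b$data) / (na + nb)
}

#' Coverage table: every structure against every library plan
#'
#' One row per plan, in library order, with the percent coverage of each
#' present structure by that plan's PTV. Absent OARs yield `NA` columns,
#' never zeros. Structure volumes (cc) are attached as the
#' `structure_volumes_cc` attribute.
#'
#' @param structures a `structure_set` with `lr_ctv` and `hr_ctv` present.
#' @param library a `plan_library` on the same grid.
#' @return a data frame of class `coverage_table` with columns `plan_id`,
#'   `lr_ctv_pct`, `hr_ctv_pct`, `bladder_pct`, `rectum_pct`, `bowel_pct`.
#' @export
coverage_table <- function(structures, library) {
  if (!inherits(structures, "structure_set")) {
    potd_stop("structures must be a structure_set", "potd_argument_error")
  }
  if (!inherits(library, "plan_library")) {
    potd_stop("library must be a plan_library", "potd_argument_error")
  }
  if (is.null(structures$masks$lr_ctv) || is.null(structures$masks$hr_ctv)) {
    potd_stop("plan assessment requires both lr_ctv and hr_ctv structures",
              "potd_data_error")
  }
  roles <- c("lr_ctv", "hr_ctv", "bladder", "rectum", "bowel")
  rows <- lapply(names(library$plans), function(pid) {
    ptv <- library$plans[[pid]]
    vals <- vapply(roles, function(r) {
      s <- structures$masks[[r]]
      if (is.null(s)) NA_real_ else percent_coverage(s, ptv)
    }, numeric(1))
    c(vals)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab) <- paste0(roles, "_pct")
  tab <- cbind(plan_id = names(library$plans), tab)
  rownames(tab) <- NULL
  vols <- vapply(roles, function(r) {
    s <- structures$masks[[r]]
    if (is.null(s)) NA_real_ else volume_cc(s)
  }, numeric(1))
  attr(tab, "structure_volumes_cc") <- vols
  attr(tab, "robust_id") <- library$robust_id
  class(tab) <- c("coverage_table", "data.frame")
  tab
}

#' Build a coverage table directly from percentages
#'
#' Used when coverage statistics come from elsewhere (e.g. values printed in
#' a clinical report) rather than from masks: validates ranges and stamps
#' the `coverage_table` class so the qSOP engine accepts it.
#'
#' @param df data frame with a `plan_id` column and any of the percentage
#'   columns `lr_ctv_pct`, `hr_ctv_pct`, `bladder_pct`, `rectum_pct`,
#'   `bowel_pct`; missing columns are filled with `NA`.
#' @param structure_volumes_cc optional named numeric vector of structure
#'   volumes in cc.
#' @return a `coverage_table`.
#' @export
as_coverage_table <- function(df, structure_volumes_cc = NULL) {
  if (!is.data.frame(df) || nrow(df) == 0L || is.null(df$plan_id)) {
    potd_stop("df must be a nonempty data frame with a plan_id column",
              "potd_data_error")
  }
  if (anyDuplicated(df$plan_id)) {
    potd_stop("plan_id values must be unique", "potd_data_error")
  }
  roles <- c("lr_ctv", "hr_ctv", "bladder", "rectum", "bowel")
  cols <- paste0(roles, "_pct")
  out <- data.frame(plan_id = as.character(df$plan_id),
                    stringsAsFactors = FALSE)
  for (cl in cols) {
    v <- if (cl %in% names(df)) as.numeric(df[[cl]]) else rep(NA_real_, nrow(df))
    if (any(!is.na(v) & (v < 0 | v > 100))) {
      potd_stop(sprintf("%s outside [0, 100]", cl), "potd_data_error")
    }
    out[[cl]] <- v
  }
  attr(out, "structure_volumes_cc") <- structure_volumes_cc
  attr(out, "robust_id") <- NA_character_
  class(out) <- c("coverage_table", "data.frame")
  out
}

#' Bowel and bladder coverage differences against a reference plan
#'
#' For each plan, the difference in covered organ volume relative to the
#' reference plan (by default as a percent of the reference's covered
#' volume, the normalisation displayed in the assessment report; set
#' `mode = "percentage_points"` for absolute percentage-point differences
#' of organ coverage). The reference plan itself maps to 0. A reference
#' with zero covered volume against a nonzero comparator yields `Inf` with
#' a warning.
#'
#' @param table a `coverage_table` with bowel and bladder columns.
#' @param reference_plan plan id of the normalisation reference.
#' @param mode `"relative"` (default) or `"percentage_points"`.
#' @return data frame with columns `plan_id`, `bowel_diff_pct`,
#'   `bladder_diff_pct`.
#' @export
oar_differences <- function(table, reference_plan,
                            mode = c("relative", "percentage_points")) {
  mode <- match.arg(mode)
  if (!(reference_plan %in% table$plan_id)) {
    potd_stop(sprintf("reference plan '%s' is not in the table", reference_plan),
              "potd_data_error")
  }
  ref <- table[table$plan_id == reference_plan, ]
  one <- function(pct, ref_pct, organ) {
    if (is.na(pct) || is.na(ref_pct)) return(NA_real_)
    if (mode == "percentage_points") return(pct - ref_pct)
    if (ref_pct == 0) {
      if (pct == 0) return(0)
      warning(sprintf("reference plan covers no %s; relative difference is infinite",
                      organ), call. = FALSE)
      return(Inf)
    }
    100 * (pct - ref_pct) / ref_pct
  }
  data.frame(
    plan_id = table$plan_id,
    bowel_diff_pct = vapply(table$bowel_pct, one, numeric(1),
                            ref_pct = ref$bowel_pct, organ = "bowel"),
    bladder_diff_pct = vapply(table$bladder_pct, one, numeric(1),
                              ref_pct = ref$bladder_pct, organ = "bladder"),
    stringsAsFactors = FALSE
  )
}
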