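#' Structure sets and plan libraries
#'
#' A `structure_set` bundles the five anatomy roles used in POTD
#' assessment -- `lr_ctv`, `hr_ctv`, `bladder`, `rectum`, `bowel` -- as
#' binary masks on one shared voxel grid. OARs may be absent; the low-risk
#' and high-risk CTVs must be present whenever plan assessment is requested.
#'
#' @param masks named list of `mask_volume` objects; names must be drawn
#'   from the five roles above.
#' @return an object of class `structure_set`.
#' @export
structure_set <- function(masks) {
  roles <- c("lr_ctv", "hr_ctv", "bladder", "rectum", "bowel")
  if (!is.list(masks) || is.null(names(masks)) ||
      !all(names(masks) %in% roles) || anyDuplicated(names(masks))) {
    potd_stop("masks must be a uniquely named list with names among: lr_ctv, hr_ctv, bladder, rectum, bowel",
              "potd_argument_error")
  }
  for (m in masks) {
    if (!is_mask_volume(m)) {
      potd_stop("every structure must be a mask_volume", "potd_argument_error")
    }
  }
  for (m in masks[-1]) check_same_grid(masks[[1]], m, "structure masks")
  structure(list(masks = masks), class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat("<structure_set>\n")
  for (nm in names(x$masks)) {
    cat(sprintf("  %-8s %8.2f cc\n", nm, volume_cc(x$masks[[nm]])))
  }
  invisible(x)
}

#' Ordered library of PTV plans
#'
#' Plan order is meaningful: it is the deterministic tie-break order of the
#' qSOP (sub-range plans first, the robust plan last among equals).
#'
#' @param plans named list of PTV `mask_volume`s, in library order.
#' @param robust_id the plan id flagged as the robust (largest-margin) plan,
#'   or `NA` if the library has none.
#' @return an object of class `plan_library`.
#' @export
plan_library <- function(plans, robust_id = NA_character_) {
  if (!is.list(plans) || length(plans) == 0L || is.null(names(plans)) ||
      any(names(plans) == "") || anyDuplicated(names(plans))) {
    potd_stop("plans must be a nonempty list with unique nonempty names",
              "potd_argument_error")
  }
  for (m in plans) {
    if (!is_mask_volume(m)) {
      potd_stop("every plan must be a mask_volume", "potd_argument_error")
    }
  }
  for (m in plans[-1]) check_same_grid(plans[[1]], m, "plan masks")
  if (!is.na(robust_id) && !(robust_id %in% names(plans))) {
    potd_stop("robust_id is not a plan in the library", "potd_argument_error")
  }
  structure(list(plans = plans, robust_id = robust_id), class = "plan_library")
}

#' @export
print.plan_library <- function(x, ...) {
  cat(sprintf("<plan_library> %d plans%s\n", length(x$plans),
              if (is.na(x$robust_id)) "" else sprintf(" (robust: %s)", x$robust_id)))
  for (nm in names(x$plans)) {
    cat(sprintf("  %-12s %8.2f cc\n", nm, volume_cc(x$plans[[nm]])))
  }
  invisible(x)
}

read_manifest_file <- function(path) {
  if (!file.exists(path)) {
    potd_stop(sprintf("manifest not found: '%s'", path), "potd_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    potd_stop(sprintf("unsupported manifest format '.%s' (use YAML or JSON)", ext),
              "potd_io_error")
  }
}

resolve_path <- function(p, base) {
  if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
}

#' Load a structure set from a manifest file
#'
#' The manifest (YAML or JSON) maps structure roles to NIfTI mask paths,
#' either at the top level or under a `structures` key. Relative paths are
#' resolved against the manifest's directory.
#'
#' @param path manifest path.
#' @return a `structure_set`.
#' @export
read_structure_manifest <- function(path) {
  mf <- read_manifest_file(path)
  if (!is.null(mf$structures)) mf <- mf$structures
  if (length(mf) == 0L || is.null(names(mf))) {
    potd_stop("structure manifest must map roles to file paths",
              "potd_data_error")
  }
  base <- dirname(normalizePath(path))
  masks <- lapply(mf, function(p) read_mask(resolve_path(as.character(p), base)))
  structure_set(masks)
}

#' Load a plan library from a manifest file
#'
#' The manifest lists plans in library order, each with an `id`, a `path`
#' and an optional logical `robust` flag (at most one plan may carry it).
#'
#' @param path manifest path.
#' @return a `plan_library`.
#' @export
read_plan_manifest <- function(path) {
  mf <- read_manifest_file(path)
  if (!is.null(mf$plans)) mf <- mf$plans
  if (length(mf) == 0L) {
    potd_stop("plan manifest lists no plans", "potd_data_error")
  }
  base <- dirname(normalizePath(path))
  ids <- vapply(mf, function(e) as.character(e$id), character(1))
  robust <- vapply(mf, function(e) isTRUE(e$robust), logical(1))
  if (sum(robust) > 1L) {
    potd_stop("plan manifest flags more than one robust plan", "potd_data_error")
  }
  plans <- lapply(mf, function(e) read_mask(resolve_path(as.character(e$path), base)))
  names(plans) <- ids
  plan_library(plans, robust_id = if (any(robust)) ids[robust] else NA_character_)
}
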