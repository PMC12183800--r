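# Assessment report rendering and end-to-end orchestration.

fmt_pct <- function(x) ifelse(is.na(x), "    --", sprintf("%6.2f", x))

fmt_diff <- function(x) {
  ifelse(is.na(x), "     --",
         ifelse(is.infinite(x), "   +Inf", sprintf("%+7.2f", x)))
}

report_as_list <- function(assessment, table, diffs) {
  ids <- table$plan_id
  if (!identical(ids, assessment$plans$plan_id) ||
      (!is.null(diffs) && !identical(ids, diffs$plan_id))) {
    potd_stop("assessment, coverage table and OAR differences disagree on plan ids",
              "potd_data_error")
  }
  num_or_null <- function(x) {
    if (is.na(x)) return(NULL)
    if (is.infinite(x)) return(if (x > 0) "+Inf" else "-Inf")
    as.numeric(x)
  }
  plans <- lapply(seq_along(ids), function(i) {
    p <- list(plan_id = ids[i],
              lr_ctv_pct = num_or_null(table$lr_ctv_pct[i]),
              hr_ctv_pct = num_or_null(table$hr_ctv_pct[i]),
              bladder_pct = num_or_null(table$bladder_pct[i]),
              rectum_pct = num_or_null(table$rectum_pct[i]),
              bowel_pct = num_or_null(table$bowel_pct[i]))
    if (!is.null(diffs)) {
      p$bowel_diff_pct <- num_or_null(diffs$bowel_diff_pct[i])
      p$bladder_diff_pct <- num_or_null(diffs$bladder_diff_pct[i])
    }
    p$status <- assessment$plans$status[i]
    p$optimal <- identical(ids[i], assessment$selected)
    p[!vapply(p, is.null, logical(1))]
  })
  list(plans = plans,
       selected = if (is.na(assessment$selected)) NULL else assessment$selected,
       tier = assessment$tier,
       intervention_required = assessment$intervention_required,
       rationale = as.list(assessment$rationale))
}

#' Render a plan-assessment report
#'
#' Text output marks each plan acceptable/unacceptable and highlights the
#' optimal one (or prints a no-acceptable-plan banner); JSON is a lossless
#' machine-readable serialisation (full precision; `+Inf` sentinels as
#' strings); CSV is the flat per-plan table. All formats are
#' deterministic.
#'
#' @param assessment a `plan_assessment`.
#' @param table the `coverage_table` it was derived from.
#' @param diffs optional OAR differences from [oar_differences()].
#' @param format `"text"`, `"json"` or `"csv"`.
#' @return a single character string.
#' @export
render_report <- function(assessment, table, diffs = NULL,
                          format = c("text", "json", "csv")) {
  format <- match.arg(format)
  rep <- report_as_list(assessment, table, diffs)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA,
                                         pretty = TRUE, null = "null")))
  }
  if (format == "csv") {
    df <- data.frame(plan_id = table$plan_id,
                     lr_ctv_pct = table$lr_ctv_pct,
                     hr_ctv_pct = table$hr_ctv_pct,
                     bladder_pct = table$bladder_pct,
                     rectum_pct = table$rectum_pct,
                     bowel_pct = table$bowel_pct,
                     stringsAsFactors = FALSE)
    if (!is.null(diffs)) {
      df$bowel_diff_pct <- diffs$bowel_diff_pct
      df$bladder_diff_pct <- diffs$bladder_diff_pct
    }
    df$status <- assessment$plans$status
    df$optimal <- table$plan_id == ifelse(is.na(assessment$selected), "",
                                          assessment$selected)
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    return(paste0(paste(out, collapse = "\n"), "\n"))
  }
  lines <- c("POTD plan assessment", "====================",
             sprintf("%-12s %7s %7s %8s %7s %7s %8s %9s  %s",
                     "plan", "LR-CTV%", "HR-CTV%", "bladder%", "rectum%",
                     "bowel%", "dBowel%", "dBladder%", "status"))
  for (i in seq_len(nrow(table))) {
    mark <- if (identical(table$plan_id[i], assessment$selected)) " <== OPTIMAL" else ""
    db <- if (is.null(diffs)) NA_real_ else diffs$bowel_diff_pct[i]
    dl <- if (is.null(diffs)) NA_real_ else diffs$bladder_diff_pct[i]
    lines <- c(lines, sprintf(
      "%-12s %7s %7s %8s %7s %7s %8s %9s  [%s]%s",
      table$plan_id[i],
      fmt_pct(table$lr_ctv_pct[i]), fmt_pct(table$hr_ctv_pct[i]),
      fmt_pct(table$bladder_pct[i]), fmt_pct(table$rectum_pct[i]),
      fmt_pct(table$bowel_pct[i]), fmt_diff(db), fmt_diff(dl),
      toupper(assessment$plans$status[i]), mark))
  }
  if (assessment$intervention_required) {
    lines <- c(lines, "",
               "*** NO ACCEPTABLE PLAN IN THE LIBRARY: INTERVENTION REQUIRED ***")
  }
  lines <- c(lines, "", "rationale:",
             paste0("  ", assessment$rationale))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Full plan-of-the-day assessment from manifest files
#'
#' Loads the daily structure set and the plan library, optionally
#' propagates the HR-CTV from reference masks via deformable
#' registration, computes the coverage table, runs the qSOP, and
#' normalises the bowel/bladder differences to the acceptable plan with
#' the least bowel coverage. Each stage is logged with its elapsed time
#' via `message()`.
#'
#' @param structure_manifest path to the structure-set manifest.
#' @param plan_manifest path to the plan-library manifest.
#' @param config optional path to a qSOP YAML configuration (package
#'   defaults otherwise).
#' @param hrctv_mode `"provided"` (the daily HR-CTV mask is in the
#'   manifest) or `"propagate"` (derive it from reference masks).
#' @param reference_lr_ctv,reference_hr_ctv NIfTI paths of the reference
#'   masks, required when `hrctv_mode = "propagate"`.
#' @param settings `demons_settings` used for propagation.
#' @return an object of class `assessment_report`: list with `table`,
#'   `assessment`, `diffs`, `diff_reference`, `provenance` and `timings`.
#' @export
run_assessment <- function(structure_manifest, plan_manifest, config = NULL,
                           hrctv_mode = c("provided", "propagate"),
                           reference_lr_ctv = NULL, reference_hr_ctv = NULL,
                           settings = demons_settings()) {
  hrctv_mode <- match.arg(hrctv_mode)
  timings <- c()
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    dt <- proc.time()[["elapsed"]] - t0
    timings[[stage]] <<- dt
    message(sprintf("[%s] %.2f s", stage, dt))
    out
  }
  cfg <- if (is.null(config)) qsop_config() else read_qsop_config(config)
  structures <- timed("load_structures", read_structure_manifest(structure_manifest))
  library <- timed("load_plans", read_plan_manifest(plan_manifest))
  if (hrctv_mode == "provided") {
    if (is.null(structures$masks$hr_ctv)) {
      potd_stop("hrctv_mode = 'provided' but the manifest has no hr_ctv mask",
                "potd_data_error")
    }
  } else {
    if (is.null(reference_lr_ctv) || is.null(reference_hr_ctv)) {
      potd_stop("hrctv_mode = 'propagate' requires reference LR-CTV and HR-CTV masks",
                "potd_data_error")
    }
    if (is.null(structures$masks$lr_ctv)) {
      potd_stop("propagation requires the daily LR-CTV", "potd_data_error")
    }
    ref_lr <- read_mask(reference_lr_ctv)
    ref_hr <- read_mask(reference_hr_ctv)
    hr <- timed("propagate_hrctv",
                propagate_hrctv(ref_hr, ref_lr, structures$masks$lr_ctv, settings))
    masks <- structures$masks
    masks$hr_ctv <- hr
    structures <- structure_set(masks)
  }
  table <- timed("coverage", coverage_table(structures, library))
  assessment <- timed("assess", assess(table, cfg))
  acc <- table$plan_id[assessment$plans$status %in% c("optimal", "acceptable")]
  pool <- if (length(acc) > 0L) acc else table$plan_id
  diffs <- NULL
  ref_id <- NA_character_
  if (!all(is.na(table$bowel_pct))) {
    sub <- table[match(pool, table$plan_id), ]
    ref_id <- sub$plan_id[which.min(sub$bowel_pct)]
    diffs <- timed("oar_differences",
                   oar_differences(table, ref_id, mode = cfg$oar_diff_mode))
  }
  prov <- list(
    structure_manifest = normalizePath(structure_manifest),
    plan_manifest = normalizePath(plan_manifest),
    config = if (is.null(config)) "defaults" else normalizePath(config),
    config_md5 = if (is.null(config)) NA_character_
                 else unname(tools::md5sum(config)),
    package_version = as.character(utils::packageVersion("potdassess")))
  structure(list(table = table, assessment = assessment, diffs = diffs,
                 diff_reference = ref_id, provenance = prov,
                 timings = timings),
            class = "assessment_report")
}

#' @export
print.assessment_report <- function(x, ...) {
  cat(render_report(x$assessment, x$table, x$diffs, format = "text"))
  invisible(x)
}

#' Virtual audit of qSOP selection accuracy under contour error
#'
#' Emulates an offline plan-selection audit at desk scale: for each case a
#' virtual patient is generated, a plan library is built from a
#' bladder-filling series of its anatomy, and the ground-truth assessment
#' is computed from the clean daily masks. The daily structures are then
#' perturbed to a target Dice level (a stand-in for segmentation error)
#' and re-assessed; agreement of the perturbed selections with the
#' ground-truth optimal/acceptable sets is reported. Cases whose clean
#' assessment finds no acceptable plan are scored as a distinct
#' no-plan outcome, so `error_dsc = 1` always yields perfect agreement.
#'
#' @param n_cases number of virtual cases (>= 1).
#' @param error_dsc contour-error level as the target Dice of perturbed vs
#'   clean masks, in `(0, 1]`.
#' @param seed master seed; case seeds and daily fillings derive from it.
#' @param params template `phantom_params`; the default uses a 64^3 grid
#'   at 3 mm to keep a many-case audit affordable.
#' @param fillings planning-series filling fractions.
#' @return list with `agreement` (from [audit_agreement()]), `selections`,
#'   `truth_optimal`, `truth_acceptable` and `case_seeds`.
#' @export
run_virtual_audit <- function(n_cases, error_dsc, seed = 1L,
                              params = phantom_params(shape = c(64, 64, 64),
                                                      spacing_mm = c(3, 3, 3)),
                              fillings = c(0.15, 0.5, 0.85)) {
  if (n_cases < 1) {
    potd_stop("n_cases must be >= 1", "potd_argument_error")
  }
  draws <- with_seed(seed, list(
    case_seeds = sample.int(2^30, n_cases),
    daily = stats::runif(n_cases)))
  selections <- character(n_cases)
  truth_opt <- vector("list", n_cases)
  truth_acc <- vector("list", n_cases)
  token <- function(sel) if (is.na(sel)) "<none>" else sel
  for (i in seq_len(n_cases)) {
    p <- params
    p$seed <- draws$case_seeds[i]
    series <- generate_filling_series(p, fillings)
    lib <- build_plan_library(series)
    p$bladder_filling <- draws$daily[i]
    daily <- generate_phantom(p)
    clean <- assess(coverage_table(daily, lib))
    truth_opt[[i]] <- token(clean$selected)
    acc <- clean$plans$plan_id[clean$plans$status %in% c("optimal", "acceptable")]
    truth_acc[[i]] <- if (length(acc) > 0L) acc else "<none>"
    observed <- if (error_dsc >= 1) daily else
      perturb_structures(daily, error_dsc, seed = draws$case_seeds[i] + 1L)
    noisy <- assess(coverage_table(observed, lib))
    selections[i] <- token(noisy$selected)
  }
  list(agreement = audit_agreement(selections, truth_opt, truth_acc),
       selections = selections, truth_optimal = truth_opt,
       truth_acceptable = truth_acc, case_seeds = draws$case_seeds)
}
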