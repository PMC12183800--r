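#' qSOP threshold configuration
#'
#' The quantitative standard operating procedure classifies library plans
#' from their coverage statistics. Defaults encode the clinically derived
#' decision rule: plans covering at least 99% of the LR-CTV and 99.8% of
#' the HR-CTV meet the optimal coverage criteria; if no plan does, 95%
#' LR-CTV coverage (with the same HR-CTV requirement) is mandatory for
#' candidacy. Among candidates the plan with least bowel coverage is
#' optimal unless a challenger buys substantial bladder sparing at a small
#' bowel cost: each exception-ladder rung grants a challenger whose bowel
#' increase is strictly below `max_bowel_increase_pct` provided its bladder
#' sparing is at least `min_bladder_sparing_pct`, and no exception may
#' exceed the overall bowel increase cap (20%). The two default rungs
#' anchor the published exception (>= 20% bladder sparing buys < 10% bowel
#' increase) and the cap; intermediate rungs are a configurable
#' placeholder -- adjust them to institutional policy.
#'
#' @param lr_optimal_pct LR-CTV coverage for the optimal tier (percent).
#' @param hr_required_pct HR-CTV coverage required in both tiers (percent).
#' @param lr_mandatory_pct LR-CTV coverage for the mandatory tier (percent).
#' @param exception_ladder list of rungs, each a list with
#'   `min_bladder_sparing_pct` and `max_bowel_increase_pct`, sorted by
#'   ascending bowel allowance.
#' @param bowel_increase_cap_pct hard cap on the bowel increase any
#'   exception may grant (percent).
#' @param oar_diff_mode how OAR differences are measured: `"relative"`
#'   (percent of the reference plan's covered volume) or
#'   `"percentage_points"` (points of organ coverage).
#' @param tie_break only `"library_order"` is supported.
#' @return an object of class `qsop_config`.
#' @export
qsop_config <- function(lr_optimal_pct = 99,
                        hr_required_pct = 99.8,
                        lr_mandatory_pct = 95,
                        exception_ladder = list(
                          list(min_bladder_sparing_pct = 20, max_bowel_increase_pct = 10),
                          list(min_bladder_sparing_pct = 40, max_bowel_increase_pct = 20)),
                        bowel_increase_cap_pct = 20,
                        oar_diff_mode = c("relative", "percentage_points"),
                        tie_break = "library_order") {
  oar_diff_mode <- match.arg(oar_diff_mode)
  if (!identical(tie_break, "library_order")) {
    potd_stop("only tie_break = 'library_order' is supported", "potd_argument_error")
  }
  if (!(lr_mandatory_pct >= 0 && lr_mandatory_pct <= lr_optimal_pct &&
        lr_optimal_pct <= 100)) {
    potd_stop("need 0 <= lr_mandatory_pct <= lr_optimal_pct <= 100",
              "potd_argument_error")
  }
  if (!(hr_required_pct >= 0 && hr_required_pct <= 100)) {
    potd_stop("hr_required_pct must lie in [0, 100]", "potd_argument_error")
  }
  lad <- lapply(exception_ladder, function(e) {
    if (is.null(e$min_bladder_sparing_pct) || is.null(e$max_bowel_increase_pct)) {
      potd_stop("each ladder rung needs min_bladder_sparing_pct and max_bowel_increase_pct",
                "potd_argument_error")
    }
    list(min_bladder_sparing_pct = as.numeric(e$min_bladder_sparing_pct),
         max_bowel_increase_pct = as.numeric(e$max_bowel_increase_pct))
  })
  if (length(lad) > 1L) {
    inc <- vapply(lad, `[[`, numeric(1), "max_bowel_increase_pct")
    if (is.unsorted(inc)) {
      potd_stop("exception_ladder must be sorted by ascending max_bowel_increase_pct",
                "potd_argument_error")
    }
  }
  for (e in lad) {
    if (e$max_bowel_increase_pct > bowel_increase_cap_pct) {
      potd_stop("a ladder rung exceeds bowel_increase_cap_pct", "potd_argument_error")
    }
  }
  structure(list(lr_optimal_pct = lr_optimal_pct,
                 hr_required_pct = hr_required_pct,
                 lr_mandatory_pct = lr_mandatory_pct,
                 exception_ladder = lad,
                 bowel_increase_cap_pct = bowel_increase_cap_pct,
                 oar_diff_mode = oar_diff_mode,
                 tie_break = tie_break),
            class = "qsop_config")
}

#' Read a qSOP configuration from YAML
#'
#' Unknown keys are rejected; omitted keys take the package defaults.
#'
#' @param path YAML file path.
#' @return a `qsop_config`.
#' @export
read_qsop_config <- function(path) {
  if (!file.exists(path)) {
    potd_stop(sprintf("qSOP config not found: '%s'", path), "potd_io_error")
  }
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  known <- names(formals(qsop_config))
  bad <- setdiff(names(y), known)
  if (length(bad) > 0L) {
    potd_stop(sprintf("unknown qSOP config keys: %s", paste(bad, collapse = ", ")),
              "potd_data_error")
  }
  do.call(qsop_config, y)
}

need_targets <- function(table) {
  if (is.null(table$lr_ctv_pct) || is.null(table$hr_ctv_pct) ||
      any(is.na(table$lr_ctv_pct)) || any(is.na(table$hr_ctv_pct))) {
    potd_stop("coverage table lacks LR-CTV/HR-CTV coverage for some plan",
              "potd_data_error")
  }
}

#' Target-coverage candidacy tier
#'
#' Plans meeting the optimal coverage criteria (inclusive thresholds) form
#' the candidate set; only if none do, plans meeting the mandatory criteria
#' are candidates. The HR-CTV requirement is identical in both tiers.
#'
#' @param table a `coverage_table`.
#' @param cfg a `qsop_config`.
#' @return list with `tier` (`"optimal_coverage"`, `"mandatory_coverage"`
#'   or `"none"`) and `candidates` (character vector of plan ids).
#' @export
candidate_tier <- function(table, cfg = qsop_config()) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    potd_stop("coverage table is empty", "potd_data_error")
  }
  need_targets(table)
  hr_ok <- table$hr_ctv_pct >= cfg$hr_required_pct
  opt <- table$plan_id[table$lr_ctv_pct >= cfg$lr_optimal_pct & hr_ok]
  if (length(opt) > 0L) {
    return(list(tier = "optimal_coverage", candidates = opt))
  }
  man <- table$plan_id[table$lr_ctv_pct >= cfg$lr_mandatory_pct & hr_ok]
  if (length(man) > 0L) {
    return(list(tier = "mandatory_coverage", candidates = man))
  }
  list(tier = "none", candidates = character(0))
}

# OAR comparison of a challenger against the minimum-bowel reference.
# Falls back to percentage points (with a warning) when the reference
# covers none of the organ and a relative change is undefined.
oar_delta <- function(pct, ref_pct, mode, organ) {
  if (mode == "percentage_points") return(pct - ref_pct)
  if (ref_pct == 0) {
    if (pct == 0) return(0)
    warning(sprintf(
      "reference plan covers no %s; comparing in percentage points instead",
      organ), call. = FALSE)
    return(pct - ref_pct)
  }
  100 * (pct - ref_pct) / ref_pct
}

#' Select the optimal plan among coverage candidates
#'
#' The default optimum is the candidate with the least bowel coverage
#' (ties broken by library order). A challenger displaces it when some
#' exception-ladder rung grants the trade (bowel increase strictly below
#' the rung's allowance, bladder sparing at least the rung's requirement)
#' and the increase does not exceed the overall cap; among qualifying
#' challengers the one with the greatest bladder sparing wins, ties again
#' by library order. A single candidate is returned directly, OARs
#' ignored.
#'
#' @param candidates character vector of candidate plan ids.
#' @param table a `coverage_table` containing them.
#' @param cfg a `qsop_config`.
#' @return the selected plan id.
#' @export
select_optimal <- function(candidates, table, cfg = qsop_config()) {
  if (length(candidates) == 0L) {
    potd_stop("select_optimal needs a nonempty candidate set", "potd_argument_error")
  }
  if (!all(candidates %in% table$plan_id)) {
    potd_stop("candidate not present in coverage table", "potd_data_error")
  }
  # preserve library order as given by the table
  candidates <- table$plan_id[table$plan_id %in% candidates]
  if (length(candidates) == 1L) return(candidates)
  sub <- table[match(candidates, table$plan_id), ]
  if (any(is.na(sub$bowel_pct)) || any(is.na(sub$bladder_pct))) {
    potd_stop("bowel/bladder coverage needed to choose among multiple candidates",
              "potd_data_error")
  }
  ref_i <- which.min(sub$bowel_pct)   # first minimum = library-order tie-break
  ref <- sub[ref_i, ]
  best <- ref$plan_id
  best_sparing <- -Inf
  for (i in seq_len(nrow(sub))) {
    if (i == ref_i) next
    ch <- sub[i, ]
    bowel_inc <- oar_delta(ch$bowel_pct, ref$bowel_pct, cfg$oar_diff_mode, "bowel")
    sparing <- -oar_delta(ch$bladder_pct, ref$bladder_pct, cfg$oar_diff_mode, "bladder")
    if (bowel_inc > cfg$bowel_increase_cap_pct) next
    granted <- any(vapply(cfg$exception_ladder, function(r) {
      bowel_inc < r$max_bowel_increase_pct &&
        sparing >= r$min_bladder_sparing_pct
    }, logical(1)))
    if (granted && sparing > best_sparing) {
      best <- ch$plan_id
      best_sparing <- sparing
    }
  }
  best
}

#' Assess a plan library against the qSOP
#'
#' Composes [candidate_tier()] and [select_optimal()]: the selected
#' candidate is `optimal`, remaining candidates are `acceptable`, all
#' other plans are `unacceptable`. When no plan reaches either coverage
#' tier every plan is unacceptable and an on-set intervention (bladder
#' filling, bowel emptying, or replanning) is flagged. Every threshold
#' comparison is recorded in the rationale.
#'
#' @param table a `coverage_table`.
#' @param cfg a `qsop_config`.
#' @return an object of class `plan_assessment`: a list with `plans`
#'   (data frame of plan_id/status/tier), `selected`, `tier`,
#'   `intervention_required`, `rationale` and `config`.
#' @export
assess <- function(table, cfg = qsop_config()) {
  tier <- candidate_tier(table, cfg)
  rat <- character(0)
  note <- function(...) rat[[length(rat) + 1L]] <<- sprintf(...)
  for (i in seq_len(nrow(table))) {
    r <- table[i, ]
    note("%s: LR-CTV %.2f%% %s %g%% (optimal) | %s %g%% (mandatory); HR-CTV %.2f%% %s %g%%",
         r$plan_id,
         r$lr_ctv_pct, ifelse(r$lr_ctv_pct >= cfg$lr_optimal_pct, ">=", "<"),
         cfg$lr_optimal_pct,
         ifelse(r$lr_ctv_pct >= cfg$lr_mandatory_pct, ">=", "<"),
         cfg$lr_mandatory_pct,
         r$hr_ctv_pct, ifelse(r$hr_ctv_pct >= cfg$hr_required_pct, ">=", "<"),
         cfg$hr_required_pct)
  }
  status <- setNames(rep("unacceptable", nrow(table)), table$plan_id)
  selected <- NA_character_
  if (tier$tier == "none") {
    note("no plan meets mandatory target coverage: intervention required")
  } else {
    note("tier: %s; candidates: %s", tier$tier,
         paste(tier$candidates, collapse = ", "))
    selected <- select_optimal(tier$candidates, table, cfg)
    status[tier$candidates] <- "acceptable"
    status[selected] <- "optimal"
    if (length(tier$candidates) > 1L) {
      sub <- table[match(tier$candidates, table$plan_id), ]
      ref_id <- sub$plan_id[which.min(sub$bowel_pct)]
      if (identical(selected, ref_id)) {
        note("selected %s: least bowel coverage among candidates", selected)
      } else {
        note("selected %s over minimum-bowel plan %s by bladder-sparing exception",
             selected, ref_id)
      }
    } else {
      note("selected %s: sole candidate", selected)
    }
  }
  structure(list(
    plans = data.frame(plan_id = table$plan_id,
                       status = unname(status[table$plan_id]),
                       tier = tier$tier,
                       stringsAsFactors = FALSE),
    selected = selected,
    tier = tier$tier,
    intervention_required = is.na(selected),
    rationale = rat,
    config = cfg
  ), class = "plan_assessment")
}

#' @export
print.plan_assessment <- function(x, ...) {
  cat("<plan_assessment>\n")
  for (i in seq_len(nrow(x$plans))) {
    mark <- if (identical(x$plans$plan_id[i], x$selected)) " <-- optimal" else ""
    cat(sprintf("  %-12s %s%s\n", x$plans$plan_id[i], x$plans$status[i], mark))
  }
  if (x$intervention_required) {
    cat("  ** no acceptable plan: intervention required **\n")
  }
  invisible(x)
}

#' Agreement of plan selections with an offline audit
#'
#' @param selections character vector of selected plan ids, one per case
#'   (`NA` allowed for cases with no selection).
#' @param reference_optimal list of character vectors: per case, the plan
#'   ids the audit deemed optimal.
#' @param reference_acceptable list of character vectors: per case, the
#'   audit's acceptable plans; must contain the optimal set.
#' @return list with `optimal_fraction`, `acceptable_fraction`, and
#'   `counts` (`n_optimal`, `n_acceptable`, `n_cases`).
#' @export
audit_agreement <- function(selections, reference_optimal, reference_acceptable) {
  n <- length(selections)
  if (length(reference_optimal) != n || length(reference_acceptable) != n) {
    potd_stop("selections and reference sets must have equal length",
              "potd_data_error")
  }
  for (i in seq_len(n)) {
    if (!all(reference_optimal[[i]] %in% reference_acceptable[[i]])) {
      potd_stop("reference optimal set must be contained in the acceptable set",
                "potd_data_error")
    }
  }
  hit <- function(sel, set) !is.na(sel) && length(set) > 0L && sel %in% set
  n_opt <- sum(vapply(seq_len(n), function(i)
    hit(selections[i], reference_optimal[[i]]), logical(1)))
  n_acc <- sum(vapply(seq_len(n), function(i)
    hit(selections[i], reference_acceptable[[i]]), logical(1)))
  list(optimal_fraction = n_opt / n,
       acceptable_fraction = n_acc / n,
       counts = list(n_optimal = n_opt, n_acceptable = n_acc, n_cases = n))
}
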