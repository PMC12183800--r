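make_fixture <- function() {
  tab <- as_coverage_table(data.frame(
    plan_id = c("PTV1", "PTV2", "PTV_Robust"),
    lr_ctv_pct = c(99.2, 100, 100), hr_ctv_pct = c(99.9, 100, 100),
    bladder_pct = c(30, 45, 50), rectum_pct = c(3, 4, 9),
    bowel_pct = c(4, 5, 9)))
  a <- assess(tab)
  d <- oar_differences(tab, a$selected)
  list(tab = tab, a = a, d = d)
}

test_that("every format marks exactly one optimal plan", {
  f <- make_fixture()
  txt <- render_report(f$a, f$tab, f$d, format = "text")
  expect_equal(lengths(regmatches(txt, gregexpr("<== OPTIMAL", txt))), 1L)
  js <- jsonlite::fromJSON(render_report(f$a, f$tab, f$d, format = "json"),
                           simplifyVector = FALSE)
  expect_equal(sum(vapply(js$plans, function(p) isTRUE(p$optimal), logical(1))), 1L)
  csv <- read.csv(text = render_report(f$a, f$tab, f$d, format = "csv"))
  expect_equal(sum(csv$optimal), 1L)
  expect_equal(csv$status, f$a$plans$status)
})

test_that("the intervention case carries an explicit banner", {
  tab <- as_coverage_table(data.frame(
    plan_id = c("A", "B"), lr_ctv_pct = c(90, 93), hr_ctv_pct = c(100, 100),
    bladder_pct = c(10, 10), bowel_pct = c(5, 5)))
  a <- assess(tab)
  txt <- render_report(a, tab, NULL, format = "text")
  expect_match(txt, "INTERVENTION REQUIRED")
  js <- jsonlite::fromJSON(render_report(a, tab, NULL, format = "json"),
                           simplifyVector = FALSE)
  expect_true(js$intervention_required)
  expect_null(js$selected)
})

test_that("JSON reports re-render byte-identically after parsing", {
  f <- make_fixture()
  js <- render_report(f$a, f$tab, f$d, format = "json")
  reparsed <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  js2 <- as.character(jsonlite::toJSON(reparsed, auto_unbox = TRUE,
                                       digits = NA, pretty = TRUE,
                                       null = "null"))
  expect_identical(js, js2)
})

test_that("mismatched plan ids are rejected", {
  f <- make_fixture()
  bad <- f$d
  bad$plan_id[1] <- "other"
  expect_error(render_report(f$a, f$tab, bad), class = "potd_data_error")
})

write_phantom_case <- function(dir, params = test_phantom_params(),
                               with_hr = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ss <- generate_phantom(params)
  lib <- test_library()
  roles <- names(ss$masks)
  if (!with_hr) roles <- setdiff(roles, "hr_ctv")
  paths <- setNames(sprintf("%s.nii.gz", roles), roles)
  for (r in roles) write_mask(ss$masks[[r]], file.path(dir, paths[[r]]))
  yaml::write_yaml(list(structures = as.list(paths)),
                   file.path(dir, "structures.yaml"))
  entries <- lapply(names(lib$plans), function(id) {
    f <- sprintf("%s.nii.gz", id)
    write_mask(lib$plans[[id]], file.path(dir, f))
    e <- list(id = id, path = f)
    if (identical(id, lib$robust_id)) e$robust <- TRUE
    e
  })
  yaml::write_yaml(list(plans = entries), file.path(dir, "plans.yaml"))
  list(structures = file.path(dir, "structures.yaml"),
       plans = file.path(dir, "plans.yaml"), set = ss)
}

test_that("manifest-driven assessment runs end to end and is deterministic", {
  dir <- file.path(tempdir(), "potd-e2e")
  case <- write_phantom_case(dir)
  rep1 <- suppressMessages(run_assessment(case$structures, case$plans))
  expect_s3_class(rep1, "assessment_report")
  cfg <- qsop_config()
  sel <- rep1$assessment$selected
  if (!is.na(sel)) {
    row <- rep1$table[rep1$table$plan_id == sel, ]
    expect_gte(row$hr_ctv_pct, cfg$hr_required_pct)
    expect_gte(row$lr_ctv_pct, cfg$lr_mandatory_pct)
  }
  # OAR differences are normalised to the least-bowel acceptable plan
  acc <- rep1$table$plan_id[rep1$assessment$plans$status != "unacceptable"]
  expect_true(rep1$diff_reference %in% acc)
  expect_equal(rep1$diffs$bowel_diff_pct[rep1$diffs$plan_id == rep1$diff_reference], 0)
  rep2 <- suppressMessages(run_assessment(case$structures, case$plans))
  expect_identical(render_report(rep1$assessment, rep1$table, rep1$diffs, "json"),
                   render_report(rep2$assessment, rep2$table, rep2$diffs, "json"))
  unlink(dir, recursive = TRUE)
})

test_that("a missing HR-CTV in provided mode is a data error", {
  dir <- file.path(tempdir(), "potd-nohr")
  case <- write_phantom_case(dir, with_hr = FALSE)
  expect_error(
    suppressMessages(run_assessment(case$structures, case$plans,
                                    hrctv_mode = "provided")),
    class = "potd_data_error")
  unlink(dir, recursive = TRUE)
})

test_that("propagate mode derives the daily HR-CTV from reference masks", {
  dir <- file.path(tempdir(), "potd-prop")
  case <- write_phantom_case(dir, with_hr = FALSE)
  ref <- test_phantom()
  ref_lr <- file.path(dir, "ref_lr.nii.gz")
  ref_hr <- file.path(dir, "ref_hr.nii.gz")
  write_mask(ref$masks$lr_ctv, ref_lr)
  write_mask(ref$masks$hr_ctv, ref_hr)
  rep <- suppressMessages(run_assessment(case$structures, case$plans,
                                         hrctv_mode = "propagate",
                                         reference_lr_ctv = ref_lr,
                                         reference_hr_ctv = ref_hr))
  expect_false(any(is.na(rep$table$hr_ctv_pct)))
  unlink(dir, recursive = TRUE)
})

test_that("a zero-error virtual audit agrees perfectly with itself", {
  res <- run_virtual_audit(3, error_dsc = 1.0, seed = 21)
  expect_equal(res$agreement$optimal_fraction, 1)
  expect_equal(res$agreement$acceptable_fraction, 1)
  expect_gte(res$agreement$acceptable_fraction, res$agreement$optimal_fraction)
  # determinism of the full audit
  res2 <- run_virtual_audit(3, error_dsc = 1.0, seed = 21)
  expect_identical(res$selections, res2$selections)
})
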