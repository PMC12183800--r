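ct <- function(...) {
  df <- data.frame(...)
  if (is.null(df$bladder_pct)) df$bladder_pct <- NA_real_
  if (is.null(df$bowel_pct)) df$bowel_pct <- NA_real_
  as_coverage_table(df)
}

test_that("candidacy tiers apply the inclusive coverage thresholds", {
  # coverage levels typically considered acceptable sit in the top tier
  t1 <- ct(plan_id = "A", lr_ctv_pct = 99.2, hr_ctv_pct = 99.9)
  expect_equal(candidate_tier(t1), list(tier = "optimal_coverage",
                                        candidates = "A"))
  # a 98.3% LR-CTV plan is excluded when a full-coverage plan exists
  t2 <- ct(plan_id = c("opt", "auto"), lr_ctv_pct = c(100, 98.3),
           hr_ctv_pct = c(100, 100))
  tier <- candidate_tier(t2)
  expect_equal(tier$tier, "optimal_coverage")
  expect_equal(tier$candidates, "opt")
  # mandatory tier only opens when the optimal tier is empty
  t3 <- ct(plan_id = c("A", "B"), lr_ctv_pct = c(96, 97),
           hr_ctv_pct = c(99.9, 99.8))
  expect_equal(candidate_tier(t3)$tier, "mandatory_coverage")
  expect_equal(candidate_tier(t3)$candidates, c("A", "B"))
  # thresholds are inclusive
  t4 <- ct(plan_id = "E", lr_ctv_pct = 99, hr_ctv_pct = 99.8)
  expect_equal(candidate_tier(t4)$tier, "optimal_coverage")
  # no plan reaches 95% LR-CTV
  t5 <- ct(plan_id = c("A", "B"), lr_ctv_pct = c(90, 94),
           hr_ctv_pct = c(100, 100))
  expect_equal(candidate_tier(t5), list(tier = "none",
                                        candidates = character(0)))
  # insufficient HR-CTV coverage blocks both tiers
  t6 <- ct(plan_id = "A", lr_ctv_pct = 100, hr_ctv_pct = 99.7)
  expect_equal(candidate_tier(t6)$tier, "none")
  expect_error(candidate_tier(ct(plan_id = "A", lr_ctv_pct = 99,
                                 hr_ctv_pct = NA)),
               class = "potd_data_error")
})

test_that("optimal selection trades bowel against bladder via the ladder", {
  base <- function(bowel_b, bladder_b) ct(
    plan_id = c("A", "B"), lr_ctv_pct = c(100, 100), hr_ctv_pct = c(100, 100),
    bowel_pct = c(10, bowel_b), bladder_pct = c(40, bladder_b))
  # +8% bowel for 25% bladder sparing: exception 1 grants the swap
  expect_equal(select_optimal(c("A", "B"), base(10.8, 30)), "B")
  # +8% bowel but only 10% sparing: no rung grants it
  expect_equal(select_optimal(c("A", "B"), base(10.8, 36)), "A")
  # +25% bowel for 90% sparing: the 20% cap binds
  expect_equal(select_optimal(c("A", "B"), base(12.5, 4)), "A")
  # boundary: exactly 20% sparing grants (inclusive), exactly 10% bowel does not
  expect_equal(select_optimal(c("A", "B"), base(10.9, 32)), "B")
  expect_equal(select_optimal(c("A", "B"), base(11.0, 30)), "A")
  # among several qualifying challengers the greatest sparing wins
  multi <- ct(plan_id = c("A", "B", "C"),
              lr_ctv_pct = c(100, 100, 100), hr_ctv_pct = c(100, 100, 100),
              bowel_pct = c(10, 10.5, 10.6), bladder_pct = c(40, 28, 20))
  expect_equal(select_optimal(c("A", "B", "C"), multi), "C")
  # single candidate returned directly even without OAR data
  solo <- ct(plan_id = c("A", "B"), lr_ctv_pct = c(100, 90),
             hr_ctv_pct = c(100, 100))
  expect_equal(select_optimal("A", solo), "A")
  # multiple candidates without OAR data is a data error
  expect_error(select_optimal(c("A", "B"),
                              ct(plan_id = c("A", "B"),
                                 lr_ctv_pct = c(100, 100),
                                 hr_ctv_pct = c(100, 100))),
               class = "potd_data_error")
})

test_that("assessment classifies the published failure cases as unacceptable", {
  # patient 09: automatic plan misses 1.7% of the LR-CTV while a
  # full-coverage plan exists
  p09 <- ct(plan_id = c("optimal", "auto"), lr_ctv_pct = c(100, 98.3),
            hr_ctv_pct = c(100, 100))
  a09 <- assess(p09)
  expect_equal(a09$plans$status[a09$plans$plan_id == "auto"], "unacceptable")
  expect_equal(a09$selected, "optimal")
  # patient 17 (fraction 3): HR-CTV coverage 99.64% fails the 99.8% rule
  # in any tier, with or without competing plans
  p17 <- ct(plan_id = c("optimal", "auto"), lr_ctv_pct = c(100, 99.51),
            hr_ctv_pct = c(100, 99.64))
  a17 <- assess(p17)
  expect_equal(a17$plans$status[a17$plans$plan_id == "auto"], "unacceptable")
  alone <- assess(ct(plan_id = "auto", lr_ctv_pct = 99.51, hr_ctv_pct = 99.64))
  expect_equal(alone$plans$status, "unacceptable")
  expect_true(alone$intervention_required)
})

test_that("assessment composes tiers, selection, and the intervention flag", {
  # all-equal plans: library order breaks the tie
  eq <- ct(plan_id = c("PTV1", "PTV2", "PTV3"),
           lr_ctv_pct = c(100, 100, 100), hr_ctv_pct = c(100, 100, 100),
           bowel_pct = c(5, 5, 5), bladder_pct = c(20, 20, 20))
  aeq <- assess(eq)
  expect_equal(aeq$selected, "PTV1")
  expect_equal(aeq$plans$status, c("optimal", "acceptable", "acceptable"))
  # empty tier: everything unacceptable, intervention flagged
  none <- assess(ct(plan_id = c("A", "B"), lr_ctv_pct = c(90, 92),
                    hr_ctv_pct = c(100, 100)))
  expect_true(none$intervention_required)
  expect_true(all(none$plans$status == "unacceptable"))
  expect_true(is.na(none$selected))
  expect_true(any(grepl("intervention", none$rationale)))
  # rationale records a comparison line per plan
  expect_gte(length(aeq$rationale), nrow(eq))
})

test_that("assessment is sound and agrees with the brute-force evaluator", {
  tables <- sample_coverage_tables(400, seed = 7)
  cfg <- qsop_config()
  for (tab in tables) {
    got <- assess(tab, cfg)
    want <- qsop_oracle(tab, cfg)
    expect_identical(got$selected, want$selected)
    expect_identical(got$plans$status, want$status)
    if (!is.na(got$selected)) {
      row <- tab[tab$plan_id == got$selected, ]
      expect_gte(row$hr_ctv_pct, cfg$hr_required_pct)
      expect_gte(row$lr_ctv_pct, cfg$lr_mandatory_pct)
      if (any(tab$lr_ctv_pct >= cfg$lr_optimal_pct &
              tab$hr_ctv_pct >= cfg$hr_required_pct)) {
        expect_gte(row$lr_ctv_pct, cfg$lr_optimal_pct)
      }
      # tier exclusivity: mandatory-only plans are never acceptable when
      # the optimal tier is occupied
      if (got$tier == "optimal_coverage") {
        mand_only <- tab$lr_ctv_pct < cfg$lr_optimal_pct
        expect_true(all(got$plans$status[mand_only] == "unacceptable"))
      }
    }
  }
})

test_that("selection is invariant to plan relabelling and reordering", {
  set.seed(31)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    tab <- as_coverage_table(data.frame(
      plan_id = paste0("P", 1:k),
      lr_ctv_pct = sample(c(96, 99, 99.5, 100), k, replace = TRUE),
      hr_ctv_pct = sample(c(99.8, 100), k, replace = TRUE),
      # distinct OAR values so no tie-break depends on order
      bladder_pct = sample(seq(20, 60, by = 1), k),
      bowel_pct = sample(seq(5, 25, by = 1), k)))
    a1 <- assess(tab)
    if (is.na(a1$selected)) next
    perm <- sample(k)
    tab2 <- tab[perm, ]
    tab2$plan_id <- paste0("Q", 1:k)
    a2 <- assess(as_coverage_table(tab2))
    r1 <- tab[tab$plan_id == a1$selected, -1]
    r2 <- tab2[tab2$plan_id == a2$selected, -1]
    rownames(r1) <- rownames(r2) <- NULL
    expect_equal(r1, r2)
  }
})

test_that("audit agreement reports matching fractions and counts", {
  sels <- c(rep("P1", 46), rep("P2", 14))
  opt <- replicate(60, "P1", simplify = FALSE)
  acc <- replicate(60, c("P1", "P2"), simplify = FALSE)
  a <- audit_agreement(sels, opt, acc)
  expect_equal(a$optimal_fraction, 46 / 60)
  expect_equal(a$counts$n_optimal, 46)
  expect_equal(a$acceptable_fraction, 1)
  perfect <- audit_agreement(c("A", "B"), list("A", "B"),
                             list(c("A", "Z"), "B"))
  expect_equal(perfect$optimal_fraction, 1)
  expect_equal(perfect$acceptable_fraction, 1)
  # an empty reference optimal set can never be matched
  e <- audit_agreement("A", list(character(0)), list("A"))
  expect_equal(e$optimal_fraction, 0)
  expect_equal(e$acceptable_fraction, 1)
  expect_error(audit_agreement("A", list("A"), list()),
               class = "potd_data_error")
  expect_error(audit_agreement("A", list(c("A", "B")), list("A")),
               class = "potd_data_error")
})

test_that("qSOP configuration validates its invariants and reads YAML", {
  expect_error(qsop_config(lr_optimal_pct = 90, lr_mandatory_pct = 95),
               class = "potd_argument_error")
  expect_error(qsop_config(exception_ladder = list(
    list(min_bladder_sparing_pct = 20, max_bowel_increase_pct = 30))),
    class = "potd_argument_error")
  path <- tempfile(fileext = ".yaml")
  writeLines(c("lr_optimal_pct: 98.5", "oar_diff_mode: percentage_points"), path)
  cfg <- read_qsop_config(path)
  expect_equal(cfg$lr_optimal_pct, 98.5)
  expect_equal(cfg$oar_diff_mode, "percentage_points")
  expect_equal(cfg$hr_required_pct, 99.8)    # default retained
  writeLines("unknown_key: 3", path)
  expect_error(read_qsop_config(path), class = "potd_data_error")
  unlink(path)
})
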