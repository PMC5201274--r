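test_that("composite scales score as the mean of 1-4 items", {
  expect_equal(score_scale(c(4, 4, 4, 4), "demands"), 4)
  expect_equal(score_scale(c(1, 1, 1, 1, 1), "support"), 1)
  expect_equal(score_scale(c(2, 3, 2, 3), "demands"), 2.5)
  # half-missing rule: 2 of 4 observed is allowed, 3 of 4 missing is not
  expect_equal(score_scale(c(2, NA, 4, NA), "demands"), 3)
  expect_true(is.na(score_scale(c(2, NA, NA, NA), "demands")))
  expect_error(score_scale(c(0, 2, 3, 4), "demands"), "coded 1-4")
  expect_error(score_scale(c(2, 3, 4), "demands"), "expected 4 items")
})

test_that("depressive sum spans 0-24 and propagates missingness", {
  expect_equal(score_scl_cd6(rep(0, 6)), 0)
  expect_equal(score_scl_cd6(rep(4, 6)), 24)
  expect_equal(score_scl_cd6(c(1, 2, 0, 3, 4, 2)), 12)
  expect_true(is.na(score_scl_cd6(c(1, 2, NA, 3, 4, 2))))
  prorate <- derivation_rules(scl_allow_missing = TRUE)
  expect_equal(score_scl_cd6(c(2, 2, NA, 2, 2, 2), prorate), 12)
  expect_error(score_scl_cd6(c(1, 2, 5, 3, 4, 2)), "coded 0-4")
})

test_that("smoking dichotomization distinguishes the two variants", {
  expect_identical(derive_smoking("sometimes", "daily"), 0L)
  expect_identical(derive_smoking("sometimes", "any"), 1L)
  expect_identical(derive_smoking("never", "any"), 0L)
  expect_identical(derive_smoking("daily", "daily"), 1L)
  expect_identical(derive_smoking(NA_character_, "daily"), NA_integer_)
  expect_error(derive_smoking("pipe", "daily"), "unknown smoking")
})

test_that("AUDIT rule applies sex-specific unit thresholds and binge", {
  expect_identical(derive_alcohol_audit("male", 21, FALSE), 1L)
  expect_identical(derive_alcohol_audit("male", 20, FALSE), 0L)
  expect_identical(derive_alcohol_audit("female", 14, FALSE), 1L)
  expect_identical(derive_alcohol_audit("female", 13, FALSE), 0L)
  expect_identical(derive_alcohol_audit("male", 0, TRUE), 1L)
  # a known-positive component decides despite the other missing
  expect_identical(derive_alcohol_audit("male", NA, TRUE), 1L)
  expect_identical(derive_alcohol_audit("female", 30, NA), 1L)
  expect_true(is.na(derive_alcohol_audit("male", 10, NA)))
  expect_error(derive_alcohol_audit("other", 10, FALSE), "unknown sex")
  expect_error(derive_alcohol_audit("male", -1, FALSE), "non-negative")
})

test_that("AUDIT rule is monotone in weekly units for each sex", {
  for (sex in c("male", "female")) {
    units <- 0:40
    flags <- derive_alcohol_audit(rep(sex, length(units)), units,
                                  rep(FALSE, length(units)))
    expect_true(all(diff(flags) >= 0))
  }
})

test_that("CAGE rule needs at least two endorsed items", {
  expect_identical(derive_alcohol_cage(c(1, 1, 0, 0)), 1L)
  expect_identical(derive_alcohol_cage(c(1, 0, 0, 0)), 0L)
  expect_identical(derive_alcohol_cage(c(1, 1, 1, 1)), 1L)
  expect_identical(derive_alcohol_cage(c(1, 1, NA, 0)), 1L)
  expect_true(is.na(derive_alcohol_cage(c(1, 0, NA, 0))))
  expect_error(derive_alcohol_cage(c(1, 1, 0)), "expected 4")
  expect_error(derive_alcohol_cage(c(2, 1, 0, 0)), "0/1")
})

test_that("diet and inactivity categories map to the documented groups", {
  expect_identical(derive_diet("a lot of fat, sugar or fast food"), 1L)
  expect_identical(derive_diet("varying/average diet"), 0L)
  expect_identical(derive_diet("special diet"), 0L)
  expect_error(derive_diet("keto"), "unknown diet")

  expect_identical(derive_inactivity("now and then", "main"), 0L)
  expect_identical(derive_inactivity("now and then", "irregular"), 1L)
  expect_identical(derive_inactivity("regularly", "irregular"), 0L)
  expect_identical(derive_inactivity("very little", "main"), 1L)
  expect_error(derive_inactivity("marathon", "main"), "unknown exercise")
})

test_that("behavior count is the sum of the four indicators", {
  expect_equal(count_unhealthy(c(0, 0, 0, 0)), 0)
  expect_equal(count_unhealthy(c(1, 1, 1, 1)), 4)
  expect_equal(count_unhealthy(c(1, 0, 1, 0)), 2)
  expect_true(is.na(count_unhealthy(c(1, NA, 0, 0))))
  expect_equal(count_unhealthy(c(1, NA, 0, 0), allow_missing = TRUE), 1)
  expect_error(count_unhealthy(c(2, 0, 0, 0)), "0/1")
  set.seed(11)
  m <- matrix(rbinom(400, 1, 0.3), 100, 4)
  expect_identical(count_unhealthy(m), rowSums(m))
})

test_that("raw items from the generator round-trip through derivation", {
  cfg <- sim_config(n_subjects = 400, seed = 31, emit_raw_items = TRUE,
                    crosslag = fix_crosslag())
  panel <- generate_panel(cfg)
  der <- derive_variables(panel)
  for (w in 1:4) {
    for (b in c("smoking", "alcohol", "diet", "inactivity")) {
      expect_identical(der[[paste0(b, "_", w)]],
                       panel[[paste0(b, "_", w)]],
                       info = paste(b, "wave", w))
    }
    expect_equal(
      der[[paste0("unhealthy_count_", w)]],
      rowSums(panel[, paste0(c("smoking", "alcohol", "diet",
                               "inactivity"), "_", w)])
    )
  }
})

test_that("per-wave instrument switch selects AUDIT then CAGE", {
  rules <- derivation_rules()
  expect_identical(rules$alcohol_instrument, c("audit", "audit",
                                               "cage", "cage"))
  cfg <- sim_config(n_subjects = 200, seed = 8, emit_raw_items = TRUE)
  panel <- generate_panel(cfg)
  # waves 1-2 carry AUDIT items, waves 3-4 CAGE items
  expect_true(all(c("alc_units_1", "alc_binge_2", "cage1_3",
                    "cage4_4") %in% names(panel)))
  expect_false("alc_units_3" %in% names(panel))
  expect_false("cage1_1" %in% names(panel))
})

test_that("rules serialize to YAML and back", {
  rules <- derivation_rules(cage_min_positive = 3)
  path <- tempfile(fileext = ".yaml")
  write_rules(rules, path)
  back <- yaml::read_yaml(path)
  expect_equal(back$cage_min_positive, 3)
  expect_equal(back$audit_units_male, 21)
  unlink(path)
})

test_that("disjointness of diet lists is enforced", {
  expect_error(
    derivation_rules(diet_unhealthy = "special diet"),
    "disjoint"
  )
})
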